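make_catalog <- function(seqs) {
  out <- data.frame(id = paste0("g", seq_along(seqs)), sequence = seqs,
                    length = nchar(seqs), stringsAsFactors = FALSE)
  class(out) <- c("gene_catalog", "data.frame")
  out
}

rand_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

as_read_set <- function(seqs) {
  out <- data.frame(read_id = sprintf("r%d", seq_along(seqs)),
                    sequence = seqs, stringsAsFactors = FALSE)
  class(out) <- c("read_set", "data.frame")
  out
}

test_that("mapper finds exact substrings, honours the identity floor,
           and keeps ties as shared hits", {
  g1 <- rand_seq(500, 1); g2 <- rand_seq(500, 2)
  catalog <- make_catalog(c(g1, g2))
  read <- substr(g1, 101, 250)
  mp <- map_reads(as_read_set(read), catalog)
  expect_identical(mp$hits[[1]], 1L)

  # 10 substitutions over 150 nt = identity 0.933 < 0.95: unmapped even
  # though a clean seed exists (positions 62..92 untouched)
  bad <- read
  for (p in c(1, 15, 29, 43, 57, 100, 110, 120, 130, 140)) {
    old <- substr(bad, p, p)
    substr(bad, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  mp2 <- map_reads(as_read_set(bad), catalog)
  expect_length(mp2$hits[[1]], 0)

  # exact substring of two identical genes: a shared read
  catalog3 <- make_catalog(c(g1, g1, g2))
  mp3 <- map_reads(as_read_set(read), catalog3)
  expect_identical(sort(mp3$hits[[1]]), c(1L, 2L))

  # reverse-complement reads still map
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  mp4 <- map_reads(as_read_set(rc), catalog)
  expect_identical(mp4$hits[[1]], 1L)

  expect_error(map_reads(as_read_set(read), make_catalog(g1)[0, ]),
               "empty")
})

test_that("smart shared counting follows the two-step attribution rule", {
  # r1->g1, r2->g1, r3->g2, r4->{g1,g2}
  mp <- make_mapping(list(1, 1, 2, c(1, 2)), c("g1", "g2"))
  tab <- smart_shared_count(mp, "s1")
  expect_equal(unname(tab["s1", ]), c(2 + 2 / 3, 1 + 1 / 3),
               tolerance = 1e-12)
  expect_equal(sum(tab), 4, tolerance = 1e-9)
  expect_equal(unname(attr(tab, "mapped_totals")), 4)

  # all reads unique: counts are plain tallies
  mp2 <- make_mapping(list(1, 2, 2, 2), c("g1", "g2"))
  expect_equal(unname(smart_shared_count(mp2)["sample_1", ]), c(1, 3))

  # shared read with all-zero unique counts: equal split
  mp3 <- make_mapping(list(c(1, 2)), c("g1", "g2"))
  expect_equal(unname(smart_shared_count(mp3)[1, ]), c(0.5, 0.5))

  # unmapped reads don't count
  mp4 <- make_mapping(list(1, integer(0)), c("g1", "g2"))
  expect_equal(unname(attr(smart_shared_count(mp4), "mapped_totals")), 1)
})

test_that("smart shared counting matches the brute-force oracle on random
           instances and conserves reads", {
  set.seed(31)
  for (i in 1:200) {
    n_genes <- sample(2:5, 1)
    n_reads <- sample(1:25, 1)
    hits <- lapply(seq_len(n_reads), function(.)
      sort(sample(n_genes, sample(1:min(3, n_genes), 1))))
    tab <- smart_shared_count(make_mapping(hits, paste0("g", 1:n_genes)))
    expect_equal(unname(tab[1, ]), brute_shared_count(hits, n_genes),
                 tolerance = 1e-12)
    expect_equal(sum(tab), n_reads, tolerance = 1e-9)
  }
})

test_that("downsizing subsamples to depth, averages reps, and excludes
           shallow samples loudly", {
  tab <- one_sample_table(c(g1 = 2, g2 = 1))
  # depth equal to the total leaves counts unchanged
  full <- downsize_counts(tab, 3, n_reps = 5, seed = 1)
  expect_equal(unname(full[1, ]), c(2, 1))
  # enumeration oracle: subsets of size 2 of {g1,g1,g2} give E[g1]=4/3
  ds <- downsize_counts(tab, 2, n_reps = 4000, seed = 2)
  expect_lt(abs(ds[1, "g1"] - 4 / 3), 0.03)
  expect_lt(abs(ds[1, "g2"] - 2 / 3), 0.03)
  expect_equal(sum(ds), 2, tolerance = 1e-9)

  two <- gene_count_table(rbind(s1 = c(5, 5), s2 = c(1, 1)), "raw",
                          c(s1 = 10, s2 = 2))
  colnames(two) <- c("g1", "g2")
  d2 <- downsize_counts(two, 4, n_reps = 3, seed = 3)
  expect_identical(rownames(d2), "s1")
  exc <- attr(d2, "exclusions")
  expect_equal(exc$sample, "s2")
  expect_match(exc$reason, "below depth")
})

test_that("rarefaction richness matches detection counts and the
           enumeration oracle", {
  tab <- one_sample_table(c(g1 = 5, g2 = 1, g3 = 0))
  expect_equal(as.numeric(compute_gene_richness(tab, 6, n_reps = 3,
                                                seed = 1)), 2)
  # {g1:2, g2:1} at depth 2: expected richness 5/3
  t2 <- one_sample_table(c(g1 = 2, g2 = 1))
  r <- compute_gene_richness(t2, 2, n_reps = 4000, seed = 2)
  mom <- enum_richness_moments(c(2, 1), 2)
  expect_equal(mom$mean, 5 / 3, tolerance = 1e-12)
  expect_lt(abs(unname(r) - mom$mean), 3 * sqrt(mom$var / 4000))
})

test_that("expected richness is non-decreasing in rarefaction depth", {
  counts <- c(3, 2, 1)
  means <- vapply(1:6, function(d)
    enum_richness_moments(counts, d)$mean, numeric(1))
  expect_true(all(diff(means) >= -1e-12))
  # and the Monte-Carlo estimator tracks the enumeration at each depth
  t3 <- one_sample_table(setNames(counts, c("a", "b", "c")))
  for (d in c(2, 4)) {
    mom <- enum_richness_moments(counts, d)
    r <- compute_gene_richness(t3, d, n_reps = 2000, seed = d)
    expect_lt(abs(unname(r) - mom$mean), 3 * sqrt(mom$var / 2000))
  }
})

test_that("FPKM normalization has the right units and equivariance", {
  catalog <- data.frame(id = c("g1", "g2"), sequence = "",
                        length = c(1000, 500))
  tab <- gene_count_table(
    matrix(c(10, 5), 1, dimnames = list("s1", c("g1", "g2"))),
    "downsized", c(s1 = 1e6))
  f <- fpkm_normalize(tab, catalog)
  expect_equal(unname(f[1, ]), c(10, 10))

  tab2 <- gene_count_table(
    matrix(c(5, 0), 1, dimnames = list("s1", c("g2", "g1"))),
    "downsized", c(s1 = 2e6))
  f2 <- fpkm_normalize(tab2, catalog)
  expect_equal(unname(f2[1, ]), c(5, 0))

  # scaling counts and totals by c leaves FPKM unchanged
  tab3 <- gene_count_table(unclass(tab) * 7, "downsized", c(s1 = 7e6))
  expect_equal(unclass(fpkm_normalize(tab3, catalog)), unclass(f),
               ignore_attr = TRUE)

  bad <- gene_count_table(
    matrix(1, 1, dimnames = list("s1", "missing_gene")), "downsized",
    c(s1 = 1e6))
  expect_error(fpkm_normalize(bad, catalog), "missing_gene")
})

test_that("gene-count classification uses a strict lower boundary", {
  expect_equal(classify_gene_count(606999, 607000), "low")
  expect_equal(classify_gene_count(607000, 607000), "high")
  expect_equal(classify_gene_count(0, 607000), "low")
  expect_error(classify_gene_count(-1, 607000), "non-negative")
})

test_that("the bimodal richness threshold lands between the modes", {
  set.seed(8)
  rich <- c(exp(rnorm(150, log(2e5), 0.12)), exp(rnorm(150, log(7e5), 0.12)))
  thr <- richness_threshold_gmm(rich)
  expect_gt(thr, 2.6e5)
  expect_lt(thr, 6e5)
})
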