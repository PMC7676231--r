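fpkm_fixture <- function(mat) {
  gene_count_table(mat, "fpkm", setNames(rep(1e4, nrow(mat)),
                                         rownames(mat)))
}

mgs_fixture <- function(gene_ids, genus = "Bacteroides", id = "mgs_001") {
  list(list(mgs_id = id, genes = gene_ids, markers = gene_ids,
            genus = genus))
}

test_that("MGS abundance applies the strict >10% marker detection rule", {
  genes <- paste0("g", 1:50)
  m <- matrix(0, 3, 50, dimnames = list(c("s6", "s5", "sall"), genes))
  m["s6", 1:6] <- 1      # 12% detected
  m["s5", 1:5] <- 1      # exactly 10%: not detected
  m["sall", ] <- 2
  ab <- compute_mgs_abundance(fpkm_fixture(m), mgs_fixture(genes))
  expect_equal(unname(ab[, 1]), c(6 / 50, 0, 2))

  missing <- mgs_fixture(c(genes[-1], "absent"))
  expect_error(compute_mgs_abundance(fpkm_fixture(m), missing), "absent")
})

test_that("genus collapse is additive and scale-invariant", {
  defs <- list(
    list(mgs_id = "m1", genes = "a", markers = "a", genus = "Bacteroides"),
    list(mgs_id = "m2", genes = "b", markers = "b", genus = "Bacteroides"),
    list(mgs_id = "m3", genes = "c", markers = "c", genus = "Prevotella"))
  mgs <- matrix(c(0.2, 0.3, 0.5), 1,
                dimnames = list("s1", c("m1", "m2", "m3")))
  g <- collapse_to_genus(mgs, defs, pseudo_total = 1e4)
  expect_equal(unname(g["s1", ]), c(5000, 5000))
  expect_equal(sum(g), 1e4)

  doubled <- collapse_to_genus(mgs * 2, defs, pseudo_total = 1e4)
  expect_identical(g, doubled)

  one_genus <- collapse_to_genus(
    matrix(0.4, 1, dimnames = list("s1", "m1")), defs[1])
  expect_equal(unname(one_genus[1, 1]), 1e4)
})

test_that("DM log-density matches closed forms and limits", {
  # single category: only one outcome, log-probability 0
  m1 <- list(K = 1L, alpha = matrix(2.5, 1, 1), pi = 1)
  cnts <- matrix(c(0, 3, 17), 3, 1)
  expect_equal(dmm_loglik(cnts, m1), 0, tolerance = 1e-12)

  # K=1, alpha=(1,1), x=(1,1): coefficient-free DM probability 1/6
  m2 <- list(K = 1L, alpha = matrix(c(1, 1), 1, 2), pi = 1)
  expect_equal(dmm_loglik(matrix(c(1, 1), 1, 2), m2), log(1 / 6),
               tolerance = 1e-12)

  # large-alpha limit approaches the coefficient-free multinomial
  p <- c(0.2, 0.3, 0.5)
  x <- matrix(c(4, 6, 10), 1, 3)
  mBig <- list(K = 1L, alpha = matrix(p * 1e7, 1, 3), pi = 1)
  expect_equal(dmm_loglik(x, mBig), sum(x * log(p)), tolerance = 1e-3)

  expect_error(dmm_loglik(x, list(K = 1L, alpha = matrix(c(-1, 1, 1), 1, 3),
                                  pi = 1)), "positive")
})

planted_dmm_counts <- function(n = 120, J = 10, N = 400, seed = 5) {
  set.seed(seed)
  a1 <- c(rep(8, J / 2), rep(0.2, J / 2))
  a2 <- c(rep(0.2, J / 2), rep(8, J / 2))
  lab <- rep(1:2, each = n / 2)
  cnt <- t(sapply(lab, function(k) {
    a <- if (k == 1) a1 else a2
    g <- rgamma(J, a); p <- g / sum(g)
    rmultinom(1, N, p)[, 1]
  }))
  colnames(cnt) <- paste0("genus", seq_len(J))
  list(counts = cnt, labels = lab)
}

test_that("EM fits recover planted mixtures with monotone likelihood", {
  pd <- planted_dmm_counts()
  m1 <- fit_dmm(pd$counts, 1, seed = 2)
  expect_true(all(m1$responsibilities == 1))
  m2 <- fit_dmm(pd$counts, 2, seed = 2)
  expect_gte(m2$loglik, m1$loglik)
  expect_true(all(diff(m1$loglik_trace) > -1e-8))
  expect_true(all(diff(m2$loglik_trace) > -1e-8))
  expect_equal(unname(rowSums(m2$responsibilities)),
               rep(1, nrow(pd$counts)), tolerance = 1e-9)
  expect_equal(sum(m2$pi), 1, tolerance = 1e-9)
  lab <- max.col(m2$responsibilities)
  expect_gte(mclust::adjustedRandIndex(lab, pd$labels), 0.95)

  expect_error(fit_dmm(pd$counts[0, , drop = FALSE], 1), "empty")
})

test_that("the mixture likelihood is invariant to component relabeling", {
  pd <- planted_dmm_counts(n = 60, seed = 11)
  m <- fit_dmm(pd$counts, 2, seed = 3)
  ll <- dmm_loglik(pd$counts, m)
  swapped <- m
  swapped$alpha <- m$alpha[2:1, ]
  swapped$pi <- m$pi[2:1]
  expect_equal(dmm_loglik(pd$counts, swapped), ll, tolerance = 1e-9)
})

test_that("BIC selection finds the planted component count", {
  pd <- planted_dmm_counts(n = 150, seed = 21)
  sel <- select_n_components(pd$counts, 1:3, seed = 4, n_init = 2)
  expect_equal(sel$K, 2)

  # homogeneous single-Dirichlet data prefers K = 1
  set.seed(33)
  hom <- t(sapply(1:120, function(i) {
    g <- rgamma(8, 3); p <- g / sum(g); rmultinom(1, 300, p)[, 1]
  }))
  colnames(hom) <- paste0("genus", 1:8)
  sel1 <- select_n_components(hom, 1:3, seed = 5, n_init = 2)
  expect_equal(sel1$K, 1)

  expect_equal(select_n_components(pd$counts, 2, seed = 6,
                                   n_init = 1)$K, 2)
})

test_that("enterotype assignment labels, descriptors and the
           Bacteroides-2 analog are correct", {
  counts <- matrix(c(9, 1, 1, 9, 8, 2, 2, 8), 4, 2, byrow = TRUE,
                   dimnames = list(paste0("s", 1:4),
                                   c("Bacteroides", "Prevotella")))
  model <- list(K = 2L,
                alpha = matrix(c(6, 1, 1, 6), 2, 2, byrow = TRUE,
                               dimnames = list(NULL, colnames(counts))),
                pi = c(0.5, 0.5),
                responsibilities = matrix(c(0.9, 0.1, 0.2, 0.8,
                                            0.7, 0.3, 0.4, 0.6),
                                          4, 2, byrow = TRUE))
  rich <- setNames(c(100, 900, 120, 880), rownames(counts))
  a <- assign_enterotypes(model, counts, richness = rich)
  expect_equal(unname(a$labels), c(1, 2, 1, 2))
  expect_equal(a$components$dominant_genus, c("Bacteroides", "Prevotella"))
  # only component 1 is Bacteroides-dominant; it is the (sole) analog
  expect_equal(a$bacteroides2, 1L)

  # two Bacteroides-dominant components: the lower-richness one is tagged
  model2 <- model
  model2$alpha <- matrix(c(6, 1, 8, 2), 2, 2, byrow = TRUE,
                         dimnames = list(NULL, colnames(counts)))
  a2 <- assign_enterotypes(model2, counts, richness = rich)
  expect_equal(a2$components$dominant_genus[2], "Bacteroides")
  expect_equal(a2$bacteroides2, 1L)  # mean richness 110 < 890
})
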