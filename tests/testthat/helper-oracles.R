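# Independent oracles and fixture builders used across tests.

# wrap a list of per-read candidate gene-index vectors as a read_mapping
make_mapping <- function(hits, gene_ids) {
  structure(list(hits = lapply(hits, as.integer),
                 read_ids = sprintf("r%d", seq_along(hits)),
                 gene_ids = gene_ids),
            class = "read_mapping")
}

# naive re-statement of two-step shared counting, written independently
# of the package implementation: tally unique reads per gene, then walk
# shared reads one by one splitting by the unique tallies
brute_shared_count <- function(hits, n_genes) {
  unique_tally <- rep(0, n_genes)
  for (h in hits) if (length(h) == 1) {
    unique_tally[h] <- unique_tally[h] + 1
  }
  total <- unique_tally
  for (h in hits) if (length(h) > 1) {
    d <- unique_tally[h]
    w <- if (sum(d) > 0) d / sum(d) else rep(1 / length(h), length(h))
    total[h] <- total[h] + w
  }
  total
}

# exact rarefaction moments by explicit enumeration of all read subsets
# of size `depth` (instances with at most ~6 reads only)
enum_richness_moments <- function(counts, depth) {
  pool <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(pool), depth)
  vals <- apply(subs, 2, function(ix) length(unique(pool[ix])))
  list(mean = mean(vals), var = stats::var(vals) *
         (length(vals) - 1) / length(vals))
}

# 1-row raw gene_count_table from a named count vector
one_sample_table <- function(counts, sample = "s1") {
  m <- matrix(counts, 1, dimnames = list(sample, names(counts) %||%
                                           paste0("g", seq_along(counts))))
  gene_count_table(m, "raw", setNames(sum(counts), sample))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal hand-built world exposing just what simulate_reads needs
tiny_world <- function(abund, lengths, read_depth = 1000, error_rate = 0,
                       seed = 7) {
  n_genes <- length(abund)
  set.seed(41)
  seqs <- vapply(lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  catalog <- data.frame(id = paste0("g", seq_len(n_genes)), sequence = seqs,
                        length = lengths, stringsAsFactors = FALSE)
  class(catalog) <- c("gene_catalog", "data.frame")
  cfg <- synthetic_world_config(n_subjects = 1, read_depth = read_depth,
                                error_rate = error_rate, seed = seed)
  w <- list(config = cfg, catalog = catalog,
            gene_abundance = matrix(abund, 1,
                                    dimnames = list("s1", catalog$id)),
            truth = data.frame(subject_id = "s1", true_urda_share = 0,
                               false_urda_share = 0,
                               true_urda_ref = NA, false_urda_ref = NA,
                               stringsAsFactors = FALSE),
            urda_refs = data.frame(id = character(0)))
  class(w) <- "synthetic_world"
  w
}
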