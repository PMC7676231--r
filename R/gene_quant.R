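#' Gene quantification configuration
#'
#' @param min_identity minimum alignment identity for a read to be
#'   retained (default 0.95)
#' @param downsize_depth common read depth samples are downsized to
#'   before normalization (default 1e4 at synthetic desk scale; cohort
#'   practice uses 1e7)
#' @param n_rarefactions independent rarefaction repetitions averaged for
#'   gene richness (default 10)
#' @param richness_threshold genes separating low from high gene count;
#'   `NULL` means estimate it with [richness_threshold_gmm()]
#' @param kmer seed k-mer length of the mapper (default 31)
#' @param seed integer seed for downsizing/rarefaction draws
#' @return list of class `gene_quant_config`
#' @export
gene_quant_config <- function(min_identity = 0.95, downsize_depth = 1e4,
                              n_rarefactions = 10,
                              richness_threshold = NULL,
                              kmer = 31L, seed = 1L) {
  if (min_identity <= 0 || min_identity > 1)
    stop_invalid("min_identity must be in (0, 1]")
  if (n_rarefactions < 1) stop_invalid("n_rarefactions must be >= 1")
  structure(as.list(environment()), class = "gene_quant_config")
}

#' Map reads to a gene catalog
#'
#' Desk-scale mapper: exact k-mer seeding (default k = 31) with ungapped
#' extension over the full overlapping span, on both strands. For each
#' read, every alignment attaining the best score (matching bases) with
#' identity >= `min_identity` is kept; ties are retained as shared hits
#' and feed the shared-counting step. Reads with no qualifying hit are
#' unmapped.
#'
#' @param reads a `read_set`
#' @param catalog a `gene_catalog`
#' @param config a `gene_quant_config`
#' @return object of class `read_mapping`: list with `hits` (per read,
#'   integer indices into the catalog; empty = unmapped), `read_ids`,
#'   `gene_ids`
#' @export
map_reads <- function(reads, catalog, config = gene_quant_config()) {
  if (inherits(catalog, "map_index")) {
    hits <- cpp_map_reads_indexed(catalog$ptr, reads$sequence,
                                  config$min_identity, TRUE)
    gene_ids <- catalog$gene_ids
  } else {
    if (nrow(catalog) == 0) stop_invalid("catalog is empty")
    hits <- cpp_map_reads(reads$sequence, catalog$sequence,
                          as.integer(config$kmer), config$min_identity,
                          TRUE)
    gene_ids <- catalog$id
  }
  structure(list(hits = hits, read_ids = reads$read_id,
                 gene_ids = gene_ids),
            class = "read_mapping")
}

#' Prebuild a reusable k-mer index over a catalog
#'
#' Indexing a large catalog dominates mapping cost; build it once and
#' pass the returned object to [map_reads()] in place of the catalog
#' when mapping many samples. The index is an in-memory handle and is
#' not serializable.
#'
#' @param catalog a `gene_catalog`
#' @param kmer seed length (must match the mapping configuration)
#' @return object of class `map_index`
#' @export
build_map_index <- function(catalog, kmer = 31L) {
  structure(list(ptr = cpp_build_index(catalog$sequence,
                                       as.integer(kmer)),
                 gene_ids = catalog$id, kmer = as.integer(kmer)),
            class = "map_index")
}

# per-sample smart shared counting on a list of per-read candidate sets
count_one_sample <- function(hits, n_genes) {
  nh <- lengths(hits)
  u_idx <- unlist(hits[nh == 1L], use.names = FALSE)
  if (is.null(u_idx)) u_idx <- integer(0)
  uniq <- as.numeric(tabulate(u_idx, n_genes))
  counts <- uniq
  for (cand in hits[nh > 1L]) {
    u <- uniq[cand]  # split by unique counts only; splits never re-enter
    s <- sum(u)
    counts[cand] <- counts[cand] + if (s > 0) u / s else 1 / length(cand)
  }
  list(counts = counts, mapped = sum(nh > 0L))
}

#' Smart shared counting of mapped reads
#'
#' Two-step attribution. Step 1: each uniquely-mapping read adds 1 to its
#' gene. Step 2: each shared read is split across its candidate genes
#' proportionally to the genes' step-1 unique counts; when all candidates
#' have zero unique counts the read is split equally (a symmetric,
#' conservation-preserving choice). Per-sample counts therefore sum to
#' the number of mapped reads.
#'
#' @param mappings a single `read_mapping` or a named list of them (one
#'   per sample)
#' @param sample_ids sample names; defaults to the names of `mappings`
#' @return a `gene_count_table` (stage "raw") with attribute
#'   `mapped_totals`
#' @export
smart_shared_count <- function(mappings, sample_ids = NULL) {
  if (inherits(mappings, "read_mapping")) mappings <- list(mappings)
  if (is.null(sample_ids))
    sample_ids <- names(mappings) %||% sprintf("sample_%d",
                                               seq_along(mappings))
  gene_ids <- mappings[[1]]$gene_ids
  mat <- matrix(0, length(mappings), length(gene_ids),
                dimnames = list(sample_ids, gene_ids))
  mapped <- numeric(length(mappings))
  for (i in seq_along(mappings)) {
    cs <- count_one_sample(mappings[[i]]$hits, length(gene_ids))
    mat[i, ] <- cs$counts
    mapped[i] <- cs$mapped
  }
  gene_count_table(mat, "raw", setNames(mapped, sample_ids))
}

#' Construct a gene count table
#' @param mat samples x genes numeric matrix
#' @param stage one of "raw", "downsized", "fpkm"
#' @param mapped_totals per-sample mapped-read totals
#' @return matrix of class `gene_count_table`
#' @export
gene_count_table <- function(mat, stage, mapped_totals) {
  stopifnot(stage %in% c("raw", "downsized", "fpkm"), all(mat >= 0))
  structure(mat, stage = stage, mapped_totals = mapped_totals,
            class = c("gene_count_table", class(mat)))
}

# subsample integer per-gene read counts to `depth` reads without
# replacement, `n_reps` times; returns reps x genes matrix of counts
rarefy_reps <- function(int_counts, depth, n_reps) {
  n_genes <- length(int_counts)
  total <- sum(int_counts)
  pool <- rep.int(seq_len(n_genes), int_counts)
  out <- matrix(0L, n_reps, n_genes)
  for (r in seq_len(n_reps)) {
    take <- if (depth >= total) pool else pool[sample.int(total, depth)]
    out[r, ] <- tabulate(take, n_genes)
  }
  out
}

# one pass shared by the pipeline: downsized means and rarefaction
# richness from the same repetitions
downsize_and_richness <- function(table, depth, n_reps, seed) {
  stopifnot(attr(table, "stage") == "raw")
  set.seed(seed)
  keep <- character(0); drop <- character(0); drop_total <- numeric(0)
  rows <- list(); rich <- numeric(0)
  for (s in rownames(table)) {
    ints <- round_preserve_sum(table[s, ])
    if (sum(ints) < depth) {
      drop <- c(drop, s); drop_total <- c(drop_total, sum(ints))
      next
    }
    reps <- rarefy_reps(ints, depth, n_reps)
    rows[[s]] <- colMeans(reps)
    rich[s] <- mean(rowSums(reps > 0))
    keep <- c(keep, s)
  }
  if (!length(keep)) stop_invalid("no sample reaches depth ", depth)
  mat <- do.call(rbind, rows)
  dimnames(mat) <- list(keep, colnames(table))
  out <- gene_count_table(mat, "downsized",
                          setNames(rep(depth, length(keep)), keep))
  exc <- data.frame(
    sample = drop, mapped_total = drop_total,
    reason = if (length(drop)) sprintf("mapped total below depth %g", depth)
             else character(0),
    stringsAsFactors = FALSE)
  attr(out, "exclusions") <- exc
  attr(rich, "exclusions") <- exc
  list(downsized = out, richness = rich)
}

#' Downsize a raw count table to a common read depth
#'
#' Reads are subsampled without replacement to exactly `depth` per
#' sample, averaged over `n_reps` repetitions. Fractional smart-shared
#' counts are first rounded to integer read assignments
#' (largest-remainder, preserving the mapped total), since subsampling
#' reads is only defined on reads. Samples with fewer mapped reads than
#' `depth` are excluded and reported in the `exclusions` attribute, never
#' silently kept.
#'
#' @param table a raw `gene_count_table`
#' @param depth target depth (reads)
#' @param n_reps repetitions averaged
#' @param seed integer seed
#' @return a `gene_count_table` (stage "downsized"); attribute
#'   `exclusions` is a data.frame of dropped samples with reasons
#' @export
downsize_counts <- function(table, depth, n_reps = 10, seed = 1L) {
  stopifnot(attr(table, "stage") == "raw")
  set.seed(seed)
  keep <- character(0); drop <- character(0); drop_total <- numeric(0)
  rows <- list()
  for (s in rownames(table)) {
    ints <- round_preserve_sum(table[s, ])
    if (sum(ints) < depth) {
      drop <- c(drop, s); drop_total <- c(drop_total, sum(ints))
      next
    }
    rows[[s]] <- colMeans(rarefy_reps(ints, depth, n_reps))
    keep <- c(keep, s)
  }
  if (!length(keep)) stop_invalid("no sample reaches depth ", depth)
  mat <- do.call(rbind, rows)
  dimnames(mat) <- list(keep, colnames(table))
  out <- gene_count_table(mat, "downsized",
                          setNames(rep(depth, length(keep)), keep))
  attr(out, "exclusions") <- data.frame(
    sample = drop, mapped_total = drop_total,
    reason = if (length(drop)) sprintf("mapped total below depth %g", depth)
             else character(0),
    stringsAsFactors = FALSE)
  out
}

#' Rarefaction-based gene richness
#'
#' Per sample, the number of genes detected at least once at a fixed
#' rarefaction depth, averaged over `n_reps` independent rarefaction
#' experiments (default 10). Samples below the depth are excluded and
#' reported, as in [downsize_counts()].
#'
#' @inheritParams downsize_counts
#' @return named numeric vector of mean richness; attribute `exclusions`
#'   as in [downsize_counts()]
#' @export
compute_gene_richness <- function(table, depth, n_reps = 10, seed = 1L) {
  stopifnot(attr(table, "stage") == "raw")
  set.seed(seed)
  rich <- numeric(0); drop <- character(0); drop_total <- numeric(0)
  for (s in rownames(table)) {
    ints <- round_preserve_sum(table[s, ])
    if (sum(ints) < depth) {
      drop <- c(drop, s); drop_total <- c(drop_total, sum(ints))
      next
    }
    reps <- rarefy_reps(ints, depth, n_reps)
    rich[s] <- mean(rowSums(reps > 0))
  }
  attr(rich, "exclusions") <- data.frame(
    sample = drop, mapped_total = drop_total,
    reason = if (length(drop)) sprintf("mapped total below depth %g", depth)
             else character(0),
    stringsAsFactors = FALSE)
  rich
}

#' FPKM normalization of a count table
#'
#' Fragments per kilobase of gene per million mapped reads:
#' `count / (length / 1e3) / (mapped_total / 1e6)`.
#'
#' @param table a `gene_count_table` (typically stage "downsized")
#' @param catalog a `gene_catalog` supplying gene lengths
#' @return a `gene_count_table` (stage "fpkm")
#' @export
fpkm_normalize <- function(table, catalog) {
  lens <- catalog$length[match(colnames(table), catalog$id)]
  if (anyNA(lens))
    stop_invalid("gene(s) missing from catalog: ",
                 paste(head(colnames(table)[is.na(lens)], 5),
                       collapse = ", "))
  totals <- attr(table, "mapped_totals")[rownames(table)]
  mat <- sweep(unclass(table), 2, lens / 1e3, "/")
  mat <- sweep(mat, 1, totals / 1e6, "/")
  out <- gene_count_table(mat, "fpkm", totals)
  attr(out, "exclusions") <- attr(table, "exclusions")
  out
}

#' Classify gene richness into low / high gene count
#'
#' Low iff richness is strictly below the threshold; at or above the
#' threshold is high (cohort practice: a 607,000-gene cut).
#'
#' @param richness numeric richness values (>= 0)
#' @param threshold gene-count threshold
#' @return character vector, "low" or "high"
#' @export
classify_gene_count <- function(richness, threshold) {
  if (any(richness < 0, na.rm = TRUE))
    stop_invalid("richness must be non-negative")
  ifelse(richness < threshold, "low", "high")
}

#' Estimate the low/high richness threshold from a bimodal stratum
#'
#' Fits a 2-component Gaussian mixture to (log-)richness of a reference
#' stratum — by convention the healthy-control group, where bimodality
#' is expected — and returns the density crossing between the two
#' component means (the valley). Falls back to the midpoint of the means
#' if no crossing is bracketed.
#'
#' @param richness numeric richness values of the reference stratum
#' @param log fit on the log scale (default TRUE); the returned threshold
#'   is always on the original scale
#' @return scalar threshold (genes)
#' @export
richness_threshold_gmm <- function(richness, log = TRUE) {
  x <- if (log) base::log(richness) else richness
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller
  fit <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  mu <- fit$parameters$mean
  sdv <- sqrt(fit$parameters$variance$sigmasq)
  pro <- fit$parameters$pro
  o <- order(mu); mu <- mu[o]; sdv <- sdv[o]; pro <- pro[o]
  f <- function(t) pro[1] * stats::dnorm(t, mu[1], sdv[1]) -
    pro[2] * stats::dnorm(t, mu[2], sdv[2])
  thr <- tryCatch(stats::uniroot(f, c(mu[1], mu[2]))$root,
                  error = function(e) mean(mu))
  if (log) exp(thr) else thr
}
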