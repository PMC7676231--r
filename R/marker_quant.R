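#' Marker quantification configuration
#'
#' @param window_nt nt added on each side of the FAD active site when
#'   excising the quantification window (default 90)
#' @param min_reads_per_sample minimum qualifying window reads for a
#'   sample to be reported (default 10; fewer reads excludes the sample)
#' @param min_overlap minimum exact-match overlap in nt (default 101,
#'   i.e. a mapping length strictly greater than 100 bp)
#' @param hutH_ko KEGG ortholog identifier whose summed FPKM defines
#'   hutH abundance (default "K01745")
#' @param kmer seed k-mer length of the exact matcher
#' @param seed integer seed
#' @return list of class `marker_quant_config`
#' @export
marker_quant_config <- function(window_nt = 90, min_reads_per_sample = 10,
                                min_overlap = 101, hutH_ko = "K01745",
                                kmer = 31L, seed = 1L) {
  if (window_nt < 0 || min_reads_per_sample <= 0 || min_overlap <= 0)
    stop_invalid("thresholds must be positive")
  structure(as.list(environment()), class = "marker_quant_config")
}

#' Classify a urocanate reductase homolog by residue 373
#'
#' Histidine at protein position 373 (1-based) prevents urocanate
#' reductase activity, so such homologs are classified `false_urda`; any
#' other residue gives `true_urda`.
#'
#' @param protein amino-acid sequence(s), length >= 373 residues
#' @return character vector, "true_urda" or "false_urda"
#' @export
classify_urda <- function(protein) {
  if (any(nchar(protein) < 373))
    stop_invalid("protein must have at least 373 residues")
  ifelse(substr(protein, 373, 373) == "H", "false_urda", "true_urda")
}

#' Excise the FAD active-site quantification window
#'
#' The window is the annotated active-site span extended by `window_nt`
#' nucleotides on each side, clipped to the reference bounds.
#'
#' @param ref one urdA reference (a row of a `urda_reference_set`, or
#'   any list with `sequence`, `site_start`, `site_end`, `id`)
#' @param window_nt extension in nt (default 90)
#' @return list of class `marker_window`: `ref_id`, `sequence`,
#'   `start`, `end` (1-based inclusive on the reference)
#' @export
build_active_site_window <- function(ref, window_nt = 90) {
  L <- nchar(ref$sequence)
  if (ref$site_start < 1 || ref$site_end > L || ref$site_start > ref$site_end)
    stop_invalid("active-site span outside reference bounds")
  start <- max(1, ref$site_start - window_nt)
  end <- min(L, ref$site_end + window_nt)
  structure(list(ref_id = ref$id,
                 sequence = substr(ref$sequence, start, end),
                 start = start, end = end),
            class = "marker_window")
}

#' Build windows for every reference in a urdA set
#' @param refs a `urda_reference_set`
#' @param window_nt extension in nt
#' @return list of `marker_window`
#' @export
build_all_windows <- function(refs, window_nt = 90) {
  lapply(seq_len(nrow(refs)), function(i)
    build_active_site_window(refs[i, ], window_nt))
}

#' Count reads matching active-site windows exactly
#'
#' A read counts toward a window iff its overlapping segment with the
#' window matches exactly — zero mismatches, no gaps — over strictly
#' more than `min_overlap - 1` nt (default: overlap of at least 101 nt,
#' i.e. a mapping length larger than 100 bp), on either strand. Reads
#' overhanging the window edges are allowed; only the overlap must
#' match. Samples whose total qualifying reads fall below
#' `min_reads_per_sample` are flagged excluded — an outcome, not an
#' error.
#'
#' @param reads a `read_set` for one sample
#' @param windows list of `marker_window`
#' @param config a `marker_quant_config`
#' @return list: `window_counts` (named per reference), `total_matched`
#'   (reads matching any window), `excluded` (logical),
#'   `exclusion_reason`
#' @export
quantify_window_reads <- function(reads, windows,
                                  config = marker_quant_config()) {
  if (!length(windows)) stop_invalid("windows must be non-empty")
  res <- cpp_match_windows(reads$sequence,
                           vapply(windows, `[[`, character(1), "sequence"),
                           as.integer(config$min_overlap),
                           as.integer(config$kmer))
  counts <- setNames(res$window_counts,
                     vapply(windows, `[[`, character(1), "ref_id"))
  total <- sum(res$read_matched)
  excluded <- total < config$min_reads_per_sample
  list(window_counts = counts, total_matched = total, excluded = excluded,
       exclusion_reason = if (excluded)
         sprintf("only %d window reads (< %d required)", total,
                 config$min_reads_per_sample) else NA_character_)
}

#' Depth-normalize marker window counts
#'
#' Reads per million: `1e6 * mapped window reads / sample read depth`,
#' reported separately for the true- and false-urdA classes.
#'
#' @param window_counts named per-window read counts (names are
#'   reference ids)
#' @param refs the `urda_reference_set` giving each reference's class
#' @param depth total reads in the sample
#' @return list: `true_urda_rpm`, `false_urda_rpm`
#' @export
normalize_marker_abundance <- function(window_counts, refs, depth) {
  if (depth <= 0) stop_invalid("depth must be positive")
  cls <- classify_urda(refs$protein[match(names(window_counts), refs$id)])
  list(true_urda_rpm = 1e6 * sum(window_counts[cls == "true_urda"]) / depth,
       false_urda_rpm = 1e6 * sum(window_counts[cls == "false_urda"]) / depth)
}

#' Quantify hutH abundance by KEGG ortholog
#'
#' Per sample, the sum of FPKM over catalog genes annotated to the
#' configured KO (default K01745, histidine ammonia-lyase). Samples with
#' no annotated gene get 0.
#'
#' @param fpkm a `gene_count_table` at stage "fpkm"
#' @param ko_annotation data.frame with columns `gene_id`, `ko`
#' @param config a `marker_quant_config`
#' @return named numeric vector of per-sample hutH abundance
#' @export
quantify_hutH <- function(fpkm, ko_annotation,
                          config = marker_quant_config()) {
  genes <- intersect(ko_annotation$gene_id[ko_annotation$ko == config$hutH_ko],
                     colnames(fpkm))
  if (!length(genes))
    return(setNames(rep(0, nrow(fpkm)), rownames(fpkm)))
  setNames(rowSums(fpkm[, genes, drop = FALSE]), rownames(fpkm))
}

#' Marker abundance table across samples
#'
#' Convenience wrapper running [quantify_window_reads()] and
#' [normalize_marker_abundance()] over a list of per-sample read sets.
#'
#' @param read_sets named list of `read_set` (one per sample)
#' @param refs a `urda_reference_set`
#' @param config a `marker_quant_config`
#' @return data.frame: sample, true_urda_rpm, false_urda_rpm, total
#'   window reads, excluded flag and reason (excluded samples carry NA
#'   abundances)
#' @export
marker_abundance_table <- function(read_sets, refs,
                                   config = marker_quant_config()) {
  windows <- build_all_windows(refs, config$window_nt)
  rows <- lapply(names(read_sets), function(s) {
    q <- quantify_window_reads(read_sets[[s]], windows, config)
    if (q$excluded)
      return(data.frame(sample = s, true_urda_rpm = NA_real_,
                        false_urda_rpm = NA_real_,
                        window_reads = q$total_matched, excluded = TRUE,
                        reason = q$exclusion_reason,
                        stringsAsFactors = FALSE))
    ab <- normalize_marker_abundance(q$window_counts, refs,
                                     nrow(read_sets[[s]]))
    data.frame(sample = s, true_urda_rpm = ab$true_urda_rpm,
               false_urda_rpm = ab$false_urda_rpm,
               window_reads = q$total_matched, excluded = FALSE,
               reason = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
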