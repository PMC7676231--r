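# File interfaces: FASTA/FASTQ through Biostrings, tables as TSV,
# run configuration as JSON.

#' Write a gene catalog or urdA reference set to FASTA
#' @param x a `gene_catalog` or `urda_reference_set`
#' @param path output FASTA path
#' @return `path`, invisibly
#' @export
write_fasta <- function(x, path) {
  ss <- Biostrings::DNAStringSet(setNames(x$sequence, x$id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write a read set to FASTQ with constant quality
#' @param reads a `read_set`
#' @param path output FASTQ path
#' @return `path`, invisibly
#' @export
write_fastq <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  q <- Biostrings::BStringSet(vapply(nchar(reads$sequence), function(L)
    paste(rep("I", L), collapse = ""), character(1)))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ file into a read set
#' @param path FASTQ path
#' @return data.frame of class `read_set`
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- data.frame(read_id = names(ss), sequence = as.character(ss),
                    stringsAsFactors = FALSE)
  class(out) <- c("read_set", "data.frame")
  out
}

#' Read a FASTA file into a gene catalog
#' @param path FASTA path
#' @return data.frame of class `gene_catalog`
#' @export
read_catalog_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- data.frame(id = names(ss), sequence = as.character(ss),
                    length = Biostrings::width(ss), stringsAsFactors = FALSE)
  class(out) <- c("gene_catalog", "data.frame")
  out
}

#' Write all synthetic-world artifacts to a directory
#'
#' Emits `catalog.fasta`, `urda_refs.fasta` with its TSV sidecar
#' (1-based inclusive active-site spans and residue 373), `mgs_defs.tsv`,
#' `ko_annotation.tsv`, `cohort.tsv`, `nutrition.tsv` and `world.json`
#' (the generating configuration, including the seed). Per-subject FASTQ
#' is written on demand by [simulate_reads()] + [write_fastq()].
#'
#' @param world a `synthetic_world`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(world$catalog, file.path(dir, "catalog.fasta"))
  write_fasta(world$urda_refs, file.path(dir, "urda_refs.fasta"))
  sidecar <- world$urda_refs[, c("id", "site_start", "site_end",
                                 "residue_373", "is_true_urda")]
  write.table(sidecar, file.path(dir, "urda_refs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  defs <- do.call(rbind, lapply(world$mgs_defs, function(d)
    data.frame(mgs_id = d$mgs_id, genus = d$genus,
               genes = paste(d$genes, collapse = ","),
               markers = paste(d$markers, collapse = ","),
               stringsAsFactors = FALSE)))
  write.table(defs, file.path(dir, "mgs_defs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(world$ko_annotation, file.path(dir, "ko_annotation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(world$truth, file.path(dir, "cohort.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(world$nutrition, file.path(dir, "nutrition.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- world$config
  cfg$dmm_alphas <- unclass(as.data.frame(cfg$dmm_alphas))
  jsonlite::write_json(cfg, file.path(dir, "world.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an MGS definition TSV written by [write_world()]
#' @param path TSV path
#' @return list of MGS definitions
#' @export
read_mgs_defs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    list(mgs_id = df$mgs_id[i],
         genes = strsplit(df$genes[i], ",")[[1]],
         markers = strsplit(df$markers[i], ",")[[1]],
         genus = df$genus[i]))
}
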