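#' Simulate single-end shotgun reads for one subject
#'
#' Reads are drawn from the subject's planted abundance profile with
#' sampling weight proportional to abundance x gene length (longer
#' templates yield more fragments at equal molar abundance), plus the
#' subject's carried urdA homolog genes at their planted read shares.
#' Start positions are uniform along each template and substitution
#' errors are injected independently per base at `error_rate`. The read
#' model is deliberately simple: substitution-only errors, constant
#' quality, forward strand; the mapping stage only needs
#' identity-threshold behavior.
#'
#' @param world a `synthetic_world`
#' @param subject_id subject identifier present in `world$truth`
#' @param depth number of reads (default: the world's `read_depth`)
#' @param seed integer seed (default derived from the world seed and the
#'   subject index, so per-subject read sets are reproducible)
#' @return data.frame of class `read_set` with columns `read_id`,
#'   `sequence`; attribute `source` records the template of each read
#' @export
simulate_reads <- function(world, subject_id, depth = NULL, seed = NULL) {
  stopifnot(inherits(world, "synthetic_world"))
  s <- match(subject_id, world$truth$subject_id)
  if (is.na(s)) stop_invalid("unknown subject: ", subject_id)
  cfg <- world$config
  if (is.null(depth)) depth <- cfg$read_depth
  if (depth < 0) stop_invalid("depth must be >= 0")
  if (is.null(seed)) seed <- derive_seed(cfg$seed, 1000 + s)
  set.seed(seed)
  rl <- cfg$read_length

  a <- world$gene_abundance[s, ]
  nz <- which(a > 0)
  w_cat <- a[nz] * world$catalog$length[nz]
  w_cat <- w_cat / sum(w_cat)
  f_true <- world$truth$true_urda_share[s]
  f_false <- world$truth$false_urda_share[s]
  src_seq <- world$catalog$sequence[nz]
  src_id <- world$catalog$id[nz]
  w <- w_cat * (1 - f_true - f_false)
  if (f_true > 0) {
    ri <- match(world$truth$true_urda_ref[s], world$urda_refs$id)
    src_seq <- c(src_seq, world$urda_refs$sequence[ri])
    src_id <- c(src_id, world$urda_refs$id[ri])
    w <- c(w, f_true)
  }
  if (f_false > 0) {
    ri <- match(world$truth$false_urda_ref[s], world$urda_refs$id)
    src_seq <- c(src_seq, world$urda_refs$sequence[ri])
    src_id <- c(src_id, world$urda_refs$id[ri])
    w <- c(w, f_false)
  }

  if (depth == 0) {
    out <- data.frame(read_id = character(0), sequence = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "source") <- character(0)
    class(out) <- c("read_set", "data.frame")
    return(out)
  }
  counts <- as.integer(rmultinom(1, depth, w))
  src_of_read <- rep.int(seq_along(w), counts)
  lens <- nchar(src_seq)[src_of_read]
  eff_rl <- pmin(rl, lens)
  starts <- floor(runif(depth) * (lens - eff_rl + 1)) + 1
  seqs <- substring(src_seq[src_of_read], starts, starts + eff_rl - 1)

  if (cfg$error_rate > 0) {
    # per-base substitutions; positions drawn with replacement (collision
    # probability ~1/read_length, negligible at realistic error rates)
    nerr <- rbinom(depth, eff_rl, cfg$error_rate)
    E <- sum(nerr)
    if (E > 0) {
      bases <- c("A", "C", "G", "T")
      err_read <- rep.int(which(nerr > 0), nerr[nerr > 0])
      err_pos <- ceiling(runif(E) * eff_rl[err_read])
      old <- substring(seqs[err_read], err_pos, err_pos)
      shift <- sample.int(3, E, replace = TRUE)
      new <- bases[(match(old, bases) - 1 + shift) %% 4 + 1]
      for (j in seq_len(E))
        substr(seqs[err_read[j]], err_pos[j], err_pos[j]) <- new[j]
    }
  }
  out <- data.frame(
    read_id = sprintf("%s_r%06d", subject_id, seq_len(depth)),
    sequence = seqs, stringsAsFactors = FALSE)
  attr(out, "source") <- src_id[src_of_read]
  class(out) <- c("read_set", "data.frame")
  out
}
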