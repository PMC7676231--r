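#' Run the full synthetic-cohort pipeline
#'
#' Executes every stage end to end: world simulation, per-subject read
#' simulation, catalog mapping with smart shared counting, urdA window
#' matching, rarefaction richness, downsizing + FPKM, MGS and genus
#' profiling, DMM enterotyping with BIC model selection, hutH
#' quantification, cohort assembly (derived indices, diet scores,
#' low/high gene-count split from a 2-component Gaussian mixture on the
#' healthy stratum) and the association block.
#'
#' @param config an `imp_world_config` (see [synthetic_world_config()])
#' @param downsize_depth,n_rarefactions gene-quantification settings
#'   (defaults 1e4 reads, 10 repetitions)
#' @param k_range candidate DMM component counts (default 2:4)
#' @param dmm_n_init k-means restarts per DMM fit (default 3)
#' @param richness_threshold optional fixed low/high gene-count
#'   threshold; `NULL` estimates it from the healthy stratum
#' @param verbose print stage progress
#' @return list of class `imp_pipeline_result`: `world`, `raw_counts`,
#'   `richness`, `richness_threshold`, `fpkm`, `mgs`, `genus_counts`,
#'   `dmm`, `enterotypes`, `markers`, `huth`, `cohort`, `associations`,
#'   `or_table`
#' @export
run_pipeline <- function(config = synthetic_world_config(),
                         downsize_depth = 1e4, n_rarefactions = 10,
                         k_range = 2:4, dmm_n_init = 3,
                         richness_threshold = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  say("simulating world")
  world <- simulate_cohort_truth(config)
  gq <- gene_quant_config(downsize_depth = downsize_depth,
                          n_rarefactions = n_rarefactions,
                          seed = derive_seed(config$seed, 91))
  mq <- marker_quant_config(seed = derive_seed(config$seed, 92))
  idx <- build_map_index(world$catalog, gq$kmer)
  windows <- build_all_windows(world$urda_refs, mq$window_nt)

  n <- nrow(world$truth)
  ids <- world$truth$subject_id
  raw <- matrix(0, n, nrow(world$catalog),
                dimnames = list(ids, world$catalog$id))
  mapped <- numeric(n)
  marker_rows <- vector("list", n)
  say("simulating + mapping reads for ", n, " subjects")
  for (s in seq_len(n)) {
    reads <- simulate_reads(world, ids[s])
    mp <- map_reads(reads, idx, gq)
    cs <- count_one_sample(mp$hits, nrow(world$catalog))
    raw[s, ] <- cs$counts
    mapped[s] <- cs$mapped
    q <- quantify_window_reads(reads, windows, mq)
    marker_rows[[s]] <- if (q$excluded)
      data.frame(sample = ids[s], true_urda_rpm = NA_real_,
                 false_urda_rpm = NA_real_, window_reads = q$total_matched,
                 excluded = TRUE, reason = q$exclusion_reason,
                 stringsAsFactors = FALSE)
    else {
      ab <- normalize_marker_abundance(q$window_counts, world$urda_refs,
                                       nrow(reads))
      data.frame(sample = ids[s], true_urda_rpm = ab$true_urda_rpm,
                 false_urda_rpm = ab$false_urda_rpm,
                 window_reads = q$total_matched, excluded = FALSE,
                 reason = NA_character_, stringsAsFactors = FALSE)
    }
  }
  raw_table <- gene_count_table(raw, "raw", setNames(mapped, ids))
  markers <- do.call(rbind, marker_rows)

  say("richness + downsizing + FPKM")
  dr <- downsize_and_richness(raw_table, downsize_depth, n_rarefactions,
                              seed = derive_seed(config$seed, 93))
  richness <- dr$richness
  fpkm <- fpkm_normalize(dr$downsized, world$catalog)

  say("MGS + genus + DMM")
  mgs <- compute_mgs_abundance(fpkm, world$mgs_defs)
  genus <- collapse_to_genus(mgs, world$mgs_defs)
  sel <- select_n_components(genus, k_range,
                             seed = derive_seed(config$seed, 95),
                             n_init = dmm_n_init, tol = 1e-4,
                             max_iter = 150)
  dmm <- sel$models[[which(k_range == sel$K)]]
  ent <- assign_enterotypes(dmm, genus, richness = richness)
  huth <- quantify_hutH(fpkm, world$ko_annotation, mq)

  say("cohort assembly")
  truth <- world$truth
  cohort <- truth
  cohort$richness <- as.numeric(richness[truth$subject_id])
  if (is.null(richness_threshold)) {
    healthy_r <- cohort$richness[cohort$diabetes_status == "healthy"]
    richness_threshold <- richness_threshold_gmm(
      healthy_r[!is.na(healthy_r)])
  }
  cohort$gene_count_class <- classify_gene_count(cohort$richness,
                                                 richness_threshold)
  cohort$enterotype <- as.integer(ent$labels[truth$subject_id])
  cohort$is_bact2 <- !is.na(ent$bacteroides2) &
    cohort$enterotype == ent$bacteroides2
  mm <- match(truth$subject_id, markers$sample)
  cohort$true_urda_rpm <- markers$true_urda_rpm[mm]
  cohort$false_urda_rpm <- markers$false_urda_rpm[mm]
  cohort$huth_fpkm <- as.numeric(huth[truth$subject_id])
  nut <- world$nutrition
  cohort$energy_kcal <- nut$energy_kcal
  cohort$histidine_g <- nut$histidine_g
  cohort$bmr <- harris_benedict_bmr(cohort$sex, cohort$weight_kg,
                                    cohort$height_cm, cohort$age)
  cohort$energy_aberrant <- energy_intake_exclusion(cohort$energy_kcal,
                                                    cohort$bmr)
  idxs <- derive_indices(cohort)
  cohort <- cbind(cohort, idxs)
  intakes <- as.matrix(nut[, world$food_groups$group])
  cohort <- cbind(cohort, compute_diet_scores(intakes))

  say("associations")
  assoc <- analyze_imp_associations(cohort)

  res <- list(world = world, raw_counts = raw_table, richness = richness,
              richness_threshold = richness_threshold, fpkm = fpkm,
              mgs = mgs, genus_counts = genus, dmm = dmm,
              enterotypes = ent, markers = markers, huth = huth,
              cohort = cohort, associations = assoc$table,
              or_table = assoc$or_table)
  class(res) <- "imp_pipeline_result"
  res
}

#' Cohort association block
#'
#' Runs the subject-level analyses on an assembled cohort table and
#' adjusts P-values by BH-FDR within each analysis block (one family per
#' heatmap-equivalent block):
#'
#' * `glycemia`: log-ImP across diabetes status (linear model adjusted
#'   for age, sex, BMI, ethnicity, creatinine clearance)
#' * `microbiome`: ImP-richness partial correlation (Model 2), ImP by
#'   low/high gene count, true-urdA abundance in the Bacteroides-2
#'   analog vs other enterotypes (Model 1), Spearman correlations of
#'   urdA and hutH with richness
#' * `nutrition`: histidine intake across ImP quartiles (adjusted for
#'   Model 2 covariates plus diabetes status and energy intake; subjects
#'   with aberrant energy declarations excluded) — the planted null
#'
#' @param cohort assembled cohort data.frame (see [run_pipeline()])
#' @return list: `table` (block, analysis, estimate, p, q, n),
#'   `or_table` (quartile multinomial ORs, Models 1 and 2)
#' @export
analyze_imp_associations <- function(cohort) {
  lt <- log_transform_policy(cohort$imp)
  log_imp <- if (lt$transformed) lt$values else log(cohort$imp)

  rows <- list()
  add <- function(block, analysis, estimate, p, n)
    rows[[length(rows) + 1]] <<- data.frame(
      block = block, analysis = analysis, estimate = estimate, p = p,
      n = n, stringsAsFactors = FALSE)

  cov1 <- imp_model_covariates(cohort, 1)
  cov2 <- imp_model_covariates(cohort, 2)

  gs <- linear_group_comparison(log_imp, cohort$diabetes_status, cov2)
  add("glycemia", "imp_by_diabetes_status",
      gs$estimate[gs$level == "type2diabetes"], gs$p_overall[1], gs$n[1])

  pc <- partial_correlation(log_imp, cohort$richness, cov2)
  add("microbiome", "imp_vs_richness_partial", pc$estimate, pc$p, pc$n)

  gc_cls <- factor(cohort$gene_count_class, levels = c("high", "low"))
  gcc <- linear_group_comparison(log_imp, gc_cls, cov2)
  add("microbiome", "imp_by_low_gene_count", gcc$estimate[1],
      gcc$p_overall[1], gcc$n[1])

  if (any(cohort$is_bact2, na.rm = TRUE)) {
    b2 <- factor(ifelse(cohort$is_bact2, "bacteroides2", "other"),
                 levels = c("other", "bacteroides2"))
    ur <- log_transform_policy(1 + cohort$true_urda_rpm)$values
    ub <- tryCatch(linear_group_comparison(ur, b2, cov1),
                   error = function(e) NULL)
    if (!is.null(ub))
      add("microbiome", "true_urda_by_bact2", ub$estimate[1],
          ub$p_overall[1], ub$n[1])
  }

  su <- tryCatch(partial_correlation(cohort$true_urda_rpm, cohort$richness,
                                     method = "spearman"),
                 error = function(e) NULL)
  if (!is.null(su))
    add("microbiome", "urda_vs_richness_spearman", su$estimate, su$p, su$n)
  sh <- tryCatch(partial_correlation(cohort$huth_fpkm, cohort$richness,
                                     method = "spearman"),
                 error = function(e) NULL)
  if (!is.null(sh))
    add("microbiome", "huth_vs_richness_spearman", sh$estimate, sh$p, sh$n)

  quart <- quartile_stratify(cohort$imp)
  nut_keep <- !cohort$energy_aberrant
  covn <- cbind(imp_model_covariates(cohort, 3),
                energy_kcal = cohort$energy_kcal)[nut_keep, , drop = FALSE]
  hq <- linear_group_comparison(cohort$histidine_g[nut_keep],
                                quart[nut_keep], covn)
  add("nutrition", "histidine_by_imp_quartile",
      hq$estimate[hq$level == "Q4"], hq$p_overall[1], hq$n[1])

  tab <- do.call(rbind, rows)
  tab$q <- NA_real_
  for (b in unique(tab$block))
    tab$q[tab$block == b] <- bh_fdr(tab$p[tab$block == b])

  or1 <- fit_multinomial_or(cohort$diabetes_status, quart, cov1)
  or1$model <- 1
  or2 <- fit_multinomial_or(cohort$diabetes_status, quart, cov2)
  or2$model <- 2
  list(table = tab, or_table = rbind(or1, or2))
}

#' @export
print.imp_pipeline_result <- function(x, ...) {
  cat("imp_pipeline_result:", nrow(x$cohort), "subjects; DMM K =",
      x$dmm$K, "; richness threshold =",
      format(x$richness_threshold, digits = 5), "\n")
  print(x$associations, row.names = FALSE)
  invisible(x)
}
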