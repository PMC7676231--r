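#' Default genus labels for the synthetic community
#'
#' Twenty common human-gut genera; the first label ("Bacteroides") is the
#' one used to tag Bacteroides-dominated enterotype analogs.
#' @return character vector of genus names
#' @export
default_genus_labels <- function() {
  c("Bacteroides", "Prevotella", "Faecalibacterium", "Ruminococcus",
    "Alistipes", "Roseburia", "Eubacterium", "Blautia", "Bifidobacterium",
    "Akkermansia", "Parabacteroides", "Dorea", "Coprococcus",
    "Oscillibacter", "Dialister", "Subdoligranulum", "Anaerostipes",
    "Butyrivibrio", "Collinsella", "Lachnospira")
}

# Enterotype scenario: three community types over the default 20 genera.
# Component 1: diverse Bacteroides-dominated ("Bacteroides 1" analog);
# component 2: low-diversity, strongly Bacteroides-dominated
# ("Bacteroides 2" analog); component 3: Prevotella-dominated.
default_dmm_alphas <- function(n_genera = 20) {
  a1 <- rep(2, n_genera);   a1[1] <- 8
  a2 <- rep(0.4, n_genera); a2[1] <- 20
  a3 <- rep(1.5, n_genera); a3[2] <- 15; a3[1] <- 1
  rbind(bact1 = a1, bact2 = a2, prevotella = a3)
}

#' Configuration of the synthetic cohort world
#'
#' Bundles every knob of the synthetic-data generator: cohort size and
#' glycemic-group mix, gene-catalog geometry, metagenomic-species (MGS)
#' panels, Dirichlet parameters of the enterotype mixture, urdA carriage,
#' the planted imidazole propionate (ImP) model, and sequencing-read
#' parameters. Defaults define the reference scenario used throughout the
#' package: 500 subjects split roughly 27.5/33.4/39.1% across healthy /
#' prediabetes / type 2 diabetes, a 5000-gene catalog organized into 60
#' MGS of 80 genes (50 markers each) over 20 genera, three enterotypes,
#' and 150-bp single-end reads.
#'
#' The planted ImP model on the log scale is
#' `log(ImP) = baseline + group_shift + beta * z(richness) +
#'   urda_coef * carrier + N(0, noise_sd)`,
#' with a negative `imp_richness_beta` so that low gene richness implies
#' high ImP, and positive group shifts for prediabetes and diabetes.
#'
#' @param n_subjects number of subjects
#' @param group_props proportions over healthy/prediabetes/type2diabetes;
#'   must sum to 1
#' @param n_genes,gene_length_range catalog size and nt length range
#' @param n_mgs,genes_per_mgs,markers_per_mgs MGS panel geometry
#' @param n_genera number of genus labels (uses [default_genus_labels()])
#' @param dmm_alphas K x n_genera matrix of positive Dirichlet parameters
#' @param enterotype_weights mixture weights, sum to 1
#' @param urda_prevalence_by_enterotype probability a subject carries a
#'   true (non-His-373) urdA gene, per enterotype
#' @param urda_true_share_by_enterotype expected read share contributed by
#'   the carried true urdA gene, per enterotype
#' @param urda_false_prevalence,urda_false_share carriage and read share
#'   of His-373 (inactive) homologs, enterotype-independent
#' @param urda_imp_coef additive log-nM ImP effect of true-urdA carriage
#' @param richness_retention_mean per-enterotype mean fraction of catalog
#'   genes a subject carries (drives gene-richness differences)
#' @param richness_retention_conc Beta concentration of retention draws
#' @param imp_baseline_log,imp_group_shift_log,imp_richness_beta,noise_sd
#'   parameters of the planted ImP model (log-nM scale)
#' @param histidine_imp_beta multiplicative log-scale dependence of
#'   dietary histidine on ImP; 0 plants the null
#' @param read_depth,read_length,error_rate sequencing-read simulation
#' @param n_urda_true,n_urda_false,urda_protein_length urdA reference set
#' @param seed integer master seed
#' @return a validated list of class `imp_world_config`
#' @export
synthetic_world_config <- function(
    n_subjects = 500,
    group_props = c(healthy = 0.275, prediabetes = 0.334,
                    type2diabetes = 0.391),
    n_genes = 5000,
    gene_length_range = c(300, 1500),
    n_mgs = 60,
    genes_per_mgs = 80,
    markers_per_mgs = 50,
    n_genera = 20,
    dmm_alphas = default_dmm_alphas(n_genera),
    enterotype_weights = c(0.40, 0.30, 0.30),
    urda_prevalence_by_enterotype = c(0.25, 0.75, 0.25),
    urda_true_share_by_enterotype = c(0.001, 0.004, 0.001),
    urda_false_prevalence = 0.5,
    urda_false_share = 0.002,
    urda_imp_coef = 0.25,
    richness_retention_mean = c(0.85, 0.55, 0.85),
    richness_retention_conc = 60,
    imp_baseline_log = log(20),
    imp_group_shift_log = c(healthy = 0, prediabetes = 0.35,
                            type2diabetes = 0.60),
    imp_richness_beta = -0.25,
    noise_sd = 0.6,
    histidine_imp_beta = 0,
    read_depth = 5e4,
    read_length = 150,
    error_rate = 0.005,
    n_urda_true = 6,
    n_urda_false = 6,
    urda_protein_length = 400,
    seed = 1L) {
  cfg <- as.list(environment())
  if (abs(sum(group_props) - 1) > 1e-9)
    stop_invalid("group_props must sum to 1")
  if (abs(sum(enterotype_weights) - 1) > 1e-9)
    stop_invalid("enterotype_weights must sum to 1")
  if (any(dmm_alphas <= 0)) stop_invalid("Dirichlet parameters must be > 0")
  if (read_depth < 0) stop_invalid("read_depth must be >= 0")
  if (error_rate < 0 || error_rate >= 1)
    stop_invalid("error_rate must be in [0, 1)")
  if (nrow(dmm_alphas) != length(enterotype_weights))
    stop_invalid("dmm_alphas rows must match enterotype_weights")
  if (ncol(dmm_alphas) != n_genera)
    stop_invalid("dmm_alphas columns must match n_genera")
  if (markers_per_mgs > genes_per_mgs)
    stop_invalid("markers_per_mgs cannot exceed genes_per_mgs")
  class(cfg) <- "imp_world_config"
  cfg
}

#' Generate a random nucleotide gene catalog
#'
#' Stand-in for a reference gene catalog: `n_genes` uniform-random A/C/G/T
#' sequences with lengths uniform in `length_range`. Deterministic given
#' `seed`.
#'
#' @param n_genes number of genes (>= 1)
#' @param length_range length-2 vector of nt bounds (min >= 150)
#' @param seed integer seed
#' @return data.frame of class `gene_catalog` with columns `id`,
#'   `sequence`, `length`
#' @examples
#' cat3 <- generate_gene_catalog(3, c(300, 300), seed = 1)
#' nchar(cat3$sequence)
#' @export
generate_gene_catalog <- function(n_genes, length_range, seed = 1L) {
  if (n_genes < 1) stop_invalid("n_genes must be >= 1")
  if (min(length_range) < 150) stop_invalid("gene lengths must be >= 150 nt")
  set.seed(seed)
  lens <- length_range[1] +
    sample.int(length_range[2] - length_range[1] + 1L, n_genes,
               replace = TRUE) - 1L
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  out <- data.frame(id = sprintf("gene_%05d", seq_len(n_genes)),
                    sequence = seqs, length = lens,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_catalog", "data.frame")
  out
}

#' Partition a catalog into metagenomic-species (MGS) panels
#'
#' Assigns disjoint blocks of catalog genes to MGS, designates
#' `n_markers` marker genes per MGS (the panel used by the abundance
#' rule), and attaches a genus label. Genus labels cycle through
#' `genus_labels` so every genus receives at least one MGS when
#' `n_mgs >= length(genus_labels)`, then the assignment is permuted.
#'
#' @param catalog a `gene_catalog`
#' @param n_mgs number of MGS
#' @param genes_per_mgs member genes per MGS
#' @param n_markers marker genes per MGS (default 50)
#' @param seed integer seed
#' @param genus_labels character vector of genus names
#' @return list of MGS definitions, each with `mgs_id`, `genes`,
#'   `markers`, `genus`
#' @export
generate_mgs_definitions <- function(catalog, n_mgs, genes_per_mgs,
                                     n_markers = 50, seed = 1L,
                                     genus_labels = default_genus_labels()) {
  if (n_mgs * genes_per_mgs > nrow(catalog))
    stop_invalid("catalog too small: need ", n_mgs * genes_per_mgs,
                 " genes, have ", nrow(catalog))
  if (n_markers > genes_per_mgs)
    stop_invalid("n_markers cannot exceed genes_per_mgs")
  set.seed(seed)
  perm <- sample(nrow(catalog))
  genera <- sample(rep(genus_labels, length.out = n_mgs))
  lapply(seq_len(n_mgs), function(m) {
    idx <- perm[((m - 1) * genes_per_mgs + 1):(m * genes_per_mgs)]
    genes <- catalog$id[idx]
    list(mgs_id = sprintf("mgs_%03d", m),
         genes = genes,
         markers = genes[seq_len(n_markers)],
         genus = genera[m])
  })
}

# inverse genetic code: amino acid -> codons (no stop codons)
aa_codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc <- gc[gc != "*"]
  split(names(gc), unname(gc))
}

#' Generate a synthetic urocanate reductase (urdA) reference set
#'
#' Builds homolog reference genes with a known truth: `n_false`
#' references carry histidine (H) at protein position 373 (1-based) and
#' are therefore catalytically inactive homologs; `n_true` carry a non-H
#' residue. Each reference has a random protein of `protein_length`
#' residues, a nucleotide sequence back-translated codon by codon
#' (3 x protein_length nt, single frame, no introns), and an annotated
#' FAD active-site span covering codons 371-375 — hence always containing
#' the codon of residue 373 (nt 1117-1119).
#'
#' @param n_true,n_false reference counts per class
#' @param protein_length residues, must be >= 373
#' @param seed integer seed
#' @return data.frame of class `urda_reference_set` with columns `id`,
#'   `sequence` (nt), `protein`, `site_start`, `site_end` (1-based
#'   inclusive nt), `residue_373`, `is_true_urda`
#' @export
generate_urda_reference_set <- function(n_true, n_false, protein_length,
                                        seed = 1L) {
  if (protein_length < 373)
    stop_invalid("protein_length must be >= 373")
  set.seed(seed)
  codons <- aa_codon_table()
  aas <- names(codons)
  non_h <- setdiff(aas, "H")
  n <- n_true + n_false
  is_true <- rep(c(TRUE, FALSE), c(n_true, n_false))
  prot <- vapply(seq_len(n), function(i) {
    p <- sample(aas, protein_length, replace = TRUE)
    p[373] <- if (is_true[i]) sample(non_h, 1) else "H"
    paste(p, collapse = "")
  }, character(1))
  nt <- vapply(prot, function(p) {
    aa <- strsplit(p, "")[[1]]
    paste(vapply(aa, function(a) sample(codons[[a]], 1), character(1)),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
  site_start <- 3L * (371L - 1L) + 1L   # first nt of codon 371
  site_end <- 3L * 375L                 # last nt of codon 375
  out <- data.frame(
    id = sprintf("urda_%s_%02d", ifelse(is_true, "true", "false"),
                 seq_len(n)),
    sequence = nt, protein = prot,
    site_start = site_start, site_end = site_end,
    residue_373 = substr(prot, 373, 373),
    is_true_urda = is_true, stringsAsFactors = FALSE)
  class(out) <- c("urda_reference_set", "data.frame")
  out
}

# food-group scenario tables -------------------------------------------------

#' Default 37-group food composition table
#'
#' Plausible per-gram energy density (kcal/g), histidine content (mg/g)
#' and typical daily intake (g/day) for 37 food groups. Scenario values,
#' not nutrient-database claims.
#' @return data.frame with columns `group`, `kcal_per_g`, `his_mg_per_g`,
#'   `mean_intake_g`
#' @export
default_food_composition <- function() {
  data.frame(
    group = c("red_meat", "processed_meat", "poultry", "fish", "shellfish",
              "eggs", "milk", "yogurt", "cheese", "butter",
              "vegetable_oils", "margarine", "leafy_vegetables",
              "other_vegetables", "legumes", "potatoes", "fruits",
              "berries", "fruit_juice", "whole_grains", "refined_grains",
              "bread", "breakfast_cereals", "rice_pasta", "nuts", "seeds",
              "sweets", "chocolate", "cakes_biscuits",
              "sugar_sweetened_beverages", "coffee", "tea",
              "alcoholic_beverages", "soups_sauces", "snacks",
              "plant_based_alternatives", "condiments"),
    kcal_per_g = c(2.5, 3.0, 1.7, 1.5, 0.9, 1.4, 0.5, 0.8, 3.5, 7.2, 8.8,
                   7.2, 0.25, 0.35, 1.2, 0.8, 0.5, 0.4, 0.45, 3.3, 3.6,
                   2.6, 3.8, 1.3, 6.0, 5.8, 4.0, 5.3, 4.2, 0.4, 0.02,
                   0.01, 0.7, 0.5, 5.0, 0.6, 1.5),
    his_mg_per_g = c(7.0, 6.0, 8.0, 7.5, 4.0, 3.0, 0.9, 1.0, 8.0, 0.1, 0,
                     0, 0.4, 0.3, 2.2, 0.4, 0.1, 0.1, 0.05, 1.5, 1.2, 1.8,
                     1.5, 1.2, 4.5, 5.0, 0.2, 1.2, 1.2, 0, 0, 0, 0.05,
                     0.8, 1.5, 1.8, 0.5),
    mean_intake_g = c(60, 30, 40, 35, 5, 25, 150, 80, 40, 10, 15, 5, 60,
                      120, 25, 100, 150, 20, 80, 50, 60, 120, 20, 80, 10,
                      3, 20, 15, 40, 150, 400, 200, 150, 100, 15, 20, 15),
    stringsAsFactors = FALSE)
}

#' Simulate the full synthetic cohort truth
#'
#' Draws, per subject: a glycemic group, an enterotype, a genus
#' composition from the enterotype's Dirichlet, a gene-retention fraction
#' (lower in the Bacteroides-2-like component, driving low gene
#' richness), a planted gene-abundance vector over the catalog, urdA
#' carriage, serum ImP from the planted log-linear model, clinical
#' covariates from documented scenario distributions, and a 37-group
#' food-frequency intake table with energy and histidine content
#' (independent of ImP unless `histidine_imp_beta != 0`).
#'
#' @param config an `imp_world_config`
#' @return list of class `synthetic_world` with elements `config`,
#'   `catalog`, `mgs_defs`, `urda_refs`, `ko_annotation`,
#'   `gene_abundance` (subjects x genes, rows sum to 1), `truth`
#'   (per-subject clinical/microbiome truth), `nutrition`, `food_groups`
#' @export
simulate_cohort_truth <- function(config) {
  stopifnot(inherits(config, "imp_world_config"))
  cfg <- config
  set.seed(cfg$seed)

  catalog <- generate_gene_catalog(cfg$n_genes, cfg$gene_length_range,
                                   seed = derive_seed(cfg$seed, 1))
  genus_labels <- default_genus_labels()[seq_len(cfg$n_genera)]
  mgs_defs <- generate_mgs_definitions(
    catalog, cfg$n_mgs, cfg$genes_per_mgs, cfg$markers_per_mgs,
    seed = derive_seed(cfg$seed, 2), genus_labels = genus_labels)
  urda_refs <- generate_urda_reference_set(
    cfg$n_urda_true, cfg$n_urda_false, cfg$urda_protein_length,
    seed = derive_seed(cfg$seed, 3))

  set.seed(derive_seed(cfg$seed, 4))
  # hutH (KO K01745): annotate 2 member genes in a third of the MGS
  huth_mgs <- sample(cfg$n_mgs, max(1, round(cfg$n_mgs / 3)))
  huth_genes <- unlist(lapply(mgs_defs[huth_mgs],
                              function(d) d$genes[1:2]))
  ko_annotation <- data.frame(gene_id = huth_genes, ko = "K01745",
                              stringsAsFactors = FALSE)

  n <- cfg$n_subjects
  groups <- c("healthy", "prediabetes", "type2diabetes")
  gidx <- sample.int(3, n, replace = TRUE, prob = cfg$group_props)
  K <- nrow(cfg$dmm_alphas)
  etype <- sample.int(K, n, replace = TRUE, prob = cfg$enterotype_weights)

  gene_idx <- match(catalog$id, catalog$id)  # identity; genes by index
  mgs_gene_idx <- lapply(mgs_defs, function(d) match(d$genes, catalog$id))
  genus_of_mgs <- vapply(mgs_defs, `[[`, character(1), "genus")
  mgs_by_genus <- split(seq_along(mgs_defs), genus_of_mgs)

  abund <- matrix(0, n, nrow(catalog),
                  dimnames = list(sprintf("subj_%04d", seq_len(n)),
                                  catalog$id))
  richness_true <- integer(n)
  genus_truth <- matrix(0, n, cfg$n_genera,
                        dimnames = list(rownames(abund), genus_labels))
  # genera without any MGS carry no genes: draw compositions over the
  # represented genera only (a Dirichlet restricted to a subset of its
  # categories, renormalized, is Dirichlet with the subset parameters)
  present <- which(genus_labels %in% names(mgs_by_genus))
  for (s in seq_len(n)) {
    k <- etype[s]
    gprop <- numeric(cfg$n_genera)
    gprop[present] <- rdirichlet1(cfg$dmm_alphas[k, present])
    genus_truth[s, ] <- gprop
    rmean <- cfg$richness_retention_mean[k]
    r_s <- rbeta(1, rmean * cfg$richness_retention_conc,
                 (1 - rmean) * cfg$richness_retention_conc)
    for (g in seq_along(genus_labels)) {
      mm <- mgs_by_genus[[genus_labels[g]]]
      if (is.null(mm)) next
      split_w <- rdirichlet1(rep(2, length(mm)))
      for (j in seq_along(mm)) {
        gi <- mgs_gene_idx[[mm[j]]]
        keep <- runif(length(gi)) < r_s
        if (!any(keep)) keep[1] <- TRUE
        a <- gprop[g] * split_w[j]
        abund[s, gi[keep]] <- a / sum(keep)
      }
    }
    richness_true[s] <- sum(abund[s, ] > 0)
  }

  # urdA carriage
  true_carrier <- runif(n) < cfg$urda_prevalence_by_enterotype[etype]
  false_carrier <- runif(n) < cfg$urda_false_prevalence
  true_ref <- ifelse(true_carrier,
                     sample(which(urda_refs$is_true_urda), n, replace = TRUE),
                     NA_integer_)
  false_ref <- ifelse(false_carrier,
                      sample(which(!urda_refs$is_true_urda), n,
                             replace = TRUE),
                      NA_integer_)
  true_share <- ifelse(true_carrier,
                       cfg$urda_true_share_by_enterotype[etype] *
                         exp(rnorm(n, 0, 0.3)), 0)
  false_share <- ifelse(false_carrier,
                        cfg$urda_false_share * exp(rnorm(n, 0, 0.3)), 0)

  # planted ImP model (log-nM)
  z_rich <- as.numeric(scale(richness_true))
  if (any(!is.finite(z_rich))) z_rich[!is.finite(z_rich)] <- 0
  log_imp <- cfg$imp_baseline_log + cfg$imp_group_shift_log[gidx] +
    cfg$imp_richness_beta * z_rich +
    cfg$urda_imp_coef * as.numeric(true_carrier) +
    rnorm(n, 0, cfg$noise_sd)

  # clinical covariates: scenario distributions with Table-1-like medians
  age <- rnorm_trunc(n, c(52, 58, 61)[gidx], c(12, 10, 9)[gidx], 20, 80)
  sex <- ifelse(runif(n) < c(0.39, 0.53, 0.56)[gidx], "male", "female")
  ethnicity <- ifelse(runif(n) < c(0.07, 0.10, 0.20)[gidx],
                      "non_caucasian", "caucasian")
  bmi <- pmin(pmax(exp(rnorm(n, log(c(26, 30, 32)[gidx]), 0.15)), 17), 55)
  crcl <- rnorm_trunc(n, 88, 16, 30, 160)
  creatinine <- exp(rnorm(n, log(0.9), 0.15))
  glucose <- exp(rnorm(n, log(c(5.0, 5.7, 7.5)[gidx]),
                       c(0.06, 0.06, 0.18)[gidx]))
  insulin <- exp(rnorm(n, log(c(6.9, 9.9, 12.5)[gidx]), 0.45))
  hba1c <- exp(rnorm(n, log(c(5.4, 5.8, 6.8)[gidx]),
                     c(0.03, 0.03, 0.09)[gidx]))
  tg <- exp(rnorm(n, log(c(1.0, 1.2, 1.5)[gidx]), 0.35))
  glucose_120 <- exp(rnorm(n, log(c(5.5, 7.5, 11.0)[gidx]), 0.15))
  insulin_120 <- exp(rnorm(n, log(c(40, 60, 80)[gidx]), 0.45))
  cpeptide_120 <- exp(rnorm(n, log(c(2.0, 2.6, 3.2)[gidx]), 0.35))
  height <- rnorm_trunc(n, ifelse(sex == "male", 177, 164), 7, 145, 205)
  weight <- bmi * (height / 100)^2
  cvd <- runif(n) < 0.20
  metformin <- gidx == 3 & runif(n) < 0.70

  truth <- data.frame(
    subject_id = rownames(abund),
    diabetes_status = factor(groups[gidx], levels = groups),
    enterotype_true = etype,
    richness_true = richness_true,
    true_urda_carrier = true_carrier,
    true_urda_share = true_share,
    false_urda_share = false_share,
    true_urda_ref = urda_refs$id[true_ref],
    false_urda_ref = urda_refs$id[false_ref],
    imp = exp(log_imp),
    age = age, sex = sex, ethnicity = ethnicity, bmi = bmi,
    height_cm = height, weight_kg = weight,
    creatinine_clearance = crcl, serum_creatinine = creatinine,
    glucose = glucose, insulin = insulin, hba1c = hba1c,
    triglycerides = tg, glucose_120 = glucose_120,
    insulin_120 = insulin_120, cpeptide_120 = cpeptide_120,
    cvd = cvd, metformin = metformin,
    stringsAsFactors = FALSE)

  # nutrition: 37-group FFQ intakes, energy, histidine
  comp <- default_food_composition()
  ng <- nrow(comp)
  intakes <- matrix(0, n, ng, dimnames = list(truth$subject_id, comp$group))
  for (j in seq_len(ng)) {
    eat <- runif(n) > 0.20
    intakes[, j] <- ifelse(eat,
                           rgamma(n, shape = 2,
                                  scale = comp$mean_intake_g[j] / 2), 0)
  }
  energy_true <- as.numeric(intakes %*% comp$kcal_per_g)
  report_factor <- exp(rnorm(n, 0, 0.15))
  mis <- runif(n)
  report_factor[mis < 0.03] <- 0.25            # gross under-reporters
  report_factor[mis > 0.98] <- 4.0             # gross over-reporters
  energy <- energy_true * report_factor
  histidine <- as.numeric(intakes %*% comp$his_mg_per_g) / 1000
  if (cfg$histidine_imp_beta != 0) {
    z_imp <- as.numeric(scale(log_imp))
    histidine <- histidine * exp(cfg$histidine_imp_beta * z_imp)
  }
  nutrition <- data.frame(subject_id = truth$subject_id,
                          intakes, energy_kcal = energy,
                          histidine_g = histidine,
                          weight_kg = weight, height_cm = height,
                          stringsAsFactors = FALSE, check.names = FALSE)

  world <- list(config = cfg, catalog = catalog, mgs_defs = mgs_defs,
                urda_refs = urda_refs, ko_annotation = ko_annotation,
                gene_abundance = abund, genus_truth = genus_truth,
                truth = truth, nutrition = nutrition, food_groups = comp)
  class(world) <- "synthetic_world"
  world
}

#' Synthetic screening cohort with planted exclusion-rule hits
#'
#' Builds a pre-exclusion cohort table for exercising the study-entry
#' accounting: `n_etiology` records flagged with a non-metabolic CVD
#' etiology, one (or `n_outlier`) record with an extreme serum ImP value
#' that the iterative Grubbs test flags on the log scale, and
#' `n_incomplete` records with missing biochemistry. The planted sets
#' are disjoint, and the background log-ImP draws are truncated at 3 SD
#' so the Grubbs rule flags exactly the planted outlier(s).
#'
#' @param n total records (default 1990)
#' @param n_etiology,n_outlier,n_incomplete planted hits per rule
#'   (defaults 25, 1, 6)
#' @param seed integer seed
#' @return data.frame: `subject_id`, `cvd_nonmetabolic`, `imp`,
#'   `glucose`, `insulin`, `hba1c`
#' @seealso [standard_exclusion_rules()], [apply_cohort_exclusions()]
#' @export
synthetic_exclusion_cohort <- function(n = 1990, n_etiology = 25,
                                       n_outlier = 1, n_incomplete = 6,
                                       seed = 1L) {
  set.seed(seed)
  log_imp <- rnorm_trunc(n, log(25), 0.8, log(25) - 2.4, log(25) + 2.4)
  out_idx <- n_etiology + seq_len(n_outlier)
  log_imp[out_idx] <- log(25) + 8  # unambiguous outliers
  df <- data.frame(
    subject_id = sprintf("scr_%04d", seq_len(n)),
    cvd_nonmetabolic = seq_len(n) <= n_etiology,
    imp = exp(log_imp),
    glucose = exp(rnorm(n, log(5.5), 0.15)),
    insulin = exp(rnorm(n, log(9), 0.4)),
    hba1c = exp(rnorm(n, log(5.7), 0.06)),
    stringsAsFactors = FALSE)
  inc_idx <- n_etiology + n_outlier + seq_len(n_incomplete)
  df$glucose[inc_idx] <- NA
  df
}

#' The standard ordered exclusion rules
#'
#' Non-metabolic CVD etiology, then Grubbs ImP outliers (iterative test
#' on log ImP at `alpha`), then incomplete biochemistry
#' (any missing glucose/insulin/HbA1c). Order matters: overlapping hits
#' are attributed to the first matching rule by
#' [apply_cohort_exclusions()].
#'
#' @param alpha Grubbs significance level (default 0.05)
#' @return named, ordered list of predicate functions
#' @export
standard_exclusion_rules <- function(alpha = 0.05) {
  list(
    non_metabolic_cvd = function(r) r$cvd_nonmetabolic,
    imp_grubbs_outlier = function(r) {
      flagged <- grubbs_outliers(log(r$imp), alpha = alpha)
      seq_len(nrow(r)) %in% flagged
    },
    incomplete_biochemistry = function(r)
      !complete.cases(r[, c("glucose", "insulin", "hba1c")]))
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("synthetic_world:", nrow(x$truth), "subjects,",
      nrow(x$catalog), "genes,", length(x$mgs_defs), "MGS,",
      nrow(x$urda_refs), "urdA references\n")
  invisible(x)
}
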