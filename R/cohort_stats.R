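#' Iterative Grubbs outlier test
#'
#' One-at-a-time Grubbs: `G = max |x - mean| / sd` compared to the
#' t-based critical value
#' `((n-1)/sqrt(n)) sqrt(t^2 / (n - 2 + t^2))` with
#' `t = qt(1 - alpha/(2n), n-2)`; the most extreme point is removed and
#' the test repeated until no rejection. A zero-variance sample yields no
#' outliers.
#'
#' @param x numeric vector, length >= 3
#' @param alpha significance level (default 0.05)
#' @return integer indices of flagged points in the original vector
#' @export
grubbs_outliers <- function(x, alpha = 0.05) {
  if (length(x) < 3) stop_invalid("Grubbs test needs n >= 3")
  idx <- seq_along(x)
  flagged <- integer(0)
  while (length(idx) >= 3) {
    v <- x[idx]
    s <- sd(v)
    if (!is.finite(s) || s == 0) break
    dev <- abs(v - mean(v))
    G <- max(dev) / s
    n <- length(v)
    tcrit <- qt(1 - alpha / (2 * n), n - 2)
    crit <- ((n - 1) / sqrt(n)) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
    if (G > crit) {
      worst <- idx[which.max(dev)]
      flagged <- c(flagged, worst)
      idx <- setdiff(idx, worst)
    } else break
  }
  sort(flagged)
}

#' Apply ordered exclusion rules with per-rule accounting
#'
#' Rules are applied in the given order; a record excluded by several
#' rules is counted once, under the first matching rule, so per-rule
#' counts always sum to input minus output.
#'
#' @param records data.frame of subject records
#' @param rules named list of predicate functions; each takes `records`
#'   and returns a logical vector (TRUE = exclude)
#' @return list: `records` (retained), `accounting` (data.frame rule /
#'   n_excluded in rule order), `n_input`, `n_retained`
#' @export
apply_cohort_exclusions <- function(records, rules) {
  if (!length(rules)) {
    return(list(records = records,
                accounting = data.frame(rule = character(0),
                                        n_excluded = integer(0)),
                n_input = nrow(records), n_retained = nrow(records)))
  }
  excluded_by <- rep(NA_character_, nrow(records))
  for (rn in names(rules)) {
    hit <- rules[[rn]](records)
    hit[is.na(hit)] <- FALSE
    excluded_by[is.na(excluded_by) & hit] <- rn
  }
  acc <- data.frame(rule = names(rules),
                    n_excluded = vapply(names(rules), function(rn)
                      sum(excluded_by == rn, na.rm = TRUE), integer(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  keep <- is.na(excluded_by)
  list(records = records[keep, , drop = FALSE], accounting = acc,
       n_input = nrow(records), n_retained = sum(keep))
}

#' Published coefficients for derived clinical indices
#'
#' Unit conversions and formula coefficients used by [derive_indices()]:
#' mmol/l to mg/dl factors, the closed-form HOMA surrogate denominators,
#' the Stumvoll insulin-sensitivity-index coefficients (BMI, 2-h insulin
#' in pmol/l, 2-h glucose in mmol/l), and the 4-variable MDRD eGFR
#' coefficients. All are configuration, overridable per analysis.
#' @return named list of coefficients
#' @export
index_coefficients <- function() {
  list(glucose_mgdl_per_mmol = 18.016,
       tg_mgdl_per_mmol = 88.57,
       insulin_pmol_per_mU = 6.945,
       homa_denominator = 22.5,
       homa_b_numerator = 20,
       homa_b_glucose_offset = 3.5,
       stumvoll = c(intercept = 0.226, bmi = -0.0032,
                    insulin_120 = -0.0000645, glucose_120 = -0.0037),
       mdrd = c(factor = 175, scr_exp = -1.154, age_exp = -0.203,
                female = 0.742, black = 1.212))
}

#' Derived insulin-resistance and kidney-function indices
#'
#' Computes, per record:
#' * TyG = `ln(TG[mg/dl] x glucose[mg/dl] / 2)`
#' * QUICKI = `1 / (log10 insulin[uU/ml] + log10 glucose[mg/dl])`
#' * HOMA-IR surrogate = `glucose[mmol/l] x insulin[mU/l] / 22.5` and
#'   HOMA-B surrogate = `20 x insulin / (glucose - 3.5)` — closed-form
#'   surrogates for the iterative HOMA2 computer model, labelled as such
#' * Stumvoll insulin sensitivity index from BMI and 2-h OGTT values
#' * MDRD eGFR from serum creatinine, age, sex, ethnicity
#'
#' Glucose and triglycerides are expected in mmol/l, insulin in mU/l
#' (= uU/ml); conversions to mg/dl and pmol/l are applied internally.
#'
#' @param records data.frame with columns `glucose`, `insulin`,
#'   `triglycerides`, `bmi`, `glucose_120`, `insulin_120`,
#'   `serum_creatinine`, `age`, `sex`, `ethnicity`
#' @param coefficients see [index_coefficients()]
#' @return data.frame of indices, one row per record
#' @export
derive_indices <- function(records, coefficients = index_coefficients()) {
  co <- coefficients
  for (f in c("glucose", "insulin", "triglycerides"))
    if (any(records[[f]] <= 0, na.rm = TRUE))
      stop_invalid("non-positive value in field '", f, "'")
  glu_mgdl <- records$glucose * co$glucose_mgdl_per_mmol
  tg_mgdl <- records$triglycerides * co$tg_mgdl_per_mmol
  tyg <- log(tg_mgdl * glu_mgdl / 2)
  quicki <- 1 / (log10(records$insulin) + log10(glu_mgdl))
  homa_ir <- records$glucose * records$insulin / co$homa_denominator
  homa_b <- ifelse(records$glucose > co$homa_b_glucose_offset,
                   co$homa_b_numerator * records$insulin /
                     (records$glucose - co$homa_b_glucose_offset), NA_real_)
  st <- co$stumvoll
  stumvoll <- if (all(c("glucose_120", "insulin_120", "bmi") %in%
                      names(records)))
    st["intercept"] + st["bmi"] * records$bmi +
      st["insulin_120"] * records$insulin_120 * co$insulin_pmol_per_mU +
      st["glucose_120"] * records$glucose_120
  else NA_real_
  md <- co$mdrd
  egfr <- if (all(c("serum_creatinine", "age", "sex", "ethnicity") %in%
                  names(records)))
    md["factor"] * records$serum_creatinine^md["scr_exp"] *
      records$age^md["age_exp"] *
      ifelse(records$sex == "female", md["female"], 1) *
      ifelse(records$ethnicity == "black", md["black"], 1)
  else NA_real_
  data.frame(tyg = tyg, quicki = quicki, homa_ir = as.numeric(homa_ir),
             homa_b = as.numeric(homa_b),
             stumvoll_isi = as.numeric(stumvoll),
             egfr_mdrd = as.numeric(egfr))
}

#' Harris-Benedict basal metabolic rate
#'
#' Original Harris-Benedict coefficients: women
#' `655.0955 + 9.5634 w + 1.8496 h - 4.6756 a`, men
#' `66.473 + 13.7516 w + 5.0033 h - 6.755 a`
#' (w in kg, h in cm, a in years).
#'
#' @param sex "male"/"female" (vectorized)
#' @param weight_kg,height_cm,age_years positive anthropometrics
#' @return kcal/day
#' @export
harris_benedict_bmr <- function(sex, weight_kg, height_cm, age_years) {
  if (!all(sex %in% c("male", "female")))
    stop_invalid("sex must be 'male' or 'female'")
  if (any(weight_kg <= 0) || any(height_cm <= 0) || any(age_years <= 0))
    stop_invalid("anthropometrics must be positive")
  ifelse(sex == "female",
         655.0955 + 9.5634 * weight_kg + 1.8496 * height_cm -
           4.6756 * age_years,
         66.473 + 13.7516 * weight_kg + 5.0033 * height_cm -
           6.755 * age_years)
}

#' Flag aberrant self-reported energy intake
#'
#' Excludes a declaration iff energy < `lower` x BMR or
#' energy > `upper` x BMR (defaults 0.5 and 3.5; the bounds themselves
#' are kept).
#'
#' @param energy_kcal reported daily energy intake
#' @param bmr_kcal Harris-Benedict BMR
#' @param lower,upper multiplicative plausibility bounds
#' @return logical, TRUE = exclude
#' @export
energy_intake_exclusion <- function(energy_kcal, bmr_kcal, lower = 0.5,
                                    upper = 3.5) {
  if (any(bmr_kcal <= 0)) stop_invalid("bmr must be positive")
  energy_kcal < lower * bmr_kcal | energy_kcal > upper * bmr_kcal
}

#' Dietary histidine intake from food-group intakes
#'
#' `sum_groups intake[g/day] x content[mg/g] / 1000`, in g/day.
#'
#' @param intakes named numeric vector, or samples x groups matrix, of
#'   g/day intakes
#' @param composition named numeric vector of histidine content (mg per
#'   g of food) covering every intake group
#' @return numeric g/day (scalar or per-sample vector)
#' @export
compute_histidine_intake <- function(intakes, composition) {
  if (is.null(dim(intakes)))
    intakes <- matrix(intakes, 1, dimnames = list(NULL, names(intakes)))
  miss <- setdiff(colnames(intakes), names(composition))
  if (length(miss))
    stop_invalid("no histidine content for group(s): ",
                 paste(miss, collapse = ", "))
  out <- as.numeric(intakes %*% composition[colnames(intakes)]) / 1000
  if (length(out) == 1) out else setNames(out, rownames(intakes))
}

#' Default diet-quality score configuration
#'
#' Simplified, configurable component definitions: each score is the
#' mean cohort-percentile rank of its components (reversed for adverse
#' components) scaled to 0-10. These are deliberately simplified analogs
#' of the published aHEI / DASH / Mediterranean definitions.
#' @return named list of score configurations
#' @export
default_diet_score_config <- function() {
  comp <- function(groups, direction)
    list(groups = groups, direction = direction)
  list(
    aHEI = list(
      veg = comp(c("leafy_vegetables", "other_vegetables"), "higher"),
      fruit = comp(c("fruits", "berries"), "higher"),
      whole_grains = comp("whole_grains", "higher"),
      nuts_legumes = comp(c("nuts", "legumes"), "higher"),
      red_processed_meat = comp(c("red_meat", "processed_meat"), "lower"),
      sugar = comp(c("sugar_sweetened_beverages", "sweets"), "lower")),
    DASH = list(
      fruit = comp(c("fruits", "berries"), "higher"),
      veg = comp(c("leafy_vegetables", "other_vegetables"), "higher"),
      whole_grains = comp("whole_grains", "higher"),
      dairy = comp(c("milk", "yogurt"), "higher"),
      red_processed_meat = comp(c("red_meat", "processed_meat"), "lower"),
      sweets = comp(c("sweets", "cakes_biscuits"), "lower"),
      ssb = comp("sugar_sweetened_beverages", "lower")),
    mediterranean = list(
      veg = comp(c("leafy_vegetables", "other_vegetables"), "higher"),
      fruit = comp(c("fruits", "berries"), "higher"),
      legumes = comp("legumes", "higher"),
      fish = comp(c("fish", "shellfish"), "higher"),
      whole_grains = comp("whole_grains", "higher"),
      nuts = comp("nuts", "higher"),
      red_meat = comp(c("red_meat", "processed_meat"), "lower"),
      dairy = comp(c("milk", "cheese", "butter"), "lower")))
}

simple_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %%
            .Machine$integer.max)
}

#' Diet-quality scores from food-group intakes
#'
#' DDS is the number of distinct food groups with nonzero intake. The
#' remaining scores are configurable sums of component sub-scores; the
#' default configuration scores each component by its cohort percentile
#' rank (reversed for adverse components) and averages to a 0-10 scale.
#' Each score is reported with the hash of its configuration.
#'
#' @param intakes samples x groups intake matrix (g/day)
#' @param config see [default_diet_score_config()]
#' @return data.frame: `dds`, one column per configured score, and
#'   attribute `config_hash`
#' @export
compute_diet_scores <- function(intakes, config = default_diet_score_config()) {
  if (!is.list(config) || is.null(names(config)))
    stop_invalid("malformed diet score config")
  n <- nrow(intakes)
  out <- data.frame(dds = as.integer(rowSums(intakes > 0)))
  pct <- function(v) if (all(v == v[1])) rep(0.5, length(v)) else
    (rank(v) - 0.5) / length(v)
  for (sc in names(config)) {
    parts <- lapply(config[[sc]], function(cp) {
      if (is.null(cp$groups) || is.null(cp$direction))
        stop_invalid("malformed diet score config component in ", sc)
      g <- intersect(cp$groups, colnames(intakes))
      if (!length(g)) return(rep(0.5, n))
      v <- pct(rowSums(intakes[, g, drop = FALSE]))
      if (cp$direction == "lower") 1 - v else v
    })
    out[[sc]] <- 10 * Reduce(`+`, parts) / length(parts)
  }
  attr(out, "config_hash") <- simple_hash(config)
  out
}

#' Quartile stratification
#'
#' Cuts at the empirical 25/50/75 percentiles (type-7 interpolation);
#' values tied with a cut point go to the lower quartile.
#'
#' @param values numeric vector, n >= 4
#' @return factor with levels Q1-Q4, named like `values` if named
#' @export
quartile_stratify <- function(values) {
  if (length(values) < 4) stop_invalid("need n >= 4 for quartiles")
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  lab <- 1L + (values > q[1]) + (values > q[2]) + (values > q[3])
  factor(paste0("Q", lab), levels = paste0("Q", 1:4))
}

#' Multinomial odds ratios across exposure quartiles
#'
#' Maximum-likelihood multinomial logit of a 3-class outcome on exposure
#' quartiles plus covariates; odds ratios are exponentiated coefficients
#' for Q2-Q4 versus Q1, per outcome class versus the reference class,
#' with Wald 95% confidence intervals. Apparent separation (huge
#' coefficients or non-convergence) is flagged, never silently
#' reported.
#'
#' @param outcome factor; first level is the reference class (healthy)
#' @param exposure factor of quartile labels; first level is the
#'   reference exposure (Q1)
#' @param covariates optional data.frame of adjustment covariates
#' @return data.frame: outcome class, contrast, `or`, `ci_lo`, `ci_hi`,
#'   `p`, `n`, `flag`
#' @export
fit_multinomial_or <- function(outcome, exposure, covariates = NULL) {
  df <- data.frame(.y = factor(outcome), .x = factor(exposure))
  if (!is.null(covariates)) df <- cbind(df, covariates)
  df <- df[complete.cases(df), , drop = FALSE]
  df <- drop_degenerate(df, keep = c(".y", ".x"))
  fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = 1000,
                        reltol = 1e-14)
  sm <- summary(fit)
  co <- coef(fit); se <- sm$standard.errors
  if (is.null(dim(co))) {  # binary outcome: coerce to 1-row matrices
    co <- matrix(co, 1, dimnames = list(levels(df$.y)[2], names(co)))
    se <- matrix(se, 1, dimnames = dimnames(co))
  }
  terms <- grep("^\\.x", colnames(co), value = TRUE)
  flag <- if (fit$convergence != 0) "non-convergence"
          else if (any(abs(co[, terms]) > 15)) "possible separation"
          else NA_character_
  rows <- expand.grid(class = rownames(co), term = terms,
                      stringsAsFactors = FALSE)
  est <- mapply(function(cl, tm) co[cl, tm], rows$class, rows$term)
  ses <- mapply(function(cl, tm) se[cl, tm], rows$class, rows$term)
  data.frame(outcome_class = rows$class,
             contrast = paste0(sub("^\\.x", "", rows$term), "_vs_",
                               levels(df$.x)[1]),
             or = exp(est), ci_lo = exp(est - 1.96 * ses),
             ci_hi = exp(est + 1.96 * ses),
             p = 2 * pnorm(-abs(est / ses)), n = nrow(df), flag = flag,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Covariate-adjusted partial correlation
#'
#' Correlates the residuals of `x` and `y` after least-squares
#' projection on the covariates (plus intercept). The Spearman variant
#' ranks all variables before projection. P-values use the t
#' distribution with `n - 2 - k` degrees of freedom (k = number of
#' independent covariate columns); the 95% CI uses the Fisher
#' z-transform. Aliased (collinear or constant) covariate columns are
#' dropped by the pivoted QR projection, so adding a zero-variance
#' covariate leaves the result unchanged.
#'
#' @param x,y numeric vectors
#' @param covariates optional data.frame/matrix of covariates
#' @param method "pearson" or "spearman"
#' @return data.frame: `estimate`, `ci_lo`, `ci_hi`, `p`, `n`, `df`,
#'   `method`
#' @export
partial_correlation <- function(x, y, covariates = NULL,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    cc <- complete.cases(x, y, covariates)
    covariates <- covariates[cc, , drop = FALSE]
  } else cc <- complete.cases(x, y)
  x <- x[cc]; y <- y[cc]
  n <- length(x)
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
    if (!is.null(covariates))
      covariates <- as.data.frame(lapply(covariates, function(v)
        if (is.numeric(v)) rank(v) else v))
  }
  if (is.null(covariates) || ncol(covariates) == 0) {
    k <- 0; rx <- x; ry <- y
  } else {
    X <- model.matrix(~ ., data = covariates)
    qx <- qr(X)
    k <- qx$rank - 1
    rx <- qr.resid(qx, x); ry <- qr.resid(qx, y)
  }
  if (n <= k + 2) stop_invalid("need n > number of covariates + 2")
  r <- cor(rx, ry)
  dfree <- n - 2 - k
  tval <- r * sqrt(dfree / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tval), dfree)
  zse <- 1 / sqrt(max(n - 3 - k, 1))
  ci <- tanh(atanh(min(max(r, -1 + 1e-15), 1 - 1e-15)) +
               c(-1.96, 1.96) * zse)
  data.frame(estimate = r, ci_lo = ci[1], ci_hi = ci[2], p = p, n = n,
             df = dfree, method = method, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH with monotonicity enforcement (as implemented by
#' `p.adjust`), after validating that inputs lie in `[0, 1]`.
#'
#' @param pvalues numeric p-values in `[0, 1]`
#' @return q-values, same length
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop_invalid("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Skewness-gated log transform
#'
#' Shapiro-Wilk on the raw values; if P < `alpha` the variable is
#' natural-log transformed (requiring positivity). Degenerate inputs
#' (constant, or too few values for the test) are passed through
#' untransformed with a flag. For n > 5000 the test runs on an
#' evenly-spaced subsample, as Shapiro-Wilk is capped at 5000.
#'
#' @param values numeric vector
#' @param alpha normality test level (default 0.05)
#' @return list: `values` (possibly transformed), `transformed`,
#'   `shapiro_p`, `flag`
#' @export
log_transform_policy <- function(values, alpha = 0.05) {
  v <- values[!is.na(values)]
  if (length(v) < 3 || sd(v) == 0)
    return(list(values = values, transformed = FALSE,
                shapiro_p = NA_real_, flag = "degenerate"))
  test_v <- if (length(v) > 5000)
    v[round(seq(1, length(v), length.out = 5000))] else v
  p <- shapiro.test(test_v)$p.value
  if (p < alpha) {
    if (any(v <= 0))
      stop_invalid("cannot log-transform: non-positive values present")
    list(values = log(values), transformed = TRUE, shapiro_p = p,
         flag = NA_character_)
  } else {
    list(values = values, transformed = FALSE, shapiro_p = p,
         flag = NA_character_)
  }
}

#' Linear group comparison with covariates
#'
#' Least-squares fit of the response on group indicators plus
#' covariates; the overall group P-value is the joint
#' (`levels - 1`)-df F test comparing the fit against the
#' covariates-only model. With two groups and no covariates this equals
#' the equal-variance two-sample t-test.
#'
#' @param response numeric response (transform beforehand if desired)
#' @param group factor; first level is the reference
#' @param covariates optional data.frame
#' @return data.frame: one row per non-reference level (`estimate` =
#'   adjusted difference vs reference, `se`, `p_level`) plus columns
#'   `p_overall` and `n`
#' @export
linear_group_comparison <- function(response, group, covariates = NULL) {
  df <- data.frame(.y = response, .g = factor(group))
  if (!is.null(covariates)) df <- cbind(df, covariates)
  df <- df[complete.cases(df), , drop = FALSE]
  df <- drop_degenerate(df, keep = c(".y", ".g"))
  df$.g <- droplevels(df$.g)
  if (nlevels(df$.g) < 2)
    stop_invalid("fewer than 2 groups present after filtering")
  full <- lm(.y ~ ., data = df)
  null <- lm(.y ~ . - .g, data = df)
  a <- anova(null, full)
  p_overall <- a[["Pr(>F)"]][2]
  sm <- summary(full)$coefficients
  gterms <- grep("^\\.g", rownames(sm), value = TRUE)
  data.frame(level = sub("^\\.g", "", gterms),
             estimate = sm[gterms, 1], se = sm[gterms, 2],
             p_level = sm[gterms, 4], p_overall = p_overall,
             n = nrow(df), row.names = NULL, stringsAsFactors = FALSE)
}

#' Residualized random-forest taxon importance
#'
#' Regression forest of (already covariate-adjusted) ImP residuals on a
#' taxon abundance matrix, with configured `mtry` and maximum node
#' count; importance is the increase in node purity, averaged over
#' `n_folds` resampling folds (each fold refits the forest on a random
#' ~80% subsample). Features are also screened by Spearman correlation
#' against the residuals with BH-FDR across taxa.
#'
#' @param residuals numeric vector of adjusted ImP residuals
#' @param abundance samples x taxa matrix (>= 2 columns)
#' @param mtry variables tried per split (default `ncol/3`)
#' @param max_nodes maximum terminal nodes per tree (default 50)
#' @param n_folds resampling folds (default 100; reduced with a warning
#'   when there are fewer samples than folds)
#' @param ntree trees per fold (default 100)
#' @param seed integer seed
#' @return data.frame ranked by mean importance: `taxon`, `importance`,
#'   `rho`, `p`, `q`
#' @export
rf_motu_importance <- function(residuals, abundance, mtry = NULL,
                               max_nodes = 50, n_folds = 100, ntree = 100,
                               seed = 1L) {
  abundance <- as.matrix(abundance)
  if (ncol(abundance) < 2) stop_invalid("need at least 2 taxa")
  n <- length(residuals)
  if (n < n_folds) {
    warning("fewer samples than folds; reducing folds to ", n)
    n_folds <- n
  }
  if (is.null(mtry)) mtry <- max(1, floor(ncol(abundance) / 3))
  set.seed(seed)
  imp <- matrix(0, n_folds, ncol(abundance))
  m <- max(2, floor(0.8 * n))
  max_nodes <- min(max_nodes, m)  # a tree cannot have more leaves
  for (f in seq_len(n_folds)) {
    idx <- sample.int(n, m)
    rf <- randomForest::randomForest(
      x = abundance[idx, , drop = FALSE], y = residuals[idx],
      mtry = mtry, maxnodes = max_nodes, ntree = ntree)
    imp[f, ] <- randomForest::importance(rf)[, "IncNodePurity"]
  }
  rho <- apply(abundance, 2, function(v)
    suppressWarnings(cor(v, residuals, method = "spearman")))
  pr <- apply(abundance, 2, function(v)
    suppressWarnings(stats::cor.test(v, residuals,
                                     method = "spearman", exact = FALSE)$p.value))
  out <- data.frame(taxon = colnames(abundance) %||%
                      paste0("taxon_", seq_len(ncol(abundance))),
                    importance = colMeans(imp), rho = rho, p = pr,
                    q = bh_fdr(pr), stringsAsFactors = FALSE)
  out[order(-out$importance), ]
}

#' Covariates of the nested adjustment models
#'
#' Model 1: age, sex, BMI, ethnicity. Model 2: Model 1 plus kidney
#' function (creatinine clearance). Model 3: Model 2 plus diabetes
#' status. The models are nested by construction.
#'
#' @param data cohort data.frame with the needed columns
#' @param model 1, 2 or 3
#' @return data.frame of covariates
#' @export
imp_model_covariates <- function(data, model = 2) {
  stopifnot(model %in% 1:3)
  cols <- c("age", "sex", "bmi", "ethnicity")
  if (model >= 2) cols <- c(cols, "creatinine_clearance")
  if (model >= 3) cols <- c(cols, "diabetes_status")
  data[, cols, drop = FALSE]
}
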