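# independent Grubbs critical value, restated from the t-based formula
grubbs_crit <- function(n, alpha = 0.05) {
  t2 <- qt(1 - alpha / (2 * n), n - 2)^2
  ((n - 1) / sqrt(n)) * sqrt(t2 / (n - 2 + t2))
}

test_that("iterative Grubbs flags the planted extreme and nothing else", {
  x <- c(1, 2, 3, 100)
  # independent check that the statistic actually exceeds the critical
  # value for this fixture
  G <- max(abs(x - mean(x))) / sd(x)
  expect_gt(G, grubbs_crit(4))
  expect_equal(grubbs_outliers(x), 4L)

  expect_length(grubbs_outliers(c(1, 1, 1, 1)), 0)  # sd = 0
  expect_length(grubbs_outliers(c(-5, 0, 5)), 0)
  expect_error(grubbs_outliers(c(1, 2)), "n >= 3")
})

test_that("exclusion accounting is ordered, disjoint and exact", {
  rec <- data.frame(a = c(TRUE, TRUE, FALSE, FALSE),
                    b = c(TRUE, FALSE, TRUE, FALSE))
  rules <- list(rule_a = function(r) r$a, rule_b = function(r) r$b)
  res <- apply_cohort_exclusions(rec, rules)
  # the record hit by both rules is attributed to the first
  expect_equal(res$accounting$n_excluded, c(2L, 1L))
  expect_equal(res$n_retained, 1)
  expect_equal(res$n_input - res$n_retained,
               sum(res$accounting$n_excluded))

  ident <- apply_cohort_exclusions(rec, list())
  expect_equal(ident$n_retained, 4)
})

test_that("derived indices match closed-form evaluations", {
  co <- index_coefficients()
  rec <- data.frame(glucose = 100 / co$glucose_mgdl_per_mmol,  # 100 mg/dl
                    insulin = 10,
                    triglycerides = 150 / co$tg_mgdl_per_mmol) # 150 mg/dl
  ix <- derive_indices(rec)
  expect_equal(ix$quicki, 1 / 3, tolerance = 1e-12)
  expect_equal(ix$tyg, log(7500), tolerance = 1e-12)

  rec2 <- data.frame(glucose = 5, insulin = 9, triglycerides = 1)
  expect_equal(derive_indices(rec2)$homa_ir, 2, tolerance = 1e-12)

  rec3 <- data.frame(glucose = -1, insulin = 9, triglycerides = 1)
  expect_error(derive_indices(rec3), "glucose")
})

test_that("Harris-Benedict BMR matches the published coefficients", {
  # woman, 70 kg, 165 cm, 50 y
  expect_equal(harris_benedict_bmr("female", 70, 165, 50), 1395.93,
               tolerance = 0.01)
  expect_error(harris_benedict_bmr("female", 0, 165, 50), "positive")
  expect_error(harris_benedict_bmr("unknown", 70, 165, 50), "sex")
  # strictly increasing in weight
  b <- harris_benedict_bmr("male", c(70, 80, 90), 180, 40)
  expect_true(all(diff(b) > 0))
})

test_that("aberrant energy declarations are excluded at 0.5/3.5 x BMR", {
  expect_true(energy_intake_exclusion(700, 1500))
  expect_false(energy_intake_exclusion(750, 1500))   # boundary kept
  expect_true(energy_intake_exclusion(6000, 1500))
  expect_false(energy_intake_exclusion(5250, 1500))  # boundary kept
})

test_that("histidine intake sums intake x content over groups", {
  comp <- c(meat = 20, veg = 10)
  expect_equal(compute_histidine_intake(c(meat = 100, veg = 0), comp), 2)
  expect_equal(compute_histidine_intake(c(meat = 0, veg = 0), comp), 0)
  expect_equal(compute_histidine_intake(c(meat = 50, veg = 50),
                                        c(meat = 10, veg = 10)), 1)
  expect_error(compute_histidine_intake(c(fish = 10), comp), "fish")
})

test_that("diet scores: DDS counts groups and is monotone", {
  groups <- default_food_composition()$group
  m <- matrix(0, 2, length(groups), dimnames = list(NULL, groups))
  m[1, 1:5] <- 10
  sc <- compute_diet_scores(m)
  expect_equal(sc$dds, c(5L, 0L))
  m2 <- m; m2[1, 6] <- 1
  expect_gt(compute_diet_scores(m2)$dds[1], sc$dds[1])
  expect_false(is.null(attr(sc, "config_hash")))
  expect_error(compute_diet_scores(m, config = list(1, 2)), "malformed")
})

test_that("quartile stratification ties go to the lower quartile", {
  q <- quartile_stratify(1:8)
  expect_equal(as.integer(table(q)), rep(2L, 4))
  expect_true(all(quartile_stratify(rep(3, 10)) == "Q1"))
  set.seed(4)
  u <- quartile_stratify(runif(1000))
  expect_true(all(abs(table(u) - 250) <= 2))
  expect_error(quartile_stratify(1:3), "n >= 4")
})

test_that("covariate-free multinomial OR equals the 2x2 cross-product", {
  # a=30 exposed-case, b=10 exposed-ctrl, c=10, d=30:
  # cross-product (30*30)/(10*10) = 9
  y <- factor(c(rep("case", 30), rep("ctrl", 10),
                rep("case", 10), rep("ctrl", 30)),
              levels = c("ctrl", "case"))
  x <- factor(c(rep("exposed", 40), rep("unexposed", 40)),
              levels = c("unexposed", "exposed"))
  fit <- fit_multinomial_or(y, x)
  expect_equal(fit$or, 9, tolerance = 1e-6)
  expect_true(is.na(fit$flag))

  set.seed(12)
  for (i in 1:8) {
    cells <- sample(5:30, 4, replace = TRUE)  # a, b, c, d
    y <- factor(rep(c("case", "ctrl", "case", "ctrl"), cells),
                levels = c("ctrl", "case"))
    x <- factor(rep(c("E", "E", "U", "U"), cells), levels = c("U", "E"))
    fit <- fit_multinomial_or(y, x)
    oracle <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    expect_equal(fit$or, oracle, tolerance = 1e-6)
  }
})

test_that("three-class multinomial ORs cover a planted effect", {
  set.seed(71)
  n <- 2000
  x <- factor(sample(paste0("Q", 1:4), n, replace = TRUE),
              levels = paste0("Q", 1:4))
  # planted OR 2.76 for Q4 vs Q1 on the type2diabetes contrast
  lin_t2d <- log(0.5) + log(2.76) * (x == "Q4")
  lin_pre <- log(0.5) + log(1.75) * (x == "Q4")
  den <- 1 + exp(lin_pre) + exp(lin_t2d)
  u <- runif(n)
  p_h <- 1 / den; p_p <- exp(lin_pre) / den
  y <- ifelse(u < p_h, "healthy",
              ifelse(u < p_h + p_p, "prediabetes", "type2diabetes"))
  fit <- fit_multinomial_or(factor(y, levels = c("healthy", "prediabetes",
                                                 "type2diabetes")), x)
  row <- fit[fit$outcome_class == "type2diabetes" &
               fit$contrast == "Q4_vs_Q1", ]
  expect_true(row$ci_lo < 2.76 && 2.76 < row$ci_hi)
})

test_that("partial correlation equals the residual-based oracle", {
  set.seed(9)
  n <- 150
  z1 <- rnorm(n); z2 <- rnorm(n)
  x <- 0.8 * z1 + rnorm(n); y <- -0.5 * z1 + 0.3 * z2 + rnorm(n)
  cov <- data.frame(z1 = z1, z2 = z2)
  pc <- partial_correlation(x, y, cov)
  rx <- resid(lm(x ~ z1 + z2)); ry <- resid(lm(y ~ z1 + z2))
  expect_equal(pc$estimate, cor(rx, ry), tolerance = 1e-10)
  expect_equal(pc$df, n - 4)

  # no covariates reduces to the plain correlation
  expect_equal(partial_correlation(x, y)$estimate, cor(x, y),
               tolerance = 1e-12)
  expect_equal(partial_correlation(x, x)$estimate, 1)

  # spearman variant ranks before projecting
  ps <- partial_correlation(x, y, cov, method = "spearman")
  rrx <- resid(lm(rank(x) ~ rank(z1) + rank(z2)))
  rry <- resid(lm(rank(y) ~ rank(z1) + rank(z2)))
  expect_equal(ps$estimate, cor(rrx, rry), tolerance = 1e-10)

  # x, y driven only by a covariate: partial r near zero
  x2 <- z1 + rnorm(n, 0, 0.3); y2 <- z1 + rnorm(n, 0, 0.3)
  expect_lt(abs(partial_correlation(x2, y2,
                                    data.frame(z1 = z1))$estimate), 0.2)
})

test_that("a zero-variance extra covariate leaves partial r unchanged", {
  set.seed(10)
  n <- 80
  x <- rnorm(n); y <- rnorm(n); z <- rnorm(n)
  m2 <- partial_correlation(x, y, data.frame(z = z))
  m3 <- partial_correlation(x, y, data.frame(z = z, status = rep(1, n)))
  expect_identical(m2$estimate, m3$estimate)
  expect_identical(m2$df, m3$df)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.037), 0.037)
  set.seed(2)
  p <- runif(30)
  q <- bh_fdr(p)
  # hand step-up: sorted p * m/i, then running minimum from the back
  ps <- sort(p)
  q_hand <- rev(cummin(rev(pmin(ps * 30 / seq_len(30), 1))))
  expect_equal(sort(q), q_hand, tolerance = 1e-12)
  expect_true(all(diff(sort(q)) >= -1e-12))
  expect_true(all(q >= p - 1e-12))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("the log-transform policy fires on skewed data only", {
  set.seed(14)
  ln <- exp(rnorm(200))
  res <- log_transform_policy(ln)
  expect_true(res$transformed)
  expect_equal(res$values, log(ln))

  nm <- rnorm(200)
  res2 <- log_transform_policy(nm)
  expect_false(res2$transformed)

  res3 <- log_transform_policy(rep(5, 50))
  expect_false(res3$transformed)
  expect_equal(res3$flag, "degenerate")
})

test_that("linear group comparison nests the two-sample t-test", {
  set.seed(15)
  y <- c(rnorm(40), rnorm(40, 0.3))
  g <- factor(rep(c("a", "b"), each = 40))
  res <- linear_group_comparison(y, g)
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(res$p_overall[1], tt$p.value, tolerance = 1e-10)
  expect_equal(res$estimate[1], unname(diff(tt$estimate)),
               tolerance = 1e-10)

  # planted 0.5 SD shift at n = 600 is detected
  y2 <- c(rnorm(300), rnorm(300, 0.5))
  g2 <- factor(rep(c("a", "b"), each = 300))
  expect_lt(linear_group_comparison(y2, g2)$p_overall[1], 0.05)
})

test_that("random-forest importance surfaces planted taxa", {
  set.seed(16)
  n <- 300; p <- 50
  ab <- matrix(rnorm(n * p), n, p,
               dimnames = list(NULL, paste0("taxon_", 1:p)))
  ab[, p] <- 0  # constant taxon
  resids <- 0.6 * ab[, 1] + 0.6 * ab[, 2] + 0.6 * ab[, 3] + rnorm(n)
  imp <- rf_motu_importance(resids, ab, n_folds = 15, ntree = 60,
                            seed = 5)
  top10 <- imp$taxon[1:10]
  expect_true(all(c("taxon_1", "taxon_2", "taxon_3") %in% top10))
  const_rank <- which(imp$taxon == paste0("taxon_", p))
  expect_gt(const_rank, 0.9 * p)  # never in the top decile
  expect_warning(rf_motu_importance(resids[1:10], ab[1:10, ],
                                    n_folds = 100, ntree = 10),
                 "reducing folds")
})
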