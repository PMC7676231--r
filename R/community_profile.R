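#' MGS abundance via the 50-marker rule
#'
#' Per sample and metagenomic species (MGS): if strictly more than 10%
#' of the MGS's marker genes have positive FPKM signal, abundance is the
#' arithmetic mean of the marker FPKMs; otherwise exactly 0. The
#' detection rule makes abundance discontinuous at the 10% boundary by
#' design (5/50 positive markers give 0, 6/50 give a positive value).
#'
#' @param fpkm a `gene_count_table` at stage "fpkm"
#' @param defs list of MGS definitions (see
#'   [generate_mgs_definitions()])
#' @param detection_fraction detection threshold (default 0.10, strict)
#' @return samples x MGS matrix of abundances
#' @export
compute_mgs_abundance <- function(fpkm, defs, detection_fraction = 0.10) {
  out <- matrix(0, nrow(fpkm), length(defs),
                dimnames = list(rownames(fpkm),
                                vapply(defs, `[[`, character(1), "mgs_id")))
  for (j in seq_along(defs)) {
    markers <- defs[[j]]$markers
    miss <- setdiff(markers, colnames(fpkm))
    if (length(miss))
      stop_invalid("marker gene(s) absent from FPKM table for ",
                   defs[[j]]$mgs_id, ": ",
                   paste(head(miss, 3), collapse = ", "))
    sub <- fpkm[, markers, drop = FALSE]
    det <- rowMeans(sub > 0)
    ab <- rowMeans(sub)
    out[, j] <- ifelse(det > detection_fraction, ab, 0)
  }
  out
}

#' Collapse MGS abundances to genus pseudo-counts
#'
#' Sums MGS abundances by genus per sample, converts to proportions, and
#' scales to integer pseudo-counts (largest-remainder rounding, total
#' `pseudo_total` per sample) as required by the multinomial mixture
#' model. Samples with zero total abundance yield all-zero rows.
#'
#' @param mgs samples x MGS abundance matrix
#' @param defs list of MGS definitions carrying genus labels
#' @param pseudo_total integer pseudo-count total per sample
#'   (default 1e4)
#' @return samples x genus integer matrix
#' @export
collapse_to_genus <- function(mgs, defs, pseudo_total = 1e4) {
  genus <- vapply(defs, `[[`, character(1), "genus")
  genera <- unique(genus)
  agg <- sapply(genera, function(g)
    rowSums(mgs[, genus == g, drop = FALSE]))
  if (is.null(dim(agg))) agg <- matrix(agg, nrow = 1,
                                       dimnames = list(rownames(mgs), genera))
  counts <- t(apply(agg, 1, function(x) {
    s <- sum(x)
    if (s <= 0) return(rep(0L, length(x)))
    round_preserve_sum(x / s * pseudo_total)
  }))
  dimnames(counts) <- list(rownames(mgs), genera)
  storage.mode(counts) <- "integer"
  counts
}

# per-sample, per-component Dirichlet-multinomial log density, with the
# multinomial coefficient omitted (constant per sample: it cancels in
# responsibilities and in model comparisons at fixed data)
dm_logdens <- function(counts, alpha) {
  A <- sum(alpha)
  N <- rowSums(counts)
  lgamma(A) - lgamma(N + A) +
    rowSums(lgamma(sweep(counts, 2, alpha, "+"))) - sum(lgamma(alpha))
}

#' Dirichlet multinomial mixture log-likelihood
#'
#' `sum_s log sum_k pi_k DM(x_s | alpha_k)` with
#' `log DM(x | a) = lgamma(A) - lgamma(N + A) +
#'  sum_j [lgamma(x_j + a_j) - lgamma(a_j)]`, `A = sum_j a_j`,
#' `N = sum_j x_j`; the multinomial coefficient is omitted consistently.
#'
#' @param counts samples x categories integer matrix
#' @param model a `dmm_model` (see [fit_dmm()])
#' @return scalar log-likelihood
#' @export
dmm_loglik <- function(counts, model) {
  if (any(model$alpha <= 0)) stop_invalid("alpha must be positive")
  L <- sapply(seq_len(model$K), function(k)
    dm_logdens(counts, model$alpha[k, ]) + log(model$pi[k]))
  if (is.null(dim(L))) L <- matrix(L, nrow = nrow(counts))
  m <- apply(L, 1, max)
  sum(m + log(rowSums(exp(L - m))))
}

# weighted single-component DM maximization in log-alpha space
maximize_alpha <- function(counts, w, alpha0, floor = 1e-6) {
  obj <- function(eta) {
    a <- exp(eta)
    sum(w * dm_logdens(counts, a))
  }
  grad <- function(eta) {
    a <- exp(eta)
    A <- sum(a)
    N <- rowSums(counts)
    common <- sum(w * (digamma(A) - digamma(N + A)))
    percat <- colSums(w * (digamma(sweep(counts, 2, a, "+")) -
                             rep(digamma(a), each = nrow(counts))))
    a * (common + percat)
  }
  fit <- tryCatch(
    optim(log(alpha0), obj, grad, method = "L-BFGS-B",
          lower = log(floor), upper = log(1e6),
          control = list(fnscale = -1, maxit = 50)),
    error = function(e) NULL)
  if (is.null(fit) || fit$value < sum(w * dm_logdens(counts, alpha0)))
    return(alpha0)
  exp(fit$par)
}

#' Fit a Dirichlet multinomial mixture by EM
#'
#' E-step: responsibilities proportional to `pi_k DM(x | alpha_k)`.
#' M-step: mixture weights from responsibility means; each `alpha_k` by
#' bounded quasi-Newton ascent (L-BFGS-B in log-alpha space, analytic
#' gradient, floor 1e-6) of the responsibility-weighted DM
#' log-likelihood, started at the current value so the EM objective is
#' non-decreasing. Initialization: k-means on proportion vectors with
#' `n_init` seeded restarts; alphas start at cluster mean proportions
#' times a precision of 50; the restart with the best final
#' log-likelihood is kept.
#'
#' @param counts samples x categories integer matrix
#' @param K number of mixture components (>= 1)
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood
#'   gain drops below `tol` or after `max_iter` iterations
#' @param seed integer seed (initialization only; EM itself is
#'   deterministic)
#' @param n_init number of k-means restarts (default 5)
#' @return list of class `dmm_model`: `K`, `alpha` (K x J), `pi`,
#'   `responsibilities`, `loglik`, `loglik_trace`, `n_iter`, `converged`
#' @export
fit_dmm <- function(counts, K, max_iter = 200, tol = 1e-6, seed = 1L,
                    n_init = 5) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0) stop_invalid("counts is empty")
  if (K < 1 || nrow(counts) < K)
    stop_invalid("need K >= 1 and at least K samples")
  J <- ncol(counts)
  props <- counts / pmax(rowSums(counts), 1)
  best <- NULL
  for (init in seq_len(n_init)) {
    set.seed(derive_seed(seed, init))
    if (K == 1) {
      cl <- rep(1L, nrow(counts))
    } else {
      cl <- tryCatch(kmeans(props, K, nstart = 3)$cluster,
                     error = function(e)
                       sample.int(K, nrow(counts), replace = TRUE))
    }
    alpha <- t(sapply(seq_len(K), function(k) {
      if (!any(cl == k)) return(rep(1, J))
      p <- colMeans(props[cl == k, , drop = FALSE])
      pmax(p, 1e-4) * 50
    }))
    if (K == 1) alpha <- matrix(alpha, 1, J)
    pi_k <- pmax(tabulate(cl, K) / nrow(counts), 1e-6)
    pi_k <- pi_k / sum(pi_k)
    ll_old <- -Inf; trace <- numeric(0); converged <- FALSE; it <- 0
    resp <- NULL
    repeat {
      it <- it + 1
      L <- sapply(seq_len(K), function(k)
        dm_logdens(counts, alpha[k, ]) + log(pi_k[k]))
      if (is.null(dim(L))) L <- matrix(L, nrow = nrow(counts))
      m <- apply(L, 1, max)
      lse <- m + log(rowSums(exp(L - m)))
      ll <- sum(lse)
      trace <- c(trace, ll)
      resp <- exp(L - lse)
      if (ll - ll_old < tol && it > 1) {
        converged <- ll - ll_old >= -1e-8
        break
      }
      if (it >= max_iter) break
      ll_old <- ll
      pi_k <- pmax(colMeans(resp), 1e-10)
      pi_k <- pi_k / sum(pi_k)
      for (k in seq_len(K))
        alpha[k, ] <- maximize_alpha(counts, resp[, k], alpha[k, ])
    }
    cand <- list(K = K, alpha = alpha, pi = pi_k,
                 responsibilities = resp, loglik = ll,
                 loglik_trace = trace, n_iter = it, converged = converged)
    if (is.null(best) || cand$loglik > best$loglik) best <- cand
  }
  colnames(best$alpha) <- colnames(counts)
  class(best) <- "dmm_model"
  best
}

#' Select the number of DMM components by BIC
#'
#' `BIC = -2 loglik + p log(n)` with `p = K J + (K - 1)` free parameters;
#' returns the K in `K_range` minimizing BIC.
#'
#' @param counts samples x categories integer matrix
#' @param K_range candidate component counts
#' @param seed integer seed passed to [fit_dmm()]
#' @param ... further arguments to [fit_dmm()]
#' @return list: `K` (selected), `bic` (named vector), `models`
#' @export
select_n_components <- function(counts, K_range, seed = 1L, ...) {
  if (!length(K_range)) stop_invalid("K_range is empty")
  models <- lapply(K_range, function(K)
    fit_dmm(counts, K, seed = derive_seed(seed, K), ...))
  n <- nrow(counts); J <- ncol(counts)
  bic <- vapply(seq_along(K_range), function(i) {
    K <- K_range[i]
    -2 * models[[i]]$loglik + (K * J + (K - 1)) * log(n)
  }, numeric(1))
  names(bic) <- K_range
  list(K = K_range[which.min(bic)], bic = bic, models = models)
}

#' Assign enterotypes from a fitted DMM
#'
#' Labels each sample with its maximum-responsibility component and
#' annotates each component with its dominant genus (largest alpha
#' share) and, when a richness vector is supplied, the mean gene
#' richness of its members. The component combining a
#' `bacteroides_genus`-dominant profile with the lowest member mean
#' richness is tagged as the Bacteroides-2 analog — an operational
#' definition of the low-richness, Bacteroides-dominated community type.
#'
#' @param model a `dmm_model`
#' @param counts the genus count matrix the model was fitted on
#' @param richness optional named per-sample gene richness
#' @param bacteroides_genus genus name defining Bacteroides-like
#'   dominance (default "Bacteroides")
#' @return list of class `enterotype_assignment`: `labels` (named
#'   integer), `components` (per-component descriptor data.frame),
#'   `bacteroides2` (component index or NA)
#' @export
assign_enterotypes <- function(model, counts, richness = NULL,
                               bacteroides_genus = "Bacteroides") {
  labels <- max.col(model$responsibilities, ties.method = "first")
  names(labels) <- rownames(counts)
  share <- model$alpha / rowSums(model$alpha)
  dom <- colnames(model$alpha)[apply(share, 1, which.max)]
  mean_rich <- rep(NA_real_, model$K)
  if (!is.null(richness)) {
    r <- richness[rownames(counts)]
    mean_rich <- vapply(seq_len(model$K), function(k)
      mean(r[labels == k], na.rm = TRUE), numeric(1))
  }
  comp <- data.frame(component = seq_len(model$K), dominant_genus = dom,
                     dominant_share = apply(share, 1, max),
                     mean_richness = mean_rich, pi = model$pi,
                     stringsAsFactors = FALSE)
  bact <- which(dom == bacteroides_genus)
  b2 <- if (length(bact) && !all(is.na(mean_rich[bact])))
    bact[which.min(mean_rich[bact])] else NA_integer_
  structure(list(labels = labels, components = comp, bacteroides2 = b2),
            class = "enterotype_assignment")
}
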