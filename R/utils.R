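# internal helpers shared across modules

# Deterministic child seed; stays well below 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 1e6) * 1009 + (i %% 1e6) * 31 + 17) %% 2147483647L
}

stop_invalid <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Largest-remainder rounding of a non-negative vector to integers summing
# to round(sum(x)); ties broken by index order.
round_preserve_sum <- function(x) {
  stopifnot(all(x >= 0))
  target <- round(sum(x))
  fl <- floor(x)
  rem <- target - sum(fl)
  if (rem > 0) {
    ord <- order(x - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  as.integer(fl)
}

# draw truncated normal by rejection (bounds are loose plausibility clips)
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), if (length(mean) > 1) mean[bad] else mean,
                    if (length(sd) > 1) sd[bad] else sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

# drop categorical model columns left with a single observed level
# (after subsetting); numeric columns are kept regardless
drop_degenerate <- function(df, keep = character(0)) {
  ok <- vapply(names(df), function(nm) {
    nm %in% keep || is.numeric(df[[nm]]) ||
      length(unique(df[[nm]][!is.na(df[[nm]])])) >= 2
  }, logical(1))
  df[, ok, drop = FALSE]
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}
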