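#' @importFrom stats rnorm runif dnorm sd quantile median weighted.mean
#'   complete.cases aggregate integrate lm coef vcov BIC logLik as.formula
#'   setNames predict rbinom rpois
#' @importFrom utils head write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analysis age bands
#'
#' The adult age bands used throughout: 18-19, 20-29, then 10-year bands to
#' 70-79, and 80+. Band midpoints are used wherever age enters a regression
#' as a continuous term (80+ is assigned a nominal midpoint of 85).
#'
#' @return A data.frame with columns `band` (label), `lower`, `upper`
#'   (inclusive integer ages; `Inf` for the open-ended band) and `midpoint`.
#' @export
age_bands <- function() {
  data.frame(
    band = c("18-19", "20-29", "30-39", "40-49", "50-59", "60-69", "70-79", "80+"),
    lower = c(18, 20, 30, 40, 50, 60, 70, 80),
    upper = c(19, 29, 39, 49, 59, 69, 79, Inf),
    midpoint = c(19, 25, 35, 45, 55, 65, 75, 85),
    stringsAsFactors = FALSE
  )
}

#' Assign ages to analysis bands
#'
#' @param age Integer vector of ages in years.
#' @return Character vector of band labels; `NA` for ages under 18.
#' @export
assign_age_band <- function(age) {
  ab <- age_bands()
  idx <- findInterval(age, ab$lower)
  out <- rep(NA_character_, length(age))
  ok <- !is.na(age) & age >= 18
  out[ok] <- ab$band[idx[ok]]
  out
}

## Univariate slice sampler (Neal 2003, stepping-out + shrinkage).
## logf must be finite at x0.
slice_sample_1d <- function(logf, x0, w = 1, max_steps = 50L) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler started at a point with zero density")
  z <- f0 - stats::rexp(1)
  u <- runif(1)
  L <- x0 - w * u
  R <- L + w
  j <- floor(runif(1) * max_steps)
  k <- max_steps - 1 - j
  while (j > 0 && logf(L) > z) { L <- L - w; j <- j - 1 }
  while (k > 0 && logf(R) > z) { R <- R + w; k <- k - 1 }
  repeat {
    x1 <- runif(1, L, R)
    if (logf(x1) > z) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(x0)
  }
}

## Split-chain potential scale reduction factor on a single vector of draws
## (or a list of chains); each chain is split in half.
split_rhat <- function(draws) {
  chains <- if (is.list(draws)) draws else list(draws)
  halves <- list()
  for (ch in chains) {
    n <- length(ch)
    h <- floor(n / 2)
    halves <- c(halves, list(ch[seq_len(h)], ch[(n - h + 1):n]))
  }
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W < 1e-300) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

## Crude effective sample size from lag-autocorrelations (initial positive
## sequence truncation).
ess_basic <- function(x) {
  n <- length(x)
  if (stats::var(x) < 1e-300) return(n)
  acfs <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (r in acfs) {
    if (r < 0.05) break
    s <- s + r
  }
  n / (1 + 2 * s)
}

## Weighted mean and its design-based standard error (ratio estimator).
weighted_mean_se <- function(x, w) {
  if (any(w <= 0)) stop("nonpositive survey weights")
  wm <- sum(w * x) / sum(w)
  n <- length(x)
  if (n == 1) return(c(mean = wm, se = NA_real_, n = 1))
  v <- sum(w^2 * (x - wm)^2) / (sum(w)^2) * n / (n - 1)
  c(mean = wm, se = sqrt(v), n = n)
}

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")))
  }
  invisible(df)
}
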