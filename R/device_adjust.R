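#' Illustrative portable-device analytical ranges
#'
#' A small table of portable-device analytical ranges (mmol/l) used by the
#' synthetic pipeline and the examples. These ranges are synthetic,
#' illustrative values chosen to clip a realistic 10-20% of the population
#' distribution; they are not the ranges of any specific commercial device,
#' and real analyses must supply their own device table via
#' `read.csv()` into the same columns.
#'
#' @return data.frame with columns `device`, `metric`, `min`, `max`.
#' @export
device_ranges_example <- function() {
  data.frame(
    device = c("portable-A", "portable-A", "portable-B", "portable-B"),
    metric = c("total", "hdl", "total", "hdl"),
    min = c(3.60, 0.60, 3.10, 0.50),
    max = c(9.00, 2.60, 10.30, 3.00),
    stringsAsFactors = FALSE
  )
}

#' Truncate values to a device's analytical range
#'
#' Keeps exactly the values strictly inside the analytical range: values
#' below or at the minimum, and at or above the maximum, are dropped —
#' mirroring how devices report out-of-range concentrations as "low"/"high"
#' codes that cannot be used.
#'
#' @param values Numeric vector (mmol/l).
#' @param range_min,range_max Analytical range bounds.
#' @return The retained values.
#' @export
truncate_to_device <- function(values, range_min, range_max) {
  stopifnot(range_min < range_max)
  values[!is.na(values) & values > range_min & values < range_max]
}

#' Apply device truncation to record-level data
#'
#' For every device-measured record, measurements outside the device's
#' analytical range become missing (the participant is dropped from that
#' metric's mean). Laboratory records are untouched.
#'
#' @param records Record-level data with `device`, `tc`, `hdl` columns.
#' @param device_ranges Device table (device, metric, min, max).
#' @return The records with out-of-range values set to `NA`.
#' @export
truncate_records <- function(records, device_ranges) {
  for (i in seq_len(nrow(device_ranges))) {
    dr <- device_ranges[i, ]
    col <- switch(dr$metric, total = "tc", hdl = "hdl",
                  stop("device ranges apply to measured metrics total/hdl"))
    idx <- records$device == dr$device & !is.na(records[[col]]) &
      (records[[col]] <= dr$min | records[[col]] >= dr$max)
    records[[col]][idx] <- NA_real_
  }
  records
}

#' Build conversion-regression training pairs from laboratory studies
#'
#' For every laboratory-measured stratum (study by sex by age band) with at
#' least `min_n` individuals, computes the response (survey-weighted
#' full-range mean of the metric) and the predictor (the mean after dropping
#' values outside the given device's analytical range, mimicking what a
#' portable device would have recorded). For non-HDL the restricted-range
#' total and HDL means are carried as additional predictors.
#'
#' @param records Cleaned record-level data (laboratory studies only are
#'   used; other rows are ignored).
#' @param device_ranges Rows of the device table for one device id.
#' @param metric One of `"total"`, `"hdl"`, `"nonhdl"`.
#' @param min_n Minimum stratum size for inclusion (default 25).
#' @return data.frame with columns `study`, `sex`, `band`, `age_mid`,
#'   `full_mean`, `restr_mean`, `n_full`, `n_restr` and, for non-HDL,
#'   `tc_restr_mean`, `hdl_restr_mean`.
#' @export
make_training_pairs <- function(records, device_ranges, metric, min_n = 25) {
  stopifnot(metric %in% c("total", "hdl", "nonhdl"),
            length(unique(device_ranges$device)) == 1)
  lab <- records[records$device == "laboratory", , drop = FALSE]
  lab$band <- assign_age_band(lab$age)
  restr <- lab
  restr$device <- device_ranges$device[1]
  restr <- truncate_records(restr, device_ranges)

  value_of <- function(d) switch(metric,
    total = d$tc, hdl = d$hdl,
    nonhdl = ifelse(!is.na(d$tc) & !is.na(d$hdl), d$tc - d$hdl, NA_real_))
  key <- interaction(lab$study, lab$sex, lab$band, drop = TRUE)
  ab <- age_bands()
  rows <- lapply(split(seq_len(nrow(lab)), key), function(ix) {
    vf <- value_of(lab[ix, ])
    vr <- value_of(restr[ix, ])
    okf <- !is.na(vf); okr <- !is.na(vr)
    if (sum(okf) < min_n) return(NULL)
    if (sum(okr) < 2) return(NULL)
    w <- lab$weight[ix]
    row <- data.frame(
      study = lab$study[ix[1]], sex = lab$sex[ix[1]], band = lab$band[ix[1]],
      age_mid = ab$midpoint[match(lab$band[ix[1]], ab$band)],
      full_mean = sum(w[okf] * vf[okf]) / sum(w[okf]),
      restr_mean = sum(w[okr] * vr[okr]) / sum(w[okr]),
      n_full = sum(okf), n_restr = sum(okr), stringsAsFactors = FALSE)
    if (metric == "nonhdl") {
      oktc <- !is.na(restr$tc[ix]); okh <- !is.na(restr$hdl[ix])
      row$tc_restr_mean <- sum(w[oktc] * restr$tc[ix][oktc]) / sum(w[oktc])
      row$hdl_restr_mean <- sum(w[okh] * restr$hdl[ix][okh]) / sum(w[okh])
    }
    row
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) {
    stop("empty conversion training set: no laboratory stratum meets the size threshold")
  }
  rownames(out) <- NULL
  out
}

#' Fit a device-conversion regression with BIC term selection
#'
#' Regresses the full-range stratum mean on the restricted-range mean, age
#' (band midpoint) and sex, plus — for non-HDL — the restricted-range total
#' and HDL means. Pairwise interactions of the restricted mean with age and
#' sex (and, for non-HDL, of the total/HDL means with sex) are toggled on or
#' off by exhaustive search over candidate term sets; the model minimizing
#' the Bayesian information criterion is returned, with ties broken toward
#' fewer terms. Aliased terms in a rank-deficient design are dropped with a
#' warning.
#'
#' @param pairs Training pairs from [make_training_pairs()].
#' @param metric Metric being converted.
#' @param device Device id the model applies to.
#' @return Object of class `conversion_model`: coefficients, covariance,
#'   residual SD, selected formula, the BIC table over candidates, and
#'   fitting-set size.
#' @export
fit_conversion <- function(pairs, metric, device) {
  base_terms <- c("restr_mean", "age_mid", "sex")
  cand <- c("restr_mean:age_mid", "restr_mean:sex")
  if (metric == "nonhdl") {
    base_terms <- c(base_terms, "tc_restr_mean", "hdl_restr_mean")
    cand <- c(cand, "tc_restr_mean:sex", "hdl_restr_mean:sex")
  }
  pairs$sex <- factor(pairs$sex, levels = c("female", "male"))
  if (nrow(pairs) < length(base_terms) + 2) {
    stop("too few training pairs for the conversion regression")
  }
  ## single-sex training sets cannot identify sex terms
  if (length(unique(pairs$sex)) < 2) {
    base_terms <- setdiff(base_terms, "sex")
    cand <- grep(":sex", cand, value = TRUE, invert = TRUE)
  }
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), length(cand)))
  fits <- vector("list", nrow(subsets))
  tab <- data.frame(terms = character(nrow(subsets)), k = 0, bic = 0)
  for (i in seq_len(nrow(subsets))) {
    terms_i <- c(base_terms, cand[unlist(subsets[i, ])])
    f <- as.formula(paste("full_mean ~", paste(terms_i, collapse = " + ")))
    fit <- lm(f, data = pairs)
    fits[[i]] <- fit
    tab$terms[i] <- paste(terms_i, collapse = " + ")
    tab$k[i] <- length(coef(fit))
    tab$bic[i] <- BIC(fit)
  }
  ## minimize BIC; within numerical ties prefer the smaller model
  best_bic <- min(tab$bic)
  tied <- which(tab$bic <= best_bic + 1e-6)
  best <- tied[which.min(tab$k[tied])]
  fit <- fits[[best]]
  beta <- coef(fit)
  if (anyNA(beta)) {
    warning(sprintf("dropping aliased conversion terms: %s",
                    paste(names(beta)[is.na(beta)], collapse = ", ")))
  }
  keep <- !is.na(beta)
  structure(list(
    metric = metric, device = device,
    formula = stats::formula(fit), fit = fit,
    coef = beta[keep],
    vcov = vcov(fit)[keep, keep, drop = FALSE],
    sigma = summary(fit)$sigma,
    n = nrow(pairs), bic_table = tab, selected = tab$terms[best]
  ), class = "conversion_model")
}

#' Adjust a device-measured stratum mean to its laboratory equivalent
#'
#' Produces posterior-style draws of the laboratory-equivalent mean for one
#' device-measured stratum, propagating (i) the sampling uncertainty of the
#' restricted-range input mean, (ii) the uncertainty of the conversion
#' coefficients, and (iii) the regression residual.
#'
#' @param stratum One-row data.frame with `mean`, `se`, `band`, `sex`,
#'   `device` (and, for non-HDL, `tc_restr_mean`, `hdl_restr_mean`).
#' @param model A [fit_conversion()] model for the same metric and device.
#' @param n_draws Number of draws.
#' @param seed Integer seed.
#' @return Numeric vector of `n_draws` adjusted-mean draws.
#' @export
apply_conversion <- function(stratum, model, n_draws = 1000, seed = 1) {
  stopifnot(inherits(model, "conversion_model"))
  if (!is.null(stratum$device) && !is.na(stratum$device) &&
      stratum$device != model$device) {
    stop(sprintf("stratum measured on '%s' but model fitted for '%s'",
                 stratum$device, model$device))
  }
  set.seed(as.integer(seed))
  ab <- age_bands()
  se <- if (is.null(stratum$se) || is.na(stratum$se)) 0 else stratum$se
  nd <- data.frame(
    restr_mean = rnorm(n_draws, stratum$mean, se),
    age_mid = ab$midpoint[match(stratum$band, ab$band)],
    sex = factor(stratum$sex, levels = c("female", "male")))
  if (model$metric == "nonhdl") {
    nd$tc_restr_mean <- stratum$tc_restr_mean
    nd$hdl_restr_mean <- stratum$hdl_restr_mean
  }
  tt <- stats::delete.response(stats::terms(model$formula))
  X <- stats::model.matrix(tt, nd)[, names(model$coef), drop = FALSE]
  k <- length(model$coef)
  betas <- matrix(model$coef, nrow = n_draws, ncol = k, byrow = TRUE)
  if (max(abs(model$vcov)) > 1e-12) {
    L <- chol(model$vcov + diag(1e-12, k))
    betas <- betas + matrix(rnorm(n_draws * k), n_draws, k) %*% L
  }
  eps <- if (model$sigma > 1e-8) rnorm(n_draws, 0, model$sigma) else 0
  as.numeric(rowSums(X * betas) + eps)
}

#' Adjust all device-measured strata in a summary table
#'
#' Convenience wrapper: fits (or takes) one conversion model per device for
#' the given metric and replaces each device-measured stratum's mean and SE
#' with the mean and SD of its adjusted draws. A `provenance` column records
#' which strata were adjusted.
#'
#' @param strata Stratum-summary table (one metric).
#' @param models Named list of `conversion_model`s keyed by device id.
#' @param n_draws Draws per stratum.
#' @param seed Integer seed.
#' @return The strata table with adjusted `mean`/`se` and a `provenance`
#'   column (`"laboratory"` or `"device-adjusted"`).
#' @export
adjust_device_strata <- function(strata, models, n_draws = 500, seed = 1) {
  strata$provenance <- ifelse(strata$device == "laboratory",
                              "laboratory", "device-adjusted")
  dev_rows <- which(strata$device != "laboratory")
  for (j in seq_along(dev_rows)) {
    i <- dev_rows[j]
    m <- models[[strata$device[i]]]
    if (is.null(m)) stop(sprintf("no conversion model for device '%s'",
                                 strata$device[i]))
    draws <- apply_conversion(strata[i, ], m, n_draws = n_draws,
                              seed = seed + j)
    strata$mean[i] <- mean(draws)
    strata$se[i] <- sd(draws)
  }
  strata
}
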