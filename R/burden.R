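#' Illustrative relative-risk curves
#'
#' Age-specific relative risks per 1 mmol/l of non-HDL cholesterol above the
#' optimal level, for ischaemic heart disease (IHD) and ischaemic stroke.
#' These are synthetic, illustrative values with the qualitative shape seen
#' in cohort meta-analyses — proportional effects attenuate with age — and
#' are not the estimates of any published meta-analysis. Supply real curves
#' as a data.frame with the same columns.
#'
#' @return data.frame: cause, band, rr.
#' @export
rr_curves_example <- function() {
  ab <- age_bands()$band
  data.frame(
    cause = rep(c("ihd", "ischaemic_stroke"), each = length(ab)),
    band = rep(ab, 2),
    rr = c(1.80, 1.75, 1.65, 1.50, 1.38, 1.28, 1.20, 1.14,   # IHD
           1.45, 1.42, 1.35, 1.28, 1.22, 1.16, 1.11, 1.07),  # stroke
    stringsAsFactors = FALSE
  )
}

rr_for_band <- function(rr_curve, band) {
  ab <- age_bands()
  pos <- match(band, ab$band)
  have <- match(rr_curve$band, ab$band)
  if (anyNA(have)) stop("unknown age band in RR curve")
  ## bands beyond the curve's range inherit the nearest provided band's RR
  idx <- vapply(pos, function(p) which.min(abs(have - p)), 0L)
  rr_curve$rr[idx]
}

#' Population attributable fraction for a continuous exposure
#'
#' Computes the PAF for a normally distributed exposure (mean, SD) relative
#' to a counterfactual distribution centred in the theoretical-minimum band.
#' The relative risk is log-linear above the band midpoint and 1 below it:
#' `RR(x) = rr ^ max(0, x - mid)`. With `counterfactual = "midpoint"` the
#' counterfactual is normal at the band midpoint with the observed SD; with
#' `"uniform"` the counterfactual mean is averaged uniformly over the band.
#' Expectations are evaluated by adaptive quadrature.
#'
#' @param mean,sd Observed exposure mean and SD (mmol/l); `sd > 0`.
#' @param rr Relative risk per 1 mmol/l above the optimal band for this age
#'   band and cause.
#' @param tmrel Length-2 vector: the optimal band (default `c(1.8, 2.2)`).
#' @param counterfactual `"midpoint"` or `"uniform"`.
#' @return PAF in `[0, 1)` (negative when the observed mean is below the
#'   counterfactual).
#' @export
compute_paf <- function(mean, sd, rr, tmrel = c(1.8, 2.2),
                        counterfactual = c("midpoint", "uniform")) {
  counterfactual <- match.arg(counterfactual)
  stopifnot(sd > 0, rr > 0, tmrel[1] > 0, tmrel[1] < tmrel[2])
  mid <- base::mean(tmrel)
  logrr <- log(rr)
  erri <- function(mu) {
    f <- function(x) exp(logrr * pmax(0, x - mid)) * dnorm(x, mu, sd)
    v <- integrate(f, mu - 10 * sd, mu + 10 * sd, rel.tol = 1e-9)$value
    if (!is.finite(v)) stop("non-finite PAF integral")
    v
  }
  e_obs <- erri(mean)
  e_cf <- if (counterfactual == "midpoint") {
    erri(mid)
  } else {
    ms <- seq(tmrel[1], tmrel[2], length.out = 21)
    base::mean(vapply(ms, erri, 0))
  }
  (e_obs - e_cf) / e_obs
}

## Fast PAF evaluation for many means: quadrature on a grid + monotone
## spline interpolation (PAF is smooth and monotone in the mean).
paf_interpolator <- function(sd, rr, tmrel = c(1.8, 2.2),
                             counterfactual = "midpoint",
                             range_mean = c(1, 12), n_grid = 80) {
  g <- seq(range_mean[1], range_mean[2], length.out = n_grid)
  pafs <- vapply(g, function(m) compute_paf(m, sd, rr, tmrel, counterfactual), 0)
  if (all(diff(pafs) > 0)) {
    stats::splinefun(g, pafs, method = "hyman")
  } else {
    ## flat or non-monotone grid (e.g. RR = 1): plain interpolation
    stats::approxfun(g, pafs, rule = 2)
  }
}

#' Attributable deaths from posterior exposure draws
#'
#' For each cause, multiplies cause-specific deaths by the PAF evaluated at
#' every posterior draw of mean non-HDL cholesterol, giving attributable
#' deaths by country, year, sex and age band with credible intervals, plus
#' totals.
#'
#' @param surface A `posterior_surface` of mean non-HDL cholesterol (one
#'   sex).
#' @param exposure_sd Population SD of non-HDL cholesterol (scalar or named
#'   by band); not estimated by the trend model, so it must be supplied.
#' @param rr_curves data.frame (cause, band, rr).
#' @param deaths data.frame (cause, country, year, sex, band, deaths) for
#'   the sex of the surface; every combination of cause and surface cell
#'   that should contribute must be present.
#' @param tmrel,counterfactual Passed to [compute_paf()].
#' @return List: `cells` (summary data.frame with PAF and attributable-death
#'   percentiles per cause-country-year-band), `totals` (per-cause and
#'   overall draws and percentiles).
#' @export
attributable_deaths <- function(surface, exposure_sd, rr_curves, deaths,
                                tmrel = c(1.8, 2.2),
                                counterfactual = "midpoint") {
  draws <- surface$draws
  dn <- dimnames(draws)
  deaths <- deaths[deaths$sex == surface$sex, , drop = FALSE]
  if (any(deaths$deaths < 0)) stop("negative death counts")
  causes <- unique(rr_curves$cause)
  cell_rows <- list()
  total_draws <- list()
  nd <- dim(draws)[1]
  for (cz in causes) {
    rrc <- rr_curves[rr_curves$cause == cz, , drop = FALSE]
    dth <- deaths[deaths$cause == cz, , drop = FALSE]
    key <- paste(dth$country, dth$year, dth$band)
    want <- expand.grid(country = dn$country, year = dn$year, band = dn$band,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    want <- want[want$year %in% as.character(unique(dth$year)), , drop = FALSE]
    idx <- match(paste(want$country, want$year, want$band), key)
    if (anyNA(idx)) {
      miss <- head(paste(want$country, want$year, want$band)[is.na(idx)], 5)
      stop(sprintf("deaths table missing cell(s) for cause %s: %s%s",
                   cz, paste(miss, collapse = "; "),
                   if (sum(is.na(idx)) > 5) " ..." else ""))
    }
    tot <- numeric(nd)
    for (b in dn$band) {
      sdb <- if (length(exposure_sd) > 1) exposure_sd[[b]] else exposure_sd
      itp <- paf_interpolator(sdb, rr_for_band(rrc, b), tmrel, counterfactual)
      sub <- want[want$band == b, , drop = FALSE]
      di <- match(paste(sub$country, sub$year, sub$band), key)
      for (i in seq_len(nrow(sub))) {
        mdraws <- draws[, sub$country[i], sub$year[i], b]
        paf_d <- pmax(itp(mdraws), 0)
        ad <- paf_d * dth$deaths[di[i]]
        tot <- tot + ad
        cell_rows[[length(cell_rows) + 1]] <- data.frame(
          cause = cz, country = sub$country[i],
          year = as.integer(sub$year[i]), sex = surface$sex, band = b,
          deaths = dth$deaths[di[i]],
          paf_median = median(paf_d),
          attrib_lo2.5 = quantile(ad, 0.025),
          attrib_median = median(ad),
          attrib_hi97.5 = quantile(ad, 0.975),
          stringsAsFactors = FALSE)
      }
    }
    total_draws[[cz]] <- tot
  }
  all_tot <- Reduce(`+`, total_draws)
  cells <- do.call(rbind, cell_rows)
  rownames(cells) <- NULL
  summ <- function(v) c(lo2.5 = quantile(v, 0.025, names = FALSE),
                        median = median(v),
                        hi97.5 = quantile(v, 0.975, names = FALSE))
  list(cells = cells,
       totals = list(draws = c(total_draws, list(all = all_tot)),
                     summary = rbind(do.call(rbind, lapply(total_draws, summ)),
                                     all = summ(all_tot))))
}
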