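#' Configuration for a synthetic survey world
#'
#' Builds the configuration object consumed by [generate_world()],
#' [generate_studies()] and [generate_records()]. The synthetic world mirrors
#' the structure of multi-country lipid surveillance: countries nested in
#' regions nested in super-regions, smooth nonlinear time trends in mean
#' cholesterol (linear terms plus a second-order random walk), nonlinear
#' sex-specific age patterns, study-level offsets for subnational and
#' community samples, and a fraction of studies measured on range-restricted
#' portable devices.
#'
#' Variance components are on the mmol/l scale; slopes are per decade.
#' Defaults are chosen to emulate the composition of the real multi-country
#' lipid database: 36.3% national, 22.2% subnational and 41.5% community
#' studies, 10% of studies on portable devices, and roughly one country in
#' five with no data at all.
#'
#' @param n_super,n_regions,n_countries Sizes of the geographic hierarchy.
#' @param years Integer vector of calendar years covered by the world.
#' @param study_mix Named numeric vector of coverage-level proportions
#'   (national, subnational, community); must sum to 1.
#' @param device_fraction Probability that a study uses a portable device.
#' @param studies_per_country Mean number of studies for countries that have
#'   any data.
#' @param p_no_data Probability that a country has no studies at all.
#' @param n_per_stratum Target number of individuals per sex-age-band stratum.
#' @param sd_int Named vector of intercept random-effect SDs by level
#'   (super, region, country).
#' @param sd_slope Named vector of linear-slope (per decade) random-effect
#'   SDs by level.
#' @param rw2_sd Named vector of second-order random-walk innovation SDs by
#'   level (global, super, region, country).
#' @param sd_age_country SD of country-level perturbations of the cubic age
#'   polynomial coefficients.
#' @param hdl_scale Multiplier applied to all variance components for the HDL
#'   surface relative to total cholesterol.
#' @param slope_global Named vector: global linear trend per decade for
#'   total and HDL cholesterol.
#' @param sd_ind Named vector: within-stratum SD of individual total and HDL
#'   cholesterol.
#' @param rho_tc_hdl Correlation between individual total and HDL deviations
#'   from their stratum means (the joint distribution of the two fractions
#'   within a person is not pinned down by published summaries, so this is
#'   an explicit modelling knob).
#' @param offset_mean,offset_sd Named vectors (subnational, community) for
#'   study-level offset distributions; national studies have offset 0.
#' @param extra_sd Named vector (national, subnational, community) of
#'   study-level extra between-stratum noise SDs.
#' @param injection_rate Fraction of records whose lipid value is replaced by
#'   an implausible value (ground truth for the cleaning filters).
#' @param pregnancy_rate Fraction of women aged 18-49 flagged pregnant.
#' @param under18_rate Number of under-18 records generated per study, as a
#'   fraction of the adult record count.
#' @param ldl_study_fraction Fraction of studies that also measure LDL.
#' @param frame_probs Sampling-frame mixture (probabilistic, school,
#'   insurance, primary-care).
#' @param device_ids Labels for the portable devices in use.
#' @return A list of class `world_config`.
#' @export
world_config <- function(n_super = 3, n_regions = 6, n_countries = 30,
                         years = 1980:2018,
                         study_mix = c(national = 0.363, subnational = 0.222,
                                       community = 0.415),
                         device_fraction = 0.10,
                         studies_per_country = 7,
                         p_no_data = 0.195,
                         n_per_stratum = 150,
                         sd_int = c(super = 0.25, region = 0.18, country = 0.25),
                         sd_slope = c(super = 0.06, region = 0.05, country = 0.12),
                         rw2_sd = c(global = 0.015, super = 0.012,
                                    region = 0.012, country = 0.03),
                         sd_age_country = 0.08,
                         hdl_scale = 0.3,
                         slope_global = c(total = -0.05, hdl = 0.01),
                         sd_ind = c(total = 1.05, hdl = 0.35),
                         rho_tc_hdl = 0.1,
                         offset_mean = c(subnational = 0.05, community = 0.10),
                         offset_sd = c(subnational = 0.12, community = 0.20),
                         extra_sd = c(national = 0, subnational = 0.05,
                                      community = 0.10),
                         injection_rate = 0.01,
                         pregnancy_rate = 0.02,
                         under18_rate = 0.02,
                         ldl_study_fraction = 0.14,
                         frame_probs = c(probabilistic = 0.90, school = 0.04,
                                         insurance = 0.03, `primary-care` = 0.03),
                         device_ids = c("portable-A", "portable-B")) {
  stopifnot(n_countries >= n_regions, n_regions >= n_super,
            abs(sum(study_mix) - 1) < 1e-8,
            device_fraction >= 0, device_fraction <= 1,
            injection_rate >= 0, injection_rate < 1,
            abs(rho_tc_hdl) <= 1)
  cfg <- as.list(environment())
  class(cfg) <- "world_config"
  cfg
}

## Sex-specific cubic age polynomials on z = (midpoint - 50)/35, mmol/l.
base_age_curve <- function(metric, sex, z) {
  if (metric == "total") {
    if (sex == "female") 4.75 + 0.50 * z - 0.28 * z^2 - 0.10 * z^3
    else                 4.70 + 0.35 * z - 0.45 * z^2 - 0.12 * z^3
  } else { # hdl
    if (sex == "female") 1.45 + 0.06 * z + 0.02 * z^2
    else                 1.25 + 0.04 * z + 0.02 * z^2
  }
}

## RW2 deviations: double cumulative sum of iid innovations, then centred and
## detrended (residual of regression on 1, t) so the linear slope stays
## identified. Returns a vector of length T with zero mean and zero trend.
rw2_deviation <- function(T, sd) {
  if (sd <= 0 || T < 3) return(rep(0, T))
  u <- cumsum(cumsum(rnorm(T, 0, sd)))
  t <- seq_len(T)
  stats::lm.fit(cbind(1, t), u)$residuals
}

#' Generate a synthetic world with known ground truth
#'
#' Draws the geographic hierarchy, country-level populations and urbanization
#' trajectories, and the true mean-cholesterol surfaces (total, HDL and
#' non-HDL, the last defined as total minus HDL at every index) by country,
#' year, sex and age band. The same `(config, seed)` pair always produces an
#' identical world.
#'
#' @param config A [world_config()] object.
#' @param seed Integer seed.
#' @return A list of class `synthetic_world` with elements `hierarchy`
#'   (countries/regions/super-regions, populations, urbanization), `truth`
#'   (named list of arrays `[country, year, sex, band]` for metrics
#'   `total`, `hdl`, `nonhdl`), and `components` (the decomposition terms,
#'   including true country slopes used by recovery tests).
#' @export
generate_world <- function(config, seed) {
  stopifnot(inherits(config, "world_config"))
  set.seed(as.integer(seed))
  ab <- age_bands()
  years <- config$years
  T <- length(years)
  t_std <- (years - mean(years)) / 10
  sexes <- c("female", "male")

  countries <- sprintf("C%03d", seq_len(config$n_countries))
  regions <- sprintf("R%02d", seq_len(config$n_regions))
  supers <- sprintf("S%d", seq_len(config$n_super))
  region_of <- regions[1 + (seq_along(countries) - 1) %% config$n_regions]
  super_of_region <- supers[1 + (seq_along(regions) - 1) %% config$n_super]
  hier <- data.frame(country = countries, region = region_of,
                     super_region = super_of_region[match(region_of, regions)],
                     stringsAsFactors = FALSE)

  ## populations: smooth growth, simple age pyramid shared across countries
  base_pop <- exp(rnorm(length(countries), 13, 0.7))
  age_w <- c(0.05, 0.24, 0.21, 0.18, 0.14, 0.10, 0.06, 0.02)
  growth <- 1 + 0.012 * (seq_len(T) - 1)
  pop <- expand.grid(country = countries, year = years, sex = sexes,
                     band = ab$band, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  pop$pop <- base_pop[match(pop$country, countries)] *
    growth[match(pop$year, years)] *
    age_w[match(pop$band, ab$band)] * 0.5

  ## urbanization: per-country logistic trajectories in [0, 1]
  ua <- rnorm(length(countries), 0.2, 0.6)
  ub <- rnorm(length(countries), 0.35, 0.15)
  urb <- expand.grid(country = countries, year = years,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  urb$prop_urban <- stats::plogis(ua[match(urb$country, countries)] +
                                  ub[match(urb$country, countries)] *
                                  t_std[match(urb$year, years)])

  ## hierarchy random effects and RW2 deviations per metric
  draw_effects <- function(scale) {
    list(
      int_super = rnorm(length(supers), 0, config$sd_int[["super"]] * scale),
      int_region = rnorm(length(regions), 0, config$sd_int[["region"]] * scale),
      int_country = rnorm(length(countries), 0, config$sd_int[["country"]] * scale),
      slope_super = rnorm(length(supers), 0, config$sd_slope[["super"]] * scale),
      slope_region = rnorm(length(regions), 0, config$sd_slope[["region"]] * scale),
      slope_country = rnorm(length(countries), 0, config$sd_slope[["country"]] * scale),
      rw2_global = rw2_deviation(T, config$rw2_sd[["global"]] * scale),
      rw2_super = vapply(supers, function(s)
        rw2_deviation(T, config$rw2_sd[["super"]] * scale), numeric(T)),
      rw2_region = vapply(regions, function(r)
        rw2_deviation(T, config$rw2_sd[["region"]] * scale), numeric(T)),
      rw2_country = vapply(countries, function(cc)
        rw2_deviation(T, config$rw2_sd[["country"]] * scale), numeric(T)),
      age_country = matrix(rnorm(length(countries) * 4, 0,
                                 config$sd_age_country * scale *
                                   rep(c(1, 0.6, 0.4, 0.25), each = length(countries))),
                           nrow = length(countries))
    )
  }
  eff <- list(total = draw_effects(1), hdl = draw_effects(config$hdl_scale))

  z <- (ab$midpoint - 50) / 35
  zbasis <- cbind(1, z, z^2, z^3)
  dims <- c(length(countries), T, length(sexes), nrow(ab))
  dn <- list(country = countries, year = as.character(years),
             sex = sexes, band = ab$band)

  build_surface <- function(metric) {
    e <- eff[[metric]]
    g_slope <- config$slope_global[[metric]]
    out <- array(0, dims, dimnames = dn)
    for (ci in seq_along(countries)) {
      ri <- match(region_of[ci], regions)
      si <- match(super_of_region[ri], supers)
      tcurve <- g_slope * t_std +
        e$slope_super[si] * t_std + e$slope_region[ri] * t_std +
        e$slope_country[ci] * t_std +
        e$rw2_global + e$rw2_super[, si] + e$rw2_region[, ri] +
        e$rw2_country[, ci] +
        e$int_super[si] + e$int_region[ri] + e$int_country[ci]
      agepert <- as.numeric(zbasis %*% e$age_country[ci, ])
      for (xi in seq_along(sexes)) {
        base <- vapply(z, function(zz) base_age_curve(metric, sexes[xi], zz), 0)
        out[ci, , xi, ] <- outer(tcurve, base + agepert, `+`)
      }
    }
    out
  }

  total <- build_surface("total")
  hdl <- build_surface("hdl")

  ## plausibility clipping audit: a config whose variance components push more
  ## than 1% of surface cells outside the plausibility windows is rejected
  clip_frac <- (sum(total <= 1.75 | total >= 20) + sum(hdl <= 0.4 | hdl >= 5)) /
    (2 * length(total))
  if (clip_frac > 0.01) {
    stop(sprintf(paste("world config rejected: %.2f%% of true surface values",
                       "fall outside the plausibility windows (limit 1%%);",
                       "reduce the variance components"), 100 * clip_frac))
  }
  total <- pmin(pmax(total, 1.7501), 19.999)
  hdl <- pmin(pmax(hdl, 0.4001), 4.999)
  nonhdl <- total - hdl

  ## true country slopes (total linear coefficient per decade), for recovery
  slope_truth <- lapply(eff, function(e) {
    ri <- match(region_of, regions)
    si <- match(super_of_region[ri], supers)
    e$slope_country + e$slope_region[ri] + e$slope_super[si]
  })
  slope_truth$total <- slope_truth$total + config$slope_global[["total"]]
  slope_truth$hdl <- slope_truth$hdl + config$slope_global[["hdl"]]

  structure(list(
    hierarchy = list(countries = hier, populations = pop, urbanization = urb),
    truth = list(total = total, hdl = hdl, nonhdl = nonhdl),
    components = list(effects = eff, country_slope = slope_truth,
                      t_std = t_std, years = years),
    config = config
  ), class = "synthetic_world")
}

#' Generate synthetic study sources
#'
#' Draws a set of studies (surveys) for a synthetic world: coverage level
#' (national / subnational / community) from the configured mixture,
#' urbanicity, sampling frame, midpoint year, portable-device assignment, and
#' the study-level offset and extra-noise SD that define each study's true
#' bias. National studies have zero offset by construction.
#'
#' @param world A `synthetic_world`.
#' @param config The world's [world_config()] (or an override).
#' @param seed Integer seed.
#' @param n_studies Optional total number of studies; when given, studies are
#'   spread over countries uniformly instead of via the per-country model.
#' @return data.frame of class `study_table`, one row per study.
#' @export
generate_studies <- function(world, config = world$config, seed,
                             n_studies = NULL) {
  set.seed(as.integer(seed))
  countries <- world$hierarchy$countries$country
  years <- world$components$years
  if (is.null(n_studies)) {
    nper <- ifelse(runif(length(countries)) < config$p_no_data, 0L,
                   1L + rpois(length(countries),
                              max(config$studies_per_country - 1, 0)))
    country_of <- rep(countries, nper)
  } else {
    country_of <- sample(countries, n_studies, replace = TRUE)
  }
  n <- length(country_of)
  if (n == 0) stop("configuration produced zero studies")
  coverage <- sample(names(config$study_mix), n, replace = TRUE,
                     prob = config$study_mix)
  urbanicity <- ifelse(coverage == "national", "mixed",
                       sample(c("rural", "urban", "mixed"), n, replace = TRUE,
                              prob = c(0.3, 0.4, 0.3)))
  frame <- sample(names(config$frame_probs), n, replace = TRUE,
                  prob = config$frame_probs)
  device <- ifelse(runif(n) < config$device_fraction,
                   sample(config$device_ids, n, replace = TRUE), "laboratory")
  offset <- numeric(n)
  for (lev in c("subnational", "community")) {
    idx <- coverage == lev
    offset[idx] <- rnorm(sum(idx), config$offset_mean[[lev]],
                         config$offset_sd[[lev]])
  }
  extra_sd <- config$extra_sd[coverage]
  out <- data.frame(
    study = sprintf("study%04d", seq_len(n)),
    country = country_of,
    year = sample(years, n, replace = TRUE),
    coverage = coverage, urbanicity = urbanicity, frame = frame,
    device = device,
    n_per_stratum = config$n_per_stratum,
    offset = offset, extra_sd = as.numeric(extra_sd),
    has_ldl = runif(n) < config$ldl_study_fraction,
    stringsAsFactors = FALSE
  )
  class(out) <- c("study_table", "data.frame")
  out
}

#' Generate individual survey records
#'
#' Draws individual lipid measurements around the true surface plus the study
#' offset for every study stratum (sex by age band), with survey weights,
#' pregnancy flags, a configurable share of under-18 records (to exercise the
#' age filter), and implausible-value injection at the configured rate.
#' Injected records carry an internal flag (`injected`) that downstream
#' cleaning tests use as ground truth. Device-measured studies record raw
#' values here; analytical-range truncation is applied downstream.
#'
#' @param world A `synthetic_world`.
#' @param studies Output of [generate_studies()].
#' @param config The [world_config()].
#' @param seed Integer seed.
#' @return data.frame of records: study, person, age, sex, pregnant, weight,
#'   tc, hdl, ldl, device, injected, injected_metric.
#' @export
generate_records <- function(world, studies, config = world$config, seed) {
  set.seed(as.integer(seed))
  ab <- age_bands()
  years <- world$components$years
  chunks <- vector("list", nrow(studies) * 2L * nrow(ab))
  k <- 0L
  for (si in seq_len(nrow(studies))) {
    st <- studies[si, ]
    yi <- match(st$year, years)
    for (sex in c("female", "male")) {
      for (bi in seq_len(nrow(ab))) {
        n <- st$n_per_stratum
        if (n <= 0) next
        mu_tc <- world$truth$total[st$country, yi, sex, bi] + st$offset
        mu_hdl <- world$truth$hdl[st$country, yi, sex, bi] +
          st$offset * config$hdl_scale
        shift <- if (st$extra_sd > 0) rnorm(1, 0, st$extra_sd) else 0
        z1 <- rnorm(n); z2 <- rnorm(n)
        rho <- config$rho_tc_hdl
        tc <- mu_tc + shift + config$sd_ind[["total"]] * z1
        hdl <- mu_hdl + shift * config$hdl_scale +
          config$sd_ind[["hdl"]] * (rho * z1 + sqrt(1 - rho^2) * z2)
        ## clean values are kept inside the plausibility windows (and above
        ## HDL) so that injected values are the only filter targets
        hdl <- pmin(pmax(hdl, 0.41), 4.99)
        tc <- pmin(pmax(tc, pmax(1.76, hdl + 0.1)), 19.99)
        ldl <- if (st$has_ldl) {
          pmax((tc - hdl) * 0.86 + rnorm(n, 0, 0.12), 0.1)
        } else rep(NA_real_, n)
        upper <- if (is.finite(ab$upper[bi])) ab$upper[bi] else 89
        age <- sample(ab$lower[bi]:upper, n, replace = TRUE)
        pregnant <- sex == "female" & age <= 49 &
          runif(n) < config$pregnancy_rate
        k <- k + 1L
        chunks[[k]] <- data.frame(
          study = st$study, age = age, sex = sex, pregnant = pregnant,
          weight = exp(rnorm(n, 0, 0.3)), tc = tc, hdl = hdl, ldl = ldl,
          device = st$device, stringsAsFactors = FALSE)
      }
    }
    ## under-18 records exercising the age filter
    n_adult <- st$n_per_stratum * 2L * nrow(ab)
    n_minor <- rpois(1, config$under18_rate * n_adult)
    if (n_minor > 0) {
      yi2 <- yi
      mu <- world$truth$total[st$country, yi2, "male", 1] + st$offset
      k <- k + 1L
      chunks[[k]] <- data.frame(
        study = st$study, age = sample(15:17, n_minor, replace = TRUE),
        sex = sample(c("female", "male"), n_minor, replace = TRUE),
        pregnant = FALSE, weight = exp(rnorm(n_minor, 0, 0.3)),
        tc = pmin(pmax(mu + rnorm(n_minor, 0, config$sd_ind[["total"]]),
                       1.76), 19.99),
        hdl = pmin(pmax(world$truth$hdl[st$country, yi2, "male", 1] +
                          rnorm(n_minor, 0, config$sd_ind[["hdl"]]),
                        0.41), 4.99),
        ldl = NA_real_, device = st$device, stringsAsFactors = FALSE)
    }
  }
  rec <- do.call(rbind, chunks[seq_len(k)])
  rec$person <- sprintf("p%07d", seq_len(nrow(rec)))
  rec$injected <- FALSE
  rec$injected_metric <- NA_character_

  ## implausible-value injection: replace with a draw from outside the
  ## plausibility window so the record is guaranteed to trip the filter
  if (config$injection_rate > 0) {
    hit <- which(runif(nrow(rec)) < config$injection_rate)
    if (length(hit)) {
      met <- sample(c("total", "hdl"), length(hit), replace = TRUE)
      lowside <- runif(length(hit)) < 0.5
      tc_lo <- runif(length(hit), 0.5, 1.74)
      tc_hi <- runif(length(hit), 20.01, 30)
      hdl_lo <- runif(length(hit), 0.05, 0.39)
      hdl_hi <- runif(length(hit), 5.01, 8)
      it <- met == "total"
      rec$tc[hit[it]] <- ifelse(lowside[it], tc_lo[it], tc_hi[it])
      rec$hdl[hit[!it]] <- ifelse(lowside[!it], hdl_lo[!it], hdl_hi[!it])
      rec$injected[hit] <- TRUE
      rec$injected_metric[hit] <- met
    }
  }
  rownames(rec) <- NULL
  rec[, c("study", "person", "age", "sex", "pregnant", "weight",
          "tc", "hdl", "ldl", "device", "injected", "injected_metric")]
}
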