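# Shared fixtures: small synthetic worlds and hand-built tables.

small_world_cfg <- function(...) {
  args <- list(n_super = 2, n_regions = 4, n_countries = 12,
               years = 2004:2013, n_per_stratum = 60,
               studies_per_country = 4, p_no_data = 0.1)
  do.call(world_config, utils::modifyList(args, list(...)))
}

make_world_data <- function(cfg = small_world_cfg(), seed = 42) {
  w <- generate_world(cfg, seed)
  st <- generate_studies(w, cfg, seed + 1)
  rec <- generate_records(w, st, cfg, seed + 2)
  list(w = w, st = st, rec = rec, cfg = cfg)
}

# strata for a single country with constant mean (conjugate-oracle fixture)
flat_strata <- function(years = 2000:2009, value = 4.6, se = 0.02,
                        bands = age_bands()$band[2:6]) {
  g <- expand.grid(year = years, band = bands, stringsAsFactors = FALSE)
  data.frame(study = sprintf("s%03d", seq_len(nrow(g))), country = "C001",
             year = g$year, sex = "female", band = g$band, metric = "total",
             mean = value, se = se, n = 200, coverage = "national",
             urbanicity = "mixed", stringsAsFactors = FALSE)
}

one_country_hier <- function(years = 2000:2009, prop_urban = 0.5) {
  list(countries = data.frame(country = "C001", region = "R01",
                              super_region = "S1", stringsAsFactors = FALSE),
       urbanization = data.frame(country = "C001", year = years,
                                 prop_urban = prop_urban))
}

# true age-standardized surface of a synthetic world, [country, year]
true_standardized <- function(world, sex = "female", metric = "total",
                              weights = who_standard_weights()) {
  apply(world$truth[[metric]][, , sex, , drop = FALSE], c(1, 2),
        function(v) sum(v * weights))
}

# independent log-likelihood BIC oracle for a linear model
bic_oracle <- function(formula, data) {
  X <- stats::model.matrix(formula, data)
  y <- stats::model.response(stats::model.frame(formula, data))
  ft <- stats::lm.fit(X, y)
  rss <- sum(ft$residuals^2)
  n <- length(y)
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  -2 * ll + (ncol(X) + 1) * log(n)
}
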