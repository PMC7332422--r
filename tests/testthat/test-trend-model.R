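# Small fits shared across this file.
years10 <- 2000:2009
hier1 <- one_country_hier(years10)
spec_small <- model_spec(years = years10, n_draws = 120, burnin = 120)
fit_small <- suppressWarnings(
  fit_mcmc(build_design(flat_strata(years10), hier1, spec_small,
                        "female", "total"), seed = 3))

test_that("design links study-type terms per the weighting rules", {
  years <- 2000:2004
  hier <- list(
    countries = data.frame(country = c("C001", "C002"),
                           region = "R01", super_region = "S1"),
    urbanization = data.frame(country = rep(c("C001", "C002"), each = 5),
                              year = rep(years, 2), prop_urban = 0.6))
  strata <- data.frame(
    study = c("nat", "rur", "urb", "sub", "sub"),
    country = "C001", year = 2002, sex = "female",
    band = c("40-49", "40-49", "40-49", "40-49", "50-59"), metric = "total",
    mean = 4.5, se = 0.1, n = 50,
    coverage = c("national", "community", "community", "subnational",
                 "subnational"),
    urbanicity = c("mixed", "rural", "urban", "mixed", "mixed"))
  des <- build_design(strata, hier, model_spec(years = years), "female",
                      "total")
  fx <- des$blocks$fixed$idx
  nm <- des$fix_names
  X <- as.matrix(des$X)
  ## national mixed study: no study-type contribution at all
  type_cols <- fx[nm %in% c("sub_fe", "com_fe", "rural_fe", "urban_fe")]
  expect_identical(unname(X[1, type_cols]), c(0, 0, 0, 0))
  ## rural-only study in a 60%-urban country enters with weight 0.6
  expect_equal(unname(X[2, fx[nm == "rural_fe"]]), 0.6)
  ## urban-only study there enters with weight 1 - 0.6
  expect_equal(unname(X[3, fx[nm == "urban_fe"]]), 0.4)
  ## two strata of one subnational study share a single random-effect column
  re <- des$blocks$re_sub$idx
  expect_identical(X[4, re], X[5, re])
  expect_identical(sum(X[4, re] != 0), 1L)
  ## hard errors for unknown countries and out-of-range years
  bad <- strata; bad$country <- "NOPE"
  expect_error(build_design(bad, hier, model_spec(years = years), "female",
                            "total"), "hierarchy")
  bad2 <- strata; bad2$year <- 1950
  expect_error(build_design(bad2, hier, model_spec(years = years), "female",
                            "total"), "year range")
})

test_that("RW2 deviations satisfy the identifiability constraints per draw", {
  des <- fit_small$design
  T <- length(des$years)
  tvec <- seq_len(T)
  for (block in c("rw2_global", "rw2_country")) {
    idx <- des$blocks[[block]]$idx[seq_len(T - 2)]
    for (dr in c(1, 50, 120)) {
      u <- des$rw2$B %*% fit_small$theta[dr, idx]
      expect_lt(abs(sum(u)), 1e-8)
      expect_lt(abs(sum(u * tvec)), 1e-8)
    }
  }
})

test_that("the sampler's draw stream is reproducible under the seed", {
  des <- build_design(flat_strata(years10), hier1,
                      model_spec(years = years10, n_draws = 40, burnin = 40),
                      "female", "total")
  f1 <- suppressWarnings(fit_mcmc(des, seed = 11))
  f2 <- suppressWarnings(fit_mcmc(des, seed = 11))
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$sigmas, f2$sigmas)
  f3 <- suppressWarnings(fit_mcmc(des, seed = 12))
  expect_false(identical(f1$theta, f3$theta))
})

test_that("prediction is the linear predictor without study terms", {
  des <- fit_small$design
  theta <- matrix(0, 2, des$p)
  theta[, des$blocks$fixed$idx[1]] <- 4.6
  fake <- structure(list(theta = theta, design = des), class = "chol_fit")
  pr <- predict_surface(fake, "C001", c(2001, 2005), "40-49")
  expect_equal(as.numeric(pr), rep(4.6, 4))
  ## with a nonzero community fixed effect the prediction is unchanged
  theta2 <- theta
  theta2[, des$blocks$fixed$idx[des$fix_names == "com_fe"]] <- 0.7
  fake2 <- structure(list(theta = theta2, design = des), class = "chol_fit")
  expect_equal(predict_surface(fake2, "C001", 2001, "40-49"),
               predict_surface(fake, "C001", 2001, "40-49"))
})

test_that("flat-truth posterior matches the conjugate normal oracle", {
  strat <- flat_strata(years10, value = 4.6, se = 0.02)
  surf <- posterior_surface(fit_small, bands = unique(strat$band))
  pm <- mean(apply(surf$draws, c(2, 3), mean))
  oracle <- sum(strat$mean / strat$se^2) /
    (sum(1 / strat$se^2) + 1 / fit_small$design$spec$sd_fixed^2)
  expect_lt(abs(pm - oracle), 0.05)
  expect_identical(dim(surf$draws)[1], nrow(fit_small$theta))
  expect_false(any(!is.finite(surf$draws)))
})

test_that("a lone community study shrinks toward the region curve", {
  years <- 2002:2007
  nc <- 5
  cn <- sprintf("C%03d", 1:nc)
  hier <- list(
    countries = data.frame(country = cn, region = "R01", super_region = "S1"),
    urbanization = expand.grid(country = cn, year = years,
                               KEEP.OUT.ATTRS = FALSE,
                               stringsAsFactors = FALSE))
  hier$urbanization$prop_urban <- 0.5
  g <- expand.grid(country = cn[1:4], year = years, stringsAsFactors = FALSE)
  strata <- data.frame(
    study = paste0("nat_", g$country, "_", g$year), country = g$country,
    year = g$year, sex = "female", band = "40-49", metric = "total",
    mean = 4.5, se = 0.05, n = 100, coverage = "national",
    urbanicity = "mixed")
  strata <- rbind(strata, data.frame(
    study = "comm1", country = "C005", year = 2004, sex = "female",
    band = "40-49", metric = "total", mean = 5.5, se = 0.10, n = 40,
    coverage = "community", urbanicity = "mixed"))
  spec <- model_spec(years = years, n_draws = 250, burnin = 250)
  fit <- suppressWarnings(
    fit_mcmc(build_design(strata, hier, spec, "female", "total"), seed = 8))
  pm <- mean(predict_surface(fit, "C005", 2004, "40-49"))
  region <- mean(predict_surface(fit, "C005", 2004, "40-49",
                                 level = "region"))
  expect_gte(pm, region - 0.05)
  expect_lte(pm, 5.5 + 0.05)
})
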