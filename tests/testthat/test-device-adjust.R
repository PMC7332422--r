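test_that("device truncation keeps exactly the strict interior of the range", {
  expect_identical(truncate_to_device(c(2.0, 3.0, 7.0), 2.5, 6.5), 3.0)
  expect_identical(truncate_to_device(c(2.5, 3.0, 6.5), 2.5, 6.5), 3.0)
  v <- c(3.1, 4.0, 5.9)
  expect_identical(truncate_to_device(v, 1, 19), v)
  ## monotonicity: an upper bound below the max lowers the mean, a lower
  ## bound above the min raises it
  set.seed(1)
  x <- rnorm(5000, 5, 1)
  expect_lt(mean(truncate_to_device(x, -Inf, 6)), mean(x))
  expect_gt(mean(truncate_to_device(x, 4, Inf)), mean(x))
})

test_that("training pairs reproduce the truncated-normal mean gap", {
  set.seed(21)
  n <- 50000
  rec <- data.frame(study = "lab1", age = 35, sex = "female",
                    pregnant = FALSE, weight = 1,
                    tc = rnorm(n, 5, 1), hdl = 1.3, ldl = NA_real_,
                    device = "laboratory")
  dr <- data.frame(device = "dev", metric = "total", min = 0.1, max = 6.0)
  pairs <- make_training_pairs(rec, dr, "total")
  ## closed form: E[X | X < 6] = 5 - phi(1)/Phi(1) for N(5, 1)
  closed <- 5 - dnorm(1) / pnorm(1)
  ## independent Monte-Carlo oracle
  set.seed(22)
  mc <- mean(truncate_to_device(rnorm(1e6, 5, 1), 0.1, 6.0))
  expect_equal(mc, closed, tolerance = 0.01)
  expect_equal(pairs$restr_mean, closed, tolerance = 0.02)
  expect_equal(pairs$full_mean, mean(rec$tc), tolerance = 1e-10)
})

test_that("strata under the 25-individual floor are excluded from training", {
  rec <- data.frame(study = rep(c("a", "b"), c(24, 30)), age = 35,
                    sex = "female", weight = 1, tc = rnorm(54, 5, 0.5),
                    hdl = 1.3, device = "laboratory")
  dr <- data.frame(device = "dev", metric = "total", min = 0.1, max = 19)
  pairs <- make_training_pairs(rec, dr, "total")
  expect_identical(unique(pairs$study), "b")
})

test_that("a non-truncating range yields the identity conversion", {
  set.seed(3)
  pairs <- data.frame(
    study = sprintf("s%02d", 1:40),
    sex = rep(c("female", "male"), 20),
    band = "40-49", age_mid = rep(c(35, 45, 55, 65), 10),
    restr_mean = runif(40, 3.5, 6.5), n_full = 100, n_restr = 100)
  pairs$full_mean <- pairs$restr_mean
  m <- suppressWarnings(fit_conversion(pairs, "total", "dev"))
  expect_equal(unname(m$coef["restr_mean"]), 1, tolerance = 1e-6)
  expect_equal(unname(m$coef["(Intercept)"]), 0, tolerance = 1e-6)
})

test_that("BIC selection matches an independent log-likelihood oracle", {
  set.seed(4)
  pairs <- data.frame(
    study = sprintf("s%02d", 1:60),
    sex = rep(c("female", "male"), 30),
    band = "40-49", age_mid = rep(c(25, 35, 45, 55, 65, 75), 10),
    restr_mean = runif(60, 3.5, 6.5), n_full = 100, n_restr = 100)
  ## a real age interaction so selection is non-trivial
  pairs$full_mean <- 0.2 + 1.05 * pairs$restr_mean +
    0.004 * pairs$age_mid * pairs$restr_mean + rnorm(60, 0, 0.05)
  m <- fit_conversion(pairs, "total", "dev")
  for (i in seq_len(nrow(m$bic_table))) {
    f <- as.formula(paste("full_mean ~", m$bic_table$terms[i]))
    expect_equal(m$bic_table$bic[i], bic_oracle(f, pairs), tolerance = 1e-8)
  }
  sel <- m$bic_table$bic[m$bic_table$terms == m$selected]
  expect_true(all(sel <= m$bic_table$bic + 1e-9))
})

test_that("conversion recovers a known affine distortion", {
  set.seed(5)
  n <- 400
  pairs <- data.frame(
    study = sprintf("s%03d", seq_len(n)),
    sex = rep(c("female", "male"), n / 2),
    band = "40-49", age_mid = sample(c(25, 35, 45, 55, 65, 75), n, TRUE),
    restr_mean = runif(n, 3.5, 6.5), n_full = 100, n_restr = 100)
  pairs$full_mean <- 0.30 + 1.10 * pairs$restr_mean + rnorm(n, 0, 0.05)
  m <- fit_conversion(pairs, "total", "dev")
  se <- sqrt(diag(m$vcov))
  expect_lt(abs(m$coef[["restr_mean"]] - 1.10), 3 * se[["restr_mean"]] + 0.01)
  expect_lt(abs(m$coef[["(Intercept)"]] - 0.30), 3 * se[["(Intercept)"]] + 0.05)
})

test_that("conversion draws propagate all three uncertainty sources", {
  set.seed(6)
  pairs <- data.frame(
    study = sprintf("s%02d", 1:40),
    sex = rep(c("female", "male"), 20),
    band = "40-49", age_mid = rep(c(35, 45, 55, 65), 10),
    restr_mean = runif(40, 3.5, 6.5), n_full = 100, n_restr = 100)
  pairs$full_mean <- pairs$restr_mean   # exact fit: sigma = 0, vcov = 0
  m <- suppressWarnings(fit_conversion(pairs, "total", "dev"))
  stratum <- data.frame(mean = 5, se = 0, band = "40-49", sex = "female",
                        device = "dev")
  d0 <- apply_conversion(stratum, m, n_draws = 50, seed = 1)
  expect_lt(diff(range(d0)), 1e-8)
  expect_equal(d0[1], 5, tolerance = 1e-6)
  ## with an input SE the draw spread is at least that SE
  stratum$se <- 0.1
  d1 <- apply_conversion(stratum, m, n_draws = 4000, seed = 2)
  expect_gte(sd(d1), 0.095)
  ## metric/device mismatch is a hard error
  stratum$device <- "other"
  expect_error(apply_conversion(stratum, m, 10, 1), "other")
})

test_that("adjustment reduces truncation bias on synthetic device strata", {
  cfg <- world_config(n_super = 2, n_regions = 3, n_countries = 10,
                      years = 2006:2008, n_per_stratum = 150,
                      injection_rate = 0, device_fraction = 0.35,
                      device_ids = "portable-A", p_no_data = 0,
                      extra_sd = c(national = 0, subnational = 0,
                                   community = 0))
  w <- generate_world(cfg, 31)
  st <- generate_studies(w, cfg, 32, n_studies = 40)
  rec <- generate_records(w, st, cfg, 33)
  fl <- filter_participants(rec)
  dr <- device_ranges_example()
  drA <- dr[dr$device == "portable-A", ]
  m <- fit_conversion(make_training_pairs(fl$records, drA, "total"),
                      "total", "portable-A")
  strata <- summarize_strata(truncate_records(fl$records, drA), st)
  dev <- strata[strata$device == "portable-A" & strata$metric == "total", ]
  expect_gt(nrow(dev), 30)
  truth <- mapply(function(cc, yy, sx, bb, so) {
    w$truth$total[cc, as.character(yy), sx, bb] + so
  }, dev$country, dev$year, dev$sex, dev$band,
     st$offset[match(dev$study, st$study)])
  adj <- adjust_device_strata(dev, list(`portable-A` = m),
                              n_draws = 300, seed = 9)
  bias_unadj <- mean(abs(dev$mean - truth))
  bias_adj <- mean(abs(adj$mean - truth))
  expect_lt(bias_adj, bias_unadj)
})
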