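test_that("world, studies and records are deterministic under (config, seed)", {
  cfg <- small_world_cfg()
  w1 <- generate_world(cfg, 7)
  w2 <- generate_world(cfg, 7)
  expect_identical(w1, w2)
  st1 <- generate_studies(w1, cfg, 8)
  expect_identical(st1, generate_studies(w2, cfg, 8))
  expect_identical(generate_records(w1, st1, cfg, 9),
                   generate_records(w2, st1, cfg, 9))
})

test_that("true surfaces are internally consistent and plausible", {
  w <- generate_world(small_world_cfg(), 7)
  expect_lt(max(abs(w$truth$nonhdl - (w$truth$total - w$truth$hdl))), 1e-12)
  expect_true(all(w$truth$total > 1.75 & w$truth$total < 20))
  expect_true(all(w$truth$hdl > 0.4 & w$truth$hdl < 5))
  urb <- w$hierarchy$urbanization$prop_urban
  expect_true(all(urb >= 0 & urb <= 1))
  expect_true(all(w$hierarchy$populations$pop > 0))
  hc <- w$hierarchy$countries
  expect_identical(anyDuplicated(hc$country), 0L)
  expect_true(all(table(hc$country) == 1))  # one region per country
})

test_that("degenerate variance configs force analytic surfaces", {
  zero <- c(super = 0, region = 0, country = 0)
  cfg <- small_world_cfg(sd_int = zero, sd_slope = zero,
                         rw2_sd = c(global = 0, super = 0, region = 0,
                                    country = 0),
                         sd_age_country = 0)
  w <- generate_world(cfg, 1)
  ## every country equals the global mean curve
  spread <- apply(w$truth$total, c(2, 3, 4), function(v) diff(range(v)))
  expect_lt(max(spread), 1e-12)
  ## zero RW2 innovation -> exactly linear time trends
  cfg2 <- small_world_cfg(rw2_sd = c(global = 0, super = 0, region = 0,
                                     country = 0))
  w2 <- generate_world(cfg2, 2)
  for (ci in c(1, 5, 12)) {
    s <- w2$truth$total[ci, , "male", 3]
    expect_lt(max(abs(diff(s, differences = 2))), 1e-10)
  }
})

test_that("configs that clip the plausibility window are rejected", {
  cfg <- small_world_cfg(sd_int = c(super = 0.2, region = 0.2, country = 8))
  expect_error(generate_world(cfg, 1), "plausibility")
})

test_that("study mixture, offsets and device assignment follow the config", {
  cfg <- small_world_cfg()
  w <- generate_world(cfg, 3)
  st <- generate_studies(w, cfg, 4, n_studies = 1000)
  ## national share within binomial 99% bounds of the configured 36.3%
  bound <- stats::qnorm(0.995) * sqrt(0.363 * 0.637 / 1000)
  expect_lt(abs(mean(st$coverage == "national") - 0.363), bound)
  expect_true(all(st$offset[st$coverage == "national"] == 0))

  cfg0 <- small_world_cfg(study_mix = c(national = 0.6, subnational = 0.4,
                                        community = 0))
  st0 <- generate_studies(w, cfg0, 5, n_studies = 300)
  expect_false(any(st0$coverage == "community"))

  cfg1 <- small_world_cfg(offset_sd = c(subnational = 0, community = 0))
  st1 <- generate_studies(w, cfg1, 6, n_studies = 400)
  expect_true(all(st1$offset[st1$coverage == "subnational"] ==
                    cfg1$offset_mean[["subnational"]]))
  expect_true(all(st1$offset[st1$coverage == "community"] ==
                    cfg1$offset_mean[["community"]]))
})

test_that("records recover stratum truth at the central-limit rate", {
  cfg <- world_config(n_super = 1, n_regions = 1, n_countries = 1,
                      years = 2000:2002, n_per_stratum = 20000,
                      injection_rate = 0, pregnancy_rate = 0,
                      under18_rate = 0, device_fraction = 0, p_no_data = 0,
                      study_mix = c(national = 1, subnational = 0,
                                    community = 0),
                      extra_sd = c(national = 0, subnational = 0,
                                   community = 0))
  w <- generate_world(cfg, 1)
  st <- generate_studies(w, cfg, 2, n_studies = 1)
  rec <- generate_records(w, st, cfg, 3)
  sub <- rec[rec$sex == "female" & rec$age >= 30 & rec$age <= 39, ]
  truth <- w$truth$total["C001", as.character(st$year), "female", "30-39"]
  expect_lt(abs(mean(sub$tc) - truth), 3 * sd(sub$tc) / sqrt(nrow(sub)))
  ## and at a smaller n the error is within its own (larger) CLT band
  sub2 <- sub[seq_len(100), ]
  expect_lt(abs(mean(sub2$tc) - truth), 4 * sd(sub$tc) / sqrt(100))
  ## nothing removable by the age/pregnancy rules was generated
  fl <- filter_participants(rec)
  expect_identical(sum(fl$log$age_under_18) + sum(fl$log$pregnant), 0L)
})

test_that("implausible-value injection hits its configured rate", {
  cfg <- world_config(n_super = 1, n_regions = 1, n_countries = 1,
                      years = 2000:2002, n_per_stratum = 625,
                      injection_rate = 0.01, pregnancy_rate = 0,
                      under18_rate = 0, device_fraction = 0, p_no_data = 0,
                      study_mix = c(national = 1, subnational = 0,
                                    community = 0))
  w <- generate_world(cfg, 5)
  st <- generate_studies(w, cfg, 6, n_studies = 1)
  rec <- generate_records(w, st, cfg, 7)
  n <- nrow(rec)
  bounds <- stats::qbinom(c(0.005, 0.995), n, 0.01)
  expect_gte(sum(rec$injected), bounds[1])
  expect_lte(sum(rec$injected), bounds[2])
  ## injected values sit outside the plausibility windows
  it <- rec$injected & rec$injected_metric == "total"
  expect_true(all(rec$tc[it] < 1.75 | rec$tc[it] > 20))
  ih <- rec$injected & rec$injected_metric == "hdl"
  expect_true(all(rec$hdl[ih] < 0.4 | rec$hdl[ih] > 5))
})
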