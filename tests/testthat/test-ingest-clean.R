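test_that("source eligibility follows the sampling-frame rules", {
  expect_true(check_source_eligibility(list(frame = "probabilistic"))$eligible)
  school_lo <- check_source_eligibility(list(frame = "school"),
                                        list(school_enrolment = 65))
  expect_false(school_lo$eligible)
  expect_match(school_lo$reasons, "70%")
  expect_true(check_source_eligibility(list(frame = "school"),
                                       list(school_enrolment = 70))$eligible)
  expect_true(check_source_eligibility(list(frame = "insurance"),
                                       list(insured = 85))$eligible)
  expect_false(check_source_eligibility(list(frame = "insurance"),
                                        list(insured = 79))$eligible)
  expect_false(check_source_eligibility(
    list(frame = "primary-care"), list(universal_insurance = FALSE))$eligible)
  ## missing context is an explicit undeterminable status, not a pass
  und <- check_source_eligibility(list(frame = "school"), list())
  expect_identical(und$status, "undeterminable")
  expect_true(is.na(und$eligible))
})

test_that("participant filters implement the plausibility rules", {
  base <- list(study = "s1", age = 40, sex = "female", pregnant = FALSE,
               weight = 1, hdl = 1.3, ldl = NA_real_)
  mk <- function(...) {
    args <- utils::modifyList(base, list(...))
    as.data.frame(args, stringsAsFactors = FALSE)
  }
  rows <- rbind(
    mk(tc = 1.70),              # below the total window -> removed
    mk(tc = 1.75),              # exactly at the bound -> retained
    mk(tc = 20.0),              # at the upper bound -> retained
    mk(tc = 20.5),              # above -> removed
    mk(tc = 4.0, hdl = 4.2),    # total below HDL -> removed
    mk(tc = 5.2, hdl = 1.3),    # clean -> retained
    mk(tc = 5.0, hdl = 0.35),   # HDL below its window -> removed
    mk(tc = 5.0, age = 17),     # under 18 -> removed
    mk(tc = 5.0, pregnant = TRUE) # pregnant -> removed
  )
  out <- filter_participants(rows)
  expect_identical(nrow(out$records), 3L)
  expect_setequal(out$records$tc, c(1.75, 20.0, 5.2))
  expect_identical(out$log$input, 9L)
  expect_identical(out$log$retained, 3L)
})

test_that("CRMLN cross-metric rule matches the hand-evaluated inequality", {
  ## with eTC = 0.089, eHDL = 0.13, eLDL = 0.12:
  ## LDL*(1-0.12) + HDL*(1-0.13) > TC*(1+0.089)
  ## TC 4.0, HDL 1.0, LDL 3.9: 3.432 + 0.870 = 4.302 <= 4.356 -> retained
  ## TC 4.0, HDL 1.0, LDL 4.2: 3.696 + 0.870 = 4.566 >  4.356 -> removed
  rows <- data.frame(study = "s1", age = 40, pregnant = FALSE, weight = 1,
                     tc = c(4.0, 4.0), hdl = c(1.0, 1.0), ldl = c(3.9, 4.2))
  out <- filter_participants(rows)
  expect_identical(nrow(out$records), 1L)
  expect_identical(out$records$ldl, 3.9)
  expect_identical(out$log$crmln_sum, 1L)
  ## missing LDL never trips the rule
  rows2 <- data.frame(study = "s1", age = 40, weight = 1,
                      tc = 4.0, hdl = 1.0, ldl = NA_real_)
  expect_identical(nrow(filter_participants(rows2)$records), 1L)
})

test_that("filtering is idempotent and the exclusion log reconciles", {
  wd <- make_world_data(small_world_cfg(injection_rate = 0.02), seed = 11)
  f1 <- filter_participants(wd$rec)
  rule_cols <- c("age_under_18", "pregnant", "tc_implausible",
                 "hdl_implausible", "tc_below_hdl", "crmln_sum")
  expect_true(all(rowSums(f1$log[, rule_cols]) + f1$log$retained ==
                    f1$log$input))
  expect_identical(sum(f1$log$input), nrow(wd$rec))
  f2 <- filter_participants(f1$records)
  expect_identical(nrow(f2$records), nrow(f1$records))
  expect_identical(sum(as.matrix(f2$log[, rule_cols])), 0L)
})

test_that("stratum summaries use survey-weighted means and design SEs", {
  rec <- data.frame(study = "s1", age = c(35, 36, 37), sex = "female",
                    weight = 1, tc = c(4, 5, 6), hdl = c(1, 1, 1))
  s <- summarize_strata(rec)
  tot <- s[s$metric == "total", ]
  expect_equal(tot$mean, 5.0)
  expect_equal(tot$se, sd(c(4, 5, 6)) / sqrt(3), tolerance = 1e-12)
  expect_equal(tot$band, "30-39")
  ## age 19 lands in the 18-19 band
  rec19 <- data.frame(study = "s1", age = c(19, 19), sex = "male", weight = 1,
                      tc = c(4, 5), hdl = 1)
  expect_identical(summarize_strata(rec19)$band[1], "18-19")
  ## weighted case against a hand-computed ratio-estimator oracle:
  ## wm = (1*4 + 3*6)/4 = 5.5; var = (1*2.25 + 9*0.25)/16 * 2 = 0.5625
  recw <- data.frame(study = "s1", age = 35, sex = "female",
                     weight = c(1, 3), tc = c(4, 6), hdl = 1)
  sw <- summarize_strata(recw)
  totw <- sw[sw$metric == "total", ]
  expect_equal(totw$mean, 5.5)
  expect_equal(totw$se, sqrt(0.5625), tolerance = 1e-12)
  ## non-HDL is the weighted mean of per-person TC - HDL
  nh <- sw[sw$metric == "nonhdl", ]
  expect_equal(nh$mean, 5.5 - 1)
  ## nonpositive weights are a hard error naming the study
  recb <- data.frame(study = "sBAD", age = 35, sex = "female",
                     weight = c(1, 0), tc = c(4, 6), hdl = 1)
  expect_error(summarize_strata(recb), "sBAD")
})
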