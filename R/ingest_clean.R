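#' Plausibility rules for individual lipid measurements
#'
#' Encodes the record-level cleaning rules: total cholesterol outside
#' (1.75, 20) mmol/l, HDL outside (0.4, 5) mmol/l, total below HDL, and —
#' when LDL is measured — the cross-metric consistency rule based on the
#' CDC Cholesterol Reference Method Laboratory Network (CRMLN) allowable
#' error limits (8.9% for total, 13% for HDL, 12% for LDL). Bounds are
#' strict: a value exactly at a bound is retained. The CRMLN rule is
#' operationalized in its most permissive form: a record is removed when
#' `LDL * (1 - eLDL) + HDL * (1 - eHDL) > TC * (1 + eTC)`, i.e. when the sum
#' of the fractions exceeds total cholesterol even after shifting every
#' component to its error-limit extreme.
#'
#' @param tc_bounds,hdl_bounds Length-2 numeric vectors: exclusive lower and
#'   upper plausibility bounds in mmol/l.
#' @param crmln_errors Named vector of allowable relative measurement errors
#'   (`tc`, `hdl`, `ldl`), each in (0, 1).
#' @return A list of class `plausibility_rules`.
#' @export
plausibility_rules <- function(tc_bounds = c(1.75, 20),
                               hdl_bounds = c(0.4, 5),
                               crmln_errors = c(tc = 0.089, hdl = 0.13,
                                                ldl = 0.12)) {
  stopifnot(tc_bounds[1] < tc_bounds[2], hdl_bounds[1] < hdl_bounds[2],
            all(crmln_errors > 0), all(crmln_errors < 1))
  structure(list(tc_bounds = tc_bounds, hdl_bounds = hdl_bounds,
                 crmln_errors = crmln_errors),
            class = "plausibility_rules")
}

#' Source-level eligibility check
#'
#' Applies the study-inclusion rules tied to the sampling frame: a
#' probabilistic frame is always eligible; school-based frames require
#' secondary-school enrolment of at least 70% in the country; health-insurance
#' frames require at least 80% of the population to be insured; general
#' practice / primary-care frames require universal insurance coverage (as
#' found in high-income and central European systems). Any frame whose
#' required context value is missing yields status `"undeterminable"` rather
#' than a silent pass.
#'
#' @param study One-row data.frame (or list) with at least a `frame` field
#'   from `{probabilistic, school, insurance, primary-care}`.
#' @param context List with optional fields `school_enrolment` (percent),
#'   `insured` (percent), `universal_insurance` (logical).
#' @return List with `eligible` (TRUE/FALSE/NA), `status`
#'   (`"eligible"`, `"ineligible"`, `"undeterminable"`) and `reasons`.
#' @export
check_source_eligibility <- function(study, context = list()) {
  frame <- study$frame
  stopifnot(is.character(frame), length(frame) == 1)
  reasons <- character()
  status <- "eligible"
  if (frame == "probabilistic") {
    # national/subnational/community probabilistic samples all qualify
  } else if (frame == "school") {
    enr <- context$school_enrolment
    if (is.null(enr) || is.na(enr)) {
      status <- "undeterminable"
      reasons <- "school frame but school enrolment unknown"
    } else if (enr < 70) {
      status <- "ineligible"
      reasons <- sprintf("school enrolment %.0f%% below the 70%% threshold", enr)
    }
  } else if (frame == "insurance") {
    ins <- context$insured
    if (is.null(ins) || is.na(ins)) {
      status <- "undeterminable"
      reasons <- "insurance frame but insured share unknown"
    } else if (ins < 80) {
      status <- "ineligible"
      reasons <- sprintf("insured share %.0f%% below the 80%% threshold", ins)
    }
  } else if (frame == "primary-care") {
    uni <- context$universal_insurance
    if (is.null(uni) || is.na(uni)) {
      status <- "undeterminable"
      reasons <- "primary-care frame but universal-insurance status unknown"
    } else if (!isTRUE(uni)) {
      status <- "ineligible"
      reasons <- "primary-care frame outside a universal-insurance system"
    }
  } else {
    status <- "ineligible"
    reasons <- sprintf("non-probabilistic sampling frame '%s'", frame)
  }
  list(eligible = switch(status, eligible = TRUE, ineligible = FALSE, NA),
       status = status, reasons = reasons)
}

#' Filter individual records by the plausibility rules
#'
#' Removes, in order: participants under 18; pregnant participants; records
#' with total cholesterol outside its plausibility window; records with HDL
#' outside its window; records where total cholesterol is below HDL; and,
#' when LDL is present, records violating the CRMLN cross-metric rule. Each
#' record is counted against the first rule it violates, so per-rule removals
#' plus retained records always reconcile with the input count. Missing lipid
#' values pass the rules that need them; a missing pregnancy flag is treated
#' as not pregnant.
#'
#' @param records data.frame with columns `study`, `age`, `tc`, `hdl` and
#'   optionally `pregnant`, `ldl`.
#' @param rules A [plausibility_rules()] object.
#' @return List with `records` (retained rows) and `log` (an
#'   `exclusion_log` data.frame: per-study, per-rule removal counts plus
#'   retained and input counts).
#' @export
filter_participants <- function(records, rules = plausibility_rules()) {
  stopifnot_cols(records, c("study", "age", "tc", "hdl"), "records")
  n <- nrow(records)
  pregnant <- if ("pregnant" %in% names(records)) {
    ifelse(is.na(records$pregnant), FALSE, records$pregnant)
  } else rep(FALSE, n)
  ldl <- if ("ldl" %in% names(records)) records$ldl else rep(NA_real_, n)
  e <- rules$crmln_errors

  bad_age <- is.na(records$age) | records$age < 18
  bad_preg <- !bad_age & pregnant
  tc_out <- !is.na(records$tc) &
    (records$tc < rules$tc_bounds[1] | records$tc > rules$tc_bounds[2])
  hdl_out <- !is.na(records$hdl) &
    (records$hdl < rules$hdl_bounds[1] | records$hdl > rules$hdl_bounds[2])
  tc_lt_hdl <- !is.na(records$tc) & !is.na(records$hdl) &
    records$tc < records$hdl
  crmln <- !is.na(records$tc) & !is.na(records$hdl) & !is.na(ldl) &
    (ldl * (1 - e[["ldl"]]) + records$hdl * (1 - e[["hdl"]]) >
       records$tc * (1 + e[["tc"]]))

  rule_names <- c("age_under_18", "pregnant", "tc_implausible",
                  "hdl_implausible", "tc_below_hdl", "crmln_sum")
  hits <- cbind(bad_age, bad_preg, tc_out, hdl_out, tc_lt_hdl, crmln)
  ## attribute each removal to the first violated rule
  first_hit <- apply(hits, 1, function(h) {
    w <- which(h)
    if (length(w)) w[1] else 0L
  })
  removed <- first_hit > 0L
  log_tab <- do.call(rbind, lapply(split(seq_len(n), records$study), function(ix) {
    cnt <- tabulate(first_hit[ix], nbins = length(rule_names))
    data.frame(study = records$study[ix[1]],
               as.list(setNames(cnt, rule_names)),
               retained = sum(first_hit[ix] == 0L),
               input = length(ix), stringsAsFactors = FALSE)
  }))
  rownames(log_tab) <- NULL
  class(log_tab) <- c("exclusion_log", "data.frame")
  list(records = records[!removed, , drop = FALSE], log = log_tab)
}

#' Collapse records into survey-weighted stratum summaries
#'
#' Computes the survey-weighted mean, its design-based standard error (ratio
#' estimator) and the sample size for every study by sex by age band by
#' metric cell. Metrics are total cholesterol (`total`), HDL (`hdl`) and
#' non-HDL (`nonhdl`), the last computed per person as total minus HDL over
#' persons with both measurements. Empty strata are omitted; single-person
#' strata carry an `NA` standard error.
#'
#' @param records Filtered records (see [filter_participants()]) with columns
#'   `study`, `age`, `sex`, `weight`, `tc`, `hdl`.
#' @param studies Optional study table; when provided, study metadata
#'   (country, year, coverage, urbanicity, device) is joined on.
#' @return data.frame of stratum summaries: study, sex, band, metric, mean,
#'   se, n (plus study metadata when available).
#' @export
summarize_strata <- function(records, studies = NULL) {
  stopifnot_cols(records, c("study", "age", "sex", "weight", "tc", "hdl"),
                 "records")
  if (any(records$weight <= 0, na.rm = TRUE) || anyNA(records$weight)) {
    bad <- unique(records$study[is.na(records$weight) | records$weight <= 0])
    stop(sprintf("nonpositive or missing survey weights in study %s",
                 paste(bad, collapse = ", ")))
  }
  records$band <- assign_age_band(records$age)
  if (anyNA(records$band)) stop("summarize_strata received under-18 records")
  vals <- list(total = records$tc, hdl = records$hdl,
               nonhdl = ifelse(!is.na(records$tc) & !is.na(records$hdl),
                               records$tc - records$hdl, NA_real_))
  out <- list()
  for (metric in names(vals)) {
    v <- vals[[metric]]
    ok <- !is.na(v)
    if (!any(ok)) next
    key <- interaction(records$study[ok], records$sex[ok], records$band[ok],
                       drop = TRUE)
    sub <- split(data.frame(v = v[ok], w = records$weight[ok]), key)
    res <- do.call(rbind, lapply(sub, function(d) weighted_mean_se(d$v, d$w)))
    parts <- do.call(rbind, strsplit(names(sub), ".", fixed = TRUE))
    out[[metric]] <- data.frame(study = parts[, 1], sex = parts[, 2],
                                band = parts[, 3], metric = metric,
                                mean = res[, "mean"], se = res[, "se"],
                                n = as.integer(res[, "n"]),
                                stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (!is.null(studies)) {
    idx <- match(out$study, studies$study)
    out$country <- studies$country[idx]
    out$year <- studies$year[idx]
    out$coverage <- studies$coverage[idx]
    out$urbanicity <- studies$urbanicity[idx]
    out$device <- studies$device[idx]
  }
  out
}
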