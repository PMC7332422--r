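#' Classify a country's data richness
#'
#' Data rich: 5 or more sources with at least one after the year 2000;
#' data poor: exactly 1 source; average: 2-4 sources. A country with 5 or
#' more sources but none after 2000 lacks the recency the rich class
#' requires and is classified as average. Countries with no sources are
#' `"no data"` and are never eligible for hold-out.
#'
#' @param inventory data.frame with columns `country`, `study`, `year`
#'   (one row per source, or per stratum — duplicates are collapsed).
#' @return Named character vector: richness class per country.
#' @export
classify_richness <- function(inventory) {
  inv <- unique(inventory[, c("country", "study", "year")])
  out <- vapply(split(inv, inv$country), function(d) {
    ns <- length(unique(d$study))
    if (ns == 0) "no data"
    else if (ns == 1) "data poor"
    else if (ns >= 5 && any(d$year > 2000)) "data rich"
    else "average"
  }, "")
  out
}

round_half_up <- function(x) floor(x + 0.5)

#' Build hold-out plans for the external-validity tests
#'
#' Two test kinds. `"countries"`: each plan removes all data from 10% of the
#' countries with data (rounded half-up), sampled within richness strata.
#' `"sources"`: each plan removes roughly 10% of data sources; countries are
#' drawn across richness strata and, alternating deterministically, either a
#' random half of the country's sources or all of its post-2000 sources are
#' held out, until the source quota is met. Five repetitions by default,
#' each holding out a different subset; fully deterministic under the seed.
#'
#' @param inventory data.frame (country, study, year), one row per source.
#' @param kind `"countries"` or `"sources"`.
#' @param seed Integer seed.
#' @param n_reps Number of repetitions (default 5).
#' @return List of `holdout_plan` objects with fields `kind`, `rep`,
#'   `heldout_countries` (kind countries) or `heldout_studies` (kind
#'   sources), `modes`, and `richness`.
#' @export
make_holdout_plans <- function(inventory, kind = c("countries", "sources"),
                               seed = 1, n_reps = 5) {
  kind <- match.arg(kind)
  inv <- unique(inventory[, c("country", "study", "year")])
  rich <- classify_richness(inv)
  rich <- rich[rich != "no data"]
  if (length(rich) < 10) stop("fewer than 10 eligible countries for hold-out")
  set.seed(as.integer(seed))
  plans <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    if (kind == "countries") {
      k <- round_half_up(0.10 * length(rich))
      picked <- character()
      strata <- split(names(rich), rich)
      ## allocate proportionally across richness strata, at least the quota
      alloc <- round_half_up(k * lengths(strata) / length(rich))
      while (sum(alloc) < k) alloc[which.max(lengths(strata) - alloc)] <-
          alloc[which.max(lengths(strata) - alloc)] + 1
      for (s in names(strata)) {
        ns <- min(alloc[[s]], length(strata[[s]]))
        if (ns > 0) picked <- c(picked, sample(strata[[s]], ns))
      }
      plans[[r]] <- structure(list(kind = kind, rep = r,
                                   heldout_countries = sort(picked[seq_len(min(k, length(picked)))]),
                                   richness = rich),
                              class = "holdout_plan")
    } else {
      n_sources <- nrow(inv)
      quota <- round_half_up(0.10 * n_sources)
      order_countries <- unlist(lapply(split(names(rich), rich), sample),
                                use.names = FALSE)
      order_countries <- sample(order_countries)
      held <- character()
      modes <- character()
      ci <- 0
      for (cc in order_countries) {
        if (length(held) >= quota) break
        ci <- ci + 1
        src <- inv$study[inv$country == cc]
        mode <- if (ci %% 2 == 1) "random-half" else "post-2000"
        out_src <- if (mode == "random-half") {
          sample(src, max(1, floor(length(src) / 2)))
        } else {
          inv$study[inv$country == cc & inv$year >= 2000]
        }
        if (!length(out_src)) next
        held <- unique(c(held, out_src))
        modes[cc] <- mode
      }
      plans[[r]] <- structure(list(kind = kind, rep = r,
                                   heldout_studies = sort(held),
                                   modes = modes, richness = rich),
                              class = "holdout_plan")
    }
  }
  plans
}

#' Compare held-out strata with posterior predictions
#'
#' Error convention: held-out value minus estimate, so over-estimation gives
#' a negative error. Coverage is the share of held-out values inside the
#' 2.5-97.5 percentile interval of the prediction.
#'
#' @param errors data.frame with columns `error` and `covered` plus a
#'   `stratum` (richness) column; typically built by [run_validation()].
#' @return data.frame: per richness stratum and overall, the median error,
#'   median absolute error and coverage percent. Overall rows pool the
#'   individual errors (medians of pooled errors, not means of stratum
#'   medians).
#' @export
validation_report <- function(errors) {
  one <- function(d, label) data.frame(
    stratum = label, n = nrow(d),
    median_error = median(d$error),
    median_abs_error = median(abs(d$error)),
    coverage_pct = 100 * mean(d$covered), stringsAsFactors = FALSE)
  parts <- lapply(split(errors, errors$stratum), function(d)
    one(d, d$stratum[1]))
  out <- rbind(do.call(rbind, parts), one(errors, "overall"))
  rownames(out) <- NULL
  out
}

#' Run an external-predictive-validity test on a synthetic database
#'
#' For each hold-out plan, refits the model on the retained 90% and predicts
#' the held-out stratum summaries; no held-out observation enters the refit
#' design (the returned object records the training studies per repetition
#' so the no-leakage property can be audited). A repetition whose refit
#' fails is marked and excluded from the pooled report.
#'
#' @param strata Full stratum-summary table.
#' @param hierarchy World hierarchy (as in [build_design()]).
#' @param plans Plans from [make_holdout_plans()].
#' @param spec A [model_spec()] sized for the validation refits.
#' @param sex,metric Which model to fit.
#' @param seed Integer seed.
#' @return List of class `validation_run`: `errors` (per held-out stratum:
#'   rep, country, stratum class, held-out value, estimate, interval,
#'   error, covered), `report` (from [validation_report()]),
#'   `training_studies` (per rep), `failed_reps`.
#' @export
run_validation <- function(strata, hierarchy, plans, spec,
                           sex = "female", metric = "total", seed = 1) {
  all_err <- list()
  training_studies <- list()
  failed <- integer()
  for (pl in plans) {
    d <- strata[strata$sex == sex & strata$metric == metric, , drop = FALSE]
    if (pl$kind == "countries") {
      hold <- d$country %in% pl$heldout_countries
    } else {
      hold <- d$study %in% pl$heldout_studies
    }
    train <- d[!hold, , drop = FALSE]
    test <- d[hold, , drop = FALSE]
    training_studies[[pl$rep]] <- unique(train$study)
    res <- tryCatch({
      des <- build_design(train, hierarchy, spec, sex, metric)
      fit <- fit_mcmc(des, seed = seed + pl$rep)
      pr <- predict_surface(fit, test$country, test$year, test$band)
      est <- apply(pr, 2, median)
      lo <- apply(pr, 2, quantile, 0.025)
      hi <- apply(pr, 2, quantile, 0.975)
      data.frame(rep = pl$rep, study = test$study, country = test$country,
                 year = test$year, band = test$band,
                 stratum = pl$richness[test$country],
                 heldout = test$mean, estimate = est, lo2.5 = lo,
                 hi97.5 = hi, error = test$mean - est,
                 covered = test$mean >= lo & test$mean <= hi,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning(sprintf("validation repetition %d failed: %s", pl$rep,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(res)) failed <- c(failed, pl$rep) else {
      all_err[[length(all_err) + 1]] <- res
    }
  }
  errors <- do.call(rbind, all_err)
  structure(list(errors = errors,
                 report = if (!is.null(errors)) validation_report(errors),
                 training_studies = training_studies,
                 failed_reps = failed,
                 n_reps = length(plans)),
            class = "validation_run")
}
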