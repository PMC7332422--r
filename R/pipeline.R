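#' Synthetic cause-specific death counts
#'
#' Generates a plausible deaths table (IHD and ischaemic stroke) from the
#' synthetic world's populations: age-increasing cardiovascular mortality
#' rates, higher for men, applied to the population counts. Purely synthetic
#' scaffolding for exercising the burden stage.
#'
#' @param world A `synthetic_world`.
#' @param years Years to tabulate (default: first and last world year,
#'   mirroring the use of the earliest and latest years with cause-specific
#'   mortality data).
#' @param seed Integer seed.
#' @return data.frame: cause, country, year, sex, band, deaths.
#' @export
synthetic_deaths <- function(world, years = NULL, seed = 1) {
  set.seed(as.integer(seed))
  pop <- world$hierarchy$populations
  years <- years %||% range(world$components$years)
  pop <- pop[pop$year %in% years, , drop = FALSE]
  ab <- age_bands()
  ## baseline IHD mortality per person-year rising steeply with age
  base_rate <- exp(-9 + 0.075 * (ab$midpoint - 40))
  rate <- base_rate[match(pop$band, ab$band)] *
    ifelse(pop$sex == "male", 1.6, 1.0)
  out <- rbind(
    data.frame(cause = "ihd", pop[, c("country", "year", "sex", "band")],
               deaths = pop$pop * rate * exp(rnorm(nrow(pop), 0, 0.1))),
    data.frame(cause = "ischaemic_stroke",
               pop[, c("country", "year", "sex", "band")],
               deaths = pop$pop * rate * 0.45 * exp(rnorm(nrow(pop), 0, 0.1)))
  )
  rownames(out) <- NULL
  out
}

#' Pipeline run configuration
#'
#' @param out_dir Output directory for artifacts.
#' @param seed Master seed; per-stage seeds are derived deterministically.
#' @param world A [world_config()] for the simulate stage.
#' @param model A [model_spec()] for the fit stage.
#' @param stages Character vector of enabled stages, a subset of
#'   `c("simulate", "clean", "adjust", "fit", "summarize", "burden",
#'   "validate")` in dependency order.
#' @param sexes Sexes to fit.
#' @param metrics Metrics to fit (`"total"` first; fraction models use the
#'   age-standardized total-cholesterol estimates as a covariate).
#' @param n_validation_reps Hold-out repetitions in the validate stage.
#' @param device_ranges Device analytical-range table.
#' @return List of class `run_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("choltrends_run_"),
                            seed = 1,
                            world = world_config(),
                            model = model_spec(years = world$years),
                            stages = c("simulate", "clean", "adjust", "fit",
                                       "summarize", "burden", "validate"),
                            sexes = "female",
                            metrics = c("total", "nonhdl"),
                            n_validation_reps = 5,
                            device_ranges = device_ranges_example()) {
  known <- c("simulate", "clean", "adjust", "fit", "summarize", "burden",
             "validate")
  stopifnot(all(stages %in% known))
  cfg <- as.list(environment())
  cfg$known <- NULL
  class(cfg) <- "run_config"
  cfg
}

## semantic hash of a config: drop the output path, which is not semantic
config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  rlang::hash(x)
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in dependency order: simulate a synthetic
#' world, clean records, truncate and adjust device-measured strata, fit the
#' trend model (total cholesterol first, then lipid fractions with the
#' age-standardized total-cholesterol covariate), post-process into estimate
#' and trend tables, compute attributable deaths, and run the hold-out
#' validation. Every artifact is written as CSV/JSON under `out_dir` and
#' stamped into a manifest with the config hash; a rerun with the same
#' config and seed reproduces all outputs.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest (invisibly also written to
#'   `manifest.json`): stage statuses, artifact paths, config hash, seeds.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(name) file.path(config$out_dir, name)
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   stages = list(), artifacts = list())
  state <- new.env(parent = emptyenv())
  failed_upstream <- character()

  stage_seeds <- setNames(config$seed + seq(0, 600, by = 100),
                          c("simulate", "clean", "adjust", "fit",
                            "summarize", "burden", "validate"))
  deps <- list(simulate = character(), clean = "simulate",
               adjust = "clean", fit = "adjust", summarize = "fit",
               burden = "summarize", validate = "adjust")

  run_stage <- function(name, fn) {
    if (!(name %in% config$stages)) {
      manifest$stages[[name]] <<- "disabled"
      return(invisible(NULL))
    }
    deps_ok <- all(vapply(deps[[name]], function(d) {
      exists(d, envir = state) && isTRUE(get(d, envir = state))
    }, TRUE))
    if (!deps_ok) {
      manifest$stages[[name]] <<- "skipped (failed or missing dependency)"
      failed_upstream <<- c(failed_upstream, name)
      return(invisible(NULL))
    }
    ok <- tryCatch({ fn(); TRUE },
                   error = function(e) {
                     manifest$stages[[name]] <<- paste("failed:",
                                                       conditionMessage(e))
                     FALSE
                   })
    if (ok) manifest$stages[[name]] <<- "ok"
    else failed_upstream <<- c(failed_upstream, name)
    invisible(NULL)
  }

  run_stage("simulate", function() {
    state$world <- generate_world(config$world, stage_seeds[["simulate"]])
    state$studies <- generate_studies(state$world, config$world,
                                      stage_seeds[["simulate"]] + 1)
    state$records <- generate_records(state$world, state$studies,
                                      config$world,
                                      stage_seeds[["simulate"]] + 2)
    write.csv(state$studies, art("studies.csv"), row.names = FALSE)
    manifest$artifacts$studies <<- art("studies.csv")
    state$simulate <- TRUE
  })

  run_stage("clean", function() {
    fl <- filter_participants(state$records)
    state$clean_records <- fl$records
    write.csv(fl$log, art("exclusion_log.csv"), row.names = FALSE)
    manifest$artifacts$exclusion_log <<- art("exclusion_log.csv")
    state$clean <- TRUE
  })

  run_stage("adjust", function() {
    rec <- truncate_records(state$clean_records, config$device_ranges)
    strata <- summarize_strata(rec, state$studies)
    models <- list()
    for (dev in unique(config$device_ranges$device)) {
      if (!any(strata$device == dev)) next
      dr <- config$device_ranges[config$device_ranges$device == dev, ]
      for (met in union("total", config$metrics)) {
        pairs <- make_training_pairs(state$clean_records, dr, met)
        models[[paste(dev, met)]] <- fit_conversion(pairs, met, dev)
      }
    }
    strata$provenance <- ifelse(strata$device == "laboratory",
                                "laboratory", "device-adjusted")
    strata0 <- strata  # unadjusted restricted-range means
    key0 <- paste(strata0$study, strata0$sex, strata0$band, strata0$metric)
    for (met in union("total", config$metrics)) {
      sub <- strata$metric == met
      if (!any(sub & strata$device != "laboratory")) next
      mods <- setNames(lapply(unique(config$device_ranges$device),
                              function(d) models[[paste(d, met)]]),
                       unique(config$device_ranges$device))
      block <- strata[sub, , drop = FALSE]
      if (met == "nonhdl") {
        kk <- paste(block$study, block$sex, block$band)
        block$tc_restr_mean <- strata0$mean[match(paste(kk, "total"), key0)]
        block$hdl_restr_mean <- strata0$mean[match(paste(kk, "hdl"), key0)]
      }
      adj <- adjust_device_strata(block, mods, n_draws = 300,
                                  seed = stage_seeds[["adjust"]])
      strata[sub, c("mean", "se")] <- adj[, c("mean", "se")]
    }
    state$strata <- strata
    write.csv(strata, art("strata.csv"), row.names = FALSE)
    manifest$artifacts$strata <<- art("strata.csv")
    state$adjust <- TRUE
  })

  run_stage("fit", function() {
    fits <- list()
    tc_cov <- list()
    metrics <- config$metrics
    if (any(metrics != "total")) metrics <- union("total", metrics)
    for (sex in config$sexes) {
      for (met in metrics) {
        cov <- if (met != "total") tc_cov[[sex]] else NULL
        des <- build_design(state$strata, state$world$hierarchy,
                            config$model, sex, met, tc_covariate = cov)
        fit <- fit_mcmc(des, seed = stage_seeds[["fit"]])
        fits[[paste(sex, met)]] <- fit
        if (met == "total") {
          surf <- posterior_surface(fit)
          std <- age_standardize(surf)
          m <- apply(std, c(2, 3), mean)
          tc_cov[[sex]] <- data.frame(
            country = rep(rownames(m), ncol(m)),
            year = rep(as.integer(colnames(m)), each = nrow(m)),
            value = as.numeric(m))
        }
      }
    }
    state$fits <- fits
    diag <- lapply(fits, function(f) f$diagnostics$table)
    jsonlite::write_json(diag, art("diagnostics.json"), dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
    manifest$artifacts$diagnostics <<- art("diagnostics.json")
    state$fit <- TRUE
  })

  run_stage("summarize", function() {
    est <- list(); trend <- list()
    for (nm in names(state$fits)) {
      fit <- state$fits[[nm]]
      surf <- posterior_surface(fit)
      std <- age_standardize(surf)
      est[[nm]] <- summarize_estimates(std, fit$design$metric,
                                       fit$design$sex)
      ch <- change_per_decade(std)
      ent <- dimnames(std)[[2]]
      pp <- t(apply(ch$draws, 2, trend_probability))
      trend[[nm]] <- data.frame(metric = fit$design$metric,
                                entity = ent, sex = fit$design$sex,
                                change_per_decade = apply(ch$draws, 2, median),
                                lo2.5 = ch$summary[, "lo2.5"],
                                hi97.5 = ch$summary[, "hi97.5"],
                                pp_decline = pp[, "pp_decline"],
                                pp_increase = pp[, "pp_increase"],
                                stringsAsFactors = FALSE)
      state$surfaces[[nm]] <- surf
    }
    est <- do.call(rbind, c(est, list(make.row.names = FALSE)))
    trend <- do.call(rbind, c(trend, list(make.row.names = FALSE)))
    write.csv(est, art("estimates.csv"), row.names = FALSE)
    write.csv(trend, art("trends.csv"), row.names = FALSE)
    manifest$artifacts$estimates <<- art("estimates.csv")
    manifest$artifacts$trends <<- art("trends.csv")
    state$summarize <- TRUE
  })

  run_stage("burden", function() {
    nm <- grep("nonhdl$", names(state$surfaces), value = TRUE)
    if (!length(nm)) stop("burden stage needs a non-HDL surface")
    deaths <- synthetic_deaths(state$world, seed = stage_seeds[["burden"]])
    res <- list()
    for (k in nm) {
      res[[k]] <- attributable_deaths(state$surfaces[[k]],
                                      exposure_sd = 0.9,
                                      rr_curves = rr_curves_example(),
                                      deaths = deaths)
    }
    cells <- do.call(rbind, c(lapply(res, `[[`, "cells"),
                              list(make.row.names = FALSE)))
    write.csv(cells, art("attributable_deaths.csv"), row.names = FALSE)
    manifest$artifacts$attributable_deaths <<- art("attributable_deaths.csv")
    state$burden <- TRUE
  })

  run_stage("validate", function() {
    inv <- unique(state$strata[, c("country", "study", "year")])
    plans <- make_holdout_plans(inv, "countries",
                                seed = stage_seeds[["validate"]],
                                n_reps = config$n_validation_reps)
    vr <- run_validation(state$strata, state$world$hierarchy, plans,
                         config$model, sex = config$sexes[1],
                         metric = "total",
                         seed = stage_seeds[["validate"]])
    write.csv(vr$report, art("validation_report.csv"), row.names = FALSE)
    manifest$artifacts$validation_report <<- art("validation_report.csv")
    state$validate <- TRUE
  })

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
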