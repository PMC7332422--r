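#' Specification of the hierarchical trend model
#'
#' Collects the structural and MCMC settings for the Bayesian hierarchical
#' model of mean cholesterol. The model links stratum summaries to a linear
#' predictor with components at four nested levels (world, super-region,
#' region, country): an intercept, a linear time slope (per decade) and a
#' second-order random-walk (RW2) deviation at each level; a natural cubic
#' spline in age (knots at the age-band midpoints 25-75) with hierarchically
#' shrunk country-level perturbations; fixed effects for subnational and
#' community studies and for rural-only/urban-only studies (the latter
#' weighted by country urbanization); study-level random effects for
#' subnational and community studies; and country-year covariates
#' (urbanization, and optionally age-standardized total cholesterol for the
#' lipid-fraction models). Observation variance is the squared standard
#' error plus a coverage-class overdispersion component.
#'
#' Priors: diffuse normal (SD `sd_fixed`) on all fixed effects;
#' half-normal priors (scales in `hn`) on every random-effect and
#' overdispersion SD. RW2 deviations are parameterized in the spectral basis
#' of the second-difference penalty, which makes every draw exactly
#' orthogonal to the level and linear trend (the identifiability constraint).
#'
#' @param years Integer vector of years modelled.
#' @param n_draws Post-burn-in draws retained (default 5000).
#' @param burnin Burn-in iterations.
#' @param thin Thinning interval.
#' @param n_chains Number of chains.
#' @param sd_fixed Prior SD for fixed effects.
#' @param hn Named vector of half-normal prior scales for the SDs of:
#'   hierarchical intercepts (`int`), slopes (`slope`), RW2 innovations
#'   (`rw2`), country spline perturbations (`spline`), study random effects
#'   (`re`), and observation overdispersion (`kappa`).
#' @param rhat_threshold Split-chain convergence threshold above which the
#'   fit is flagged.
#' @return List of class `model_spec`.
#' @export
model_spec <- function(years = 1980:2018, n_draws = 5000, burnin = 2000,
                       thin = 1, n_chains = 1, sd_fixed = 10,
                       hn = c(int = 0.5, slope = 0.3, rw2 = 0.1,
                              spline = 0.3, re = 0.3, kappa = 0.3),
                       rhat_threshold = 1.05) {
  stopifnot(length(years) >= 3, n_draws >= 1, burnin >= 0, thin >= 1)
  structure(as.list(environment()), class = "model_spec")
}

## Spectral basis of the RW2 penalty on T time points: columns are the
## eigenvectors of crossprod(D2) with positive eigenvalue; the null space
## {1, t} is excluded, so any combination of the basis has zero sum and zero
## linear trend. Prior precision of coefficient j is lambda_j / sigma^2.
rw2_basis <- function(T) {
  K <- crossprod(diff(diag(T), differences = 2))
  e <- eigen(K, symmetric = TRUE)
  keep <- e$values > 1e-8
  ## scale so that the marginal variances average 1 at sigma = 1 (keeps the
  ## half-normal prior scale interpretable across year-range lengths)
  B <- e$vectors[, keep, drop = FALSE]
  lam <- e$values[keep]
  gv <- exp(mean(log(1 / lam)))
  list(B = B, lambda = lam * gv)
}

age_spline_basis <- function() {
  ab <- age_bands()
  S <- splines::ns(ab$midpoint, knots = c(25, 35, 45, 55, 65, 75),
                   Boundary.knots = c(19, 85))
  S <- scale(S, center = TRUE, scale = FALSE)
  attr(S, "scaled:center") <- NULL
  rownames(S) <- ab$band
  unclass(S)
}

#' Assemble the model design from stratum summaries
#'
#' Builds the sparse observation design matrix, prior blocks and index maps
#' linking each stratum summary to its hierarchy, time, age, study-type and
#' covariate terms. One design is built per sex and metric.
#'
#' @param strata Stratum-summary table (columns study, country, year, sex,
#'   band, metric, mean, se, n, coverage, urbanicity) already cleaned and
#'   device-adjusted; rows are filtered to `sex` and `metric`.
#' @param hierarchy Hierarchy list with `countries` (country, region,
#'   super_region) and `urbanization` (country, year, prop_urban).
#' @param spec A [model_spec()].
#' @param sex `"female"` or `"male"`.
#' @param metric `"total"`, `"hdl"` or `"nonhdl"`.
#' @param tc_covariate Optional data.frame (country, year, value) of
#'   age-standardized mean total cholesterol, required by convention for the
#'   lipid-fraction models.
#' @return Object of class `chol_design`.
#' @export
build_design <- function(strata, hierarchy, spec, sex, metric,
                         tc_covariate = NULL) {
  d <- strata[strata$sex == sex & strata$metric == metric, , drop = FALSE]
  if (nrow(d) == 0) stop("no stratum summaries for this sex/metric")
  hc <- hierarchy$countries
  urb <- hierarchy$urbanization
  bad <- setdiff(unique(d$country), hc$country)
  if (length(bad)) stop(sprintf("countries absent from hierarchy: %s",
                                paste(bad, collapse = ", ")))
  if (any(!d$year %in% spec$years)) {
    stop("stratum years outside the modelled year range")
  }
  ## single-individual strata carry no usable SE
  d <- d[!is.na(d$se) & d$n > 1, , drop = FALSE]
  if (any(d$se <= 0)) stop("nonpositive standard errors in stratum summaries")

  countries <- hc$country
  regions <- sort(unique(hc$region))
  supers <- sort(unique(hc$super_region))
  years <- spec$years
  T <- length(years)
  t_std <- (years - mean(years)) / 10
  rb <- rw2_basis(T)
  S <- age_spline_basis()
  nS <- ncol(S)
  ab <- age_bands()

  ci <- match(d$country, countries)
  ri <- match(hc$region[ci], regions)
  si <- match(hc$super_region[ci], supers)
  ti <- match(d$year, years)
  bi <- match(d$band, ab$band)
  urb_key <- paste(urb$country, urb$year)
  uval <- urb$prop_urban[match(paste(d$country, d$year), urb_key)]
  if (anyNA(uval)) stop("urbanization covariate missing for some country-years")
  urb_center <- mean(urb$prop_urban[urb$country %in% countries &
                                      urb$year %in% years])
  tc_center <- NULL
  tcv <- NULL
  if (!is.null(tc_covariate)) {
    tc_key <- paste(tc_covariate$country, tc_covariate$year)
    tcv <- tc_covariate$value[match(paste(d$country, d$year), tc_key)]
    if (anyNA(tcv)) stop("total-cholesterol covariate missing for some country-years")
    tc_center <- mean(tc_covariate$value)
  } else if (metric != "total") {
    warning("fitting a lipid-fraction model without the total-cholesterol covariate")
  }
  sub_studies <- sort(unique(d$study[d$coverage == "subnational"]))
  com_studies <- sort(unique(d$study[d$coverage == "community"]))

  ## ---- column layout ----
  blocks <- list()
  pcol <- 0L
  add_block <- function(name, ncols, type, scale = rep(1, ncols),
                        hn_scale = NA_real_) {
    if (ncols == 0) return(invisible(NULL))
    blocks[[length(blocks) + 1]] <<- list(
      name = name, idx = pcol + seq_len(ncols), type = type,
      scale = scale, hn = hn_scale)
    pcol <<- pcol + ncols
    invisible(NULL)
  }
  hn <- spec$hn
  nfix <- 2 + nS + 1 + (!is.null(tcv)) + 4
  fix_names <- c("intercept", "slope", paste0("spline", seq_len(nS)), "urban_cov",
                 if (!is.null(tcv)) "tc_cov", "sub_fe", "com_fe",
                 "rural_fe", "urban_fe")
  add_block("fixed", nfix, "fixed")
  add_block("rw2_global", T - 2, "varcomp", rb$lambda, hn[["rw2"]])
  add_block("int_super", length(supers), "varcomp", hn_scale = hn[["int"]])
  add_block("slope_super", length(supers), "varcomp", hn_scale = hn[["slope"]])
  add_block("rw2_super", length(supers) * (T - 2), "varcomp",
            rep(rb$lambda, length(supers)), hn[["rw2"]])
  add_block("int_region", length(regions), "varcomp", hn_scale = hn[["int"]])
  add_block("slope_region", length(regions), "varcomp", hn_scale = hn[["slope"]])
  add_block("rw2_region", length(regions) * (T - 2), "varcomp",
            rep(rb$lambda, length(regions)), hn[["rw2"]])
  add_block("int_country", length(countries), "varcomp", hn_scale = hn[["int"]])
  add_block("slope_country", length(countries), "varcomp", hn_scale = hn[["slope"]])
  add_block("rw2_country", length(countries) * (T - 2), "varcomp",
            rep(rb$lambda, length(countries)), hn[["rw2"]])
  add_block("spline_country", length(countries) * nS, "varcomp",
            hn_scale = hn[["spline"]])
  add_block("re_sub", length(sub_studies), "varcomp", hn_scale = hn[["re"]])
  add_block("re_com", length(com_studies), "varcomp", hn_scale = hn[["re"]])
  names(blocks) <- vapply(blocks, `[[`, "", "name")
  p <- pcol
  col_of <- function(name) blocks[[name]]$idx

  ## ---- observation rows ----
  n <- nrow(d)
  trip_i <- list(); trip_j <- list(); trip_x <- list()
  add <- function(rows, cols, vals) {
    trip_i[[length(trip_i) + 1]] <<- rows
    trip_j[[length(trip_j) + 1]] <<- cols
    trip_x[[length(trip_x) + 1]] <<- vals
  }
  rw2_cols <- function(block, group, tt) {
    ## columns of the RW2 basis for group `group`, all T-2 of them
    col_of(block)[(group - 1) * (T - 2) + seq_len(T - 2)]
  }
  rows <- seq_len(n)
  fx <- col_of("fixed")
  add(rows, rep(fx[1], n), rep(1, n))                       # intercept
  add(rows, rep(fx[2], n), t_std[ti])                       # global slope
  for (k in seq_len(nS)) {
    add(rows, rep(fx[2 + k], n), S[bi, k])                  # global spline
  }
  ucol <- fx[2 + nS + 1]
  add(rows, rep(ucol, n), uval - urb_center)                # urbanization
  off <- 2 + nS + 1
  if (!is.null(tcv)) {
    off <- off + 1
    add(rows, rep(fx[off], n), tcv - tc_center)
  }
  sub_fe <- fx[off + 1]; com_fe <- fx[off + 2]
  rur_fe <- fx[off + 3]; urb_fe <- fx[off + 4]
  is_sub <- d$coverage == "subnational"
  is_com <- d$coverage == "community"
  if (any(is_sub)) add(rows[is_sub], rep(sub_fe, sum(is_sub)), rep(1, sum(is_sub)))
  if (any(is_com)) add(rows[is_com], rep(com_fe, sum(is_com)), rep(1, sum(is_com)))
  ## rural-only/urban-only effects weighted by distance from national
  ## urbanization: a rural study in a highly urban country is far from
  ## nationally representative, so its effect enters with weight prop_urban
  is_rur <- d$urbanicity == "rural"
  is_urb <- d$urbanicity == "urban"
  if (any(is_rur)) add(rows[is_rur], rep(rur_fe, sum(is_rur)), uval[is_rur])
  if (any(is_urb)) add(rows[is_urb], rep(urb_fe, sum(is_urb)), 1 - uval[is_urb])
  ## hierarchy terms
  for (lev in list(list("super", si, length(supers)),
                   list("region", ri, length(regions)),
                   list("country", ci, length(countries)))) {
    g <- lev[[2]]
    add(rows, col_of(paste0("int_", lev[[1]]))[g], rep(1, n))
    add(rows, col_of(paste0("slope_", lev[[1]]))[g], t_std[ti])
    bcols <- col_of(paste0("rw2_", lev[[1]]))
    for (k in seq_len(T - 2)) {
      add(rows, bcols[(g - 1) * (T - 2) + k], rb$B[ti, k])
    }
  }
  for (k in seq_len(T - 2)) {
    add(rows, rep(col_of("rw2_global")[k], n), rb$B[ti, k])
  }
  spc <- col_of("spline_country")
  for (k in seq_len(nS)) {
    add(rows, spc[(ci - 1) * nS + k], S[bi, k])
  }
  if (length(sub_studies)) {
    m <- is_sub & d$study %in% sub_studies
    add(rows[m], col_of("re_sub")[match(d$study[m], sub_studies)],
        rep(1, sum(m)))
  }
  if (length(com_studies)) {
    m <- is_com
    add(rows[m], col_of("re_com")[match(d$study[m], com_studies)],
        rep(1, sum(m)))
  }
  ii <- unlist(trip_i); jj <- unlist(trip_j); xx <- unlist(trip_x)
  keep <- xx != 0
  X <- Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = xx[keep],
                            dims = c(n, p))

  kappa_class <- factor(d$coverage,
                        levels = c("national", "subnational", "community"))
  structure(list(
    y = d$mean, se2 = d$se^2, X = X, n = n, p = p,
    blocks = blocks, fix_names = fix_names,
    kappa_class = kappa_class,
    data = d, sex = sex, metric = metric, spec = spec,
    countries = countries, regions = regions, supers = supers,
    region_of = hc$region[match(countries, hc$country)],
    super_of = hc$super_region[match(countries, hc$country)],
    years = years, t_std = t_std, rw2 = rb, S = S,
    urb = urb, urb_center = urb_center,
    tc_covariate = tc_covariate, tc_center = tc_center
  ), class = "chol_design")
}

## Build prediction rows (linear predictor without study-type terms) for
## given cells; level = "region" zeroes the country-level blocks, giving the
## curve implied by the hierarchy for a generic country of that region.
prediction_matrix <- function(design, country, year, band,
                              level = c("country", "region")) {
  level <- match.arg(level)
  cells <- data.frame(country = country, year = year, band = band,
                      stringsAsFactors = FALSE)
  n <- nrow(cells)
  ab <- age_bands()
  T <- length(design$years)
  nS <- ncol(design$S)
  ci <- match(cells$country, design$countries)
  ri <- match(design$region_of[ci], design$regions)
  si <- match(design$super_of[ci], design$supers)
  ti <- match(cells$year, design$years)
  bi <- match(cells$band, ab$band)
  if (anyNA(ci) || anyNA(ti) || anyNA(bi)) {
    stop("prediction indices outside the fitted design")
  }
  urb_key <- paste(design$urb$country, design$urb$year)
  uval <- design$urb$prop_urban[match(paste(cells$country, cells$year), urb_key)]
  blocks <- design$blocks
  col_of <- function(name) blocks[[name]]$idx
  trip_i <- list(); trip_j <- list(); trip_x <- list()
  add <- function(rows, cols, vals) {
    trip_i[[length(trip_i) + 1]] <<- rows
    trip_j[[length(trip_j) + 1]] <<- cols
    trip_x[[length(trip_x) + 1]] <<- vals
  }
  rows <- seq_len(n)
  fx <- col_of("fixed")
  add(rows, rep(fx[1], n), rep(1, n))
  add(rows, rep(fx[2], n), design$t_std[ti])
  for (k in seq_len(nS)) add(rows, rep(fx[2 + k], n), design$S[bi, k])
  add(rows, rep(fx[2 + nS + 1], n), uval - design$urb_center)
  if (!is.null(design$tc_covariate)) {
    tc_key <- paste(design$tc_covariate$country, design$tc_covariate$year)
    tcv <- design$tc_covariate$value[match(paste(cells$country, cells$year), tc_key)]
    if (anyNA(tcv)) stop("total-cholesterol covariate missing for prediction cells")
    add(rows, rep(fx[2 + nS + 2], n), tcv - design$tc_center)
  }
  for (k in seq_len(T - 2)) {
    add(rows, rep(col_of("rw2_global")[k], n), design$rw2$B[ti, k])
  }
  levs <- list(list("super", si), list("region", ri))
  if (level == "country") levs <- c(levs, list(list("country", ci)))
  for (lv in levs) {
    g <- lv[[2]]
    add(rows, col_of(paste0("int_", lv[[1]]))[g], rep(1, n))
    add(rows, col_of(paste0("slope_", lv[[1]]))[g], design$t_std[ti])
    bcols <- col_of(paste0("rw2_", lv[[1]]))
    for (k in seq_len(T - 2)) {
      add(rows, bcols[(g - 1) * (T - 2) + k], design$rw2$B[ti, k])
    }
  }
  if (level == "country") {
    spc <- col_of("spline_country")
    for (k in seq_len(nS)) add(rows, spc[(ci - 1) * nS + k], design$S[bi, k])
  }
  ii <- unlist(trip_i); jj <- unlist(trip_j); xx <- unlist(trip_x)
  keep <- xx != 0
  Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = xx[keep],
                       dims = c(n, design$p))
}

#' Fit the hierarchical model by MCMC
#'
#' Blocked Gibbs sampler: the full coefficient vector is drawn jointly from
#' its Gaussian full conditional via a sparse Cholesky factorization; every
#' random-effect SD and the coverage-class overdispersion SDs are updated by
#' slice sampling under their half-normal priors. Returns the post-burn-in
#' coefficient draws together with split-chain convergence diagnostics.
#'
#' @param design A [build_design()] object.
#' @param seed Integer seed; the draw stream is fully reproducible.
#' @return Object of class `chol_fit` with elements `theta` (draws x
#'   coefficients), `sigmas`, `kappas`, `diagnostics` (per-parameter split
#'   R-hat and effective sample size, and a `flagged` indicator), `design`.
#' @export
fit_mcmc <- function(design, seed = 1) {
  spec <- design$spec
  X <- design$X
  Xt <- Matrix::t(X)
  y <- design$y
  n <- design$n; p <- design$p
  vblocks <- Filter(function(b) b$type == "varcomp", design$blocks)
  prior_prec_fixed <- 1 / spec$sd_fixed^2
  kap_lvls <- levels(design$kappa_class)
  kclass <- as.integer(design$kappa_class)
  n_iter <- spec$burnin + spec$n_draws * spec$thin

  run_chain <- function(chain) {
    set.seed(as.integer(seed) + 7919L * (chain - 1L))
    sigmas <- vapply(vblocks, function(b) b$hn / 2, 0)
    kappas <- setNames(rep(spec$hn[["kappa"]] / 4, length(kap_lvls)), kap_lvls)
    theta <- numeric(p)
    theta[design$blocks$fixed$idx[1]] <- mean(y)
    keep_theta <- matrix(NA_real_, spec$n_draws, p)
    keep_sig <- matrix(NA_real_, spec$n_draws, length(sigmas) + length(kappas))
    colnames(keep_sig) <- c(names(sigmas), paste0("kappa_", kap_lvls))
    chol_cache <- NULL
    saved <- 0L
    for (it in seq_len(n_iter)) {
      v <- design$se2 + kappas[kclass]^2
      w <- 1 / v
      prec <- rep(prior_prec_fixed, p)
      for (b in vblocks) prec[b$idx] <- b$scale / sigmas[[b$name]]^2
      Xw <- X * sqrt(w)
      Q <- Matrix::forceSymmetric(Matrix::crossprod(Xw)) +
        Matrix::Diagonal(p, prec)
      b_vec <- as.numeric(Xt %*% (w * y))
      if (is.null(chol_cache)) {
        chol_cache <- Matrix::Cholesky(Q, LDL = FALSE, perm = TRUE)
      } else {
        chol_cache <- Matrix::update(chol_cache, Q)
      }
      mu <- as.numeric(Matrix::solve(chol_cache, b_vec, system = "A"))
      z <- rnorm(p)
      u <- Matrix::solve(chol_cache, z, system = "Lt")
      theta <- mu + as.numeric(Matrix::solve(chol_cache, u, system = "Pt"))
      if (any(!is.finite(theta))) {
        stop(sprintf("non-finite sampler state at iteration %d", it))
      }
      ## variance components
      for (bn in names(vblocks)) {
        b <- vblocks[[bn]]
        g <- theta[b$idx]
        ssq <- sum(g^2 * b$scale)
        m <- length(b$idx)
        A2 <- b$hn^2
        logf <- function(l) {
          if (l < -11 || l > 4) return(-Inf)
          s2 <- exp(2 * l)
          -m * l - ssq / (2 * s2) - s2 / (2 * A2) + l
        }
        sigmas[[bn]] <- exp(slice_sample_1d(logf, log(sigmas[[bn]]), w = 0.7))
      }
      ## overdispersion
      r <- y - as.numeric(X %*% theta)
      for (kix in seq_along(kap_lvls)) {
        obs <- which(kclass == kix)
        if (!length(obs)) next
        se2o <- design$se2[obs]; ro <- r[obs]
        A2 <- spec$hn[["kappa"]]^2
        logf <- function(l) {
          if (l < -11 || l > 4) return(-Inf)
          k2 <- exp(2 * l)
          vv <- se2o + k2
          -0.5 * sum(log(vv) + ro^2 / vv) - k2 / (2 * A2) + l
        }
        kappas[kix] <- exp(slice_sample_1d(logf, log(kappas[kix]), w = 0.7))
      }
      if (it > spec$burnin && (it - spec$burnin) %% spec$thin == 0) {
        saved <- saved + 1L
        keep_theta[saved, ] <- theta
        keep_sig[saved, ] <- c(sigmas, kappas)
      }
    }
    list(theta = keep_theta, sig = keep_sig)
  }

  chains <- lapply(seq_len(spec$n_chains), run_chain)
  theta <- do.call(rbind, lapply(chains, `[[`, "theta"))
  sig <- do.call(rbind, lapply(chains, `[[`, "sig"))

  ## diagnostics on top-level parameters: fixed effects + log SDs
  fix_idx <- design$blocks$fixed$idx
  diag_tab <- list()
  for (k in seq_along(fix_idx)) {
    per_chain <- lapply(chains, function(ch) ch$theta[, fix_idx[k]])
    diag_tab[[design$fix_names[k]]] <-
      c(rhat = split_rhat(per_chain), ess = ess_basic(theta[, fix_idx[k]]))
  }
  for (nm in colnames(sig)) {
    per_chain <- lapply(chains, function(ch) log(ch$sig[, nm]))
    diag_tab[[paste0("log_sd_", nm)]] <-
      c(rhat = split_rhat(per_chain), ess = ess_basic(log(sig[, nm])))
  }
  diag_df <- data.frame(parameter = names(diag_tab),
                        rhat = vapply(diag_tab, `[[`, 0, "rhat"),
                        ess = vapply(diag_tab, `[[`, 0, "ess"),
                        row.names = NULL)
  flagged <- any(diag_df$rhat > spec$rhat_threshold, na.rm = TRUE)
  if (flagged) {
    warning(sprintf("convergence flag: max split R-hat %.3f exceeds %.2f",
                    max(diag_df$rhat, na.rm = TRUE), spec$rhat_threshold))
  }
  structure(list(theta = theta, sigmas = sig, design = design,
                 diagnostics = list(table = diag_df, flagged = flagged),
                 seed = seed),
            class = "chol_fit")
}

#' Per-draw predictions of mean cholesterol
#'
#' Evaluates the full linear predictor — hierarchy, time, age and covariate
#' terms, excluding all study-type terms, since the estimand is the general
#' national population — for the requested cells.
#'
#' @param fit A [fit_mcmc()] result.
#' @param country,year,band Vectors (recycled against each other) defining
#'   the cells.
#' @param level `"country"` for national estimates; `"region"` evaluates the
#'   hierarchy curve with all country-level terms set to zero.
#' @return Matrix draws x cells.
#' @export
predict_surface <- function(fit, country, year, band,
                            level = c("country", "region")) {
  mx <- max(length(country), length(year), length(band))
  country <- rep_len(country, mx); year <- rep_len(year, mx)
  band <- rep_len(band, mx)
  P <- prediction_matrix(fit$design, country, year, band, match.arg(level))
  as.matrix(Matrix::tcrossprod(Matrix::Matrix(fit$theta, sparse = FALSE), P))
}

#' Materialize the full posterior surface
#'
#' @param fit A [fit_mcmc()] result.
#' @param countries,years,bands Cell labels (defaults: all fitted).
#' @return Object of class `posterior_surface`: array
#'   `[draw, country, year, band]` plus metric and sex attributes.
#' @export
posterior_surface <- function(fit, countries = fit$design$countries,
                              years = fit$design$years,
                              bands = age_bands()$band) {
  cells <- expand.grid(band = bands, year = years, country = countries,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pr <- predict_surface(fit, cells$country, cells$year, cells$band)
  arr <- array(pr, dim = c(nrow(pr), length(bands), length(years),
                           length(countries)),
               dimnames = list(NULL, band = bands,
                               year = as.character(years),
                               country = countries))
  arr <- aperm(arr, c(1, 4, 3, 2))
  structure(list(draws = arr, metric = fit$design$metric,
                 sex = fit$design$sex), class = "posterior_surface")
}
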