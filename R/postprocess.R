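#' WHO standard population weights on the analysis age bands
#'
#' Collapses the WHO 2000-2025 world standard population (5-year groups)
#' onto the adult analysis bands. The 18-19 band receives two fifths of the
#' 15-19 weight; 80+ pools all weights from age 80 up. Weights are
#' renormalized to sum to 1 over the adult bands.
#'
#' @return Named numeric vector of weights by band, summing to 1.
#' @export
who_standard_weights <- function() {
  ## WHO world standard population, percent by 5-year group (0-4 ... 85+)
  std <- c(8.86, 8.69, 8.60, 8.47, 8.22, 7.93, 7.61, 7.15, 6.59, 6.04,
           5.37, 4.55, 3.72, 2.96, 2.21, 1.52, 0.91, 0.635)
  w <- c(`18-19` = std[4] * 2 / 5,
         `20-29` = std[5] + std[6],
         `30-39` = std[7] + std[8],
         `40-49` = std[9] + std[10],
         `50-59` = std[11] + std[12],
         `60-69` = std[13] + std[14],
         `70-79` = std[15] + std[16],
         `80+` = std[17] + std[18])
  w / sum(w)
}

#' Age-standardize a posterior surface
#'
#' Weighted average of age-band means with a fixed standard population, per
#' draw and entity-year.
#'
#' @param surface A `posterior_surface` (or a bare array
#'   `[draw, entity, year, band]`).
#' @param weights Named weight vector by band (default
#'   [who_standard_weights()]).
#' @return Array `[draw, entity, year]`.
#' @export
age_standardize <- function(surface, weights = who_standard_weights()) {
  draws <- if (inherits(surface, "posterior_surface")) surface$draws else surface
  bands <- dimnames(draws)[[4]]
  if (!all(bands %in% names(weights))) {
    stop(sprintf("standard-population weights missing for band(s): %s",
                 paste(setdiff(bands, names(weights)), collapse = ", ")))
  }
  w <- weights[bands]
  w <- w / sum(w)   # renormalize over the bands actually present
  d <- dim(draws)
  out <- array(0, d[1:3], dimnames = dimnames(draws)[1:3])
  for (b in seq_along(bands)) {
    sl <- draws[, , , b, drop = FALSE]
    dim(sl) <- d[1:3]
    out <- out + sl * w[b]
  }
  out
}

#' Population-weighted aggregation of country surfaces
#'
#' Aggregates country-level posterior surfaces to regions (or the world) as
#' population-weighted averages of the constituent countries at the age-band
#' level. The result can then be age-standardized like any surface;
#' aggregation at band level followed by age-standardization is invariant to
#' grouping order.
#'
#' @param surface A `posterior_surface` over countries.
#' @param populations data.frame (country, year, sex, band, pop).
#' @param groups Named character vector mapping country to group (e.g.
#'   region id, or a constant for the world).
#' @return A `posterior_surface` whose entity dimension is the groups.
#' @export
aggregate_surface <- function(surface, populations, groups) {
  draws <- surface$draws
  dn <- dimnames(draws)
  countries <- dn$country
  years <- dn$year
  bands <- dn$band
  if (!all(countries %in% names(groups))) {
    stop("grouping must cover every country in the surface")
  }
  gl <- sort(unique(groups[countries]))
  pop <- populations[populations$sex == surface$sex, , drop = FALSE]
  key <- paste(pop$country, pop$year, pop$band)
  out <- array(NA_real_, c(dim(draws)[1], length(gl), length(years),
                           length(bands)),
               dimnames = list(NULL, country = gl, year = years, band = bands))
  for (gi in seq_along(gl)) {
    members <- countries[groups[countries] == gl[gi]]
    if (!length(members)) stop(sprintf("empty group '%s'", gl[gi]))
    for (yi in seq_along(years)) {
      for (bi in seq_along(bands)) {
        wts <- pop$pop[match(paste(members, years[yi], bands[bi]), key)]
        if (anyNA(wts)) {
          stop(sprintf("population missing for group '%s', year %s, band %s",
                       gl[gi], years[yi], bands[bi]))
        }
        sub <- draws[, members, yi, bi, drop = FALSE]
        dim(sub) <- c(dim(draws)[1], length(members))
        out[, gi, yi, bi] <- as.numeric(sub %*% (wts / sum(wts)))
      }
    }
  }
  structure(list(draws = out, metric = surface$metric, sex = surface$sex),
            class = "posterior_surface")
}

#' Change per decade of an age-standardized series
#'
#' Per draw, the difference between the endpoint years divided by the number
#' of elapsed decades (by default `(end - start) / 10`; the divisor can be
#' overridden, e.g. to use the inclusive year count).
#'
#' @param series Matrix `[draw, year]` (dimnames on year) or array
#'   `[draw, entity, year]`.
#' @param start,end Endpoint years (defaults: first and last column).
#' @param divisor Number of decades to divide by; default elapsed years / 10.
#' @return For a matrix: list with `draws` (per-draw change), `summary`
#'   (2.5/50/97.5 percentiles). For an array: matrix of per-draw changes
#'   `[draw, entity]` plus a summary table.
#' @export
change_per_decade <- function(series, start = NULL, end = NULL,
                              divisor = NULL) {
  if (length(dim(series)) == 3) {
    yrs <- as.numeric(dimnames(series)[[3]])
    start <- start %||% min(yrs); end <- end %||% max(yrs)
    div <- divisor %||% ((end - start) / 10)
    ch <- (series[, , as.character(end)] - series[, , as.character(start)]) / div
    if (is.null(dim(ch))) ch <- matrix(ch, ncol = 1,
                                       dimnames = list(NULL, dimnames(series)[[2]]))
    summ <- t(apply(ch, 2, quantile, c(0.025, 0.5, 0.975)))
    colnames(summ) <- c("lo2.5", "median", "hi97.5")
    return(list(draws = ch, summary = summ))
  }
  yrs <- as.numeric(colnames(series))
  start <- start %||% min(yrs); end <- end %||% max(yrs)
  if (!all(as.character(c(start, end)) %in% colnames(series))) {
    stop("series does not cover both endpoint years")
  }
  div <- divisor %||% ((end - start) / 10)
  ch <- (series[, as.character(end)] - series[, as.character(start)]) / div
  list(draws = ch,
       summary = quantile(ch, c(0.025, 0.5, 0.975)))
}

#' Posterior probability of a declining or increasing trend
#'
#' @param change_draws Numeric vector of per-draw changes.
#' @return Named vector: `pp_decline` (fraction of draws below zero) and
#'   `pp_increase` (fraction above zero).
#' @export
trend_probability <- function(change_draws) {
  stopifnot(length(change_draws) >= 1)
  c(pp_decline = mean(change_draws < 0),
    pp_increase = mean(change_draws > 0))
}

#' Summarize an age-standardized series into an estimates table
#'
#' @param std Array `[draw, entity, year]` from [age_standardize()].
#' @param metric,sex Labels carried into the table.
#' @param entity_type Label for the entity column (country/region/world).
#' @return data.frame: metric, entity_type, entity, sex, year, mean, lo2.5,
#'   median, hi97.5 (mmol/l; multiply by 38.61 for mg/dl).
#' @export
summarize_estimates <- function(std, metric, sex, entity_type = "country") {
  dn <- dimnames(std)
  rows <- expand.grid(entity = dn[[2]], year = as.integer(dn[[3]]),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  qs <- t(vapply(seq_len(nrow(rows)),
                 function(i) {
                   v <- std[, rows$entity[i], as.character(rows$year[i])]
                   c(mean(v), quantile(v, c(0.025, 0.5, 0.975)))
                 }, numeric(4)))
  data.frame(metric = metric, entity_type = entity_type,
             entity = rows$entity, sex = sex, year = rows$year,
             mean = qs[, 1], lo2.5 = qs[, 2], median = qs[, 3],
             hi97.5 = qs[, 4], stringsAsFactors = FALSE)
}
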