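# Whole-plant-population leaf age structures reconstructed from tagged
# representative leaves.
#
# At each census the fraction of a cohort's tagged leaves still alive is
# multiplied by the cohort's total initial leaf count, so extant + cumulative
# withered equals the initial total exactly at every census (conservation).
# Tagged leaves censored by sampling drop out of the ratio's denominator.

#' Reconstruct leaf age structure from tagged leaves
#'
#' @param leaves tagged leaf records: \code{cohort_date}, \code{end_date},
#'   \code{event} (a \code{leaf_census} is accepted; its tagged leaves are
#'   used and totals default to all its leaves).
#' @param totals data.frame \code{cohort_date}, \code{total}: the total
#'   initial number of leaves per cohort (from [cohort_totals()] or field
#'   counts).
#' @param census_dates dates at which to evaluate the structure; defaults to
#'   a biweekly grid from the first cohort to the last leaf end date.
#' @param class_width_d width of a leaf age class in days (default 30, i.e.
#'   monthly classes).
#' @return data.frame of class \code{age_structure}: one row per (census,
#'   cohort) with \code{census_date}, \code{cohort_date}, \code{age_class}
#'   (completed classes since emergence), \code{extant_est},
#'   \code{withered_cum_est}, \code{withered_inc_est}, \code{tracked}
#'   (\code{FALSE} where no tagged leaf was under observation and the last
#'   available ratio was carried forward). Estimated counts are fractional;
#'   rounding is left to final reporting.
#' @export
age_structure <- function(leaves, totals = NULL, census_dates = NULL,
                          class_width_d = 30) {
  if (inherits(leaves, "leaf_census")) {
    if (is.null(totals)) totals <- cohort_totals(leaves$leaves)
    leaves <- leaves$leaves[leaves$leaves$tagged, ]
  }
  if (is.null(totals)) totals <- cohort_totals(leaves)
  stopifnot(all(c("cohort_date", "total") %in% names(totals)))
  if (is.null(census_dates))
    census_dates <- seq(min(leaves$cohort_date), max(leaves$end_date), by = 14)
  census_dates <- sort(as.Date(census_dates))
  cohorts <- sort(unique(totals$cohort_date))

  out <- vector("list", length(cohorts))
  for (ci in seq_along(cohorts)) {
    cd <- cohorts[ci]
    total <- totals$total[totals$cohort_date == cd][1]
    g <- leaves[leaves$cohort_date == cd, ]
    if (nrow(g) > total) stop("tagged leaves exceed the cohort's initial total")
    cds <- census_dates[census_dates >= cd]
    if (!length(cds)) next
    ratio_prev <- 1
    rows <- vector("list", length(cds))
    wc_prev <- 0
    for (ti in seq_along(cds)) {
      t <- cds[ti]
      alive <- sum(g$end_date > t)
      withered <- sum(g$event == 1L & g$end_date <= t)
      denom <- alive + withered    # censored-by-t tagged leaves drop out
      tracked <- denom > 0
      ratio <- if (tracked) alive / denom else ratio_prev
      ratio <- min(ratio, ratio_prev)   # extant estimate never increases
      extant <- ratio * total
      wc <- total - extant
      rows[[ti]] <- data.frame(
        census_date = t, cohort_date = cd,
        age_class = floor(as.numeric(t - cd) / class_width_d),
        extant_est = extant, withered_cum_est = wc,
        withered_inc_est = wc - wc_prev, tracked = tracked)
      ratio_prev <- ratio
      wc_prev <- wc
    }
    out[[ci]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "class_width_d") <- class_width_d
  class(res) <- c("age_structure", "data.frame")
  res
}

#' Adjust an age structure for missing plants
#'
#' Scales counts so that plants missing at a census contribute the average
#' per-present-plant count: \code{adjusted = observed * n_reference /
#' n_present}. Cumulative withered counts are rescaled the same way and the
#' per-census increments recomputed by differencing within each cohort.
#'
#' @param ast an [age_structure()] table.
#' @param n_present plants actually censused: a single number, or a
#'   data.frame \code{census_date}, \code{n_present}.
#' @param n_reference reference population size (default 30 plants).
#' @return the adjusted \code{age_structure} table.
#' @export
adjust_missing_plants <- function(ast, n_present, n_reference = 30) {
  if (is.data.frame(n_present)) {
    np <- n_present$n_present[match(ast$census_date, n_present$census_date)]
    np[is.na(np)] <- n_reference
  } else {
    np <- rep(n_present, nrow(ast))
  }
  if (any(np < 1) || any(np > n_reference))
    stop("n_present must be in [1, n_reference]")
  f <- n_reference / np
  ast$extant_est <- ast$extant_est * f
  ast$withered_cum_est <- ast$withered_cum_est * f
  for (cd in unique(ast$cohort_date)) {
    ix <- which(ast$cohort_date == cd)
    ix <- ix[order(ast$census_date[ix])]
    ast$withered_inc_est[ix] <- diff(c(0, ast$withered_cum_est[ix]))
  }
  ast
}

#' Per-census leaf population turnover
#'
#' Column sums of an age structure: total extant leaves, newly withered
#' leaves since the previous census, and the oldest age class still
#' represented among extant leaves.
#'
#' @param ast an [age_structure()] table.
#' @return data.frame: \code{census_date}, \code{extant_total},
#'   \code{newly_withered}, \code{max_age_class} (\code{NA} when no extant
#'   leaves).
#' @export
summarize_turnover <- function(ast) {
  stopifnot(nrow(ast) > 0)
  dates <- sort(unique(ast$census_date))
  rows <- lapply(dates, function(t) {
    g <- ast[ast$census_date == t, ]
    present <- g$age_class[g$extant_est > 1e-9]
    data.frame(census_date = t,
               extant_total = sum(g$extant_est),
               newly_withered = sum(g$withered_inc_est),
               max_age_class = if (length(present)) max(present) else NA_integer_)
  })
  do.call(rbind, rows)
}
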