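# Per-leaf and per-cohort growth descriptors from biweekly length series.
#
# Mature leaf length is the first measured length reaching 90% of the leaf's
# maximum; the growth period runs from the cohort census date (the assigned
# emergence date) to that measurement; the growth rate is mature length over
# growth period. Leaves with maximum length under 10 mm are excluded from
# cohort means.

#' Growth summary of a single leaf
#'
#' @param dates measurement dates (\code{Date} or numeric days), length >= 2,
#'   all on or after \code{cohort_date}.
#' @param lengths_mm measured lengths (mm), same length as \code{dates}.
#' @param cohort_date the cohort census date assigned as emergence date.
#' @param min_length_mm inclusion threshold on the maximum length (mm).
#' @return one-row data.frame: \code{max_length_mm}, \code{mature_length_mm},
#'   \code{growth_period_d}, \code{growth_rate_mm_per_d}, \code{included}.
#'   A zero growth period (mature at the emergence census) leaves the rate
#'   \code{NA}; \code{included} is \code{FALSE} below the length threshold.
#' @examples
#' leaf_growth_summary(c(14, 28, 42, 56), c(3, 8, 9.5, 10), 0)
#' @export
leaf_growth_summary <- function(dates, lengths_mm, cohort_date,
                                min_length_mm = 10) {
  if (length(dates) < 2L) stop("need at least two length measurements")
  if (length(dates) != length(lengths_mm)) stop("dates and lengths differ in length")
  d <- as.numeric(dates) - as.numeric(cohort_date)
  if (any(d < 0)) stop("measurement dates must be on or after the cohort date")
  o <- order(d)
  d <- d[o]; lengths_mm <- lengths_mm[o]
  mx <- max(lengths_mm)
  i <- which(lengths_mm >= 0.9 * mx)[1]   # first measurement at >= 90% of max
  mature <- lengths_mm[i]
  period <- d[i]
  rate <- if (period > 0) mature / period else NA_real_
  data.frame(max_length_mm = mx, mature_length_mm = mature,
             growth_period_d = period, growth_rate_mm_per_d = rate,
             included = mx >= min_length_mm & period > 0)
}

#' Growth summaries for all measured leaves
#'
#' Applies [leaf_growth_summary()] to every leaf with at least two length
#' measurements, joining each leaf's cohort date from the leaf table.
#'
#' @param lengths long table with \code{leaf_id}, \code{date},
#'   \code{length_mm} (the \code{lengths} component of a
#'   \code{leaf_census}).
#' @param leaves leaf table with \code{leaf_id}, \code{cohort_date}; a
#'   \code{leaf_census} object supplies both tables.
#' @param min_length_mm inclusion threshold (mm).
#' @return data.frame: \code{leaf_id}, \code{cohort_date} and the
#'   [leaf_growth_summary()] columns.
#' @export
growth_summaries <- function(lengths, leaves = NULL, min_length_mm = 10) {
  if (inherits(lengths, "leaf_census")) {
    leaves <- lengths$leaves
    lengths <- lengths$lengths
  }
  if (is.null(lengths) || nrow(lengths) == 0L)
    return(data.frame(leaf_id = character(), cohort_date = as.Date(character()),
                      max_length_mm = numeric(), mature_length_mm = numeric(),
                      growth_period_d = numeric(),
                      growth_rate_mm_per_d = numeric(), included = logical()))
  cd <- leaves$cohort_date[match(lengths$leaf_id, leaves$leaf_id)]
  keep <- !is.na(cd)
  lengths <- lengths[keep, ]; cd <- cd[keep]
  sp <- split(seq_len(nrow(lengths)), lengths$leaf_id)
  sp <- sp[lengths(sp) >= 2L]
  rows <- lapply(names(sp), function(id) {
    ix <- sp[[id]]
    s <- leaf_growth_summary(lengths$date[ix], lengths$length_mm[ix],
                             cd[ix][1], min_length_mm)
    cbind(data.frame(leaf_id = id, cohort_date = cd[ix][1]), s)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort means of growth descriptors
#'
#' Arithmetic means over included leaves only (maximum length >= the
#' threshold and a positive growth period). Cohorts with no included leaf are
#' kept with \code{NA} means and \code{n_included = 0} so that exclusions
#' stay visible.
#'
#' @param growth per-leaf table from [growth_summaries()].
#' @return data.frame: \code{cohort_date}, \code{n_measured},
#'   \code{n_included}, \code{growth_rate_mm_per_d}, \code{growth_period_d},
#'   \code{mature_length_mm}.
#' @export
cohort_growth_means <- function(growth) {
  cohorts <- sort(unique(growth$cohort_date))
  rows <- lapply(cohorts, function(cd) {
    g <- growth[growth$cohort_date == cd, ]
    inc <- g[g$included, ]
    data.frame(cohort_date = cd, n_measured = nrow(g), n_included = nrow(inc),
               growth_rate_mm_per_d = if (nrow(inc)) mean(inc$growth_rate_mm_per_d) else NA_real_,
               growth_period_d = if (nrow(inc)) mean(inc$growth_period_d) else NA_real_,
               mature_length_mm = if (nrow(inc)) mean(inc$mature_length_mm) else NA_real_)
  })
  do.call(rbind, rows)
}
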