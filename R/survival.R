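# Product-limit estimation and Weibull survival-curve fitting per cohort.
#
# The cohort survival curve is summarised by fitting
#   S(x) = exp(-(x / beta)^alpha)
# to the Kaplan-Meier estimate by nonlinear least squares over the event
# times. alpha (shape) measures within-cohort synchrony of senescence
# (alpha ~ 1: age-independent mortality; large alpha: synchronised death);
# beta (scale, days) sets the time scale; the fitted median is
# beta * log(2)^(1/alpha).

#' Kaplan-Meier curve of leaf longevity
#'
#' Product-limit survival estimate for one cohort or arm. Computed via
#' \code{survival::survfit}; the returned object keeps the distinct event
#' times (deaths at the same census are one event time with multiplicity),
#' the numbers at risk and of events, and the survival estimate after each
#' event time. Individuals censored exactly at an event time are counted at
#' risk at that time (standard convention). With only censored observations
#' the estimate is identically 1 and \code{time} is empty.
#'
#' @param time positive longevities in days.
#' @param event 1/TRUE = died, 0/FALSE = right-censored; defaults to all died.
#' @return object of class \code{km_curve}: list with \code{time},
#'   \code{n_risk}, \code{n_event}, \code{surv}, \code{n},
#'   \code{n_censored}, \code{max_followup}.
#' @examples
#' km <- km_curve(c(7, 14, 21), c(1, 0, 1))
#' km$surv
#' @export
km_curve <- function(time, event = NULL) {
  if (length(time) == 0L) stop("empty longevity vector")
  if (is.null(event)) event <- rep(1L, length(time))
  event <- as.integer(as.logical(event))
  if (length(event) != length(time)) stop("time and event lengths differ")
  if (any(!is.finite(time)) || any(time <= 0)) stop("longevities must be positive and finite")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, conf.type = "none")
  ev <- sf$n.event > 0
  structure(list(time = sf$time[ev], n_risk = sf$n.risk[ev],
                 n_event = sf$n.event[ev], surv = sf$surv[ev],
                 n = length(time), n_censored = sum(event == 0L),
                 max_followup = max(time)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d (%d censored), %d event times",
              x$n, x$n_censored, length(x$time)))
  if (length(x$time))
    cat(sprintf(", S(last event %g d) = %.3f", max(x$time), min(x$surv)))
  cat("\n")
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "days after emergence",
                          ylab = "survival", ...) {
  tt <- c(0, rep(x$time, each = 2), x$max_followup)
  ss <- c(1, 1, rep(x$surv, each = 2))[seq_along(tt)]
  graphics::plot(tt, ss, type = "l", ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Fit a Weibull survival curve to a Kaplan-Meier estimate
#'
#' Estimates shape (alpha) and scale (beta, days) by minimising the
#' unweighted sum of squared differences between
#' \code{exp(-(t/beta)^alpha)} and the Kaplan-Meier survival values over the
#' event times. Initial values come from the linearised regression of
#' \code{log(-log S)} on \code{log t} (points with S equal to 0 or 1 are
#' excluded from the initialiser but kept in the objective); the objective is
#' then minimised by Nelder-Mead on log-parameters, restarted once from its
#' own solution, with alpha bounded in (0.05, 50] and beta in
#' (0, 10 * max event time].
#'
#' @param km a [km_curve()], or a numeric vector of longevities (then
#'   \code{event} may be given and a curve is built first).
#' @param event optional event flags when \code{km} is a numeric vector.
#' @param reltol convergence tolerance on the objective.
#' @return object of class \code{weibull_km_fit}: list with
#'   \code{coefficients} (named \code{shape}, \code{scale}), \code{sse},
#'   \code{converged}, \code{fitted}, \code{km}, \code{n_points}.
#' @seealso [l50_weibull()], [l50_empirical()]
#' @examples
#' set.seed(1)
#' fit <- fit_weibull_km(km_curve(rweibull(200, 2, 100)))
#' coef(fit)
#' @export
fit_weibull_km <- function(km, event = NULL, reltol = 1e-10) {
  if (!inherits(km, "km_curve")) km <- km_curve(km, event)
  t <- km$time
  S <- km$surv
  if (length(t) < 2L)
    stop("unfittable cohort: fewer than two distinct event times")
  a_lo <- 0.05; a_hi <- 50; b_hi <- 10 * max(t)

  ok <- S > 0 & S < 1
  if (sum(ok) >= 2L) {
    lf <- stats::lm(log(-log(S[ok])) ~ log(t[ok]))
    a0 <- unname(stats::coef(lf)[2])
    b0 <- exp(-unname(stats::coef(lf)[1]) / a0)
    if (!is.finite(a0) || a0 <= 0) a0 <- 1
    if (!is.finite(b0) || b0 <= 0) b0 <- stats::median(t) / log(2)
  } else {
    a0 <- 1
    b0 <- t[which.min(abs(S - 0.5))] / log(2)
  }
  a0 <- min(max(a0, a_lo * 1.1), a_hi * 0.9)
  b0 <- min(max(b0, 1e-3), b_hi * 0.9)

  obj <- function(th) {
    a <- exp(th[1]); b <- exp(th[2])
    if (a < a_lo || a > a_hi || b > b_hi)
      return(1e6 + sum(th^2))
    sum((exp(-(t / b)^a) - S)^2)
  }
  o <- stats::optim(log(c(a0, b0)), obj, method = "Nelder-Mead",
                    control = list(reltol = reltol, maxit = 2000))
  o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                    control = list(reltol = reltol, maxit = 2000))
  a <- exp(o$par[1]); b <- exp(o$par[2])
  structure(list(coefficients = c(shape = a, scale = b),
                 sse = o$value, converged = o$convergence == 0L,
                 fitted = exp(-(t / b)^a), km = km, n_points = length(t)),
            class = "weibull_km_fit")
}

#' @export
coef.weibull_km_fit <- function(object, ...) object$coefficients

#' @export
print.weibull_km_fit <- function(x, digits = 4, ...) {
  a <- x$coefficients[["shape"]]; b <- x$coefficients[["scale"]]
  cat("Weibull fit to Kaplan-Meier survival curve\n")
  cat(sprintf("  shape (alpha, synchrony): %s\n  scale (beta, days):       %s\n",
              format(a, digits = digits), format(b, digits = digits)))
  cat(sprintf("  fitted median L50: %s d;  SSE %.3g over %d event times%s\n",
              format(l50_weibull(a, b), digits = digits), x$sse, x$n_points,
              if (x$converged) "" else "  (not converged)"))
  invisible(x)
}

#' @export
summary.weibull_km_fit <- function(object, ...) {
  print(object, ...)
  r <- residuals(object)
  cat(sprintf("  residuals (KM - fitted): min %.3g, median %.3g, max %.3g\n",
              min(r), stats::median(r), max(r)))
  emp <- l50_empirical(object$km)
  cat(sprintf("  empirical KM median: %s d\n",
              if (is.na(emp)) "undefined (survival never reaches 0.5)"
              else format(emp, digits = 4)))
  invisible(object)
}

#' Predicted survival from a fitted Weibull curve
#' @param object a [fit_weibull_km()] fit.
#' @param times days after emergence; defaults to the KM event times.
#' @param ... unused.
#' @return survival probabilities.
#' @export
predict.weibull_km_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$km$time
  a <- object$coefficients[["shape"]]; b <- object$coefficients[["scale"]]
  exp(-(times / b)^a)
}

#' @export
residuals.weibull_km_fit <- function(object, ...) object$km$surv - object$fitted

#' @export
plot.weibull_km_fit <- function(x, xlab = "days after emergence",
                                ylab = "survival", ...) {
  km <- x$km
  plot(km, xlab = xlab, ylab = ylab, ...)
  tt <- seq(0, km$max_followup, length.out = 200)
  graphics::lines(tt, predict(x, tt), lty = 2)
  graphics::legend("topright", legend = c("Kaplan-Meier", "Weibull fit"),
                   lty = 1:2, bty = "n")
  invisible(x)
}

#' @export
simulate.weibull_km_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  a <- object$coefficients[["shape"]]; b <- object$coefficients[["scale"]]
  n <- object$km$n
  as.data.frame(replicate(nsim, stats::rweibull(n, a, b)))
}

#' Median of a fitted Weibull survival curve
#'
#' Closed-form days to 50\% survival, \code{scale * log(2)^(1/shape)}.
#' Approaches \code{scale} as \code{shape} grows (perfect synchrony).
#'
#' @param shape,scale Weibull parameters (both > 0); vectorised.
#' @return median longevity in days.
#' @examples
#' l50_weibull(1, 100) # 100 * log(2)
#' @export
l50_weibull <- function(shape, scale) {
  if (any(shape <= 0) || any(scale <= 0)) stop("shape and scale must be positive")
  scale * log(2)^(1 / shape)
}

#' Empirical median longevity from a Kaplan-Meier curve
#'
#' The primary per-cohort L50: days to 50\% survival read off the
#' product-limit estimate. When the estimate hits exactly 0.5 the median is
#' the midpoint of the flat interval to the next event time; when it jumps
#' across 0.5 the crossing is linearly interpolated between the bracketing
#' step points; when the very first event already drops survival below 0.5
#' that event time is returned. Heavily censored cohorts whose survival never
#' reaches 0.5 have no defined median and return \code{NA}.
#'
#' @param km a [km_curve()].
#' @return median longevity in days, or \code{NA_real_} when undefined.
#' @examples
#' l50_empirical(km_curve(c(10, 20, 30, 40))) # 25
#' @export
l50_empirical <- function(km) {
  stopifnot(inherits(km, "km_curve"))
  t <- km$time; S <- km$surv
  i <- which(S <= 0.5 + 1e-12)[1]
  if (is.na(i)) return(NA_real_)
  if (abs(S[i] - 0.5) < 1e-9) {
    if (i < length(t)) return((t[i] + t[i + 1]) / 2) else return(t[i])
  }
  if (i == 1L) return(t[1])
  t[i - 1] + (S[i - 1] - 0.5) * (t[i] - t[i - 1]) / (S[i - 1] - S[i])
}

#' Two-sample log-rank test
#'
#' Standard log-rank comparison of two arms (observed minus expected deaths
#' over the pooled event times, hypergeometric variance), via
#' \code{survival::survdiff}; p-value from chi-square with 1 df.
#'
#' @param time_a,time_b longevities of the two arms (days).
#' @param event_a,event_b event flags (1 died / 0 censored); default all died.
#' @return object of class \code{logrank_test}: list with \code{chisq},
#'   \code{df}, \code{p_value}, \code{n}.
#' @examples
#' logrank_test(c(5, 10), c(7, 12))
#' @export
logrank_test <- function(time_a, time_b, event_a = NULL, event_b = NULL) {
  if (length(time_a) == 0L || length(time_b) == 0L) stop("both arms must be nonempty")
  if (is.null(event_a)) event_a <- rep(1L, length(time_a))
  if (is.null(event_b)) event_b <- rep(1L, length(time_b))
  time <- c(time_a, time_b)
  event <- as.integer(as.logical(c(event_a, event_b)))
  grp <- rep(c("a", "b"), c(length(time_a), length(time_b)))
  if (sum(event) == 0L) {
    res <- list(chisq = 0, df = 1L, p_value = 1, n = length(time))
  } else {
    sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
    res <- list(chisq = unname(sd$chisq), df = 1L,
                p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
                n = length(time))
  }
  structure(res, class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chisq = %.4g on %d df, p = %.4g (n = %d)\n",
              x$chisq, x$df, x$p_value, x$n))
  invisible(x)
}

#' Per-cohort survival summaries
#'
#' Groups a leaf table by cohort, estimates each cohort's Kaplan-Meier curve,
#' fits the Weibull survival curve, and reports both L50 conventions: the
#' empirical KM median (primary) and the fitted-curve median. Cohorts with
#' fewer than two distinct event times cannot be fitted; they are kept with
#' \code{NA} parameters and \code{converged = FALSE}, and a warning lists
#' them (no cohort is silently dropped).
#'
#' @param leaves a leaf table with \code{cohort_date},
#'   \code{observed_longevity_d} and \code{event} (a \code{leaf_census}
#'   object is accepted and its tagged leaves used).
#' @param tagged_only when \code{leaves} is a \code{leaf_census}, restrict to
#'   tagged leaves (the field protocol only follows tagged leaves).
#' @return data.frame of class \code{cohort_survival}: one row per cohort
#'   with \code{cohort_date}, \code{n_leaves}, \code{n_events},
#'   \code{L50_empirical_d}, \code{L50_weibull_d}, \code{alpha}, \code{beta},
#'   \code{sse}, \code{converged}.
#' @export
cohort_survival <- function(leaves, tagged_only = TRUE) {
  if (inherits(leaves, "leaf_census")) {
    leaves <- if (tagged_only) leaves$leaves[leaves$leaves$tagged, ] else leaves$leaves
  }
  stopifnot(all(c("cohort_date", "observed_longevity_d", "event") %in% names(leaves)))
  cohorts <- sort(unique(leaves$cohort_date))
  rows <- lapply(cohorts, function(cd) {
    g <- leaves[leaves$cohort_date == cd, ]
    km <- km_curve(g$observed_longevity_d, g$event)
    out <- data.frame(cohort_date = cd, n_leaves = nrow(g),
                      n_events = sum(g$event == 1L),
                      L50_empirical_d = l50_empirical(km),
                      L50_weibull_d = NA_real_, alpha = NA_real_,
                      beta = NA_real_, sse = NA_real_, converged = FALSE)
    if (length(km$time) >= 2L) {
      fit <- fit_weibull_km(km)
      out$alpha <- fit$coefficients[["shape"]]
      out$beta <- fit$coefficients[["scale"]]
      out$L50_weibull_d <- l50_weibull(out$alpha, out$beta)
      out$sse <- fit$sse
      out$converged <- fit$converged
    }
    out
  })
  res <- do.call(rbind, rows)
  bad <- res$cohort_date[!res$converged]
  if (length(bad))
    warning(sprintf("%d cohort(s) unfittable or not converged: %s",
                    length(bad), paste(format(bad), collapse = ", ")))
  class(res) <- c("cohort_survival", "data.frame")
  res
}
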