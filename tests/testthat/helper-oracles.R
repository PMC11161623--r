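# Independent oracles used across the suite. Each is deliberately written
# from a different formulation than the implementation it checks.

# Day length from the NOAA sunrise equation (Fourier-series declination,
# geometric horizon), independent of the package's cosine-declination form.
noaa_day_length_h <- function(latitude_deg, doy) {
  g <- 2 * pi / 365 * (doy - 1 + 0.5)
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  lat <- latitude_deg * pi / 180
  x <- pmin(1, pmax(-1, -tan(lat) * tan(decl)))
  24 / pi * acos(x)
}

# Hand product-limit estimator: prod(1 - d_i/n_i) over distinct event times.
hand_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(time = ts, surv = surv)
}

# Hand two-sample log-rank: explicit O - E and hypergeometric variance
# tabulated over the pooled event times.
hand_logrank <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c(0L, 1L), c(length(time_a), length(time_b)))
  ts <- sort(unique(time[event == 1]))
  OmE <- 0; V <- 0
  for (t in ts) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & grp == 1L)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == 1L)
    OmE <- OmE + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  OmE^2 / V
}

# A km_curve built directly from known (time, survival) points, for checks
# that fit exactly specified curves.
make_km <- function(time, surv, n = length(time) + 1) {
  structure(list(time = time, n_risk = rev(seq_along(time)) + 1,
                 n_event = rep(1L, length(time)), surv = surv,
                 n = n, n_censored = 0L, max_followup = max(time)),
            class = "km_curve")
}

# Numeric median of a Weibull survival curve by root finding (oracle for the
# closed form).
l50_numeric <- function(shape, scale) {
  stats::uniroot(function(x) exp(-(x / scale)^shape) - 0.5,
                 c(1e-9, scale * 50), tol = 1e-12)$root
}

# Small leaf table builder for survival/age-structure unit tests.
toy_leaves <- function(cohort_date, longevity, event = NULL, tagged = TRUE) {
  cohort_date <- as.Date(cohort_date)
  if (is.null(event)) event <- rep(1L, length(longevity))
  data.frame(plant_id = seq_along(longevity),
             leaf_id = sprintf("T%03d", seq_along(longevity)),
             cohort_date = cohort_date,
             tagged = tagged, true_regime = NA_character_,
             true_longevity_d = NA_real_,
             observed_longevity_d = longevity,
             end_date = cohort_date + longevity,
             event = as.integer(event),
             treatment_arm = NA_character_)
}
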