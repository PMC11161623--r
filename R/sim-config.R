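#' Simulation configuration for the synthetic leaf world
#'
#' Full parameterisation of the generative model used by [sim_leaves()] and
#' [sim_treatment()]: site and census schedule, seasonal emergence rates, the
#' photoperiod-switched longevity regimes, growth, censoring, treatment shift
#' and seed. Defaults describe a temperate rosette perennial monitored over
#' four years: biweekly tagging censuses, weekly fate censuses, 30 plants.
#'
#' Leaves emerging when the mean photoperiod over the \code{window_d} days
#' after emergence exceeds \code{regime_threshold_h} follow the growth-season
#' (GS) regime: short, desynchronised longevity drawn from
#' Weibull(\code{gs_alpha}, \code{gs_beta}) (the default shape 1 gives
#' age-independent mortality with median \code{gs_beta * log(2)} = 59.8 d).
#' Other leaves follow the overwintering (OW) regime: death is anchored in
#' calendar time, drawn as Gaussian around the next flowering onset
#' (\code{flowering_onset_doy}, spread \code{flowering_sd_d}), so the fitted
#' Weibull shape of OW cohorts emerges high (synchronised senescence) even
#' though no age-domain Weibull is sampled. \code{ow_alpha} records the
#' nominal age-domain shape such a calendar-anchored cohort exhibits; it is
#' not sampled from.
#'
#' @param latitude_deg site latitude (degrees).
#' @param start_date,end_date first and last biweekly tagging census.
#' @param n_plants number of monitored plants.
#' @param census_interval_tag_d days between tagging/length censuses.
#' @param census_interval_fate_d days between fate (alive/withered) censuses.
#' @param emergence_rate_fn function of day-of-year giving the expected number
#'   of new leaves per plant per tagging census (Poisson mean).
#' @param regime_threshold_h photoperiod (h) separating GS from OW at
#'   emergence, applied to the mean over \code{window_d} days after emergence.
#' @param gs_alpha,gs_beta Weibull shape and scale (days) of GS longevity.
#' @param ow_alpha nominal (emergent) OW shape; documentation only, see above.
#' @param flowering_onset_doy day-of-year around which OW leaves die.
#' @param flowering_sd_d spread (days) of the synchronised OW death date.
#' @param min_survival_d floor (days) on any drawn longevity.
#' @param growth_rate_gs,growth_rate_ow regime mean linear leaf growth rates
#'   (mm/d).
#' @param growth_rate_cohort_sd,growth_rate_leaf_sd lognormal standard
#'   deviations of the multiplicative growth-rate scatter between cohorts
#'   and between leaves within a cohort (mean-one multipliers; 0 = none).
#'   Cohort means of observed growth rate vary substantially within a
#'   regime in field data; the defaults reproduce that scatter.
#' @param mature_length_mean_mm,mature_length_sd_mm mature-length distribution.
#' @param length_noise_sd_mm measurement noise on lengths; 0 = noiseless mode.
#' @param censor_prob_per_census probability a live leaf is removed (sampled)
#'   at each fate census, producing right-censoring.
#' @param treatment_delta_d additive shift (days) applied to every drawn
#'   longevity before census discretisation; used for treatment arms.
#' @param experiment_alpha Weibull shape used for GS-type arms in
#'   [sim_treatment()]: the same-aged tagged leaves of a manipulation
#'   experiment senesce far more synchronously than the regime-average
#'   shape-1 mixture, and their survival drop is correspondingly steep.
#' @param window_d length (days) of the post-emergence environmental window.
#' @param seed integer seed; every stochastic draw derives from it.
#' @return object of class \code{sim_config} (a validated list).
#' @examples
#' cfg <- sim_config(n_plants = 5, seed = 42)
#' cfg$gs_beta * log(2) # GS median longevity, days
#' @export
sim_config <- function(latitude_deg = 35.1,
                       start_date = as.Date("2017-10-10"),
                       end_date = as.Date("2021-09-21"),
                       n_plants = 30,
                       census_interval_tag_d = 14,
                       census_interval_fate_d = 7,
                       emergence_rate_fn = NULL,
                       regime_threshold_h = 11.4,
                       gs_alpha = 1, gs_beta = 86.3,
                       ow_alpha = 8,
                       flowering_onset_doy = 110, flowering_sd_d = 10,
                       min_survival_d = 14,
                       growth_rate_gs = 0.9, growth_rate_ow = 0.35,
                       growth_rate_cohort_sd = 0.12, growth_rate_leaf_sd = 0.18,
                       mature_length_mean_mm = 40, mature_length_sd_mm = 8,
                       length_noise_sd_mm = 0,
                       censor_prob_per_census = 0.02,
                       treatment_delta_d = 0,
                       experiment_alpha = 3.5,
                       window_d = 33,
                       seed = 1L) {
  if (is.null(emergence_rate_fn)) {
    # summer-peaked sinusoid; ~1.1 leaves/plant/biweek on average so that 30
    # plants yield cohorts of a few dozen leaves
    emergence_rate_fn <- function(doy) pmax(0.05, 1.1 + 0.9 * cos(2 * pi * (doy - 190) / 365.25))
  }
  cfg <- list(latitude_deg = latitude_deg,
              start_date = as.Date(start_date), end_date = as.Date(end_date),
              n_plants = as.integer(n_plants),
              census_interval_tag_d = census_interval_tag_d,
              census_interval_fate_d = census_interval_fate_d,
              emergence_rate_fn = emergence_rate_fn,
              regime_threshold_h = regime_threshold_h,
              gs_alpha = gs_alpha, gs_beta = gs_beta, ow_alpha = ow_alpha,
              flowering_onset_doy = flowering_onset_doy,
              flowering_sd_d = flowering_sd_d,
              min_survival_d = min_survival_d,
              growth_rate_gs = growth_rate_gs, growth_rate_ow = growth_rate_ow,
              growth_rate_cohort_sd = growth_rate_cohort_sd,
              growth_rate_leaf_sd = growth_rate_leaf_sd,
              mature_length_mean_mm = mature_length_mean_mm,
              mature_length_sd_mm = mature_length_sd_mm,
              length_noise_sd_mm = length_noise_sd_mm,
              censor_prob_per_census = censor_prob_per_census,
              treatment_delta_d = treatment_delta_d,
              experiment_alpha = experiment_alpha,
              window_d = window_d,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$gs_alpha > 0, cfg$gs_beta > 0, cfg$ow_alpha > 0,
            cfg$experiment_alpha > 0,
            cfg$censor_prob_per_census >= 0, cfg$censor_prob_per_census < 1,
            cfg$regime_threshold_h > 0, cfg$regime_threshold_h < 24,
            cfg$n_plants >= 0,
            cfg$census_interval_fate_d >= 1, cfg$census_interval_tag_d >= 1,
            cfg$flowering_sd_d >= 0, cfg$min_survival_d >= 1,
            cfg$growth_rate_cohort_sd >= 0, cfg$growth_rate_leaf_sd >= 0,
            cfg$window_d >= 1,
            is.function(cfg$emergence_rate_fn))
  if (cfg$end_date <= cfg$start_date) stop("end_date must be after start_date")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Leaf simulation configuration\n")
  cat(sprintf("  site: %.1f deg lat; censuses %s .. %s (tag every %d d, fate every %d d)\n",
              x$latitude_deg, format(x$start_date), format(x$end_date),
              x$census_interval_tag_d, x$census_interval_fate_d))
  cat(sprintf("  plants: %d; regime threshold: %.1f h photoperiod (mean over %d d)\n",
              x$n_plants, x$regime_threshold_h, x$window_d))
  cat(sprintf("  GS longevity: Weibull(shape %.2f, scale %.1f d) -> median %.1f d\n",
              x$gs_alpha, x$gs_beta, x$gs_beta * log(2)^(1 / x$gs_alpha)))
  cat(sprintf("  OW death: calendar day %d +/- %.0f d (next flowering onset)\n",
              x$flowering_onset_doy, x$flowering_sd_d))
  cat(sprintf("  censor prob/census: %.3f; treatment delta: %+.1f d; seed: %d\n",
              x$censor_prob_per_census, x$treatment_delta_d, x$seed))
  invisible(x)
}
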