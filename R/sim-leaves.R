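# Generative model for leaf census tables.
#
# Each biweekly tagging census, each plant emits Poisson(seasonal rate) new
# leaves whose emergence date is set to the census date (the cohort date).
# A leaf's regime is decided by the mean photoperiod over the post-emergence
# window; GS longevity is Weibull in age, OW death is anchored in calendar
# time around the next flowering onset. Deaths are detected at the next
# weekly fate census; sampling removes live leaves with a per-census
# probability (right-censoring). Lengths are recorded biweekly for the two
# tagged leaves per plant and cohort.

next_flowering_onset <- function(cohort_date, onset_doy, min_gap_d = 30) {
  yr <- as.integer(format(cohort_date, "%Y"))
  cand <- as.Date(paste0(yr, "-01-01")) + (onset_doy - 1)
  later <- as.Date(paste0(yr + 1, "-01-01")) + (onset_doy - 1)
  out <- cand
  out[as.numeric(cand - cohort_date) < min_gap_d] <-
    later[as.numeric(cand - cohort_date) < min_gap_d]
  out
}

#' Simulate a tagged-leaf census table
#'
#' Draws a complete leaf population under the generative model in
#' [sim_config()] and observes it through the field protocol: biweekly
#' tagging censuses that count all new leaves and tag two per plant, weekly
#' fate censuses that detect deaths (discretising each lifespan up to the
#' next census), per-census sampling censoring, and biweekly length
#' measurements of tagged leaves. Fully reproducible from \code{config$seed}.
#'
#' @param config a [sim_config()] object.
#' @param env optional environment series from [sim_environment()]; must
#'   cover \code{[start_date - 40 d, end_date + 400 d]}. Generated from the
#'   config's latitude when omitted.
#' @return object of class \code{leaf_census}: a list with
#'   \describe{
#'     \item{leaves}{one row per leaf: \code{plant_id}, \code{leaf_id},
#'       \code{cohort_date}, \code{tagged}, \code{true_regime},
#'       \code{true_longevity_d}, \code{observed_longevity_d},
#'       \code{end_date}, \code{event} (1 died, 0 censored),
#'       \code{treatment_arm} (NA for the observational census).}
#'     \item{lengths}{biweekly length series of tagged leaves:
#'       \code{leaf_id}, \code{date}, \code{length_mm}.}
#'     \item{env}{the daily environment series used.}
#'     \item{config}{the configuration.}
#'   }
#' @examples
#' cen <- sim_leaves(sim_config(n_plants = 3, end_date = "2018-10-09", seed = 7))
#' head(cen$leaves)
#' @export
sim_leaves <- function(config = sim_config(), env = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  if (cfg$n_plants < 1L) stop("zero plants: n_plants must be >= 1")
  if (is.null(env))
    env <- sim_environment(cfg$latitude_deg, cfg$start_date - 40, cfg$end_date + 430)
  if (min(env$date) > cfg$start_date - 40 || max(env$date) < cfg$end_date + 400)
    stop("env must cover [start_date - 40 d, end_date + 400 d]")
  set.seed(cfg$seed)

  tag_dates <- seq(cfg$start_date, cfg$end_date, by = cfg$census_interval_tag_d)
  if (length(tag_dates) == 0L) stop("empty census date range")
  fate_d <- cfg$census_interval_fate_d
  grid_end <- max(env$date)
  env_idx <- function(d) as.integer(d - env$date[1]) + 1L

  # regime of each cohort: mean photoperiod over the post-emergence window
  win_mean <- vapply(tag_dates, function(d) {
    mean(env$photoperiod_h[env_idx(d) + seq_len(cfg$window_d) - 1L])
  }, numeric(1))
  regime <- ifelse(win_mean > cfg$regime_threshold_h, "GS", "OW")
  gs_l50 <- cfg$gs_beta * log(2)^(1 / cfg$gs_alpha)

  leaf_list <- vector("list", length(tag_dates))
  len_list <- vector("list", length(tag_dates))
  for (i in seq_along(tag_dates)) {
    cd <- tag_dates[i]
    doy <- as.POSIXlt(cd)$yday + 1
    n_new <- stats::rpois(cfg$n_plants, cfg$emergence_rate_fn(doy))
    total <- sum(n_new)
    if (total == 0L) next
    plant <- rep(seq_len(cfg$n_plants), n_new)
    idx <- sequence(n_new)
    tagged <- idx <= 2L

    if (regime[i] == "GS") {
      L <- stats::rweibull(total, cfg$gs_alpha, cfg$gs_beta)
    } else {
      onset <- next_flowering_onset(cd, cfg$flowering_onset_doy)
      L <- as.numeric(onset - cd) + stats::rnorm(total, 0, cfg$flowering_sd_d)
    }
    L <- pmax(cfg$min_survival_d, L)
    if (cfg$treatment_delta_d != 0) L <- pmax(1, L + cfg$treatment_delta_d)

    # deaths detected at the next weekly fate census (grid anchored at start)
    off <- as.numeric(cd - cfg$start_date)
    obs <- fate_d * ceiling((off + L) / fate_d) - off
    m <- as.integer(round(obs / fate_d))   # censuses from emergence to detection

    event <- rep(1L, total)
    if (cfg$censor_prob_per_census > 0) {
      g <- stats::rgeom(total, cfg$censor_prob_per_census) + 1L
      cens <- g <= m - 1L
      event[cens] <- 0L
      obs[cens] <- g[cens] * fate_d
    }
    # administrative censoring at the last fate census inside the grid
    lim <- as.numeric(grid_end - cd)
    over <- obs > lim
    if (any(over)) {
      obs[over] <- fate_d * floor(lim / fate_d)
      event[over] <- 0L
    }

    leaf_id <- sprintf("P%03d_%s_L%02d", plant, format(cd, "%Y%m%d"), idx)
    leaf_list[[i]] <- data.frame(
      plant_id = plant, leaf_id = leaf_id, cohort_date = cd,
      tagged = tagged, true_regime = regime[i],
      true_longevity_d = L, observed_longevity_d = obs,
      end_date = cd + obs, event = event,
      treatment_arm = NA_character_)

    # biweekly lengths of tagged leaves while alive
    wt <- which(tagged)
    if (length(wt)) {
      mature <- pmax(5, stats::rnorm(length(wt), cfg$mature_length_mean_mm,
                                     cfg$mature_length_sd_mm))
      rate0 <- if (regime[i] == "GS") cfg$growth_rate_gs else cfg$growth_rate_ow
      # mean-one lognormal scatter between cohorts and between leaves
      csd <- cfg$growth_rate_cohort_sd
      lsd <- cfg$growth_rate_leaf_sd
      rate_c <- rate0 * exp(stats::rnorm(1, -csd^2 / 2, csd))
      rate <- rate_c * exp(stats::rnorm(length(wt), -lsd^2 / 2, lsd))
      kmax <- pmax(0L, floor((obs[wt] - 1) / cfg$census_interval_tag_d))
      if (any(kmax > 0L)) {
        rep_i <- rep(seq_along(wt), kmax)
        t_meas <- cfg$census_interval_tag_d * sequence(kmax)
        lg <- pmin(mature[rep_i], rate[rep_i] * t_meas)
        if (cfg$length_noise_sd_mm > 0)
          lg <- pmax(0, lg + stats::rnorm(length(lg), 0, cfg$length_noise_sd_mm))
        len_list[[i]] <- data.frame(
          leaf_id = leaf_id[wt][rep_i], date = cd + t_meas, length_mm = lg)
      }
    }
  }
  leaves <- do.call(rbind, leaf_list)
  lengths <- do.call(rbind, len_list)
  if (is.null(leaves)) stop("no leaves emerged; check emergence_rate_fn and n_plants")
  rownames(leaves) <- NULL
  if (!is.null(lengths)) rownames(lengths) <- NULL
  structure(list(leaves = leaves, lengths = lengths, env = env, config = cfg),
            class = "leaf_census")
}

#' @export
print.leaf_census <- function(x, ...) {
  cat(sprintf("Leaf census: %d leaves (%d tagged) in %d cohorts, %d plants\n",
              nrow(x$leaves), sum(x$leaves$tagged),
              length(unique(x$leaves$cohort_date)), x$config$n_plants))
  cat(sprintf("  cohorts %s .. %s; %.1f%% censored; regimes: %s\n",
              format(min(x$leaves$cohort_date)), format(max(x$leaves$cohort_date)),
              100 * mean(x$leaves$event == 0),
              paste(names(table(x$leaves$true_regime)),
                    table(x$leaves$true_regime), collapse = ", ", sep = "=")))
  invisible(x)
}

#' Initial leaf totals per cohort
#'
#' Counts all leaves (tagged and untagged) per cohort, i.e. the "total
#' initial number of leaves" recorded at each tagging census, which anchors
#' the age-structure reconstruction.
#'
#' @param leaves a leaf table (the \code{leaves} component of a
#'   \code{leaf_census}, or any data.frame with \code{cohort_date}).
#' @return data.frame with \code{cohort_date}, \code{total}.
#' @export
cohort_totals <- function(leaves) {
  if (inherits(leaves, "leaf_census")) leaves <- leaves$leaves
  agg <- stats::aggregate(list(total = leaves$cohort_date),
                          by = list(cohort_date = leaves$cohort_date), FUN = length)
  agg[order(agg$cohort_date), , drop = FALSE]
}

#' Simulate a paired treatment experiment
#'
#' Generates leaf longevity records for a control arm and one or more treated
#' arms drawn from the same cohort regime, with the treated arm's underlying
#' longevity shifted additively by \code{delta_d} days before census
#' discretisation. Arms are matched: every treated leaf shares its baseline
#' longevity draw with its control partner, mirroring the paired field
#' designs (shading arms within plants, sink arms between paired plants).
#'
#' GS-type arms draw Weibull longevities with shape
#' \code{config$experiment_alpha} and median equal to the GS regime median:
#' the same-aged tagged leaves of a manipulation experiment senesce much more
#' synchronously than the regime-average shape-1 mixture. OW-type arms use
#' the calendar-anchored death model of the population simulator.
#'
#' @param config a [sim_config()].
#' @param regime \code{"GS"} or \code{"OW"}: the cohort regime of the
#'   experimental leaves.
#' @param delta_d additive longevity shifts (days), one per non-control arm.
#' @param n_per_arm leaves per arm.
#' @param arm_labels labels; the first is the control.
#' @param design \code{"within_plant"} (both arms on each plant, as in
#'   shading) or \code{"between_plant"} (arms on paired neighbouring plants,
#'   as in sink removal).
#' @param emergence_date cohort date of the experimental leaves; defaults to
#'   an early-July (GS) or late-January (OW) census in the simulation's
#'   second year.
#' @param seed integer seed; defaults to \code{config$seed}.
#' @return data.frame of class \code{treatment_experiment}: one row per leaf
#'   with \code{arm}, \code{pair_id}, \code{plant_id}, \code{leaf_id},
#'   \code{cohort_date}, \code{true_longevity_d}, \code{observed_longevity_d},
#'   \code{event}, \code{true_regime}. Attributes: \code{design},
#'   \code{control}, \code{deltas_d}.
#' @examples
#' ex <- sim_treatment(sim_config(seed = 3), regime = "OW", delta_d = 27.1,
#'                     n_per_arm = 70)
#' table(ex$arm)
#' @export
sim_treatment <- function(config = sim_config(), regime = c("OW", "GS"),
                          delta_d, n_per_arm = 70,
                          arm_labels = c("control", "treated"),
                          design = c("within_plant", "between_plant"),
                          emergence_date = NULL, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  regime <- match.arg(regime)
  design <- match.arg(design)
  n_arms <- length(arm_labels)
  if (n_arms < 2L) stop("need a control and at least one treated arm")
  if (length(delta_d) != n_arms - 1L)
    stop("one delta per non-control arm required")
  deltas <- c(0, delta_d)
  cfg <- config
  if (is.null(emergence_date)) {
    yr <- as.integer(format(cfg$start_date, "%Y")) + 1L
    emergence_date <- if (regime == "GS") as.Date(paste0(yr, "-07-02"))
                      else as.Date(paste0(yr + 1L, "-01-25"))
  }
  emergence_date <- as.Date(emergence_date)
  set.seed(as.integer(seed))

  if (regime == "GS") {
    gs_l50 <- cfg$gs_beta * log(2)^(1 / cfg$gs_alpha)
    scale <- gs_l50 / log(2)^(1 / cfg$experiment_alpha)
    base <- stats::rweibull(n_per_arm, cfg$experiment_alpha, scale)
  } else {
    onset <- next_flowering_onset(emergence_date, cfg$flowering_onset_doy)
    base <- as.numeric(onset - emergence_date) +
      stats::rnorm(n_per_arm, 0, cfg$flowering_sd_d)
  }
  base <- pmax(cfg$min_survival_d, base)

  fate_d <- cfg$census_interval_fate_d
  arm_rows <- vector("list", n_arms)
  for (j in seq_len(n_arms)) {
    L <- pmax(1, base + deltas[j])
    obs <- fate_d * ceiling(L / fate_d)
    m <- as.integer(round(obs / fate_d))
    event <- rep(1L, n_per_arm)
    if (cfg$censor_prob_per_census > 0) {
      g <- stats::rgeom(n_per_arm, cfg$censor_prob_per_census) + 1L
      cens <- g <= m - 1L
      event[cens] <- 0L
      obs[cens] <- g[cens] * fate_d
    }
    pair <- seq_len(n_per_arm)
    plant <- if (design == "within_plant") pair else (pair - 1L) * n_arms + j
    arm_rows[[j]] <- data.frame(
      arm = arm_labels[j], pair_id = pair, plant_id = plant,
      leaf_id = sprintf("%s_%03d", arm_labels[j], pair),
      cohort_date = emergence_date,
      true_longevity_d = L, observed_longevity_d = obs, event = event,
      true_regime = regime)
  }
  out <- do.call(rbind, arm_rows)
  rownames(out) <- NULL
  attr(out, "design") <- design
  attr(out, "control") <- arm_labels[1]
  attr(out, "deltas_d") <- stats::setNames(delta_d, arm_labels[-1])
  class(out) <- c("treatment_experiment", "data.frame")
  out
}
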