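# End-to-end cohort demography analysis: survival -> growth -> environmental
# windows -> regime classification -> decision threshold -> age structure.

#' Fit the full leaf-cohort demography analysis
#'
#' Runs the whole analysis on a leaf census: per-cohort Kaplan-Meier and
#' Weibull survival summaries (L50, synchrony alpha), cohort growth means,
#' 33-day post-emergence environmental means, GS/OW classification by
#' k-means on (L50, growth rate) with silhouette-selected k, the photoperiod
#' decision threshold by a single-split entropy tree, and the whole-plant
#' age-structure reconstruction. With no data arguments a census is
#' simulated from \code{config}.
#'
#' Regime labels are always taken from the two-cluster solution (the GS/OW
#' dichotomy is the object of the analysis); the silhouette table reports
#' whether two clusters is indeed optimal. Cohorts lacking growth data or an
#' estimable L50 are excluded from classification but kept, flagged, in the
#' cohort table.
#'
#' @param census a \code{leaf_census} from [sim_leaves()], or \code{NULL} to
#'   simulate from \code{config}.
#' @param config a [sim_config()], used when \code{census} is \code{NULL}.
#' @param window_d environmental window length (days).
#' @param class_width_d age-class width (days) for the age structure.
#' @param k_range candidate cluster numbers for the silhouette method.
#' @param seed integer seed for the clustering restarts; defaults to the
#'   census' configuration seed.
#' @return object of class \code{leaf_demography}: list with
#'   \code{cohorts} (per-cohort table joining survival, growth,
#'   environmental means and the \code{regime} label), \code{silhouette},
#'   \code{split_rule}, \code{age_structure}, \code{turnover},
#'   \code{n_leaves}, \code{config}, \code{seed}, \code{call}.
#' @examples
#' \donttest{
#' ld <- leaf_demography(config = sim_config(n_plants = 10, seed = 2))
#' print(ld)
#' }
#' @export
leaf_demography <- function(census = NULL, config = sim_config(),
                            window_d = config$window_d, class_width_d = 30,
                            k_range = 2:6, seed = NULL) {
  cl <- match.call()
  if (is.null(census)) census <- sim_leaves(config)
  stopifnot(inherits(census, "leaf_census"))
  if (is.null(seed)) seed <- census$config$seed

  surv <- suppressWarnings(cohort_survival(census))
  growth <- cohort_growth_means(growth_summaries(census))
  envm <- env_window_mean(census$env, surv$cohort_date, window_d)

  cohorts <- merge(merge(as.data.frame(surv), growth, by = "cohort_date",
                         all.x = TRUE),
                   envm, by = "cohort_date", all.x = TRUE)
  cohorts <- cohorts[order(cohorts$cohort_date), ]
  complete <- is.finite(cohorts$L50_empirical_d) &
    is.finite(cohorts$growth_rate_mm_per_d)
  cohorts$complete <- complete
  if (sum(complete) < max(3, min(k_range) + 1))
    stop("too few cohorts with complete (L50, growth rate) features to classify")

  feats <- cohorts[complete, c("L50_empirical_d", "growth_rate_mm_per_d")]
  sil <- silhouette_select_k(feats, k_range = k_range, seed = seed)
  km2 <- kmeans_cohorts(feats, k = 2, seed = seed)
  cohorts$regime <- NA_character_
  cohorts$regime[complete] <- km2$labels

  envf <- cohorts[complete, c("mean_photoperiod_h", "mean_temperature_C",
                              "mean_radiation")]
  split <- entropy_split(envf, km2$labels)

  ast <- age_structure(census, class_width_d = class_width_d)
  turn <- summarize_turnover(ast)

  rownames(cohorts) <- NULL
  structure(list(cohorts = cohorts, silhouette = sil, split_rule = split,
                 kmeans = km2, age_structure = ast, turnover = turn,
                 n_leaves = nrow(census$leaves), config = census$config,
                 seed = seed, call = cl),
            class = "leaf_demography")
}

#' @export
print.leaf_demography <- function(x, ...) {
  co <- x$cohorts
  cat("Leaf cohort demography analysis\n")
  cat(sprintf("  %d cohorts (%d with complete features), %d leaves\n",
              nrow(co), sum(co$complete), x$n_leaves))
  for (r in c("GS", "OW")) {
    g <- co[!is.na(co$regime) & co$regime == r, ]
    if (nrow(g))
      cat(sprintf("  %s: %d cohorts, mean L50 %.1f d (range %.1f-%.1f), mean alpha %.2f, mean growth %.2f mm/d\n",
                  r, nrow(g), mean(g$L50_empirical_d),
                  min(g$L50_empirical_d), max(g$L50_empirical_d),
                  mean(g$alpha, na.rm = TRUE),
                  mean(g$growth_rate_mm_per_d, na.rm = TRUE)))
  }
  cat(sprintf("  silhouette-optimal k: %d\n", x$silhouette$best_k))
  cat("  "); print(x$split_rule)
  invisible(x)
}

#' @export
summary.leaf_demography <- function(object, ...) {
  print(object, ...)
  cat("\nPer-cohort table (head):\n")
  print(utils::head(object$cohorts[, c("cohort_date", "n_leaves",
                                       "L50_empirical_d", "alpha", "beta",
                                       "growth_rate_mm_per_d",
                                       "mean_photoperiod_h", "regime")]))
  invisible(object)
}

#' @export
plot.leaf_demography <- function(x, ...) {
  co <- x$cohorts[x$cohorts$complete, ]
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  col <- ifelse(co$regime == "GS", "darkorange", "steelblue")
  graphics::plot(co$mean_photoperiod_h, co$L50_empirical_d, col = col, pch = 19,
                 xlab = "photoperiod over 33 d after emergence (h)",
                 ylab = "L50 (d)", main = "Longevity vs photoperiod")
  if (x$split_rule$feature == "mean_photoperiod_h")
    graphics::abline(v = x$split_rule$threshold, lty = 3)
  graphics::plot(co$cohort_date, co$alpha, col = col, pch = 19, log = "y",
                 xlab = "cohort emergence date", ylab = "Weibull shape (alpha)",
                 main = "Senescence synchrony")
  graphics::plot(co$growth_rate_mm_per_d, co$L50_empirical_d, col = col,
                 pch = 19, xlab = "growth rate (mm/d)", ylab = "L50 (d)",
                 main = "Clustering features")
  graphics::plot(x$turnover$census_date, x$turnover$extant_total, type = "l",
                 xlab = "census date", ylab = "extant leaves",
                 main = "Reconstructed foliage size")
  invisible(x)
}

#' Compare treatment arms of a longevity experiment
#'
#' For a two-arm (or multi-arm) experiment, estimates each arm's L50 by both
#' conventions and tests the arms against the control with the log-rank
#' test. The headline effect \code{delta_L50_d} is the difference of
#' Weibull-fitted medians (treated minus control): under weekly fate
#' censuses the empirical KM median moves on a 7-day lattice, while the
#' fitted median interpolates smoothly through the discretised curve; the
#' empirical difference is reported alongside.
#'
#' @param experiment a \code{treatment_experiment} from [sim_treatment()],
#'   or any data.frame with \code{arm}, \code{observed_longevity_d},
#'   \code{event}; the control arm is taken from the \code{control}
#'   attribute (default: first arm level).
#' @param control optional control arm label overriding the attribute.
#' @return data.frame of class \code{treatment_comparison}: one row per
#'   treated arm with \code{arm}, \code{n_control}, \code{n_treated},
#'   \code{L50_control_d}, \code{L50_treated_d}, \code{delta_L50_d},
#'   \code{delta_L50_empirical_d}, \code{chisq}, \code{p_value}. Positive
#'   \code{delta_L50_d} means the treatment delayed senescence.
#' @examples
#' ex <- sim_treatment(sim_config(seed = 5), "OW", delta_d = 27.1, n_per_arm = 70)
#' compare_treatments(ex)
#' @export
compare_treatments <- function(experiment, control = NULL) {
  stopifnot(all(c("arm", "observed_longevity_d", "event") %in% names(experiment)))
  arms <- unique(experiment$arm)
  if (is.null(control)) control <- attr(experiment, "control")
  if (is.null(control)) control <- arms[1]
  if (!control %in% arms) stop("control arm not present")
  arm_l50 <- function(a) {
    g <- experiment[experiment$arm == a, ]
    km <- km_curve(g$observed_longevity_d, g$event)
    fit <- fit_weibull_km(km)
    c(wei = l50_weibull(fit$coefficients[["shape"]], fit$coefficients[["scale"]]),
      emp = l50_empirical(km), n = nrow(g))
  }
  ctl <- arm_l50(control)
  gc_ <- experiment[experiment$arm == control, ]
  rows <- lapply(setdiff(arms, control), function(a) {
    tr <- arm_l50(a)
    gt <- experiment[experiment$arm == a, ]
    lr <- logrank_test(gc_$observed_longevity_d, gt$observed_longevity_d,
                       gc_$event, gt$event)
    data.frame(arm = a, n_control = ctl[["n"]], n_treated = tr[["n"]],
               L50_control_d = ctl[["wei"]], L50_treated_d = tr[["wei"]],
               delta_L50_d = tr[["wei"]] - ctl[["wei"]],
               delta_L50_empirical_d = tr[["emp"]] - ctl[["emp"]],
               chisq = lr$chisq, p_value = lr$p_value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("treatment_comparison", "data.frame")
  out
}

#' @export
print.treatment_comparison <- function(x, ...) {
  cat("Treatment comparison (delta = treated - control, fitted medians)\n")
  df <- as.data.frame(x)
  df$delta_L50_d <- round(df$delta_L50_d, 2)
  df$delta_L50_empirical_d <- round(df$delta_L50_empirical_d, 2)
  df$L50_control_d <- round(df$L50_control_d, 1)
  df$L50_treated_d <- round(df$L50_treated_d, 1)
  df$chisq <- signif(df$chisq, 4)
  df$p_value <- signif(df$p_value, 3)
  print(df)
  invisible(x)
}
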