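short_cfg <- function(...) {
  sim_config(start_date = "2019-04-02", end_date = "2019-09-24", ...)
}

test_that("GS longevities reproduce the planted Weibull median", {
  # median 60 d: scale = 60 / log(2); ~10,000 GS leaves, no censoring
  cfg <- sim_config(start_date = "2019-04-02", end_date = "2019-08-27",
                    n_plants = 400, gs_beta = 60 / log(2),
                    regime_threshold_h = 0.5,   # every cohort is GS
                    censor_prob_per_census = 0, seed = 11,
                    emergence_rate_fn = function(doy) rep(2.5, length(doy)))
  cen <- sim_leaves(cfg)
  expect_true(all(cen$leaves$true_regime == "GS"))
  expect_gt(nrow(cen$leaves), 8000)
  # oracle: direct median of the sampled draws before census discretisation
  expect_lt(abs(median(cen$leaves$true_longevity_d) - 60), 2)
})

test_that("census discretisation detects deaths at the next weekly census", {
  cen <- sim_leaves(short_cfg(n_plants = 40, censor_prob_per_census = 0, seed = 2))
  lv <- cen$leaves
  expect_true(all(lv$event == 1L))                    # no censoring planted
  expect_true(all(lv$observed_longevity_d %% 7 == 0))
  gap <- lv$observed_longevity_d - lv$true_longevity_d
  expect_true(all(gap >= 0 & gap <= 7))
})

test_that("simulation is byte-identical under equal seeds and differs otherwise", {
  a <- sim_leaves(short_cfg(n_plants = 15, seed = 5))
  b <- sim_leaves(short_cfg(n_plants = 15, seed = 5))
  d <- sim_leaves(short_cfg(n_plants = 15, seed = 6))
  expect_identical(a$leaves, b$leaves)
  expect_identical(a$lengths, b$lengths)
  expect_false(identical(a$leaves, d$leaves))
})

test_that("regime assignment follows the photoperiod window rule exactly", {
  cfg <- sim_config(n_plants = 8, end_date = "2019-10-08", seed = 3)
  cen <- sim_leaves(cfg)
  env <- cen$env
  by_cohort <- unique(cen$leaves[, c("cohort_date", "true_regime")])
  # one regime per cohort
  expect_equal(nrow(by_cohort), length(unique(by_cohort$cohort_date)))
  wm <- env_window_mean(env, by_cohort$cohort_date, cfg$window_d)
  expect_identical(by_cohort$true_regime,
                   ifelse(wm$mean_photoperiod_h > cfg$regime_threshold_h, "GS", "OW"))
})

test_that("OW leaves die synchronised around the next flowering onset", {
  cfg <- sim_config(start_date = "2018-11-06", end_date = "2019-01-29",
                    n_plants = 60, censor_prob_per_census = 0, seed = 8)
  cen <- sim_leaves(cfg)
  lv <- cen$leaves
  expect_true(all(lv$true_regime == "OW"))
  death_doy <- as.numeric(format(lv$cohort_date + lv$true_longevity_d, "%j"))
  expect_lt(abs(mean(death_doy) - cfg$flowering_onset_doy), 3)
  expect_lt(sd(death_doy), 2 * cfg$flowering_sd_d)
})

test_that("lengths are nondecreasing in noiseless mode and only for tagged leaves", {
  cen <- sim_leaves(short_cfg(n_plants = 25, seed = 4))
  expect_true(all(cen$lengths$leaf_id %in% cen$leaves$leaf_id[cen$leaves$tagged]))
  mono <- tapply(cen$lengths$length_mm, cen$lengths$leaf_id,
                 function(x) all(diff(x) >= 0))
  expect_true(all(mono))
})

test_that("per-census sampling produces the planted censoring pattern", {
  cen <- sim_leaves(short_cfg(n_plants = 120, censor_prob_per_census = 0.05, seed = 9))
  lv <- cen$leaves
  expect_gt(mean(lv$event == 0L), 0.05)  # several censuses at risk each
  expect_true(all(lv$observed_longevity_d > 0))
  expect_true(all(lv$end_date == lv$cohort_date + lv$observed_longevity_d))
})

test_that("input validation rejects degenerate simulations", {
  expect_error(sim_leaves(short_cfg(n_plants = 0)), "zero plants|n_plants")
  expect_error(sim_config(start_date = "2019-01-01", end_date = "2018-01-01"), "after")
  env_short <- sim_environment(35.1, "2019-04-02", "2019-10-01")
  expect_error(sim_leaves(short_cfg(n_plants = 5), env = env_short), "cover")
})

test_that("paired treatment arms share baselines and recover the planted shift", {
  cfg <- sim_config(seed = 21)
  ex <- sim_treatment(cfg, regime = "OW", delta_d = 27, n_per_arm = 2000,
                      seed = 21)
  ctl <- ex[ex$arm == "control", ]
  trt <- ex[ex$arm == "treated", ]
  # pairing: underlying draws differ by exactly delta
  expect_true(all(abs(trt$true_longevity_d - ctl$true_longevity_d - 27) < 1e-9))
  # oracle: difference of empirical medians of the pre-discretisation draws
  d_true <- median(trt$true_longevity_d) - median(ctl$true_longevity_d)
  cmp <- compare_treatments(ex)
  expect_lt(abs(cmp$delta_L50_d - d_true), 2)
})

test_that("null treatment experiments do not separate", {
  cfg <- sim_config(seed = 31)
  ex <- sim_treatment(cfg, regime = "GS", delta_d = 0, n_per_arm = 500, seed = 31)
  cmp <- compare_treatments(ex)
  expect_gt(cmp$p_value, 0.1)   # identical baselines, censoring only
  expect_lt(abs(cmp$delta_L50_d), 3)
})

test_that("a planted GS shading advance is detected in nearly all replicates", {
  hits <- vapply(1:200, function(s) {
    ex <- sim_treatment(sim_config(seed = s), regime = "GS", delta_d = -11.7,
                        n_per_arm = 60, seed = s)
    cmp <- compare_treatments(ex)
    cmp$delta_L50_d < 0 && cmp$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("treatment experiments validate their arm structure", {
  cfg <- sim_config(seed = 1)
  expect_error(sim_treatment(cfg, "GS", delta_d = c(1, 2)), "one delta")
  expect_error(sim_treatment(cfg, "GS", delta_d = 5, arm_labels = "only"), "control")
  ex <- sim_treatment(cfg, "OW", delta_d = c(10, 20), n_per_arm = 30,
                      arm_labels = c("control", "mid", "high"),
                      design = "between_plant", seed = 2)
  expect_setequal(unique(ex$arm), c("control", "mid", "high"))
  expect_equal(length(unique(ex$plant_id)), 90)  # between-plant: all distinct
})
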