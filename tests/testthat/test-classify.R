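test_that("environmental window means are exact arithmetic means over 33 days", {
  env <- data.frame(date = seq(as.Date("2019-01-01"), by = "day", length.out = 100),
                    photoperiod_h = 12, temperature_C = 5, radiation = 10)
  m <- env_window_mean(env, "2019-01-10")
  expect_equal(m$mean_photoperiod_h, 12)

  # linear ramp: mean equals the explicit sum over the 33 sampled days
  env$photoperiod_h <- seq(10, by = 1 / 99, length.out = 100)
  m2 <- env_window_mean(env, "2019-01-10", window_d = 33)
  i0 <- 10
  expect_equal(m2$mean_photoperiod_h,
               sum(env$photoperiod_h[i0:(i0 + 32)]) / 33, tolerance = 1e-12)

  expect_error(env_window_mean(env, "2019-03-25"), "coverage")
  expect_error(env_window_mean(env, "2018-12-01"), "coverage")
})

test_that("k-means separates two planted clouds and names GS/OW by longevity", {
  set.seed(20)
  n <- 30
  f <- data.frame(
    L50_d = c(rnorm(n, 60, 3), rnorm(n, 130, 3)),
    rate = c(rnorm(n, 1.0, 0.05), rnorm(n, 0.4, 0.05)))
  km <- kmeans_cohorts(f, k = 2, seed = 1)
  # oracle: threshold the L50 axis at the midpoint
  planted <- ifelse(f$L50_d < 95, "GS", "OW")
  expect_identical(km$labels, planted)
  expect_lt(km$centers[which.min(km$centers[, 1]), 1], 70)

  # k = 1: single label, centroid = feature means
  km1 <- kmeans_cohorts(f, k = 1)
  expect_equal(unname(km1$centers[1, ]), unname(colMeans(as.matrix(f))))
  expect_length(unique(km1$labels), 1L)

  # duplicated data: duplicates end in the same cluster
  f2 <- rbind(f, f)
  km2 <- kmeans_cohorts(f2, k = 2, seed = 1)
  expect_identical(km2$labels[1:(2 * n)], km2$labels[(2 * n + 1):(4 * n)])

  expect_error(kmeans_cohorts(f[1:2, ], k = 5), "distinct")
})

test_that("silhouette method recovers the planted number of clusters", {
  set.seed(21)
  two <- data.frame(x = c(rnorm(25, 0), rnorm(25, 8)),
                    y = c(rnorm(25, 0), rnorm(25, 8)))
  expect_equal(silhouette_select_k(two, 2:5, seed = 1)$best_k, 2L)

  three <- data.frame(x = c(rnorm(20, 0), rnorm(20, 8), rnorm(20, 16)),
                      y = c(rnorm(20, 0), rnorm(20, 8), rnorm(20, 0)))
  expect_equal(silhouette_select_k(three, 2:5, seed = 1)$best_k, 3L)
})

test_that("entropy split places the threshold at the separating midpoint", {
  f <- data.frame(photoperiod_h = c(10.5, 10.9, 11.2, 11.6, 12.0, 12.8))
  lab <- c("OW", "OW", "OW", "GS", "GS", "GS")
  sr <- entropy_split(f, lab)
  expect_equal(sr$threshold, (11.2 + 11.6) / 2)
  expect_equal(sr$training_error, 0L)
  expect_equal(sr$class_below, "OW")
  expect_equal(sr$class_above, "GS")
  expect_equal(sr$gain, 1)        # 1 bit: balanced classes, pure children

  expect_error(entropy_split(f, rep("GS", 6)), "single-class")
})

test_that("the informative feature wins and the gain matches hand computation", {
  set.seed(22)
  pp <- c(10.8, 11.0, 11.1, 11.3, 11.5, 11.7, 12.0, 12.4)
  lab <- ifelse(pp > 11.4, "GS", "OW")
  f <- data.frame(mean_photoperiod_h = pp,
                  mean_temperature_C = rnorm(8, 15, 1))  # uninformative
  sr <- entropy_split(f, lab)
  expect_equal(sr$feature, "mean_photoperiod_h")
  expect_equal(sr$threshold, (11.3 + 11.5) / 2)

  # oracle: exhaustive gain over all candidate splits of both features
  h <- function(l) { p <- table(l) / length(l); -sum(ifelse(p > 0, p * log2(p), 0)) }
  best_gain <- -Inf
  for (col in names(f)) {
    sv <- sort(unique(f[[col]]))
    for (thr in (sv[-1] + sv[-length(sv)]) / 2) {
      b <- f[[col]] <= thr
      g <- h(lab) - (sum(b) * h(lab[b]) + sum(!b) * h(lab[!b])) / length(lab)
      best_gain <- max(best_gain, g)
    }
  }
  expect_equal(sr$gain, best_gain, tolerance = 1e-12)
})

test_that("information gain is nonnegative and zero for uninformative splits", {
  # proportions identical in both children for every midpoint of x
  f <- data.frame(x = c(1, 1, 2, 2))
  lab <- c("A", "B", "A", "B")
  sr <- entropy_split(f, lab)
  expect_gte(sr$gain, 0)
  expect_equal(sr$gain, 0, tolerance = 1e-12)
})

test_that("recovered threshold tracks the planted regime rule on simulated cohorts", {
  cen <- sim_leaves(sim_config(n_plants = 10, seed = 13))
  wm <- env_window_mean(cen$env, sort(unique(cen$leaves$cohort_date)))
  truth <- unique(cen$leaves[, c("cohort_date", "true_regime")])
  m <- merge(wm, truth, by = "cohort_date")
  sr <- entropy_split(m[, c("mean_photoperiod_h", "mean_temperature_C",
                            "mean_radiation")], m$true_regime)
  expect_equal(sr$feature, "mean_photoperiod_h")
  expect_equal(sr$training_error, 0L)
  # threshold within the empty gap bracketing the planted 11.4 h rule
  below <- max(m$mean_photoperiod_h[m$mean_photoperiod_h <= 11.4])
  above <- min(m$mean_photoperiod_h[m$mean_photoperiod_h > 11.4])
  expect_lt(abs(sr$threshold - 11.4), above - below)
})
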