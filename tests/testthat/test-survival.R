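test_that("Kaplan-Meier estimate matches hand product-limit computations", {
  # uncensored: empirical survival function
  km <- km_curve(c(7, 14, 21))
  expect_equal(km$surv, c(2, 1, 0) / 3)

  # censoring at 14: S(7) = 2/3, S(21) = 2/3 * (1 - 1/1) = 0
  km2 <- km_curve(c(7, 14, 21), c(1, 0, 1))
  expect_equal(km2$time, c(7, 21))
  expect_equal(km2$surv, c(2 / 3, 0))

  # oracle agreement on a larger mixed sample
  set.seed(42)
  t <- sample(7 * (1:20), 60, replace = TRUE)
  e <- rbinom(60, 1, 0.8)
  km3 <- km_curve(t, e)
  or <- hand_km(t, e)
  expect_equal(km3$time, or$time)
  expect_equal(km3$surv, or$surv, tolerance = 1e-12)

  # all censored: survival identically 1
  km4 <- km_curve(c(10, 20, 30), c(0, 0, 0))
  expect_length(km4$time, 0)
  expect_equal(km4$n_censored, 3L)

  expect_error(km_curve(numeric(0)), "empty")
  expect_error(km_curve(c(5, -1)), "positive")
})

test_that("uncensored KM equals the empirical survival function", {
  set.seed(7)
  t <- ceiling(rweibull(300, 1.5, 80) / 7) * 7
  km <- km_curve(t)
  emp <- vapply(km$time, function(x) mean(t > x), numeric(1))
  expect_equal(km$surv, emp, tolerance = 1e-12)
})

test_that("fitting an exactly-Weibull curve recovers the parameters", {
  for (p in list(c(1, 100), c(2.5, 60), c(8, 150))) {
    tt <- seq(10, p[2] * 1.8, length.out = 25)
    km <- make_km(tt, exp(-(tt / p[2])^p[1]))
    fit <- fit_weibull_km(km)
    expect_lt(abs(coef(fit)[["shape"]] - p[1]) / p[1], 1e-6)
    expect_lt(abs(coef(fit)[["scale"]] - p[2]) / p[2], 1e-6)
    expect_true(fit$converged)
    expect_lt(fit$sse, 1e-12)
  }
})

test_that("NLS-on-KM agrees with a maximum-likelihood oracle on raw draws", {
  skip_if_not_installed("fitdistrplus")
  set.seed(1)
  x <- rweibull(5000, 2, 100)
  fit <- fit_weibull_km(km_curve(x))
  mle <- fitdistrplus::fitdist(x, "weibull")
  expect_lt(abs(coef(fit)[["shape"]] - mle$estimate[["shape"]]) / mle$estimate[["shape"]], 0.03)
  expect_lt(abs(coef(fit)[["scale"]] - mle$estimate[["scale"]]) / mle$estimate[["scale"]], 0.03)
  expect_true(coef(fit)[["shape"]] > 1.9 && coef(fit)[["shape"]] < 2.1)
  expect_true(coef(fit)[["scale"]] > 97 && coef(fit)[["scale"]] < 103)

  # exponential sample: shape near 1
  set.seed(2)
  y <- rweibull(2000, 1, 90)
  fit1 <- fit_weibull_km(km_curve(y))
  expect_true(coef(fit1)[["shape"]] > 0.9 && coef(fit1)[["shape"]] < 1.1)
})

test_that("degenerate KM curves are rejected as unfittable", {
  expect_error(fit_weibull_km(km_curve(rep(42, 10))), "unfittable")
})

test_that("fit methods are coherent with the fitted curve", {
  set.seed(3)
  fit <- fit_weibull_km(km_curve(rweibull(400, 3, 70)))
  expect_equal(predict(fit), fit$fitted)
  expect_equal(residuals(fit), fit$km$surv - fit$fitted)
  expect_equal(predict(fit, 0), 1)
  s <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(s), c(fit$km$n, 2L))
  expect_output(print(fit), "shape")
  expect_output(summary(fit), "empirical KM median")
})

test_that("Weibull median: closed form, numeric oracle and limits agree", {
  expect_equal(l50_weibull(1, 100), 100 * log(2), tolerance = 1e-12)
  expect_equal(l50_weibull(2, 100), l50_numeric(2, 100), tolerance = 1e-6)
  expect_equal(l50_weibull(2, 100), 83.2555, tolerance = 1e-5)
  expect_lt(abs(l50_weibull(500, 77) - 77), 0.1)     # shape -> Inf limit
  expect_error(l50_weibull(-1, 10), "positive")
})

test_that("empirical KM median follows the interpolation conventions", {
  expect_equal(l50_empirical(km_curve(c(10, 20, 30, 40))), 25)
  expect_equal(l50_empirical(km_curve(rep(42, 5))), 42)
  # survival never reaches 0.5: undefined
  km <- km_curve(c(10, 20, 30, 40), c(1, 0, 0, 0))
  expect_true(is.na(l50_empirical(km)))
  # large uncensored sample: order-statistic median within one census interval
  set.seed(4)
  x <- rweibull(1001, 1.3, 90)
  expect_lt(abs(l50_empirical(km_curve(x)) - median(x)), 7)
})

test_that("log-rank test matches a hand O-E tabulation and behaves at the extremes", {
  lr0 <- logrank_test(c(5, 10, 15), c(5, 10, 15))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)

  # small worked example over 4 event times
  lr <- logrank_test(c(5, 10), c(7, 12))
  expect_equal(lr$chisq, hand_logrank(c(5, 10), c(1, 1), c(7, 12), c(1, 1)),
               tolerance = 1e-9)

  set.seed(5)
  a <- rweibull(400, 2, 70)
  b <- rweibull(400, 2, 70) + 30
  expect_lt(logrank_test(a, b)$p_value, 1e-6)

  expect_error(logrank_test(numeric(0), c(1, 2)), "nonempty")
})

test_that("shape and scale are recovered across the cohort parameter range", {
  set.seed(6)
  n_sim <- 200
  shapes <- runif(n_sim, 0.8, 6)
  scales <- runif(n_sim, 40, 200)
  rel_a <- rel_b <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    x <- rweibull(50, shapes[i], scales[i])
    fit <- fit_weibull_km(km_curve(x))
    rel_a[i] <- abs(coef(fit)[["shape"]] - shapes[i]) / shapes[i]
    rel_b[i] <- abs(coef(fit)[["scale"]] - scales[i]) / scales[i]
  }
  expect_lt(median(rel_a), 0.15)
  expect_lt(median(rel_b), 0.10)
})

test_that("per-cohort summaries keep unfittable cohorts flagged, not dropped", {
  lv <- rbind(toy_leaves("2019-01-01", c(10, 20, 30, 40)),
              toy_leaves("2019-01-15", rep(42, 4)))   # single event time
  expect_warning(cs <- cohort_survival(lv), "unfittable|not converged")
  expect_equal(nrow(cs), 2L)
  expect_equal(cs$L50_empirical_d, c(25, 42))
  expect_true(is.na(cs$alpha[2]) && !cs$converged[2])
  expect_false(is.na(cs$alpha[1]))
})
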