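test_that("count-based estimator applies the informative-pair exclusion rule", {
  r <- ratio_sample_of(c(2.0, 0.5, 1.5, 0.8), c(1, 1, 1, 0))
  est <- estimate_count(r, 1.3)
  expect_equal(est$n_informative, 3)       # censored 0.8 is non-informative
  expect_equal(est$s_hat, 2/3)
  expect_equal(est$n_total, 4)

  # a censored ratio at or above delta is a definite success
  est <- estimate_count(ratio_sample_of(c(1.5, 0.5), c(0, 1)), 1.3)
  expect_equal(est$s_hat, 1/2)

  # no censoring: plain empirical proportion with Clopper-Pearson CI
  set.seed(8)
  x <- rlnorm(30)
  est <- estimate_count(ratio_sample_of(x, rep(1, 30)), 1.3)
  expect_equal(est$s_hat, mean(x >= 1.3))
  expect_equal(c(est$ci_low, est$ci_high),
               as.numeric(binom.test(sum(x >= 1.3), 30)$conf.int))

  expect_error(estimate_count(ratio_sample_of(c(0.5, 0.9), c(0, 0)), 1.3),
               "informative")
})

test_that("Kaplan-Meier estimator evaluates the ratio curve just before delta", {
  # event at 0.5 (risk set 3), censor at 1.0: S on (0.5, 2.0) = 2/3
  r <- ratio_sample_of(c(0.5, 1.0, 2.0), c(1, 0, 1))
  expect_equal(estimate_km(r, 1.3)$s_hat, 2/3)

  # ratios tied with delta count as successes
  r <- ratio_sample_of(c(0.5, 1.3, 2.0), c(1, 1, 1))
  expect_equal(estimate_km(r, 1.3)$s_hat, 2/3)

  set.seed(9)
  x <- rlnorm(20)
  expect_equal(estimate_km(ratio_sample_of(x, rep(1, 20)), 1.3)$s_hat,
               mean(x >= 1.3))
  expect_equal(estimate_km(ratio_sample_of(x, rep(1, 20)), min(x) / 2)$s_hat, 1)

  # beyond the data with the curve still positive: indeterminate CI
  est <- estimate_km(ratio_sample_of(c(0.5, 1.0), c(1, 0)), 5)
  expect_true(is.na(est$ci_low))
})

test_that("parametric estimator honours the log-logistic closed form", {
  # synthetic check of the formula itself: S(delta) = 1/(1+(delta/R)^shape)
  set.seed(10)
  x <- exp(rlogis(4000, location = log(1), scale = 1/2))  # R = 1, shape = 2
  est <- estimate_parametric(ratio_sample_of(x, rep(1, 4000)), 2)
  expect_equal(est$fit$shape, 2, tolerance = 0.08)
  expect_equal(est$fit$median_ratio, 1, tolerance = 0.05)
  expect_equal(est$s_hat, 1 / (1 + (2 / est$fit$median_ratio)^est$fit$shape),
               tolerance = 1e-10)
  # at delta = fitted median the estimate is exactly one half
  at_median <- estimate_parametric(ratio_sample_of(x, rep(1, 4000)),
                                   est$fit$median_ratio)
  expect_equal(at_median$s_hat, 0.5, tolerance = 1e-10)

  expect_error(estimate_parametric(ratio_sample_of(c(1, 1, 2), c(1, 0, 0)), 1.3),
               "distinct event ratios")
})

test_that("ratio of Weibull-Gamma pairs is log-logistic(shape=kappa, median=R)", {
  coh <- sim_weibull_gamma(1000, median1 = 3, ratio_R = 1.3, kappa = 1.5,
                           theta = 1, seed = 77)
  r <- compute_ratios(coh)
  est <- estimate_parametric(r, 1.3)
  expect_equal(est$fit$shape, 1.5, tolerance = 0.1)
  expect_equal(est$fit$median_ratio, 1.3, tolerance = 0.08)
  # the fitted curve tracks the empirical ratio distribution
  expect_equal(est$s_hat, mean(r$ratio >= 1.3), tolerance = 0.03)
})

test_that("parametric MLE agrees with survreg's log-logistic fit under censoring", {
  coh <- apply_censoring(sim_weibull_gamma(300, kappa = 1.2, seed = 13),
                         "exponential", 0.25, seed = 14)
  r <- compute_ratios(coh)
  est <- estimate_parametric(r, 1.3)
  sr <- survival::survreg(survival::Surv(ratio, event) ~ 1, data = r,
                          dist = "loglogistic")
  expect_equal(est$fit$median_ratio, unname(exp(coef(sr))), tolerance = 1e-4)
  expect_equal(est$fit$shape, 1 / sr$scale, tolerance = 1e-4)
})

test_that("midrank estimator reduces to the count estimate without censoring", {
  set.seed(11)
  for (i in 1:10) {
    x <- rlnorm(25)
    delta <- runif(1, 0.5, 2)
    expect_equal(estimate_midrank(ratio_sample_of(x, rep(1, 25)), delta,
                                  n_boot = 0)$s_hat,
                 estimate_count(ratio_sample_of(x, rep(1, 25)), delta)$s_hat)
  }
})

test_that("midrank redistributes censored mass instead of failing", {
  # every ratio censored below delta: count errors, midrank stays inside (0,1)
  r <- ratio_sample_of(c(0.3, 0.6, 0.9), c(0, 0, 0))
  est <- estimate_midrank(r, 1.3, n_boot = 0)
  expect_gt(est$s_hat, 0)
  expect_lt(est$s_hat, 1)
  expect_error(estimate_count(r, 1.3), "informative")
})

test_that("kernel-KM equals the empirical proportion when nothing is censored", {
  coh <- fixture_uncensored()
  r <- compute_ratios(coh)
  for (delta in c(0.8, 1.3, 2)) {
    for (h in c(0.05, 0.3, 5)) {
      expect_equal(estimate_kernel_km(r, delta, bandwidth = h, n_boot = 0)$s_hat,
                   mean(r$ratio >= delta), tolerance = 1e-12)
    }
  }
})

test_that("kernel-KM tends to the plain KM as the bandwidth grows", {
  coh <- apply_censoring(fixture_uncensored(100, seed = 15), "exponential",
                         0.3, seed = 16)
  r <- compute_ratios(coh)
  for (delta in c(1, 1.3, 1.8)) {
    expect_equal(estimate_kernel_km(r, delta, bandwidth = 1e6, n_boot = 0)$s_hat,
                 estimate_km(r, delta)$s_hat, tolerance = 1e-10)
  }
})

test_that("kernel-KM is invariant to relabeling of patients", {
  coh <- apply_censoring(fixture_uncensored(80, seed = 17), "administrative",
                         0.3, seed = 18)
  r <- compute_ratios(coh)
  perm <- sample(nrow(r))
  r2 <- r[perm, ]
  expect_equal(estimate_kernel_km(r, 1.3, n_boot = 0)$s_hat,
               estimate_kernel_km(r2, 1.3, n_boot = 0)$s_hat,
               tolerance = 1e-12)
})

test_that("estimator dispatcher enforces the censoring guardrails", {
  coh <- fixture_uncensored(40, seed = 19)
  coh$event2[1:10] <- 0L   # 25% censoring
  r <- compute_ratios(coh)
  expect_warning(estimate_pfsratio(r, 1.3, method = "km"), "20%")
  coh$event2[1:22] <- 0L   # 55%
  r <- compute_ratios(coh)
  expect_error(estimate_pfsratio(r, 1.3, method = "km"), "50%")
  est <- suppressWarnings(estimate_pfsratio(r, 1.3, method = "km", force = TRUE))
  expect_s3_class(est, "ratio_estimate")
})

test_that("s_curve is non-increasing in delta for every method", {
  coh <- apply_censoring(fixture_uncensored(120, seed = 23), "administrative",
                         0.2, seed = 24)
  r <- compute_ratios(coh)
  grid <- seq(0.2, 2.5, by = 0.1)
  for (m in c("count", "km", "kernel_km", "midrank", "parametric")) {
    crv <- s_curve(r, grid, method = m)
    s <- crv$s_hat[!is.na(crv$s_hat)]
    expect_true(all(diff(s) <= 1e-9), info = m)
    expect_true(all(s >= 0 & s <= 1), info = m)
  }
  # constant ratios at 1: survival 1 below and at the ratio, 0 above
  r1 <- ratio_sample_of(rep(1, 10), rep(1, 10))
  expect_equal(s_curve(r1, c(0.5, 1, 1.5), method = "km")$s_hat, c(1, 1, 0))
})

test_that("median_ratio agrees with its estimators", {
  r <- ratio_sample_of(c(0.5, 1.0, 2.0), c(1, 1, 1))
  expect_equal(median_ratio(r, "km")$median, 1.0)

  coh <- fixture_uncensored(200, seed = 25)
  r <- compute_ratios(coh)
  est <- estimate_parametric(r, 1.3)
  mp <- median_ratio(r, "parametric")
  expect_equal(mp$median, est$fit$median_ratio)
  # the kernel curve at its own median estimate is (just) at or below one half
  mk <- median_ratio(r, "kernel_km", n_boot = 0)
  eps <- 1e-9
  above <- estimate_kernel_km(r, mk$median - eps, n_boot = 0)$s_hat
  at <- estimate_kernel_km(r, mk$median + eps, n_boot = 0)$s_hat
  expect_gt(above, 0.5)
  expect_lte(at, 0.5)

  # heavy censoring keeping the curve above one half: indeterminate
  rc <- ratio_sample_of(c(2, 3, 4, 0.5), c(0, 0, 0, 1))
  expect_true(is.na(suppressWarnings(median_ratio(rc, "km")$median)))
})

test_that("efficacy verdict requires the lower bound to clear p0 strictly", {
  est <- new_est <- structure(list(delta = 1.3, s_hat = 0.41, ci_low = 0.34,
                                   ci_high = 0.49, method = "kernel_km",
                                   n_total = 100, n_informative = 100,
                                   conf_level = 0.95),
                              class = "ratio_estimate")
  expect_true(test_efficacy(est, 0.15)$success)     # MOSCATO-style p0 = 15%
  est$ci_low <- 0.17
  expect_false(test_efficacy(est, 0.40)$success)    # WINTHER-style p0 = 40%
  est$ci_low <- 0.40
  expect_false(test_efficacy(est, 0.40)$success)    # boundary: strict
})
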