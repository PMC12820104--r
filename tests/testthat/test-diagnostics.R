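test_that("km_curve matches hand product-limit calculations", {
  # all events: complement of the ECDF
  crv <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(crv$surv, c(2/3, 1/3, 0))

  # censoring at 2 shrinks the risk set: S(1)=2/3, S(3)=0
  crv <- km_curve(c(1, 2, 3), c(1, 0, 1))
  expect_equal(crv$surv[crv$times == 1], 2/3)
  expect_equal(crv$surv[crv$times == 3], 0)

  # single event defines the median
  crv <- km_curve(5, 1)
  expect_equal(crv$median, 5)

  # no censoring: curve equals 1 - ECDF at the event times
  set.seed(3)
  x <- rexp(40)
  crv <- km_curve(x, rep(1, 40))
  expect_equal(crv$surv, 1 - ecdf(x)(sort(x)))
})

test_that("km_curve is monotone within [0,1] and median is NA when undefined", {
  set.seed(4)
  x <- rexp(60); ev <- rbinom(60, 1, 0.7)
  crv <- km_curve(x, ev)
  expect_true(all(diff(crv$surv) <= 1e-12))
  expect_true(all(crv$surv >= 0 & crv$surv <= 1))
  ok <- !is.na(crv$ci_low) & !is.na(crv$ci_high)
  expect_true(all(crv$ci_low[ok] <= crv$surv[ok] + 1e-12))
  expect_true(all(crv$ci_high[ok] >= crv$surv[ok] - 1e-12))

  heavy <- km_curve(c(1, 2, 3, 4), c(1, 0, 0, 0))
  expect_true(is.na(heavy$median))
})

test_that("censoring_rate counts censored PFS2 out of the total", {
  coh <- as_cohort(data.frame(pfs1 = rep(1, 10), pfs2 = rep(1, 10),
                              event2 = c(rep(1, 8), 0, 0)))
  expect_equal(censoring_rate(coh), 0.2)
  coh$event2 <- rep(1L, 10)
  expect_equal(censoring_rate(coh), 0)
  coh$event2 <- rep(0L, 10)
  expect_equal(censoring_rate(coh), 1)
})

test_that("log cumulative hazard slopes recover the Weibull shape", {
  # log(-log S(t)) = log(lambda) + kappa log(t): slope is the shape
  for (kap in c(1, 2)) {
    coh <- sim_weibull_gamma(2000, median1 = 3, ratio_R = 1, kappa = kap,
                             theta = 0, seed = 50 + kap)
    chk <- weibull_check(coh)
    s1 <- chk$fits$slope[chk$fits$margin == "pfs1"]
    expect_equal(s1, kap, tolerance = 0.1)
    expect_gt(chk$fits$r2[1], 0.98)
  }
  # both margins kappa = 1.5: parallel lines, slope ratio near one
  coh <- sim_weibull_gamma(2000, median1 = 3, ratio_R = 1.3, kappa = 1.5,
                           theta = 0.5, seed = 60)
  chk <- weibull_check(coh)
  expect_equal(chk$slope_ratio, 1, tolerance = 0.1)
  expect_error(weibull_check(as_cohort(data.frame(pfs1 = c(1, 2), pfs2 = c(1, 2),
                                                  event2 = c(1, 1)))),
               "fewer than 3")
})

test_that("frailty fit: tau is exactly theta/(theta+2) and recovery works", {
  coh <- sim_weibull_gamma(400, theta = 1, seed = 21)
  fit <- fit_weibull_gamma(coh)
  expect_equal(fit$tau, fit$theta / (fit$theta + 2))   # derived, never estimated
  expect_true(fit$converged)

  # independence: theta (hence tau) near zero
  fit0 <- fit_weibull_gamma(sim_weibull_gamma(600, theta = 0, seed = 22))
  expect_lt(fit0$tau, 0.05)

  # full parameter recovery at kappa=1.5, lambda1=0.2, lambda2=0.1, theta=2
  set.seed(99)
  n <- 1000; th <- 2; kap <- 1.5; l1 <- 0.2; l2 <- 0.1
  w <- rgamma(n, 1 / th, scale = th)
  coh <- as_cohort(data.frame(pfs1 = (rexp(n) / (w * l1))^(1 / kap),
                              pfs2 = (rexp(n) / (w * l2))^(1 / kap),
                              event2 = 1))
  fit <- fit_weibull_gamma(coh)
  expect_equal(fit$kappa, kap, tolerance = 0.1)
  expect_equal(fit$lambda1, l1, tolerance = 0.3)   # relative
  expect_equal(fit$lambda2, l2, tolerance = 0.3)
  expect_equal(fit$theta, th, tolerance = 0.15)    # relative
})

test_that("frailty likelihood at theta=0 matches independent Weibull fits", {
  coh <- sim_weibull_gamma(500, median1 = 3, ratio_R = 1.2, kappa = 1.3,
                           theta = 0, seed = 31)
  fit <- fit_weibull_gamma(coh)
  # independent-margin oracle: survreg on each margin
  sr1 <- survival::survreg(survival::Surv(pfs1, rep(1, nrow(coh))) ~ 1,
                           data = coh, dist = "weibull")
  shape1 <- 1 / sr1$scale
  expect_equal(fit$kappa, shape1, tolerance = 0.1)
  expect_lt(fit$theta, 0.1)
  rate1 <- exp(-coef(sr1) / sr1$scale)       # S(t) = exp(-rate * t^shape)
  expect_equal(fit$lambda1, unname(rate1), tolerance = 0.25)
})
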