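test_that("gamma_from_rho inverts the GBVE correlation map", {
  expect_equal(gamma_from_rho(0), 1)
  # the map is strictly decreasing and its root reproduces rho
  g <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), gamma_from_rho, numeric(1))
  expect_true(all(diff(g) < 0))
  for (i in seq_along(g)) {
    rho_back <- exp(log(g[i]) + 2 * lgamma(g[i]) - lgamma(2 * g[i])) - 1
    expect_equal(rho_back, c(0.1, 0.3, 0.5, 0.7, 0.9)[i], tolerance = 1e-8)
  }
  expect_error(gamma_from_rho(-0.1), "rho")
  expect_error(gamma_from_rho(1), "rho")
})

test_that("simulated GBVE pairs reproduce the requested Pearson correlation", {
  coh <- sim_gbve(2e5, rho = 0.5, seed = 11)
  expect_equal(cor(coh$pfs1, coh$pfs2), 0.5, tolerance = 0.02)
})

test_that("closed-form GTEs match their models", {
  # independent exponentials: P(T2 >= d*T1) = 1/(1 + d/R)
  expect_equal(gte_gbve(1, 1.3, 0), 1.3 / 2.3)
  expect_equal(gte_weibull(1, 1.3, 1), 1.3 / 2.3)   # kappa=1 coincides
  expect_equal(gte_gbve(1.3, 1.3, 0.4), 0.5)        # zero effect is one half
  expect_equal(gte_weibull(1.3, 1.3, 2), 0.5)
  # dependence and shape sharpen the effect
  expect_gt(gte_gbve(1, 1.3, 0.6), gte_gbve(1, 1.3, 0.2))
  expect_gt(gte_weibull(1, 1.3, 2), gte_weibull(1, 1.3, 1))
})

test_that("sample size formula and non-informative inflation are exact", {
  d <- sample_size(alpha = 0.05, power = 0.9, model = "direct", gte1 = 0.75)
  expect_equal(d$n_events, 31)   # hand evaluation of the normal-approx formula

  # N = ceiling(n / (1 - p)): pick (by root-finding) a GTE whose raw normal
  # approximation lands at 89.5, so n = 90 and 10% non-informative gives N = 100
  raw_n <- function(g1, alpha = 0.05, power = 0.9) {
    (qnorm(1 - alpha) * 0.5 + qnorm(power) * sqrt(g1 * (1 - g1)))^2 / (g1 - 0.5)^2
  }
  g90 <- uniroot(function(g) raw_n(g) - 89.5, c(0.55, 0.74), tol = 1e-12)$root
  d <- sample_size(alpha = 0.05, power = 0.9, model = "direct", gte1 = g90,
                   p_noninformative = 0.10)
  expect_equal(d$n_events, 90)
  expect_equal(d$n_total, 100)

  expect_error(sample_size(model = "direct", gte1 = 0.5), "non-positive effect")
  expect_error(sample_size(model = "gbve", delta0 = 1.3, delta1 = 1.3,
                           rho = 0.3), "delta1")
})

test_that("required N is monotone in correlation, shape, effect size and power", {
  Ns <- vapply(c(0, 0.2, 0.4, 0.6, 0.8), function(rho)
    sample_size(power = 0.8, delta0 = 1, delta1 = 1.3, model = "gbve",
                rho = rho)$n_total, numeric(1))
  expect_true(all(diff(Ns) <= 0))

  Nk <- vapply(c(0.8, 1, 1.5, 2), function(k)
    sample_size(power = 0.8, delta0 = 1, delta1 = 1.3, model = "weibull",
                kappa = k)$n_total, numeric(1))
  expect_true(all(diff(Nk) <= 0))

  Nd <- vapply(c(1.2, 1.3, 1.5, 1.8), function(d1)
    sample_size(power = 0.8, delta0 = 1, delta1 = d1, model = "gbve",
                rho = 0.3)$n_total, numeric(1))
  expect_true(all(diff(Nd) <= 0))

  Np <- vapply(c(0.7, 0.8, 0.9), function(pw)
    sample_size(power = pw, delta0 = 1, delta1 = 1.3, model = "gbve",
                rho = 0.3)$n_total, numeric(1))
  expect_true(all(diff(Np) > 0))

  # clear expected superiority (delta0 below 1) with moderate-to-strong
  # correlation keeps the trial in the 20-30 patient range
  expect_lte(sample_size(alpha = 0.05, power = 0.8, delta0 = 0.8, delta1 = 1.3,
                         model = "gbve", rho = 0.6)$n_total, 30)
})

test_that("power calculation inverts the sample-size calculation", {
  for (rho in c(0.2, 0.5)) for (pw in c(0.8, 0.9)) {
    d <- sample_size(alpha = 0.05, power = pw, delta0 = 1, delta1 = 1.3,
                     model = "gbve", rho = rho, p_noninformative = 0.1)
    back <- trial_power(d$n_total, alpha = 0.05, delta0 = 1, delta1 = 1.3,
                        model = "gbve", rho = rho, p_noninformative = 0.1)
    expect_gte(back$achieved_power, pw - 0.01)
  }
  # power grows with correlation at fixed N
  pws <- vapply(c(0.1, 0.3, 0.5, 0.7), function(rho)
    trial_power(40, delta0 = 1, delta1 = 1.3, model = "gbve",
                rho = rho)$achieved_power, numeric(1))
  expect_true(all(diff(pws) > 0))
  # tiny effect: power collapses towards alpha
  expect_lt(trial_power(10, model = "direct", gte1 = 0.51)$achieved_power, 0.15)
})

test_that("exact binomial design attains its nominal operating characteristics", {
  d <- sample_size(alpha = 0.05, power = 0.9, model = "direct", gte1 = 0.75,
                   exact = TRUE)
  expect_equal(d$n_events, 33)
  pw <- trial_power(d$n_events, model = "direct", gte1 = 0.75,
                    exact = TRUE)$achieved_power
  expect_gte(pw, 0.9)
  pw_less <- trial_power(d$n_events - 1, model = "direct", gte1 = 0.75,
                         exact = TRUE)$achieved_power
  expect_lt(pw_less, 0.9)
  # the exact test's size never exceeds alpha
  k <- pfsratio:::exact_critical(33, 0.5, 0.05)
  expect_lte(pbinom(k - 1, 33, 0.5, lower.tail = FALSE), 0.05)
})
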