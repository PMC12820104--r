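#' GBVE dependence parameter from the Pearson correlation
#'
#' Under the Gumbel type-B bivariate extreme-value (GBVE) model with
#' exponential margins and joint survival
#' \eqn{\exp\{-[(\lambda_1 t_1)^{1/\gamma} + (\lambda_2 t_2)^{1/\gamma}]^\gamma\}},
#' the Pearson correlation of the pair is
#' \eqn{\rho = \gamma\,\Gamma(\gamma)^2/\Gamma(2\gamma) - 1}, a strictly
#' decreasing function of \eqn{\gamma \in (0, 1]} with \eqn{\rho(1) = 0}
#' (independence) and \eqn{\rho \to 1} as \eqn{\gamma \to 0}. This solves the
#' inverse by bracketed root-finding.
#'
#' @param rho Pearson correlation between PFS1 and PFS2 on the raw time scale;
#'   must be in \eqn{[0, 1)} (negative intra-patient correlation is clinically
#'   implausible and rejected).
#' @return dependence parameter `gamma` in (0, 1].
#' @export
gamma_from_rho <- function(rho) {
  if (!is.finite(rho) || rho < 0 || rho >= 1) {
    stop("rho must be in [0, 1): negative PFS1-PFS2 correlation is not ",
         "supported and rho = 1 is degenerate", call. = FALSE)
  }
  if (rho == 0) return(1)
  f <- function(g) exp(log(g) + 2 * lgamma(g) - lgamma(2 * g)) - 1 - rho
  uniroot(f, c(1e-8, 1), tol = 1e-12)$root
}

#' Generalized treatment effect under the GBVE model
#'
#' The GTE is \eqn{P(PFS2 \ge \delta_0\,PFS1)} under the alternative that the
#' true median ratio equals \eqn{\delta_1}. Under GBVE dependence the clocks
#' \eqn{(\delta_0 t_1)} and \eqn{t_2} compete exponentially conditional on the
#' shared positive-stable frailty, giving the closed form
#' \eqn{GTE_1 = 1/(1 + (\delta_0/\delta_1)^{1/\gamma(\rho)})}. Under the null
#' (true median ratio \eqn{\delta_0}) the GTE is exactly 1/2.
#'
#' @param delta0 effectiveness cutoff under the null hypothesis.
#' @param delta1 effectiveness level targeted under the alternative
#'   (`delta1 > delta0`).
#' @param rho Pearson correlation between PFS1 and PFS2 (see
#'   [gamma_from_rho()]).
#' @return probability `GTE1`.
#' @export
gte_gbve <- function(delta0, delta1, rho) {
  stopifnot(delta0 > 0, delta1 > 0)
  g <- gamma_from_rho(rho)
  1 / (1 + (delta0 / delta1)^(1 / g))
}

#' Generalized treatment effect under the Weibull-Gamma model
#'
#' With conditional Weibull margins of common shape `kappa` and a shared gamma
#' frailty, the ratio is log-logistic with shape `kappa` and median
#' \eqn{\delta_1} under the alternative, so
#' \eqn{GTE_1 = 1/(1 + (\delta_0/\delta_1)^{\kappa})}; the frailty cancels and
#' the PFS1-PFS2 correlation does not enter. With `kappa = 1` this coincides
#' with the independent (`rho = 0`) GBVE value.
#'
#' @inheritParams gte_gbve
#' @param kappa Weibull shape (> 0).
#' @return probability `GTE1`.
#' @export
gte_weibull <- function(delta0, delta1, kappa) {
  stopifnot(delta0 > 0, delta1 > 0, kappa > 0)
  1 / (1 + (delta0 / delta1)^kappa)
}

resolve_gte <- function(model, delta0, delta1, rho, kappa, gte1, gte0) {
  g1 <- switch(model,
               direct = {
                 if (is.null(gte1)) stop("model 'direct' requires gte1", call. = FALSE)
                 gte1
               },
               gbve = {
                 if (is.null(rho)) stop("model 'gbve' requires rho", call. = FALSE)
                 gte_gbve(delta0, delta1, rho)
               },
               weibull = {
                 if (is.null(kappa)) stop("model 'weibull' requires kappa", call. = FALSE)
                 gte_weibull(delta0, delta1, kappa)
               })
  if (g1 <= gte0) {
    stop(sprintf("non-positive effect: GTE1 = %.4f is not above GTE0 = %.4f",
                 g1, gte0), call. = FALSE)
  }
  g1
}

# smallest k with P(Bin(n, g0) >= k) <= alpha (one-sided exact test)
exact_critical <- function(n, g0, alpha) {
  k <- qbinom(1 - alpha, n, g0)             # in the neighbourhood of the answer
  while (k <= n && pbinom(k - 1, n, g0, lower.tail = FALSE) > alpha) k <- k + 1
  k
}

exact_power <- function(n, g0, g1, alpha) {
  k <- exact_critical(n, g0, alpha)
  if (k > n) return(0)
  pbinom(k - 1, n, g1, lower.tail = FALSE)
}

#' Sample size for a PFS-ratio trial
#'
#' The analysis is a one-sided test, on the informative pairs, of
#' \eqn{P(PFS2 \ge \delta_0 PFS1) = GTE_0} (1/2 under the null that the true
#' median ratio is \eqn{\delta_0}) against the alternative GTE resolved from
#' the chosen model. The default (normal approximation, unpooled variances)
#' number of informative pairs is
#' \deqn{n = \lceil (z_{1-\alpha}\sqrt{g_0(1-g_0)} +
#'   z_{1-\beta}\sqrt{g_1(1-g_1)})^2 / (g_1-g_0)^2 \rceil,}
#' and the total accrual is inflated for the expected proportion `p` of
#' non-informative pairs (censored PFS2 with ratio below \eqn{\delta_0}):
#' \eqn{N = \lceil n/(1-p) \rceil}. With `exact = TRUE`, `n` is instead the
#' smallest size at which the exact one-sided binomial test of size
#' \eqn{\le \alpha} reaches the requested power; the normal-approximation `n`
#' can miss the nominal power by several points at phase II sizes because of
#' the discreteness of the binomial critical value.
#'
#' @param alpha one-sided significance level (default 0.05).
#' @param power target power (1 - beta).
#' @param delta0,delta1 null and alternative effectiveness cutoffs
#'   (`delta1 > delta0 > 0`).
#' @param model `"direct"` (supply `gte1`), `"gbve"` (supply `rho`) or
#'   `"weibull"` (supply `kappa`).
#' @param rho,kappa,gte1 model inputs, see `model`.
#' @param gte0 null GTE, 1/2 unless specified directly.
#' @param p_noninformative expected proportion of non-informative pairs in
#'   `[0, 1)`.
#' @param exact use the exact binomial design instead of the normal
#'   approximation.
#' @return a `pfs_design` list: `gte0`, `gte1`, `n_events` (informative
#'   pairs), `n_total` (inflated accrual), plus the inputs.
#' @export
sample_size <- function(alpha = 0.05, power = 0.8, delta0 = 1, delta1 = 1.3,
                        model = c("gbve", "weibull", "direct"),
                        rho = NULL, kappa = NULL, gte1 = NULL, gte0 = 0.5,
                        p_noninformative = 0, exact = FALSE) {
  model <- match.arg(model)
  stopifnot(alpha > 0, alpha < 0.5, power > 0, power < 1,
            delta0 > 0 || model == "direct",
            p_noninformative >= 0, p_noninformative < 1,
            gte0 > 0, gte0 < 1)
  if (model != "direct" && delta1 <= delta0) {
    stop("delta1 must exceed delta0", call. = FALSE)
  }
  g1 <- resolve_gte(model, delta0, delta1, rho, kappa, gte1, gte0)
  za <- qnorm(1 - alpha); zb <- qnorm(power)
  n_norm <- ceiling((za * sqrt(gte0 * (1 - gte0)) +
                       zb * sqrt(g1 * (1 - g1)))^2 / (g1 - gte0)^2)
  n <- if (exact) {
    nn <- max(2, n_norm - 10)
    while (exact_power(nn, gte0, g1, alpha) < power) nn <- nn + 1
    nn
  } else n_norm
  structure(list(gte0 = gte0, gte1 = g1, n_events = n,
                 n_total = as.integer(ceiling(n / (1 - p_noninformative))),
                 alpha = alpha, power = power, delta0 = delta0,
                 delta1 = delta1, model = model, rho = rho, kappa = kappa,
                 p_noninformative = p_noninformative, exact = exact),
            class = "pfs_design")
}

#' @export
print.pfs_design <- function(x, ...) {
  cat(sprintf(paste0("PFS-ratio design (%s%s): GTE0=%.3f GTE1=%.3f -> ",
                     "n=%d informative pairs, N=%d patients ",
                     "(alpha=%.3g one-sided, power=%.2f, p_noninf=%.2f)\n"),
              x$model, if (isTRUE(x$exact)) ", exact binomial" else "",
              x$gte0, x$gte1, x$n_events, x$n_total, x$alpha,
              if (is.null(x$achieved_power)) x$power else x$achieved_power,
              x$p_noninformative))
  invisible(x)
}

#' Achieved power of a PFS-ratio trial of given size
#'
#' The reverse calculation: deflate the accrual `n_total` to the expected
#' informative pairs \eqn{n = \lfloor N (1-p) \rfloor} and evaluate the
#' one-sided test's power at the model-resolved GTE. Normal approximation by
#' default (the analytic counterpart of [sample_size()]); `exact = TRUE`
#' evaluates the exact binomial test instead.
#'
#' @inheritParams sample_size
#' @param n_total total number of patients accrued.
#' @return a `pfs_design` list with `achieved_power` filled in.
#' @export
trial_power <- function(n_total, alpha = 0.05, delta0 = 1, delta1 = 1.3,
                        model = c("gbve", "weibull", "direct"),
                        rho = NULL, kappa = NULL, gte1 = NULL, gte0 = 0.5,
                        p_noninformative = 0, exact = FALSE) {
  model <- match.arg(model)
  stopifnot(n_total >= 1, alpha > 0, alpha < 0.5)
  g1 <- resolve_gte(model, delta0, delta1, rho, kappa, gte1, gte0)
  n <- max(1L, floor(n_total * (1 - p_noninformative)))
  pw <- if (exact) {
    exact_power(n, gte0, g1, alpha)
  } else {
    za <- qnorm(1 - alpha)
    pnorm((sqrt(n) * (g1 - gte0) - za * sqrt(gte0 * (1 - gte0))) /
            sqrt(g1 * (1 - g1)))
  }
  structure(list(gte0 = gte0, gte1 = g1, n_events = n,
                 n_total = as.integer(n_total), achieved_power = pw,
                 alpha = alpha, power = pw, delta0 = delta0, delta1 = delta1,
                 model = model, rho = rho, kappa = kappa,
                 p_noninformative = p_noninformative, exact = exact),
            class = "pfs_design")
}
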