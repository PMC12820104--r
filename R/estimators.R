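#' Truncated Silverman kernel
#'
#' \eqn{K(u) = \tfrac12 e^{-|u|/\sqrt2} \sin(|u|/\sqrt2 + \pi/4)}, set to zero
#' beyond its first zero crossing at \eqn{|u| = 3\pi\sqrt2/4} and renormalized
#' to integrate to one. The kernel is flatter than the Gaussian, which keeps
#' kernel-weighted risk sets away from near-zero denominators; the truncation
#' removes the oscillating negative side lobes so all weights are
#' non-negative. Any other kernel function can be passed to
#' [estimate_kernel_km()] in its place.
#'
#' @param u numeric vector of scaled distances.
#' @return kernel values (non-negative, zero beyond the support).
#' @export
silverman_kernel <- local({
  u0 <- 3 * pi * sqrt(2) / 4
  base <- function(u) 0.5 * exp(-abs(u) / sqrt(2)) * sin(abs(u) / sqrt(2) + pi / 4)
  c0 <- integrate(base, -u0, u0)$value
  function(u) {
    k <- 0.5 * exp(-abs(u) / sqrt(2)) * sin(abs(u) / sqrt(2) + pi / 4) / c0
    k[abs(u) > u0] <- 0
    pmax(k, 0)
  }
})

new_ratio_estimate <- function(delta, s_hat, ci_low, ci_high, method,
                               n_total, n_informative, conf_level,
                               extra = NULL) {
  out <- list(delta = delta, s_hat = s_hat,
              ci_low = ci_low, ci_high = ci_high, method = method,
              n_total = n_total, n_informative = n_informative,
              conf_level = conf_level)
  out <- c(out, extra)
  class(out) <- "ratio_estimate"
  out
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf("S_PFSratio(%.3g) = %.3f (%.0f%% CI %.3f-%.3f) [%s, %d/%d informative]\n",
              x$delta, x$s_hat, 100 * x$conf_level, x$ci_low, x$ci_high,
              x$method, x$n_informative, x$n_total))
  invisible(x)
}

# S evaluated just before delta on a right-continuous step curve, so that
# ratios tied with delta count towards P(ratio >= delta)
step_at_minus <- function(times, surv, delta) {
  k <- sum(times < delta)
  if (k == 0) 1 else surv[k]
}

#' Count-based estimator of S_PFSratio(delta)
#'
#' The proportion of ratios at or above `delta` among informative pairs.
#' A pair is non-informative when PFS2 is censored and the (censored) ratio is
#' below `delta`: the true ratio could fall on either side, so such pairs are
#' excluded. A censored ratio at or above `delta` is a definite success (the
#' true ratio is even larger). The confidence interval is exact
#' (Clopper-Pearson) on the informative count.
#'
#' @param ratios a `ratio_sample` (or `pfs_cohort`).
#' @param delta effectiveness cutoff (> 0).
#' @param conf_level confidence level.
#' @return a `ratio_estimate`.
#' @export
estimate_count <- function(ratios, delta, conf_level = 0.95) {
  r <- as_ratio_sample(ratios)
  stopifnot(delta > 0)
  informative <- r$event == 1 | r$ratio >= delta
  n_inf <- sum(informative)
  if (n_inf == 0) {
    stop("no informative pairs at delta = ", delta,
         " (all ratios censored below delta)", call. = FALSE)
  }
  x <- sum(r$ratio >= delta)
  ci <- binom.test(x, n_inf, conf.level = conf_level)$conf.int
  new_ratio_estimate(delta, x / n_inf, ci[1], ci[2], "count",
                     nrow(r), n_inf, conf_level)
}

#' Kaplan-Meier estimator of S_PFSratio(delta)
#'
#' Treats the ratio as a time-to-event variable (PFS2 measured in units of
#' PFS1; a censored PFS2 censors the ratio) and evaluates the product-limit
#' curve just before `delta`, so ratios exactly at `delta` count as successes.
#' Confidence interval by the complementary log-log transform. When `delta`
#' lies beyond the last observation and the curve has not reached zero, the
#' point estimate carries the last defined value and the interval is reported
#' as indeterminate (`NA`).
#'
#' @inheritParams estimate_count
#' @return a `ratio_estimate`.
#' @export
estimate_km <- function(ratios, delta, conf_level = 0.95) {
  r <- as_ratio_sample(ratios)
  stopifnot(delta > 0)
  fit <- survival::survfit(survival::Surv(r$ratio, r$event) ~ 1,
                           conf.type = "log-log", conf.int = conf_level)
  k <- sum(fit$time < delta)
  if (k == 0) {
    est <- c(1, NA, NA)
  } else {
    est <- c(fit$surv[k], fit$lower[k], fit$upper[k])
  }
  if (delta > max(r$ratio) && est[1] > 0) est[2:3] <- NA  # beyond the data
  new_ratio_estimate(delta, est[1], est[2], est[3], "km",
                     nrow(r), nrow(r), conf_level)
}

neg_loglogis <- function(par, x, ev) {
  b <- exp(par[1]); R <- exp(par[2])
  z <- b * (log(x) - log(R))
  ll <- ifelse(ev == 1,
               log(b) - log(x) + z - 2 * log1p(exp(z)),
               -log1p(exp(z)))
  s <- sum(ll)
  if (!is.finite(s)) 1e10 else -s
}

#' Parametric (log-logistic) estimator of S_PFSratio(delta)
#'
#' Under the Weibull-Gamma frailty model with common shape \eqn{\kappa}, the
#' ratio of the paired times is log-logistic with shape \eqn{\kappa} and
#' median \eqn{R = (\lambda_1/\lambda_2)^{1/\kappa}} (the frailty cancels in
#' the ratio). The censored ratios are fitted by maximum likelihood and
#' \eqn{S(\delta) = 1/(1 + (\delta/R)^{shape})} evaluated at the estimates;
#' the confidence interval is by the delta method on
#' \eqn{q = shape(\log\delta - \log R)}.
#'
#' @inheritParams estimate_count
#' @return a `ratio_estimate` with the fitted model attached as `$fit`
#'   (a `loglogistic_fit`: `shape`, `median_ratio`, `loglik`, `vcov`,
#'   `converged`).
#' @export
estimate_parametric <- function(ratios, delta, conf_level = 0.95) {
  r <- as_ratio_sample(ratios)
  stopifnot(delta > 0)
  if (length(unique(r$ratio[r$event == 1])) < 2) {
    stop("parametric fit needs at least 2 distinct event ratios", call. = FALSE)
  }
  start <- c(0, log(median(r$ratio)))
  opt <- optim(start, neg_loglogis, x = r$ratio, ev = r$event,
               method = "BFGS", hessian = TRUE,
               control = list(maxit = 500, reltol = 1e-12))
  b <- exp(opt$par[1]); R <- exp(opt$par[2])
  V <- tryCatch(solve(opt$hessian), error = function(e) matrix(NA, 2, 2))
  q <- b * (log(delta) - log(R))
  grad <- c(q, -b)                       # d q / d(log b, log R)
  se_q <- sqrt(drop(t(grad) %*% V %*% grad))
  z <- qnorm(1 - (1 - conf_level) / 2)
  s_hat <- plogis(-q)
  ci <- if (is.finite(se_q)) plogis(-(q + c(1, -1) * z * se_q)) else c(NA, NA)
  fit <- structure(list(shape = b, median_ratio = R, loglik = -opt$value,
                        vcov = V, converged = opt$convergence == 0),
                   class = "loglogistic_fit")
  new_ratio_estimate(delta, s_hat, ci[1], ci[2], "parametric",
                     nrow(r), nrow(r), conf_level, extra = list(fit = fit))
}

#' @export
print.loglogistic_fit <- function(x, ...) {
  cat(sprintf("log-logistic ratio fit: shape=%.3f, median=%.3f (loglik %.2f%s)\n",
              x$shape, x$median_ratio, x$loglik,
              if (x$converged) "" else "; NOT converged"))
  invisible(x)
}

# point estimate used by estimate_midrank and its bootstrap
midrank_point <- function(ratio, event, delta) {
  n <- length(ratio)
  a <- c(ratio, delta)
  mins <- rank(a, ties.method = "min")
  minrank <- mins[seq_len(n)]
  pos_d <- mins[n + 1]
  m <- n + 1
  p <- ifelse(event == 1,
              as.numeric(minrank >= pos_d),
              ifelse(minrank >= pos_d, 1,
                     (m - pos_d + 1) / (m - minrank + 1)))
  mean(p)
}

#' Midrank estimator of S_PFSratio(delta)
#'
#' Rank-based nonparametric estimate in the spirit of the Hudgens-Satten
#' procedure: a censored ratio's true rank is only known to lie in an
#' admissible range (from its rank at the censoring value up to the top of the
#' sample), so its probability mass is spread uniformly over that range in the
#' `delta`-augmented ranking, and the estimate is the total mass at or above
#' `delta`'s position. With no censoring this reduces exactly to the
#' count-based proportion. The underlying equal-censoring assumption is
#' violated in the paired-PFS setting (PFS1 is never censored), which is why
#' this estimator over-states the ratio survival when censoring is
#' appreciable; it is included for comparison. Confidence interval by seeded
#' nonparametric pairs bootstrap (percentile).
#'
#' @inheritParams estimate_count
#' @param n_boot bootstrap resamples for the CI (0 skips the CI).
#' @param seed optional integer seed for the bootstrap.
#' @return a `ratio_estimate`.
#' @export
estimate_midrank <- function(ratios, delta, conf_level = 0.95,
                             n_boot = 2000, seed = NULL) {
  r <- as_ratio_sample(ratios)
  stopifnot(delta > 0)
  s_hat <- midrank_point(r$ratio, r$event, delta)
  ci <- c(NA, NA)
  if (n_boot > 0) {
    boots <- with_seed(seed, {
      n <- nrow(r)
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        midrank_point(r$ratio[idx], r$event[idx], delta)
      }, numeric(1))
    })
    alpha <- 1 - conf_level
    ci <- unname(quantile(boots, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE))
  }
  new_ratio_estimate(delta, s_hat, ci[1], ci[2], "midrank",
                     nrow(r), nrow(r), conf_level)
}

# balance a symmetric non-negative weight matrix to doubly stochastic
# (Sinkhorn scaling): every anchor's weights sum to one AND every observation
# contributes unit total mass across anchors, so the stage-2 average has no
# edge bias and reduces exactly to the empirical estimator without censoring
sinkhorn <- function(W, tol = 1e-12, max_iter = 200) {
  for (i in seq_len(max_iter)) {
    W <- W / rowSums(W)
    cs <- colSums(W)
    W <- sweep(W, 2, cs, "/")
    if (max(abs(cs - 1)) < tol) break
  }
  W / rowSums(W)
}

# Kernel-weighted conditional product-limit (Beran) curve of the ratio given
# PFS1, averaged over the observed PFS1 values. Returns the marginal step
# curve: distinct event ratios and the averaged survival just after each.
beran_marginal_curve <- function(ratio, event, anchor, bandwidth, kernel,
                                 rank_scale = TRUE) {
  n <- length(ratio)
  u <- if (rank_scale) rank(anchor, ties.method = "average") / n else anchor
  ord <- order(ratio)
  r <- ratio[ord]; ev <- event[ord]; u <- u[ord]
  ev_times <- unique(r[ev == 1])
  if (length(ev_times) == 0) {
    return(list(times = numeric(0), surv = numeric(0)))
  }
  W <- outer(u, u, function(a, b) kernel((b - a) / bandwidth))  # row = anchor
  tot <- rowSums(W)
  if (any(tot <= 0)) {                       # widen once, then give up
    bandwidth <- 2 * bandwidth
    W <- outer(u, u, function(a, b) kernel((b - a) / bandwidth))
    tot <- rowSums(W)
    if (any(tot <= 0)) {
      stop("kernel weights degenerate at some PFS1 anchors even after ",
           "doubling the bandwidth; supply a larger bandwidth", call. = FALSE)
    }
  }
  W <- sinkhorn(W)
  # at-risk mass per anchor just before each observation (obs sorted by ratio)
  AR <- W[, n:1, drop = FALSE]
  AR <- t(apply(AR, 1, cumsum))[, n:1, drop = FALSE]
  first_idx <- match(ev_times, r)            # risk set at each distinct event time
  D <- vapply(ev_times, function(s) {
    cols <- which(r == s & ev == 1)
    if (length(cols) == 1) W[, cols] else rowSums(W[, cols, drop = FALSE])
  }, numeric(n))
  Y <- AR[, first_idx, drop = FALSE]
  F <- 1 - D / Y
  F[!is.finite(F)] <- 1                      # zero mass at risk: no information
  F[F < 0] <- 0
  logF <- log(F)
  S <- exp(t(apply(logF, 1, cumsum)))        # anchor x event-time conditional survival
  list(times = ev_times, surv = colMeans(S))
}

default_bandwidth <- function(anchor, rank_scale) {
  n <- length(anchor)
  if (rank_scale) {
    1.06 * sqrt(1 / 12) * n^(-1 / 5)         # normal-reference rule, U(0,1) ranks
  } else {
    sigma <- min(sd(anchor), IQR(anchor) / 1.349)
    1.06 * sigma * n^(-1 / 5)
  }
}

#' Two-stage kernel-based Kaplan-Meier estimator of S_PFSratio(delta)
#'
#' Stage one estimates the conditional survival of the ratio given PFS1 by a
#' kernel-weighted product-limit (Beran) estimator; stage two averages the
#' conditional curves over the observed PFS1 values. Only conditional
#' independence of the ratio and its censoring given PFS1 is required, which
#' holds whenever PFS2 itself is independently censored given PFS1 -- so the
#' estimator stays consistent under the informative censoring that biases the
#' plain Kaplan-Meier on ratios.
#'
#' By default the kernel operates on the rank-transformed PFS1 (ranks scaled
#' to (0, 1]), a nearest-neighbour-type weighting that keeps local risk sets
#' comparable even though the PFS1 marginal is strongly right-skewed; the
#' bandwidth then defaults to the normal-reference rule on that scale,
#' \eqn{1.06\,\sigma n^{-1/5}} with \eqn{\sigma = 1/\sqrt{12}}. Set
#' `rank_scale = FALSE` for raw-scale weighting (bandwidth rule applied to
#' `min(sd, IQR/1.349)` of PFS1). The kernel weight matrix is balanced to
#' doubly stochastic before use, so every patient carries unit total mass
#' across the conditional curves: this removes the edge bias of the stage-2
#' average and makes the estimator reduce exactly to the empirical proportion
#' when no ratio is censored, at any bandwidth. Confidence interval by seeded
#' pairs bootstrap (percentile).
#'
#' @inheritParams estimate_midrank
#' @param bandwidth kernel bandwidth; `NULL` for the default rule.
#' @param kernel kernel function (default [silverman_kernel()]).
#' @param rank_scale logical; apply kernel weights on the PFS1 rank scale
#'   (default `TRUE`).
#' @return a `ratio_estimate` (with `bandwidth` attached).
#' @export
estimate_kernel_km <- function(ratios, delta, bandwidth = NULL,
                               kernel = silverman_kernel,
                               conf_level = 0.95, n_boot = 2000, seed = NULL,
                               rank_scale = TRUE) {
  r <- as_ratio_sample(ratios)
  stopifnot(delta > 0)
  if (anyNA(r$pfs1_anchor)) {
    stop("kernel-based estimation needs the pfs1_anchor of every ratio",
         call. = FALSE)
  }
  if (is.null(bandwidth)) bandwidth <- default_bandwidth(r$pfs1_anchor, rank_scale)
  crv <- beran_marginal_curve(r$ratio, r$event, r$pfs1_anchor, bandwidth,
                              kernel, rank_scale)
  s_hat <- step_at_minus(crv$times, crv$surv, delta)
  ci <- c(NA, NA)
  if (n_boot > 0) {
    boots <- with_seed(seed, {
      n <- nrow(r)
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        cb <- beran_marginal_curve(r$ratio[idx], r$event[idx],
                                   r$pfs1_anchor[idx], bandwidth, kernel,
                                   rank_scale)
        step_at_minus(cb$times, cb$surv, delta)
      }, numeric(1))
    })
    alpha <- 1 - conf_level
    ci <- unname(quantile(boots, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE))
  }
  new_ratio_estimate(delta, s_hat, ci[1], ci[2], "kernel_km",
                     nrow(r), nrow(r), conf_level,
                     extra = list(bandwidth = bandwidth))
}

#' Estimate S_PFSratio(delta) by any of the five methods
#'
#' Dispatcher with the censoring-rate guardrails: a warning at or above 20%
#' censoring recommending the kernel-based method, and a refusal at or above
#' 50% unless `force = TRUE` (estimates degrade badly there).
#'
#' @inheritParams estimate_kernel_km
#' @param method one of `"count"`, `"km"`, `"kernel_km"`, `"parametric"`,
#'   `"midrank"`.
#' @param force proceed despite a censoring rate of 50% or more.
#' @param ... passed to the method-specific estimator.
#' @return a `ratio_estimate`.
#' @export
estimate_pfsratio <- function(ratios, delta,
                              method = c("kernel_km", "count", "km",
                                         "parametric", "midrank"),
                              conf_level = 0.95, force = FALSE, ...) {
  method <- match.arg(method)
  r <- as_ratio_sample(ratios)
  cens <- mean(r$event == 0)
  if (cens >= 0.5 && !force) {
    stop(sprintf(paste0("PFS2 censoring rate is %.0f%%; the PFS ratio should ",
                        "only be used when censoring is below 50%% ",
                        "(use force = TRUE to override)"), 100 * cens),
         call. = FALSE)
  }
  if (cens >= 0.2 && method != "kernel_km") {
    warning(sprintf(paste0("censoring rate is %.0f%%; the kernel-based ",
                           "Kaplan-Meier method is preferred at or above 20%%"),
                    100 * cens), call. = FALSE)
  }
  switch(method,
         count = estimate_count(r, delta, conf_level),
         km = estimate_km(r, delta, conf_level),
         kernel_km = estimate_kernel_km(r, delta, conf_level = conf_level, ...),
         parametric = estimate_parametric(r, delta, conf_level),
         midrank = estimate_midrank(r, delta, conf_level, ...))
}

#' S_PFSratio(delta) over a grid of thresholds
#'
#' One estimate per grid point; for a fixed method the curve is non-increasing
#' in `delta`. Count-based points where every pair is non-informative are
#' returned as `NA` rows. For the bootstrap-based methods the resamples are
#' shared across the grid so the exported curve is internally consistent.
#'
#' @inheritParams estimate_pfsratio
#' @param deltas increasing positive grid (default 0.1 to 3 in steps of 0.05).
#' @param n_boot bootstrap resamples for kernel/midrank CIs (0 skips them).
#' @param bandwidth,kernel,rank_scale kernel method options.
#' @param seed integer seed for bootstrap CIs.
#' @return data frame: `method`, `delta`, `s_hat`, `ci_low`, `ci_high`,
#'   `n_informative`.
#' @export
s_curve <- function(ratios, deltas = seq(0.1, 3, by = 0.05),
                    method = c("kernel_km", "count", "km", "parametric",
                               "midrank"),
                    conf_level = 0.95, n_boot = 0, bandwidth = NULL,
                    kernel = silverman_kernel, rank_scale = TRUE, seed = NULL) {
  method <- match.arg(method)
  r <- as_ratio_sample(ratios)
  stopifnot(all(deltas > 0), !is.unsorted(deltas))
  n <- nrow(r)
  row_of <- function(est, d) {
    data.frame(method = method, delta = d, s_hat = est$s_hat,
               ci_low = est$ci_low, ci_high = est$ci_high,
               n_informative = est$n_informative)
  }
  if (method %in% c("count", "km", "parametric")) {
    out <- lapply(deltas, function(d) {
      est <- tryCatch(switch(method,
                             count = estimate_count(r, d, conf_level),
                             km = estimate_km(r, d, conf_level),
                             parametric = estimate_parametric(r, d, conf_level)),
                      error = function(e) NULL)
      if (is.null(est)) {
        data.frame(method = method, delta = d, s_hat = NA, ci_low = NA,
                   ci_high = NA, n_informative = NA)
      } else row_of(est, d)
    })
    return(do.call(rbind, out))
  }
  point_fun <- if (method == "midrank") {
    function(idx) vapply(deltas, function(d)
      midrank_point(r$ratio[idx], r$event[idx], d), numeric(1))
  } else {
    if (is.null(bandwidth)) bandwidth <- default_bandwidth(r$pfs1_anchor, rank_scale)
    function(idx) {
      crv <- beran_marginal_curve(r$ratio[idx], r$event[idx],
                                  r$pfs1_anchor[idx], bandwidth, kernel,
                                  rank_scale)
      vapply(deltas, function(d) step_at_minus(crv$times, crv$surv, d),
             numeric(1))
    }
  }
  s <- point_fun(seq_len(n))
  lo <- hi <- rep(NA_real_, length(deltas))
  if (n_boot > 0) {
    B <- with_seed(seed, {
      vapply(seq_len(n_boot),
             function(b) point_fun(sample.int(n, n, replace = TRUE)),
             numeric(length(deltas)))
    })
    alpha <- 1 - conf_level
    lo <- apply(B, 1, quantile, probs = alpha / 2, na.rm = TRUE)
    hi <- apply(B, 1, quantile, probs = 1 - alpha / 2, na.rm = TRUE)
  }
  data.frame(method = method, delta = deltas, s_hat = s,
             ci_low = lo, ci_high = hi, n_informative = n)
}

#' Median PFS ratio
#'
#' The smallest `delta` at which the estimated ratio-survival curve drops to
#' 0.5 or below. For the Kaplan-Meier method the confidence interval uses the
#' CI-crossing rule; for the kernel method a seeded pairs bootstrap; for the
#' parametric method the closed form (the fitted median and its log-scale
#' standard error). Curves that never reach 0.5 give an indeterminate (`NA`)
#' median.
#'
#' @inheritParams estimate_kernel_km
#' @param method `"km"`, `"kernel_km"` or `"parametric"`.
#' @return list with `median`, `ci_low`, `ci_high`, `method`.
#' @export
median_ratio <- function(ratios, method = c("km", "kernel_km", "parametric"),
                         conf_level = 0.95, bandwidth = NULL,
                         kernel = silverman_kernel, rank_scale = TRUE,
                         n_boot = 2000, seed = NULL) {
  method <- match.arg(method)
  r <- as_ratio_sample(ratios)
  if (method == "km") {
    fit <- survival::survfit(survival::Surv(r$ratio, r$event) ~ 1,
                             conf.type = "log-log", conf.int = conf_level)
    q <- quantile(fit, probs = 0.5)
    return(list(median = unname(q$quantile), ci_low = unname(q$lower),
                ci_high = unname(q$upper), method = "km"))
  }
  if (method == "parametric") {
    est <- estimate_parametric(r, delta = 1, conf_level = conf_level)
    z <- qnorm(1 - (1 - conf_level) / 2)
    se_logR <- sqrt(est$fit$vcov[2, 2])
    return(list(median = est$fit$median_ratio,
                ci_low = est$fit$median_ratio * exp(-z * se_logR),
                ci_high = est$fit$median_ratio * exp(z * se_logR),
                method = "parametric"))
  }
  if (is.null(bandwidth)) bandwidth <- default_bandwidth(r$pfs1_anchor, rank_scale)
  med_of <- function(idx) {
    crv <- beran_marginal_curve(r$ratio[idx], r$event[idx], r$pfs1_anchor[idx],
                                bandwidth, kernel, rank_scale)
    k <- which(crv$surv <= 0.5)
    if (length(k) == 0) NA_real_ else crv$times[min(k)]
  }
  med <- med_of(seq_len(nrow(r)))
  ci <- c(NA, NA)
  if (n_boot > 0 && !is.na(med)) {
    boots <- with_seed(seed, {
      n <- nrow(r)
      vapply(seq_len(n_boot),
             function(b) med_of(sample.int(n, n, replace = TRUE)), numeric(1))
    })
    alpha <- 1 - conf_level
    ci <- unname(quantile(boots, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE))
  }
  list(median = med, ci_low = ci[1], ci_high = ci[2], method = "kernel_km")
}

#' Efficacy test of S_PFSratio(delta) against a minimal proportion
#'
#' The trial is supportive of efficacy when the estimate's lower confidence
#' bound exceeds the targeted minimal proportion `p0` (strict inequality).
#'
#' @param estimate a `ratio_estimate`.
#' @param p0 targeted minimal proportion of responders (0 < p0 < 1).
#' @return an `efficacy_test` list: `delta`, `p0`, `s_hat`, `ci_low`,
#'   `success`, `method`.
#' @export
test_efficacy <- function(estimate, p0) {
  stopifnot(inherits(estimate, "ratio_estimate"), p0 > 0, p0 < 1)
  structure(list(delta = estimate$delta, p0 = p0, s_hat = estimate$s_hat,
                 ci_low = estimate$ci_low,
                 success = isTRUE(estimate$ci_low > p0),
                 method = estimate$method),
            class = "efficacy_test")
}

#' @export
print.efficacy_test <- function(x, ...) {
  cat(sprintf("Efficacy vs p0 = %.2f: S(%.3g) = %.3f, lower bound %.3f -> %s [%s]\n",
              x$p0, x$delta, x$s_hat, x$ci_low,
              if (x$success) "SUCCESS" else "NOT supportive", x$method))
  invisible(x)
}
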