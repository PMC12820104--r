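#' Kaplan-Meier survival curve with log(-log) confidence intervals
#'
#' Thin wrapper around [survival::survfit()] returning a plot-ready structure.
#' Confidence intervals use the complementary log-log transform (Greenwood
#' variance); the median and its confidence interval come from the
#' CI-crossing rule (first time each curve drops through 0.5).
#'
#' @param times positive durations (months).
#' @param events 1 = event observed, 0 = censored.
#' @param conf_level confidence level (default 0.95).
#' @return a `pfs_survcurve` list: `times`, `surv`, `ci_low`, `ci_high`,
#'   `n_risk`, `n_event`, `median`, `median_ci` (NA when indeterminate) and the
#'   underlying `survfit` object (`fit`).
#' @export
km_curve <- function(times, events, conf_level = 0.95) {
  stopifnot(length(times) == length(events), all(times > 0),
            all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log-log", conf.int = conf_level)
  q <- quantile(fit, probs = 0.5)
  med <- unname(q$quantile)
  structure(list(times = fit$time, surv = fit$surv,
                 ci_low = fit$lower, ci_high = fit$upper,
                 n_risk = fit$n.risk, n_event = fit$n.event,
                 median = med,
                 median_ci = c(unname(q$lower), unname(q$upper)),
                 conf_level = conf_level, fit = fit),
            class = "pfs_survcurve")
}

#' @export
print.pfs_survcurve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d events; median %s (%.0f%% CI %s-%s)\n",
              x$fit$n, sum(x$n_event), format(round(x$median, 2)),
              100 * x$conf_level,
              format(round(x$median_ci[1], 2)), format(round(x$median_ci[2], 2))))
  invisible(x)
}

# step-function lookup: S(t-), the probability of reaching t
surv_at <- function(times, surv, t) {
  idx <- findInterval(t - sqrt(.Machine$double.eps), times)
  if (idx == 0) 1 else surv[idx]
}

#' PFS2 censoring rate of a cohort
#'
#' @param cohort a `pfs_cohort`.
#' @return proportion of patients with censored PFS2.
#' @export
censoring_rate <- function(cohort) {
  stopifnot(inherits(cohort, "pfs_cohort"), nrow(cohort) >= 1)
  mean(cohort$event2 == 0)
}

#' Graphical Weibull adequacy check for PFS1 and PFS2
#'
#' If a PFS margin is Weibull with shape \eqn{\kappa}, then
#' \eqn{\log(-\log S(t)) = \log\lambda + \kappa \log t} is linear in
#' \eqn{\log t}, so plotting the log cumulative hazard of the Kaplan-Meier
#' estimate against log time should give a straight line per margin, and two
#' parallel lines if PFS1 and PFS2 share the shape. The check is reported as
#' numbers (slopes, intercepts, R-squared, slope ratio) plus the plot-ready
#' point sets; the accept/reject judgment is deliberately left to the analyst.
#'
#' @param cohort a `pfs_cohort`; PFS1 is treated as fully observed, PFS2 uses
#'   `event2`.
#' @return a `weibull_check` list: `points` (margin, log_time,
#'   loglog_cumhaz), `fits` (margin, slope, intercept, r2) and `slope_ratio`
#'   (PFS2 slope over PFS1 slope).
#' @export
weibull_check <- function(cohort) {
  stopifnot(inherits(cohort, "pfs_cohort"))
  one_margin <- function(times, events, label) {
    fit <- survival::survfit(survival::Surv(times, events) ~ 1)
    keep <- fit$n.event > 0 & fit$surv > 0 & fit$surv < 1
    if (sum(keep) < 3) {
      stop("margin ", label, " has fewer than 3 usable event times for the ",
           "Weibull check", call. = FALSE)
    }
    data.frame(margin = label, log_time = log(fit$time[keep]),
               loglog_cumhaz = log(-log(fit$surv[keep])))
  }
  pts <- rbind(one_margin(cohort$pfs1, rep(1L, nrow(cohort)), "pfs1"),
               one_margin(cohort$pfs2, cohort$event2, "pfs2"))
  fits <- do.call(rbind, lapply(split(pts, pts$margin), function(d) {
    m <- lm(loglog_cumhaz ~ log_time, data = d)
    data.frame(margin = d$margin[1], slope = unname(coef(m)[2]),
               intercept = unname(coef(m)[1]),
               r2 = summary(m)$r.squared)
  }))
  rownames(fits) <- NULL
  structure(list(points = pts, fits = fits,
                 slope_ratio = fits$slope[fits$margin == "pfs2"] /
                   fits$slope[fits$margin == "pfs1"]),
            class = "weibull_check")
}

#' @export
print.weibull_check <- function(x, ...) {
  cat("Weibull adequacy check (log cumulative hazard vs log time)\n")
  print(x$fits, row.names = FALSE)
  cat(sprintf("slope ratio (pfs2/pfs1): %.3f  [parallel straight lines support a shared Weibull shape]\n",
              x$slope_ratio))
  invisible(x)
}

# Weibull-Gamma shared-frailty log-likelihood.
# Joint survival S(t1,t2) = [1 + theta (l1 t1^k + l2 t2^k)]^(-1/theta);
# PFS1 is always an event, PFS2 may be censored:
#   event pair:   d2 S/dt1 dt2 = l1 k t1^(k-1) l2 k t2^(k-1) (1+theta) A^(-1/theta - 2)
#   t2 censored:  -dS/dt1      = l1 k t1^(k-1)               A^(-1/theta - 1)
# with A = 1 + theta H, H = l1 t1^k + l2 t2^k. theta -> 0 gives independent
# Weibull margins (A^(-1/theta) -> exp(-H)).
wg_loglik <- function(par, t1, t2, ev2) {
  k <- exp(par[1]); l1 <- exp(par[2]); l2 <- exp(par[3]); theta <- exp(par[4])
  H <- l1 * t1^k + l2 * t2^k
  base <- log(l1) + log(k) + (k - 1) * log(t1)
  if (theta < 1e-8) {
    cum <- H
    ll <- ifelse(ev2 == 1,
                 base + log(l2) + log(k) + (k - 1) * log(t2) - cum,
                 base - cum)
  } else {
    logA <- log1p(theta * H)
    ll <- ifelse(ev2 == 1,
                 base + log(l2) + log(k) + (k - 1) * log(t2) + log1p(theta) -
                   (1 / theta + 2) * logA,
                 base - (1 / theta + 1) * logA)
  }
  s <- sum(ll)
  if (!is.finite(s)) -1e10 else s
}

#' Fit the Weibull-Gamma shared-frailty model to paired PFS times
#'
#' Both margins are conditionally Weibull with a common shape \eqn{\kappa} and
#' rates \eqn{\lambda_1, \lambda_2}, multiplied by a patient-level gamma
#' frailty with mean 1 and variance \eqn{\theta} (Clayton-type dependence).
#' The intra-patient dependence is summarized by Kendall's
#' \eqn{\tau = \theta/(\theta+2)}, a derived quantity, never independently
#' estimated. Maximum likelihood on the log scale of all four parameters, with
#' deterministic multi-starts; PFS1 enters as an observed event for every
#' patient, PFS2 through its censoring indicator.
#'
#' @param cohort a `pfs_cohort` (at least 10 pairs recommended).
#' @param start optional named numeric vector `c(kappa, lambda1, lambda2,
#'   theta)` used as an additional start.
#' @return a `frailty_fit` list: `kappa`, `lambda1`, `lambda2`, `theta`,
#'   `tau`, `loglik`, `converged`.
#' @export
fit_weibull_gamma <- function(cohort, start = NULL) {
  stopifnot(inherits(cohort, "pfs_cohort"))
  t1 <- cohort$pfs1; t2 <- cohort$pfs2; ev2 <- cohort$event2
  m1 <- median(t1); m2 <- median(t2)
  starts <- list(c(1, log(2) / m1, log(2) / m2, 0.5),
                 c(1.5, log(2) / m1^1.5, log(2) / m2^1.5, 1),
                 c(0.7, log(2) / m1^0.7, log(2) / m2^0.7, 0.1))
  if (!is.null(start)) starts <- c(list(unname(start)), starts)
  best <- NULL
  for (s0 in starts) {
    fit <- tryCatch(
      optim(log(pmax(s0, 1e-8)), wg_loglik, t1 = t1, t2 = t2, ev2 = ev2,
            method = "Nelder-Mead",
            control = list(fnscale = -1, maxit = 3000, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value > best$value)) best <- fit
  }
  if (is.null(best)) stop("Weibull-Gamma frailty fit failed from all starts", call. = FALSE)
  # polish with a second pass from the best point
  best2 <- tryCatch(
    optim(best$par, wg_loglik, t1 = t1, t2 = t2, ev2 = ev2,
          method = "Nelder-Mead",
          control = list(fnscale = -1, maxit = 3000, reltol = 1e-10)),
    error = function(e) best)
  if (best2$value >= best$value) best <- best2
  p <- exp(best$par)
  theta <- if (p[4] < 1e-6) 0 else p[4]
  structure(list(kappa = p[1], lambda1 = p[2], lambda2 = p[3],
                 theta = theta, tau = theta / (theta + 2),
                 loglik = best$value,
                 converged = best$convergence == 0),
            class = "frailty_fit")
}

#' @export
print.frailty_fit <- function(x, ...) {
  cat(sprintf(paste0("Weibull-Gamma frailty fit: kappa=%.3f lambda1=%.4f ",
                     "lambda2=%.4f theta=%.3f -> Kendall's tau=%.3f ",
                     "(loglik %.2f%s)\n"),
              x$kappa, x$lambda1, x$lambda2, x$theta, x$tau, x$loglik,
              if (x$converged) "" else "; NOT converged"))
  invisible(x)
}
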