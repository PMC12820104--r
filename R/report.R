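#' Full PFS-ratio analysis of a cohort
#'
#' Runs the recommended workflow: marginal Kaplan-Meier summaries of PFS1 and
#' PFS2, the PFS2 censoring rate (with its guardrails: a warning at >= 20%
#' recommending the kernel-based method, refusal at >= 50% unless
#' `force = TRUE`), the Weibull adequacy check, the Weibull-Gamma frailty fit
#' (Kendall's tau), then the requested \eqn{S(\delta)} estimators, the median
#' PFS ratio, and -- when `p0` is given -- the efficacy verdict.
#'
#' @param cohort a `pfs_cohort`, or a path to a cohort CSV.
#' @param delta effectiveness cutoff (default 1.3).
#' @param p0 optional targeted minimal proportion for the efficacy test.
#' @param methods estimators to run (default all five).
#' @param conf_level confidence level.
#' @param transform optional [transform_policy()] applied before analysis.
#' @param bandwidth optional kernel bandwidth override.
#' @param n_boot bootstrap resamples for kernel/midrank CIs.
#' @param seed integer seed for the bootstrap CIs (recorded in the report).
#' @param force proceed despite a censoring rate of 50% or more.
#' @param column_map passed to [read_cohort()] when `cohort` is a path.
#' @return a `pfsratio_report` list; see the fields of the printed output.
#' @export
analyze_cohort <- function(cohort, delta = 1.3, p0 = NULL,
                           methods = c("count", "km", "kernel_km",
                                       "parametric", "midrank"),
                           conf_level = 0.95, transform = NULL,
                           bandwidth = NULL, n_boot = 2000, seed = 1,
                           force = FALSE, column_map = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort, column_map)
  stopifnot(inherits(cohort, "pfs_cohort"))
  methods <- match.arg(methods, several.ok = TRUE)
  n_transformed <- 0L
  if (!is.null(transform) && transform$scheme != "none") {
    cohort <- apply_transform(cohort, transform)
    n_transformed <- attr(cohort, "n_transformed")
  }
  cens <- censoring_rate(cohort)
  if (cens >= 0.5 && !force) {
    stop(sprintf(paste0("PFS2 censoring rate is %.0f%%, at or above the 50%% ",
                        "guardrail below which the PFS ratio is a reliable ",
                        "endpoint; rerun with force = TRUE to override"),
                 100 * cens), call. = FALSE)
  }
  if (cens >= 0.2) {
    warning(sprintf(paste0("PFS2 censoring rate is %.0f%%; the kernel-based ",
                           "Kaplan-Meier estimates should be preferred"),
                    100 * cens), call. = FALSE)
  }
  km1 <- km_curve(cohort$pfs1, rep(1L, nrow(cohort)), conf_level)
  km2 <- km_curve(cohort$pfs2, cohort$event2, conf_level)
  wcheck <- tryCatch(weibull_check(cohort), error = function(e) conditionMessage(e))
  frailty <- tryCatch(fit_weibull_gamma(cohort), error = function(e) NULL)
  ratios <- compute_ratios(cohort)
  ests <- lapply(setNames(methods, methods), function(m) {
    tryCatch(switch(m,
                    count = estimate_count(ratios, delta, conf_level),
                    km = estimate_km(ratios, delta, conf_level),
                    kernel_km = estimate_kernel_km(ratios, delta,
                                                   bandwidth = bandwidth,
                                                   conf_level = conf_level,
                                                   n_boot = n_boot, seed = seed),
                    parametric = estimate_parametric(ratios, delta, conf_level),
                    midrank = estimate_midrank(ratios, delta, conf_level,
                                               n_boot = n_boot, seed = seed)),
             error = function(e) conditionMessage(e))
  })
  med_method <- if ("kernel_km" %in% methods) "kernel_km" else "km"
  med <- median_ratio(ratios, med_method, conf_level, bandwidth = bandwidth,
                      n_boot = n_boot, seed = seed)
  efficacy <- NULL
  if (!is.null(p0)) {
    pick <- if ("kernel_km" %in% methods) "kernel_km" else methods[1]
    if (inherits(ests[[pick]], "ratio_estimate")) {
      efficacy <- test_efficacy(ests[[pick]], p0)
    }
  }
  structure(list(
    n = nrow(cohort), censoring_rate = cens, delta = delta,
    n_transformed = n_transformed,
    median_pfs1 = list(median = km1$median, ci = km1$median_ci),
    median_pfs2 = list(median = km2$median, ci = km2$median_ci),
    weibull_check = wcheck,
    frailty = frailty,
    tau = if (!is.null(frailty)) frailty$tau else NA,
    estimates = ests,
    median_pfsratio = med,
    efficacy = efficacy,
    provenance = list(package = "pfsratio",
                      version = as.character(packageVersion("pfsratio")),
                      seed = seed, conf_level = conf_level,
                      n_boot = n_boot,
                      transform = if (is.null(transform)) "none" else transform$scheme)),
    class = "pfsratio_report")
}

#' @export
print.pfsratio_report <- function(x, ...) {
  cat(sprintf("PFS-ratio analysis report (delta = %.3g)\n", x$delta))
  cat(sprintf("  N = %d, PFS2 censoring %.0f%%%s\n", x$n,
              100 * x$censoring_rate,
              if (x$n_transformed > 0)
                sprintf(", %d records transformed", x$n_transformed) else ""))
  cat(sprintf("  median PFS1 %.2f (%.2f-%.2f), median PFS2 %.2f (%.2f-%.2f) months\n",
              x$median_pfs1$median, x$median_pfs1$ci[1], x$median_pfs1$ci[2],
              x$median_pfs2$median, x$median_pfs2$ci[1], x$median_pfs2$ci[2]))
  if (inherits(x$weibull_check, "weibull_check")) {
    cat(sprintf("  Weibull check: slopes %.2f / %.2f (r2 %.3f / %.3f), slope ratio %.2f\n",
                x$weibull_check$fits$slope[1], x$weibull_check$fits$slope[2],
                x$weibull_check$fits$r2[1], x$weibull_check$fits$r2[2],
                x$weibull_check$slope_ratio))
  }
  if (!is.null(x$frailty)) {
    cat(sprintf("  Kendall's tau (Weibull-Gamma frailty): %.3f\n", x$tau))
  }
  for (m in names(x$estimates)) {
    e <- x$estimates[[m]]
    if (inherits(e, "ratio_estimate")) print(e) else
      cat(sprintf("  %s: failed (%s)\n", m, e))
  }
  med <- x$median_pfsratio
  cat(sprintf("  median PFSratio %.2f (%.2f-%.2f) [%s]\n",
              med$median, med$ci_low, med$ci_high, med$method))
  if (!is.null(x$efficacy)) print(x$efficacy)
  invisible(x)
}

report_as_list <- function(x) {
  ests <- lapply(x$estimates, function(e) {
    if (!inherits(e, "ratio_estimate")) return(list(error = e))
    list(delta = e$delta, s_hat = e$s_hat, ci_low = e$ci_low,
         ci_high = e$ci_high, n_total = e$n_total,
         n_informative = e$n_informative, conf_level = e$conf_level)
  })
  list(schema = "pfsratio_report/1",
       n = x$n, censoring_rate = x$censoring_rate, delta = x$delta,
       n_transformed = x$n_transformed,
       median_pfs1 = x$median_pfs1, median_pfs2 = x$median_pfs2,
       weibull_check = if (inherits(x$weibull_check, "weibull_check"))
         list(fits = x$weibull_check$fits,
              slope_ratio = x$weibull_check$slope_ratio)
       else list(error = x$weibull_check),
       tau = x$tau,
       frailty = if (!is.null(x$frailty))
         x$frailty[c("kappa", "lambda1", "lambda2", "theta", "tau",
                     "loglik", "converged")] else NULL,
       estimates = ests,
       median_pfsratio = x$median_pfsratio,
       efficacy = if (!is.null(x$efficacy)) unclass(x$efficacy) else NULL,
       provenance = x$provenance)
}

#' Write an analysis report to disk
#'
#' Emits `report.json` (machine-readable, schema-versioned) plus tidy CSVs of
#' the marginal survival curves and the Weibull-check points under `dir`.
#'
#' @param report a `pfsratio_report`.
#' @param dir output directory (created if needed).
#' @param cohort optionally, the analyzed cohort, to re-derive the marginal
#'   curves for the CSV exports.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, cohort = NULL) {
  stopifnot(inherits(report, "pfsratio_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report_as_list(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  if (!is.null(cohort)) {
    rows <- lapply(c(pfs1 = "pfs1", pfs2 = "pfs2"), function(m) {
      crv <- km_curve(cohort[[m]],
                      if (m == "pfs1") rep(1L, nrow(cohort)) else cohort$event2)
      data.frame(margin = m, time = crv$times, surv = crv$surv,
                 lo = crv$ci_low, hi = crv$ci_high)
    })
    write.csv(do.call(rbind, rows), file.path(dir, "km_curves.csv"),
              row.names = FALSE)
    if (inherits(report$weibull_check, "weibull_check")) {
      write.csv(report$weibull_check$points,
                file.path(dir, "weibull_check.csv"), row.names = FALSE)
    }
  }
  invisible(dir)
}
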