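#' Paired-PFS cohorts
#'
#' A cohort is a data frame with one row per patient and columns `id`
#' (character, unique), `pfs1` and `pfs2` (durations in months, strictly
#' positive) and `event2` (1 = progression observed on the investigational
#' line, 0 = censored). PFS1 carries no censoring flag: only patients who have
#' progressed on the prior line move to the next one, so PFS1 is an observed
#' event by construction.
#'
#' @param x data frame with columns `pfs1`, `pfs2`, `event2` and optionally
#'   `id`.
#' @return `x` with class `pfs_cohort`, a generated `id` column if absent, and
#'   the unit label (months) attached.
#' @examples
#' as_cohort(data.frame(pfs1 = c(3, 2), pfs2 = c(6, 2), event2 = c(1, 0)))
#' @export
as_cohort <- function(x) {
  x <- as.data.frame(x)
  for (col in c("pfs1", "pfs2", "event2")) {
    if (!col %in% names(x)) {
      stop("cohort is missing required column '", col, "'", call. = FALSE)
    }
  }
  if (nrow(x) < 1L) stop("cohort must contain at least one record", call. = FALSE)
  if (!"id" %in% names(x)) {
    x$id <- sprintf("P%04d", seq_len(nrow(x)))
  }
  x$id <- as.character(x$id)
  if (anyDuplicated(x$id)) stop("cohort ids must be unique", call. = FALSE)
  for (col in c("pfs1", "pfs2")) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad)) {
      stop(sprintf("column '%s' must be a positive duration; offending row(s): %s",
                   col, paste(bad, collapse = ", ")), call. = FALSE)
    }
    x[[col]] <- v
  }
  ev <- suppressWarnings(as.numeric(x$event2))
  bad <- which(!(ev %in% c(0, 1)))
  if (length(bad)) {
    stop("column 'event2' must be 0 (censored) or 1 (progression); offending row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  x$event2 <- as.integer(ev)
  x <- x[, c("id", "pfs1", "pfs2", "event2")]
  attr(x, "units") <- "months"
  class(x) <- c("pfs_cohort", "data.frame")
  x
}

#' Read a paired-PFS cohort from CSV
#'
#' Expects a comma-separated file with a header naming columns `pfs1`, `pfs2`
#' and `event2` (plus an optional `id`). Differently named columns can be
#' mapped with `column_map`.
#'
#' @param path path to a CSV file.
#' @param column_map optional named character vector mapping file column names
#'   to the canonical names, e.g. `c(t1 = "pfs1", t2 = "pfs2", ev = "event2")`.
#' @return a [as_cohort()] cohort; row order of the file is preserved.
#' @export
read_cohort <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    miss <- setdiff(names(column_map), names(df))
    if (length(miss)) {
      stop("column_map refers to absent column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    names(df)[match(names(column_map), names(df))] <- unname(column_map)
  }
  as_cohort(df)
}

#' Write a cohort to CSV
#'
#' @param cohort a `pfs_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "pfs_cohort"))
  write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.pfs_cohort <- function(x, ...) {
  cat(sprintf("Paired-PFS cohort: %d patients, %.0f%% PFS2 censoring (months)\n",
              nrow(x), 100 * mean(x$event2 == 0)))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more rows)\n", sep = "")
  invisible(x)
}

#' Derive censored ratio observations from a cohort
#'
#' The PFS ratio of each patient is `pfs2/pfs1`; when PFS2 is censored the
#' ratio is censored at the same point (its censoring variable is
#' `C2/pfs1`). The PFS1 denominator is retained as `pfs1_anchor` because the
#' kernel-based estimator conditions on it.
#'
#' @param cohort a `pfs_cohort`.
#' @return data frame of class `ratio_sample` with columns `ratio`, `event`,
#'   `pfs1_anchor` (one row per patient, order preserved).
#' @export
compute_ratios <- function(cohort) {
  stopifnot(inherits(cohort, "pfs_cohort"))
  out <- data.frame(ratio = cohort$pfs2 / cohort$pfs1,
                    event = cohort$event2,
                    pfs1_anchor = cohort$pfs1)
  class(out) <- c("ratio_sample", "data.frame")
  out
}

as_ratio_sample <- function(ratios) {
  if (inherits(ratios, "pfs_cohort")) return(compute_ratios(ratios))
  stopifnot(is.data.frame(ratios), all(c("ratio", "event") %in% names(ratios)))
  if (is.null(ratios$pfs1_anchor)) ratios$pfs1_anchor <- NA_real_
  ratios
}

#' Modified-PFSratio transform policies
#'
#' Very short PFS1 inflates the ratio and very long PFS2 deflates it relative
#' to clinical benefit; modified-PFSratio rules address both before the ratio
#' is formed. Two schemes are provided:
#' \describe{
#'   \item{`mock`}{PFS1 below 2 months is floored at 2 months, and PFS2 longer
#'     than 6 months is replaced by 24 months.}
#'   \item{`alternative`}{PFS1 is floored the same way; then any patient whose
#'     PFS2 is at least `min_satisfying_pfs2` (a clinically satisfying duration,
#'     default 6 months) but whose ratio still falls below `delta` has PFS2
#'     reset to `pfs1 * delta + bonus`. The 0.25-month bonus is about one week
#'     on the months scale, a minimal advantage that keeps such patients just
#'     above the threshold.}
#' }
#' Threshold comparisons follow the rules' wording: flooring applies strictly
#' below `pfs1_floor`, conversion strictly above `mock_pfs2_threshold`.
#'
#' @param scheme one of `"none"`, `"mock"`, `"alternative"`.
#' @param pfs1_floor months; PFS1 below this is raised to it (default 2).
#' @param mock_pfs2_threshold,mock_pfs2_replacement months; mock scheme only.
#' @param min_satisfying_pfs2 months; alternative scheme only (default 6).
#' @param delta effectiveness cutoff; required by the alternative scheme.
#' @param bonus months added on top of `pfs1 * delta` (default 0.25).
#' @return a `transform_policy` list.
#' @export
transform_policy <- function(scheme = c("none", "mock", "alternative"),
                             pfs1_floor = 2,
                             mock_pfs2_threshold = 6,
                             mock_pfs2_replacement = 24,
                             min_satisfying_pfs2 = 6,
                             delta = NULL,
                             bonus = 0.25) {
  scheme <- match.arg(scheme)
  durs <- c(pfs1_floor, mock_pfs2_threshold, mock_pfs2_replacement,
            min_satisfying_pfs2, bonus)
  if (any(!is.finite(durs) | durs <= 0)) {
    stop("all transform durations must be positive", call. = FALSE)
  }
  if (!is.null(delta) && (!is.finite(delta) || delta <= 0)) {
    stop("delta must be positive", call. = FALSE)
  }
  structure(list(scheme = scheme, pfs1_floor = pfs1_floor,
                 mock_pfs2_threshold = mock_pfs2_threshold,
                 mock_pfs2_replacement = mock_pfs2_replacement,
                 min_satisfying_pfs2 = min_satisfying_pfs2,
                 delta = delta, bonus = bonus),
            class = "transform_policy")
}

#' Apply a modified-PFSratio transform
#'
#' Returns a new cohort with the policy applied (see [transform_policy()]);
#' the input cohort is not modified and `event2` is never changed.
#'
#' @param cohort a `pfs_cohort`.
#' @param policy a [transform_policy()] with scheme `"mock"` or
#'   `"alternative"`.
#' @return a transformed `pfs_cohort` with attribute `n_transformed`, the
#'   number of records in which either duration changed.
#' @export
apply_transform <- function(cohort, policy) {
  stopifnot(inherits(cohort, "pfs_cohort"), inherits(policy, "transform_policy"))
  if (policy$scheme == "none") {
    attr(cohort, "n_transformed") <- 0L
    return(cohort)
  }
  out <- cohort
  out$pfs1 <- pmax(cohort$pfs1, policy$pfs1_floor)
  if (policy$scheme == "mock") {
    out$pfs2 <- ifelse(cohort$pfs2 > policy$mock_pfs2_threshold,
                       policy$mock_pfs2_replacement, cohort$pfs2)
  } else {
    if (is.null(policy$delta)) {
      stop("the alternative scheme requires delta to be set in the policy",
           call. = FALSE)
    }
    needs <- cohort$pfs2 >= policy$min_satisfying_pfs2 &
      cohort$pfs2 / out$pfs1 < policy$delta
    out$pfs2 <- ifelse(needs, out$pfs1 * policy$delta + policy$bonus, cohort$pfs2)
  }
  attr(out, "n_transformed") <-
    sum(out$pfs1 != cohort$pfs1 | out$pfs2 != cohort$pfs2)
  attr(out, "units") <- "months"
  class(out) <- class(cohort)
  out
}
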