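#' Z-score outlier screen for a paired sample
#'
#' Single-pass screen: using means and SDs of the full sample, an
#' observation is dropped when it lies more than `k` standard deviations
#' from the mean of either variable. Applied once (moments are not
#' recomputed after removal).
#'
#' @param x,y paired numeric vectors (>= 4 complete pairs).
#' @param k z-score cutoff (default 3).
#' @return Integer vector of kept indices.
#' @export
screen_outliers <- function(x, y, k = 3) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 4) stop("need at least 4 paired observations")
  zx <- abs(x - mean(x)) / stats::sd(x)
  zy <- abs(y - mean(y)) / stats::sd(y)
  zx[!is.finite(zx)] <- 0  # zero-variance variable: nothing is an outlier
  zy[!is.finite(zy)] <- 0
  keep <- which(zx <= k & zy <= k)
  if (length(keep) == 0) stop("outlier screen removed every observation")
  keep
}

#' Simple linear regression of an assessment score on ROI DVR
#'
#' Ordinary least squares of `y` on `x`, with Pearson correlation,
#' adjusted R-squared for the single-predictor model
#' (`1 - (1 - r^2)(n - 1)/(n - 2)`), and a two-sided p-value from the t
#' distribution on `n - 2` degrees of freedom.
#'
#' @param x predictor (ROI DVR values).
#' @param y response (assessment scores).
#' @return An object of class `dvr_regression`: `n_used`, `slope`,
#'   `intercept`, `pearson_r`, `r2`, `adjusted_r2`, `p_raw`, plus fitted
#'   values and standardized residuals for diagnostics.
#' @export
simple_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  n <- length(x)
  if (n < 4) stop("need at least 4 observations, got ", n)
  if (stats::sd(x) == 0) stop("zero variance in predictor")
  fit <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  r2 <- r^2
  tval <- r * sqrt((n - 2) / (1 - r2))
  p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  res <- stats::residuals(fit)
  structure(list(n_used = n,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 pearson_r = r, r2 = r2,
                 adjusted_r2 = adjusted_r2(r, n),
                 p_raw = p,
                 fitted = unname(stats::fitted(fit)),
                 std_residuals = unname(res / stats::sd(res))),
            class = "dvr_regression")
}

#' Adjusted R-squared of a single-predictor regression
#'
#' `1 - (1 - r^2)(n - 1)/(n - 2)`.
#'
#' @param r Pearson correlation coefficient.
#' @param n sample size.
#' @return Adjusted R-squared.
#' @examples
#' adjusted_r2(0.66, 19)  # 0.40 to 2 dp
#' @export
adjusted_r2 <- function(r, n) 1 - (1 - r^2) * (n - 1) / (n - 2)

#' @export
print.dvr_regression <- function(x, ...) {
  cat(sprintf("DVR regression (n = %d): slope %.4g, r = %.3f, adj R^2 = %.3f, p = %.4g\n",
              x$n_used, x$slope, x$pearson_r, x$adjusted_r2, x$p_raw))
  invisible(x)
}

#' @export
coef.dvr_regression <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Regress ROI DVR against the nine-assessment battery
#'
#' For each of the nine assessments: pairwise-complete cases are taken,
#' the z-score outlier screen ([screen_outliers()]) applied, and
#' [simple_regression()] run with the assessment score as the response.
#' Raw p-values are Bonferroni-corrected with a fixed divisor of 9 (the
#' size of the battery), regardless of how many assessments could actually
#' be fitted. Assessments with fewer than 4 usable pairs or a degenerate
#' predictor are reported as skipped, not errors.
#'
#' @param cohort cohort `data.frame` containing the [ASSESSMENTS] columns.
#' @param roi_dvr named numeric vector of ROI DVR per subject (names =
#'   `subject_id`).
#' @param k outlier z-score cutoff (default 3).
#' @return A list: `results` (data.frame, one row per assessment:
#'   `assessment`, `n_used`, `slope`, `intercept`, `pearson_r`, `r2`,
#'   `adjusted_r2`, `p_raw`, `p_bonferroni`, `n_outliers_removed`,
#'   `skipped`, `skip_reason`), `outliers` (named list of removed subject
#'   ids), `diagnostics` (long data.frame of fitted values and
#'   standardized residuals).
#' @export
run_assessment_battery <- function(cohort, roi_dvr, k = 3) {
  if (anyDuplicated(names(cohort)))
    stop("duplicate column(s) in cohort table: ",
         paste(unique(names(cohort)[duplicated(names(cohort))]),
               collapse = ", "))
  miss <- setdiff(ASSESSMENTS, names(cohort))
  if (length(miss))
    stop("cohort table lacks assessment column(s): ",
         paste(miss, collapse = ", "))
  dvr <- roi_dvr[match(cohort$subject_id, names(roi_dvr))]

  rows <- list(); outliers <- list(); diagnostics <- list()
  for (a in ASSESSMENTS) {
    y_all <- cohort[[a]]
    ok <- is.finite(dvr) & is.finite(y_all)
    row <- data.frame(assessment = a, n_used = NA_integer_,
                      slope = NA_real_, intercept = NA_real_,
                      pearson_r = NA_real_, r2 = NA_real_,
                      adjusted_r2 = NA_real_, p_raw = NA_real_,
                      p_bonferroni = NA_real_, n_outliers_removed = 0L,
                      skipped = FALSE, skip_reason = "",
                      stringsAsFactors = FALSE)
    if (sum(ok) < 4) {
      row$skipped <- TRUE
      row$skip_reason <- sprintf("only %d complete pairs", sum(ok))
      rows[[a]] <- row
      next
    }
    x <- dvr[ok]; y <- y_all[ok]; ids <- cohort$subject_id[ok]
    keep <- screen_outliers(x, y, k = k)
    removed <- ids[-keep]
    if (length(x[keep]) < 4 || stats::sd(x[keep]) == 0 ||
        stats::sd(y[keep]) == 0) {
      row$skipped <- TRUE
      row$skip_reason <- "degenerate data after outlier screen"
      rows[[a]] <- row
      next
    }
    fit <- simple_regression(x[keep], y[keep])
    row$n_used <- fit$n_used
    row$slope <- fit$slope; row$intercept <- fit$intercept
    row$pearson_r <- fit$pearson_r; row$r2 <- fit$r2
    row$adjusted_r2 <- fit$adjusted_r2
    row$p_raw <- fit$p_raw
    row$p_bonferroni <- min(1, 9 * fit$p_raw)
    row$n_outliers_removed <- length(removed)
    rows[[a]] <- row
    if (length(removed)) outliers[[a]] <- removed
    diagnostics[[a]] <- data.frame(assessment = a,
                                   subject_id = ids[keep],
                                   dvr = x[keep], score = y[keep],
                                   fitted = fit$fitted,
                                   std_residual = fit$std_residuals,
                                   stringsAsFactors = FALSE)
  }
  bind <- function(lst) if (length(lst))
    do.call(rbind, c(lst, list(make.row.names = FALSE))) else NULL
  list(results = bind(rows), outliers = outliers,
       diagnostics = bind(diagnostics))
}
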