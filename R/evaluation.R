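#' 3-D targeting errors
#'
#' Euclidean distance between predicted and actual internal positions at each
#' validation/imaging point.
#'
#' @param predicted n x 3 matrix (or 3-channel `marker_trace`) of predicted
#'   positions, mm.
#' @param actual n x 3 matrix (or 3-channel `marker_trace`) of imaged
#'   positions, mm.
#' @return Numeric vector of non-negative errors (mm).
#' @export
targeting_errors <- function(predicted, actual) {
  if (inherits(predicted, "marker_trace")) predicted <- predicted$values
  if (inherits(actual, "marker_trace")) actual <- actual$values
  predicted <- as.matrix(predicted); actual <- as.matrix(actual)
  if (!all(dim(predicted) == dim(actual))) {
    stop("predicted and actual must have matching dimensions")
  }
  sqrt(rowSums((predicted - actual)^2))
}

#' Root-mean-square error
#'
#' @param errors Non-empty numeric vector of errors (mm).
#' @return sqrt(mean(errors^2)).
#' @export
rmse <- function(errors) {
  if (length(errors) == 0L) stop("cannot take RMSE of an empty error vector")
  sqrt(mean(errors^2))
}

#' Cohort summary: median and interquartile range of per-patient RMSEs
#'
#' Quantiles use linear interpolation with the inclusive convention
#' (`stats::quantile` type 7); the IQR is Q3 - Q1.
#'
#' @param rmses Numeric vector, one RMSE per patient (mm).
#' @return List with `median` and `iqr` (mm).
#' @export
cohort_summary <- function(rmses) {
  if (length(rmses) < 1L) stop("need at least one patient RMSE")
  q <- stats::quantile(rmses, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2L], iqr = q[3L] - q[1L])
}

#' Empirical cumulative distribution of pooled targeting errors
#'
#' @param errors Non-empty numeric vector of pooled errors (mm).
#' @return List with `support` (sorted unique error values) and `fraction`
#'   (right-continuous cumulative fractions, ending at 1), plus
#'   `fraction_above_6mm`, the tail fraction beyond the 6 mm threshold of
#'   clinical interest.
#' @export
empirical_cdf <- function(errors) {
  if (length(errors) == 0L) stop("cannot form a CDF from no errors")
  fn <- stats::ecdf(errors)
  support <- sort(unique(errors))
  list(support = support, fraction = fn(support),
       fraction_above_6mm = mean(errors > 6))
}

#' Per-patient tracking report
#'
#' @param errors Per-imaging-point 3-D targeting errors (mm).
#' @param timestamps Optional timestamps of the imaging points.
#' @return An object of class `tracking_report` with the errors, their RMSE,
#'   the empirical CDF and summary quantiles.
#' @export
tracking_report <- function(errors, timestamps = NULL) {
  structure(list(errors = errors, timestamps = timestamps,
                 rmse = rmse(errors), cdf = empirical_cdf(errors),
                 median = stats::median(errors),
                 iqr = stats::IQR(errors, type = 7)),
            class = "tracking_report")
}

#' @export
print.tracking_report <- function(x, ...) {
  cat(sprintf("tracking_report: %d points, RMSE %.3f mm, median %.3f mm, IQR %.3f mm, >6 mm: %.1f%%\n",
              length(x$errors), x$rmse, x$median, x$iqr,
              100 * x$cdf$fraction_above_6mm))
  invisible(x)
}
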