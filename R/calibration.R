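# Mapping from ensemble precision s_Z to expected absolute error Z_err.

#' Calibrate prediction error against ensemble precision
#'
#' Bins the blind cross-validated predictions by their ensemble spread `s_Z`
#' (decile bins by default), computes the mean absolute error
#' `|Z_obs - Z_pred|` in each bin, and enforces a monotone non-decreasing
#' precision-to-error mapping by isotonic regression. Queries outside the
#' observed `s_Z` range clamp to the end bins.
#'
#' @param z_pred Blind predicted Z-scores.
#' @param s_z Ensemble spread for the same residues (>= 0).
#' @param z_obs Observed Z-scores.
#' @param n_bins Number of quantile bins (default 10). If there are fewer
#'   residues than bins the bin count is reduced with a warning.
#' @return An object of class `calibration_curve` with fields `edges`,
#'   `s_z_mean`, `z_err` (monotone), `n` (per-bin counts).
#' @export
calibrate_error <- function(z_pred, s_z, z_obs, n_bins = 10L) {
  stopifnot(length(z_pred) == length(s_z), length(s_z) == length(z_obs))
  keep <- is.finite(z_pred) & is.finite(s_z) & is.finite(z_obs)
  z_pred <- z_pred[keep]; s_z <- s_z[keep]; z_obs <- z_obs[keep]
  n <- length(z_pred)
  if (n < 2L) stop("need at least 2 residues to calibrate")
  if (n < n_bins) {
    warning("only ", n, " residues; reducing calibration bins to ", n)
    n_bins <- n
  }
  edges <- unique(stats::quantile(s_z, probs = seq(0, 1, length.out =
                                                     n_bins + 1L)))
  if (length(edges) < 3L) {
    # essentially constant s_z: one bin
    edges <- c(min(s_z), max(s_z) + 1e-12)
  }
  nb <- length(edges) - 1L
  bin <- findInterval(s_z, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  err <- abs(z_obs - z_pred)
  present <- sort(unique(bin))
  s_mean <- as.numeric(tapply(s_z, bin, mean)[as.character(present)])
  e_mean <- as.numeric(tapply(err, bin, mean)[as.character(present)])
  counts <- as.integer(tapply(err, bin, length)[as.character(present)])
  e_iso <- if (length(e_mean) > 1L) stats::isoreg(s_mean, e_mean)$yf else
    e_mean
  # route any empty interval to the nearest populated bin
  interval_map <- vapply(seq_len(nb), function(j) {
    which.min(abs(present - j))
  }, integer(1))
  structure(
    list(edges = as.numeric(edges), s_z_mean = s_mean, z_err = e_iso,
         n = counts, interval_map = interval_map),
    class = "calibration_curve"
  )
}

#' Look up the calibrated error for a precision value
#'
#' Piecewise-constant monotone lookup: each `s_Z` falls into its calibration
#' bin, values outside the calibrated range clamp to the first or last bin.
#'
#' @param curve A [calibrate_error()] result.
#' @param s_z Numeric vector of precisions (>= 0).
#' @return Numeric vector of expected absolute errors.
#' @export
predict_zerr <- function(curve, s_z) {
  stopifnot(inherits(curve, "calibration_curve"))
  bin <- findInterval(s_z, curve$edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  curve$z_err[curve$interval_map[bin]]
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("<calibration_curve> ", length(x$z_err), " bins; Z_err ",
      format(min(x$z_err), digits = 3), "..",
      format(max(x$z_err), digits = 3), "\n", sep = "")
  invisible(x)
}
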