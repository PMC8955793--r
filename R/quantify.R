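#' Fit a linear calibration curve
#'
#' Least-squares line of detector response on analyte concentration, with
#' the linearity (r squared) and residual standard error (RMSE, n - 2 df)
#' used by the detection- and quantification-limit formulas.
#'
#' @param conc Concentrations, ug/mL (at least three distinct values).
#' @param response Detector responses (peak areas by convention; heights
#'   work equally).
#' @return Object of class `calibration`: `slope`, `intercept`,
#'   `r_squared`, `rmse`, `n`, and the underlying [stats::lm] fit.
#' @seealso [lod()], [loq()], [tablet_content()]
#' @export
fit_calibration <- function(conc, response) {
  stopifnot(is.numeric(conc), is.numeric(response),
            length(conc) == length(response))
  if (length(conc) < 3L)
    stop("calibration needs at least 3 points", call. = FALSE)
  if (length(unique(conc)) < 2L)
    stop("calibration needs at least two distinct concentrations",
         call. = FALSE)
  fit <- stats::lm(response ~ conc)
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((response - mean(response))^2)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = 1 - rss / tss,
                 rmse = sqrt(rss / (length(conc) - 2L)),
                 n = length(conc), fit = fit,
                 conc = conc, response = response),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("calibration: response = %.6g + %.6g * conc (n = %d)\n",
              x$intercept, x$slope, x$n))
  cat(sprintf("r^2 = %.4f, RMSE = %.4g, LOD = %.3g, LOQ = %.3g ug/mL\n",
              x$r_squared, x$rmse, lod(x), loq(x)))
  invisible(x)
}

#' Limits of detection and quantification
#'
#' `LOD = 3.3 RMSE / slope` and `LOQ = 10 RMSE / slope`, where RMSE is the
#' residual standard error of the calibration regression. Their ratio is
#' always 10/3.3.
#'
#' @param curve A [fit_calibration()] object.
#' @return Limit in concentration units (ug/mL).
#' @export
lod <- function(curve) {
  stopifnot(inherits(curve, "calibration"))
  if (curve$slope <= 0) stop("calibration slope must be positive",
                             call. = FALSE)
  3.3 * curve$rmse / curve$slope
}

#' @rdname lod
#' @export
loq <- function(curve) {
  stopifnot(inherits(curve, "calibration"))
  if (curve$slope <= 0) stop("calibration slope must be positive",
                             call. = FALSE)
  10 * curve$rmse / curve$slope
}

#' Analyte content of a tablet sample
#'
#' Back-calculates the sample concentration through the calibration line,
#' `conc = (signal - intercept) / slope`, and converts it to mg per tablet
#' through the dilution factor and extraction volume. By convention the
#' signal of the first-migrating (S) enantiomer peak is used; multiply by
#' 2 (`racemic_total = TRUE`) for the racemic total of a 50:50 sample.
#'
#' @param curve A [fit_calibration()] object.
#' @param signal Measured detector response of the sample.
#' @param dilution Dilution factor from extract to injected solution.
#' @param volume_ml Extraction volume per tablet, mL.
#' @param racemic_total Double the single-enantiomer amount?
#' @return Content in mg per tablet; vectorized over `signal`.
#' @export
tablet_content <- function(curve, signal, dilution = 1, volume_ml = 1,
                           racemic_total = FALSE) {
  stopifnot(inherits(curve, "calibration"), is.numeric(signal))
  if (dilution <= 0 || volume_ml <= 0)
    stop("dilution and volume must be positive", call. = FALSE)
  conc <- (signal - curve$intercept) / curve$slope     # ug/mL injected
  mg <- conc * dilution * volume_ml / 1000
  if (racemic_total) mg <- 2 * mg
  mg
}

#' Recovery against the label claim
#'
#' @param measured_mg Measured content, mg.
#' @param label_mg Label claim, mg.
#' @return Recovery in percent: `100 * measured / label`.
#' @examples
#' recovery(5.32, 5)    # 106.4
#' recovery(10.18, 10)  # 101.8
#' @export
recovery <- function(measured_mg, label_mg) {
  stopifnot(is.numeric(measured_mg), is.numeric(label_mg))
  if (any(label_mg <= 0)) stop("label claim must be positive", call. = FALSE)
  100 * measured_mg / label_mg
}

#' Relative standard deviation of replicate measurements
#'
#' @param values Numeric vector of at least two replicate values.
#' @return RSD in percent: `100 * sd / mean`.
#' @export
precision_rsd <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) < 2L) stop("RSD needs at least two values", call. = FALSE)
  100 * stats::sd(values) / mean(values)
}
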