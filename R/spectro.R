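#' Total monomeric anthocyanins by the pH-differential method
#'
#' Quantifies monomeric anthocyanin pigment from paired absorbance readings
#' at pH 1.0 and pH 4.5. The differential absorbance is
#' `A = (A520 - A700)_pH1 - (A520 - A700)_pH4.5`; pigment concentration in
#' mg/L follows from Beer-Lambert,
#' `A * MW * DF * 1000 / (epsilon * path)`, with cyanidin-3-O-glucoside as
#' the reference (MW 449.2 g/mol, molar absorptivity 26900 L/(mol cm)).
#' Dividing by the sample mass concentration expresses the result per gram
#' dry weight.
#'
#' @param a520_ph1,a700_ph1 Absorbances at 520 and 700 nm in the pH 1.0
#'   buffer.
#' @param a520_ph45,a700_ph45 Absorbances in the pH 4.5 buffer.
#' @param dilution_factor Dilution factor applied to the sample (>= 1).
#' @param path_length Cuvette path length (cm).
#' @param mw Molar mass of the reference anthocyanin (g/mol).
#' @param epsilon Molar absorptivity of the reference (L/(mol cm)).
#' @param sample_mass_per_volume Optional sample concentration (g dry
#'   weight per litre); when given the result is mg C3G equivalents per g
#'   DW, otherwise mg/L of extract solution.
#' @return Total anthocyanin content (mg C3G/L, or mg C3G/g DW). A
#'   negative differential absorbance (no monomeric pigment signal) gives 0
#'   with a warning.
#' @examples
#' tac_ph_differential(0.55, 0.05, 0.05, 0.05, dilution_factor = 10)
#' @export
tac_ph_differential <- function(a520_ph1, a700_ph1, a520_ph45, a700_ph45,
                                dilution_factor = 1, path_length = 1,
                                mw = 449.2, epsilon = 26900,
                                sample_mass_per_volume = NULL) {
  abso <- c(a520_ph1, a700_ph1, a520_ph45, a700_ph45)
  if (any(!is.finite(abso)) || any(abso < 0))
    stop("absorbances must be non-negative", call. = FALSE)
  if (any(dilution_factor < 1))
    stop("'dilution_factor' must be >= 1", call. = FALSE)
  if (any(path_length <= 0))
    stop("'path_length' must be positive", call. = FALSE)
  A <- (a520_ph1 - a700_ph1) - (a520_ph45 - a700_ph45)
  if (any(A < 0)) {
    warning("negative differential absorbance set to 0 ",
            "(no monomeric anthocyanin signal)", call. = FALSE)
    A <- pmax(0, A)
  }
  conc <- A * mw * dilution_factor * 1000 / (epsilon * path_length)
  if (!is.null(sample_mass_per_volume)) {
    if (any(sample_mass_per_volume <= 0))
      stop("'sample_mass_per_volume' must be positive", call. = FALSE)
    conc <- conc / sample_mass_per_volume
  }
  conc
}

#' Fit a spectrophotometric standard curve
#'
#' Ordinary least squares of absorbance on standard concentration, the
#' calibration step behind gallic-acid-equivalent (Folin-Ciocalteu) and
#' Trolox-equivalent (DPPH) reporting.
#'
#' @param concentration Standard concentrations (>= 3 distinct values).
#' @param absorbance Measured absorbances (or % inhibition for DPPH).
#' @param standard Label of the calibration standard (e.g. `"gallic acid"`,
#'   `"Trolox"`).
#' @return Object of class `"standard_curve"` with `slope`, `intercept`,
#'   `r2`, `standard` and the underlying `lm`; `predict()` maps new
#'   absorbances back to concentrations.
#' @examples
#' curve <- calibrate_standard(c(0, 50, 100, 200), c(0.01, 0.26, 0.51, 1.01),
#'                             standard = "gallic acid")
#' curve
#' @export
calibrate_standard <- function(concentration, absorbance,
                               standard = "standard") {
  if (length(concentration) != length(absorbance))
    stop("'concentration' and 'absorbance' must have equal length",
         call. = FALSE)
  if (length(concentration) < 3L || length(unique(concentration)) < 3L)
    stop("at least 3 distinct standard concentrations are required",
         call. = FALSE)
  fit <- stats::lm(absorbance ~ concentration)
  slope <- unname(stats::coef(fit)[["concentration"]])
  if (slope == 0) stop("calibration slope is zero", call. = FALSE)
  structure(
    list(slope = slope,
         intercept = unname(stats::coef(fit)[["(Intercept)"]]),
         r2 = r_squared(fit),
         standard = standard, n = length(concentration), lm = fit),
    class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, digits = 4, ...) {
  cat("Standard curve (", x$standard, "): absorbance = ",
      signif(x$intercept, digits), " + ", signif(x$slope, digits),
      " x conc   R^2 = ", signif(x$r2, digits), "\n", sep = "")
  invisible(x)
}

#' @export
predict.standard_curve <- function(object, absorbance, ...) {
  (absorbance - object$intercept) / object$slope
}

#' Quantify a sample against a standard curve
#'
#' Inverts the calibration line, `(A - intercept) / slope`, and scales by
#' the dilution factor and (inverse) sample mass concentration to express
#' the result in standard equivalents per gram dry weight.
#'
#' @param absorbance Sample absorbance (or % inhibition for DPPH).
#' @param curve A [calibrate_standard()] fit.
#' @param dilution_factor Dilution applied to the sample.
#' @param sample_mass_per_volume Sample concentration (g DW/L).
#' @return Equivalent concentration per g DW; negative back-calculated
#'   values are floored at 0 with a warning.
#' @examples
#' curve <- calibrate_standard(c(0, 50, 100), c(0, 0.25, 0.5))
#' quantify_against_curve(0.3, curve, dilution_factor = 2,
#'                        sample_mass_per_volume = 2)
#' @export
quantify_against_curve <- function(absorbance, curve, dilution_factor = 1,
                                   sample_mass_per_volume = 1) {
  stopifnot(inherits(curve, "standard_curve"))
  if (any(dilution_factor < 1))
    stop("'dilution_factor' must be >= 1", call. = FALSE)
  if (any(sample_mass_per_volume <= 0))
    stop("'sample_mass_per_volume' must be positive", call. = FALSE)
  conc <- (absorbance - curve$intercept) / curve$slope
  if (any(conc < 0)) {
    warning("back-calculated concentration below 0 floored at 0",
            call. = FALSE)
    conc <- pmax(0, conc)
  }
  conc * dilution_factor / sample_mass_per_volume
}
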