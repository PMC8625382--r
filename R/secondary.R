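#' Arrhenius regression for activation energy
#'
#' Fits the Arrhenius model by ordinary least squares of `ln k` on `1/T_K`
#' (`T_K = T + 273.15`). The activation energy is `Ea = -slope * R / 1000`
#' in kJ/mol (R = 8.314 J/(mol K)); the intercept is `ln A`. The fit is
#' unweighted.
#'
#' @param temperature Temperatures (degC), at least two distinct.
#' @param k First-order rate constants (min^-1), all positive.
#' @return Object of class `"arrhenius_fit"` with components `Ea` (kJ/mol),
#'   `Ea_se` (from the slope standard error), `lnA`, `r2`, `n`, and the
#'   underlying `lm` fit. `coef()` returns `c(Ea, lnA)`; `predict()` gives
#'   rate constants at new temperatures.
#' @examples
#' arrhenius_fit(c(75, 95, 115, 135, 155),
#'               c(0.0069, 0.0138, 0.0253, 0.0737, 0.1865))
#' @export
arrhenius_fit <- function(temperature, k) {
  if (length(temperature) != length(k))
    stop("'temperature' and 'k' must have equal length", call. = FALSE)
  if (any(!is.finite(k)) || any(k <= 0))
    stop("all rate constants must be positive", call. = FALSE)
  if (length(unique(temperature)) < 2L)
    stop("at least two distinct temperatures are required", call. = FALSE)
  inv_tk <- 1 / celsius_to_kelvin(temperature)
  fit <- stats::lm(log(k) ~ inv_tk)
  slope <- unname(stats::coef(fit)[["inv_tk"]])
  slope_se <- sqrt(diag(vcov_quiet(fit)))[["inv_tk"]]
  structure(
    list(Ea = -slope * .R_GAS / 1000,
         Ea_se = unname(slope_se) * .R_GAS / 1000,
         lnA = unname(stats::coef(fit)[["(Intercept)"]]),
         r2 = r_squared(fit),
         n = length(k),
         temperature = temperature, k = k, lm = fit),
    class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, digits = 4, ...) {
  cat("Arrhenius fit (ln k vs 1/T)\n")
  cat("  Ea  = ", signif(x$Ea, digits), " +/- ", signif(x$Ea_se, digits),
      " kJ/mol\n", sep = "")
  cat("  lnA = ", signif(x$lnA, digits), "  R^2 = ", signif(x$r2, digits),
      "  (n = ", x$n, " temperatures)\n", sep = "")
  invisible(x)
}

#' @export
coef.arrhenius_fit <- function(object, ...) {
  c(Ea = object$Ea, lnA = object$lnA)
}

#' Predict rate constants from an Arrhenius fit
#'
#' @param object An [arrhenius_fit()].
#' @param temperature Temperatures (degC).
#' @param ... Unused.
#' @return Predicted rate constants (same time unit as the fitted `k`).
#' @export
predict.arrhenius_fit <- function(object, temperature, ...) {
  unname(arrhenius_rates(object$Ea, object$lnA, temperature))
}

#' @export
plot.arrhenius_fit <- function(x, ...) {
  inv_tk <- 1 / celsius_to_kelvin(x$temperature)
  graphics::plot(inv_tk, log(x$k), xlab = "1/T (1/K)", ylab = "ln k",
                 main = "Arrhenius plot", ...)
  graphics::abline(stats::coef(x$lm), lty = 2)
  invisible(x)
}

#' z-value regression on decimal reduction times
#'
#' Fits `log10 D` against temperature (degC) by ordinary least squares; the
#' z-value — the temperature rise producing a tenfold drop in D — is
#' `z = -1/slope`. Its standard error follows by the delta method,
#' `se(z) = se(slope) / slope^2`. The slope is offset-invariant, so Celsius
#' and Kelvin give the same z.
#'
#' @param temperature Temperatures (degC), at least two distinct.
#' @param d_value Decimal reduction times (min), all positive.
#' @return Object of class `"z_value_fit"` with `z` (degC), `z_se`, `r2`,
#'   `slope`, `n` and the underlying `lm`.
#' @examples
#' z_value_fit(c(75, 95, 115, 135, 155),
#'             c(333.33, 166.67, 90.91, 31.25, 12.35))
#' @export
z_value_fit <- function(temperature, d_value) {
  if (length(temperature) != length(d_value))
    stop("'temperature' and 'd_value' must have equal length", call. = FALSE)
  if (any(!is.finite(d_value)) || any(d_value <= 0))
    stop("all D-values must be positive", call. = FALSE)
  if (length(unique(temperature)) < 2L)
    stop("at least two distinct temperatures are required", call. = FALSE)
  if (stats::sd(log10(d_value)) == 0)
    stop("zero slope: z-value undefined (D does not change with ",
         "temperature)", call. = FALSE)
  fit <- stats::lm(log10(d_value) ~ temperature)
  slope <- unname(stats::coef(fit)[["temperature"]])
  if (slope == 0 || !is.finite(1 / slope))
    stop("zero slope: z-value undefined (D does not change with ",
         "temperature)", call. = FALSE)
  slope_se <- unname(sqrt(diag(vcov_quiet(fit)))[["temperature"]])
  structure(
    list(z = -1 / slope, z_se = slope_se / slope^2,
         slope = slope, r2 = r_squared(fit),
         n = length(d_value),
         temperature = temperature, d_value = d_value, lm = fit),
    class = "z_value_fit")
}

#' @export
print.z_value_fit <- function(x, digits = 4, ...) {
  cat("z-value fit (log10 D vs temperature)\n")
  cat("  z = ", signif(x$z, digits), " +/- ", signif(x$z_se, digits),
      " degC   R^2 = ", signif(x$r2, digits), "\n", sep = "")
  invisible(x)
}

#' @export
coef.z_value_fit <- function(object, ...) c(z = object$z)
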