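#' Specify a thermal-degradation measurement design
#'
#' Describes the heating experiment the simulator emulates: which
#' temperatures are sampled, at which times, with how many replicate tubes,
#' and how large the multiplicative measurement noise is. The default is a
#' five-temperature (75-155 degC), five-time (0-60 min), triplicate design
#' with 3% lognormal measurement noise, the scale typical of
#' spectrophotometric assays of heat-treated plant extracts.
#'
#' @param temperatures Numeric vector of heating temperatures (degC),
#'   strictly increasing.
#' @param times Numeric vector of sampling times (min); must include 0 and
#'   be strictly increasing.
#' @param replicates Number of independent replicate tubes per
#'   (temperature, time) point.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   measurement noise (dimensionless, >= 0).
#' @return An object of class `"degradation_design"` (a validated list).
#' @seealso [simulate_degradation()]
#' @examples
#' degradation_design()
#' degradation_design(temperatures = c(80, 100), times = c(0, 10, 20),
#'                    replicates = 2, noise_cv = 0)
#' @export
degradation_design <- function(temperatures = c(75, 95, 115, 135, 155),
                               times = c(0, 15, 30, 45, 60),
                               replicates = 3,
                               noise_cv = 0.03) {
  if (length(temperatures) == 0L || anyNA(temperatures))
    stop("'temperatures' must be a non-empty numeric vector", call. = FALSE)
  if (is.unsorted(temperatures, strictly = TRUE))
    stop("'temperatures' must be strictly increasing", call. = FALSE)
  if (length(times) < 1L || anyNA(times) || any(times < 0))
    stop("'times' must be non-negative", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing", call. = FALSE)
  if (!any(times == 0))
    stop("'times' must include 0 (the untreated reference)", call. = FALSE)
  if (length(replicates) != 1L || replicates < 1 ||
      replicates != round(replicates))
    stop("'replicates' must be a positive integer", call. = FALSE)
  if (length(noise_cv) != 1L || !is.finite(noise_cv) || noise_cv < 0)
    stop("'noise_cv' must be a single non-negative number", call. = FALSE)
  structure(
    list(temperatures = as.numeric(temperatures),
         times = as.numeric(times),
         replicates = as.integer(replicates),
         noise_cv = as.numeric(noise_cv)),
    class = "degradation_design")
}

#' @export
print.degradation_design <- function(x, ...) {
  cat("Thermal degradation design\n")
  cat("  temperatures (degC):", paste(x$temperatures, collapse = ", "), "\n")
  cat("  times (min):        ", paste(x$times, collapse = ", "), "\n")
  cat("  replicates:         ", x$replicates, "\n")
  cat("  noise CV:           ", x$noise_cv, "\n")
  invisible(x)
}

#' Simulate first-order thermal degradation time-series
#'
#' Generates replicated response-versus-time measurements at each design
#' temperature from the first-order decay model `C(t) = C0 exp(-k t)`,
#' multiplied by lognormal measurement noise with median 1 and coefficient
#' of variation `design$noise_cv`. With `noise_cv = 0` the output is the
#' exact exponential. Responses are strictly positive by construction.
#'
#' @param design A [degradation_design()].
#' @param k First-order rate constants (min^-1): either a vector named by
#'   temperature (degC) covering every design temperature, or an unnamed
#'   vector of the same length as `design$temperatures`.
#' @param c0 Initial response at time 0 (arbitrary concentration units, > 0).
#' @param analyte Label recorded in the output (e.g. `"TAC"`).
#' @param seed Optional integer seed; with a seed the output is exactly
#'   reproducible and the caller's RNG state is left untouched.
#' @return A data frame in the package's tidy time-series layout with
#'   columns `analyte`, `temperature_C`, `time_min`, `replicate`,
#'   `response`.
#' @examples
#' des <- degradation_design(noise_cv = 0)
#' sim <- simulate_degradation(des, k = c(`75` = 0.0069, `95` = 0.0138,
#'   `115` = 0.0253, `135` = 0.0737, `155` = 0.1865), c0 = 1)
#' head(sim)
#' @export
simulate_degradation <- function(design, k, c0 = 1, analyte = "TAC",
                                 seed = NULL) {
  if (!inherits(design, "degradation_design"))
    design <- do.call(degradation_design, as.list(design))
  if (length(c0) != 1L || !is.finite(c0) || c0 <= 0)
    stop("'c0' must be a single positive number", call. = FALSE)
  if (anyNA(k) || any(k < 0))
    stop("rate constants 'k' must be non-negative", call. = FALSE)
  temps <- design$temperatures
  if (!is.null(names(k))) {
    want <- as.character(temps)
    miss <- setdiff(want, names(k))
    if (length(miss))
      stop("no rate constant supplied for temperature(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    k <- as.numeric(k[want])
  } else if (length(k) == length(temps)) {
    k <- as.numeric(k)
  } else {
    stop("'k' must be named by temperature or match 'temperatures' in length",
         call. = FALSE)
  }

  grid <- expand.grid(replicate = seq_len(design$replicates),
                      time_min = design$times,
                      temperature_C = temps,
                      KEEP.OUT.ATTRS = FALSE)
  mu <- c0 * exp(-k[match(grid$temperature_C, temps)] * grid$time_min)
  eps <- with_seed(seed, {
    if (design$noise_cv > 0) {
      sdlog <- sqrt(log(1 + design$noise_cv^2))  # CV on the natural scale
      stats::rlnorm(nrow(grid), meanlog = 0, sdlog = sdlog)
    } else rep(1, nrow(grid))
  })
  out <- data.frame(analyte = analyte,
                    temperature_C = grid$temperature_C,
                    time_min = grid$time_min,
                    replicate = grid$replicate,
                    response = mu * eps,
                    stringsAsFactors = FALSE)
  out[order(out$temperature_C, out$time_min, out$replicate), , drop = FALSE]
}

#' Arrhenius-consistent rate constants
#'
#' Deterministically inverts the Arrhenius model,
#' `k(T) = exp(lnA - Ea * 1000 / (R T_K))`, to produce a rate-constant set
#' whose activation energy is known exactly; used for round-trip tests of
#' the secondary-model fits.
#'
#' @param Ea Activation energy (kJ/mol).
#' @param lnA Natural log of the pre-exponential factor (ln min^-1).
#' @param temperatures Temperatures (degC).
#' @return Named numeric vector of rate constants (min^-1), names are the
#'   temperatures.
#' @examples
#' arrhenius_rates(Ea = 50, lnA = 12, temperatures = c(75, 115, 155))
#' @export
arrhenius_rates <- function(Ea, lnA, temperatures) {
  stopifnot(length(Ea) == 1L, is.finite(Ea),
            length(lnA) == 1L, is.finite(lnA))
  if (length(temperatures) == 0L)
    stop("'temperatures' must be non-empty", call. = FALSE)
  tk <- celsius_to_kelvin(temperatures)
  k <- exp(lnA - Ea * 1000 / (.R_GAS * tk))
  names(k) <- as.character(temperatures)
  k
}

#' Simulate enzyme-inhibition dose-response measurements
#'
#' Generates percent-inhibition readings from the linear-in-log model
#' `inhibition(c) = 50 + slope * (log10 c - log10 ic50)` plus additive
#' Gaussian noise on the percentage scale, clipped to \[0, 100\]. The
#' default three-concentration design (0.5, 1 and 5 ug/mL, triplicate)
#' mirrors a typical microplate inhibition assay.
#'
#' @param ic50 True half-maximal inhibitory concentration (ug/mL, > 0).
#' @param slope Percent inhibition per log10 concentration unit.
#' @param concentrations Tested extract concentrations (ug/mL, > 0).
#' @param replicates Replicate measurements per concentration.
#' @param noise_sd Standard deviation of the additive noise (percentage
#'   points).
#' @param enzyme Label recorded in the output.
#' @param seed Optional integer seed (see [simulate_degradation()]).
#' @return Data frame with columns `enzyme`, `concentration_ug_mL`,
#'   `replicate`, `inhibition_pct`.
#' @examples
#' simulate_dose_response(ic50 = 2.4, slope = 25, noise_sd = 0)
#' @export
simulate_dose_response <- function(ic50, slope,
                                   concentrations = c(0.5, 1, 5),
                                   replicates = 3,
                                   noise_sd = 3,
                                   enzyme = "enzyme",
                                   seed = NULL) {
  if (length(ic50) != 1L || !is.finite(ic50) || ic50 <= 0)
    stop("'ic50' must be a single positive concentration", call. = FALSE)
  if (any(!is.finite(concentrations)) || any(concentrations <= 0))
    stop("'concentrations' must be positive", call. = FALSE)
  if (length(noise_sd) != 1L || noise_sd < 0)
    stop("'noise_sd' must be non-negative", call. = FALSE)
  grid <- expand.grid(replicate = seq_len(replicates),
                      concentration_ug_mL = concentrations,
                      KEEP.OUT.ATTRS = FALSE)
  mu <- 50 + slope * (log10(grid$concentration_ug_mL) - log10(ic50))
  noise <- with_seed(seed, {
    if (noise_sd > 0) stats::rnorm(nrow(grid), sd = noise_sd)
    else rep(0, nrow(grid))
  })
  inh <- pmin(100, pmax(0, mu + noise))
  out <- data.frame(enzyme = enzyme,
                    concentration_ug_mL = grid$concentration_ug_mL,
                    replicate = grid$replicate,
                    inhibition_pct = inh,
                    stringsAsFactors = FALSE)
  out[order(out$concentration_ug_mL, out$replicate), , drop = FALSE]
}
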