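#' Activation enthalpy at a temperature
#'
#' `dH = Ea - R T / 1000` (kJ/mol), the transition-state enthalpy barrier
#' implied by an Arrhenius activation energy at absolute temperature `T`.
#'
#' @param Ea Activation energy (kJ/mol).
#' @param T Absolute temperature (K, > 0); vectorised.
#' @return Activation enthalpy (kJ/mol).
#' @examples
#' activation_enthalpy(50.77, 348) # ~47.88
#' @export
activation_enthalpy <- function(Ea, T) {
  if (any(!is.finite(T)) || any(T <= 0))
    stop("'T' must be positive (Kelvin)", call. = FALSE)
  Ea - .R_GAS * T / 1000
}

#' Gibbs free energy of activation
#'
#' Eyring relation `dG = R T ln(kB T / (h k_s)) / 1000` (kJ/mol) with the
#' rate constant converted to s^-1 (`k_s = k / 60`); transmission
#' coefficient 1.
#'
#' @param k First-order rate constant in min^-1 (> 0); vectorised.
#' @param T Absolute temperature (K, > 0).
#' @return Gibbs free energy of activation (kJ/mol).
#' @examples
#' gibbs_free_energy(0.0069, 348) # ~111.92
#' @export
gibbs_free_energy <- function(k, T) {
  if (any(!is.finite(k)) || any(k <= 0))
    stop("'k' must be positive", call. = FALSE)
  if (any(!is.finite(T)) || any(T <= 0))
    stop("'T' must be positive (Kelvin)", call. = FALSE)
  k_s <- k / 60
  .R_GAS * T * log(.K_BOLTZ * T / (.H_PLANCK * k_s)) / 1000
}

#' Activation entropy
#'
#' `dS = (dH - dG) * 1000 / T` in J/(mol K).
#'
#' @param dH Activation enthalpy (kJ/mol).
#' @param dG Gibbs free energy of activation (kJ/mol).
#' @param T Absolute temperature (K, > 0).
#' @return Activation entropy (J/(mol K)).
#' @examples
#' activation_entropy(47.88, 111.91, 348) # ~-184.0
#' @export
activation_entropy <- function(dH, dG, T) {
  if (any(!is.finite(T)) || any(T <= 0))
    stop("'T' must be positive (Kelvin)", call. = FALSE)
  (dH - dG) * 1000 / T
}

#' Eyring rate constant from activation parameters
#'
#' Inverts the Eyring equation:
#' `k_s = (kB T / h) exp(-(dH * 1000 - T dS) / (R T))`, returned in min^-1.
#' Used as the algebraic round-trip check of the thermodynamic chain.
#'
#' @param dH Activation enthalpy (kJ/mol).
#' @param dS Activation entropy (J/(mol K)).
#' @param T Absolute temperature (K, > 0).
#' @return Rate constant (min^-1).
#' @examples
#' eyring_rate(47.88, -184.02, 348)
#' @export
eyring_rate <- function(dH, dS, T) {
  if (any(!is.finite(T)) || any(T <= 0))
    stop("'T' must be positive (Kelvin)", call. = FALSE)
  k_s <- (.K_BOLTZ * T / .H_PLANCK) *
    exp(-(dH * 1000 - T * dS) / (.R_GAS * T))
  k_s * 60
}

#' Per-temperature activation thermodynamics table
#'
#' Combines a cross-temperature activation energy with the per-temperature
#' rate constants to give the Eyring activation parameters at each
#' temperature: enthalpy from `Ea`, Gibbs free energy from that
#' temperature's `k`, entropy from both. A single global `Ea` is applied at
#' every temperature. When rate-constant SDs are supplied, first-order
#' delta-method standard errors are attached (`dG_se = R T sd(k)/k / 1000`
#' and its propagation into `dS`); these are labelled delta-method errors,
#' not replicate SDs.
#'
#' @param arrhenius An [arrhenius_fit()], or a single numeric activation
#'   energy (kJ/mol).
#' @param fits A list of [first_order_fit()] objects, or a data frame with
#'   columns `temperature_C` and `k` (optionally `k_sd`).
#' @return A data frame of class `"thermo_table"`: one row per temperature
#'   with columns `analyte`, `temperature_C`, `T_K`, `k`, `dH`, `dG`, `dS`
#'   (and `dH_se`, `dG_se`, `dS_se` when uncertainties are available),
#'   ordered by temperature.
#' @examples
#' k <- c(0.0069, 0.0138, 0.0253, 0.0737, 0.1865)
#' tt <- thermo_table(50.77, data.frame(temperature_C = c(75, 95, 115, 135,
#'                                                        155), k = k))
#' tt
#' @export
thermo_table <- function(arrhenius, fits) {
  Ea <- if (inherits(arrhenius, "arrhenius_fit")) arrhenius$Ea
        else as.numeric(arrhenius)
  Ea_se <- if (inherits(arrhenius, "arrhenius_fit")) arrhenius$Ea_se
           else NA_real_
  if (is.data.frame(fits)) {
    tab <- fits
    if (!all(c("temperature_C", "k") %in% names(tab)))
      stop("'fits' data frame needs columns 'temperature_C' and 'k'",
           call. = FALSE)
    if (!"k_sd" %in% names(tab)) tab$k_sd <- NA_real_
    if (!"analyte" %in% names(tab)) tab$analyte <- NA_character_
  } else {
    stopifnot(is.list(fits), all(vapply(fits, inherits, logical(1),
                                        "first_order_fit")))
    tab <- data.frame(
      analyte = vapply(fits, function(f) f$analyte, character(1)),
      temperature_C = vapply(fits, function(f) f$temperature, numeric(1)),
      k = vapply(fits, function(f) f$k, numeric(1)),
      k_sd = vapply(fits, function(f) f$k_sd, numeric(1)),
      stringsAsFactors = FALSE)
  }
  if (any(!is.finite(tab$k)) || any(tab$k <= 0))
    stop("every rate constant must be positive", call. = FALSE)
  tab <- tab[order(tab$temperature_C), , drop = FALSE]
  tk <- celsius_to_kelvin(tab$temperature_C)
  dH <- activation_enthalpy(Ea, tk)
  dG <- gibbs_free_energy(tab$k, tk)
  dS <- activation_entropy(dH, dG, tk)
  out <- data.frame(analyte = tab$analyte,
                    temperature_C = tab$temperature_C,
                    T_K = tk, k = tab$k,
                    dH = dH, dG = dG, dS = dS,
                    stringsAsFactors = FALSE)
  if (any(is.finite(tab$k_sd)) || is.finite(Ea_se)) {
    dH_se <- rep(if (is.finite(Ea_se)) Ea_se else 0, nrow(out))
    dG_se <- ifelse(is.finite(tab$k_sd),
                    .R_GAS * tk * (tab$k_sd / tab$k) / 1000, 0)
    out$dH_se <- dH_se
    out$dG_se <- dG_se
    out$dS_se <- sqrt(dH_se^2 + dG_se^2) * 1000 / tk
  }
  rownames(out) <- NULL
  class(out) <- c("thermo_table", "data.frame")
  attr(out, "Ea") <- Ea
  out
}

#' @export
print.thermo_table <- function(x, digits = 5, ...) {
  cat("Activation thermodynamics (Ea = ",
      signif(attr(x, "Ea"), digits), " kJ/mol)\n", sep = "")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], signif, digits = digits)
  print(y, row.names = FALSE, ...)
  invisible(x)
}
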