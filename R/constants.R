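#' Physical constants used in the Eyring and Arrhenius calculations
#'
#' Fixed CODATA values: the molar gas constant `R` in J/(mol K), the
#' Boltzmann constant `kB` in J/K and the Planck constant `h` in J s.
#' They are deliberately not user-configurable; every published table this
#' package reproduces assumes them.
#'
#' @return A named list with elements `R`, `kB` and `h`.
#' @examples
#' physical_constants()$R
#' @export
physical_constants <- function() {
  list(R = 8.314, kB = 1.380649e-23, h = 6.62607015e-34)
}

# internal shorthands
.R_GAS <- 8.314
.K_BOLTZ <- 1.380649e-23
.H_PLANCK <- 6.62607015e-34

#' Convert Celsius to Kelvin
#'
#' @param temp_c Temperature in degrees Celsius.
#' @return Absolute temperature in Kelvin.
#' @examples
#' celsius_to_kelvin(75)
#' @export
celsius_to_kelvin <- function(temp_c) {
  stopifnot(is.numeric(temp_c))
  temp_c + 273.15
}

# R^2 of a least-squares fit without summary.lm()'s perfect-fit warning;
# clamped to [0, 1], 1 when the response is constant
r_squared <- function(fit) {
  r <- stats::residuals(fit)
  y <- stats::fitted(fit) + r
  tot <- sum((y - mean(y))^2)
  if (tot <= 0) return(1)
  max(0, min(1, 1 - sum(r^2) / tot))
}

# vcov() routes through summary.lm(), which warns on zero-residual fits;
# noiseless round trips are legitimate here, so muffle just that warning
vcov_quiet <- function(fit) {
  withCallingHandlers(stats::vcov(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

# Run an expression under a fixed RNG seed without disturbing the caller's
# RNG state. seed = NULL leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number or NULL", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
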