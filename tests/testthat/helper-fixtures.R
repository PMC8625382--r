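# shared fixtures built in code

# published per-temperature kinetics of the red onion skin extract study,
# via the packaged reference CSV
ref_tac <- function() reference_kinetics("TAC")
ref_ao <- function() reference_kinetics("antioxidant_activity")

# noiseless tidy time-series from a named rate-constant set
noiseless_series <- function(k_by_temp, times = c(0, 15, 30, 45, 60),
                             replicates = 3, c0 = 1, analyte = "TAC") {
  des <- degradation_design(
    temperatures = as.numeric(names(k_by_temp)), times = times,
    replicates = replicates, noise_cv = 0)
  simulate_degradation(des, k = k_by_temp, c0 = c0, analyte = analyte)
}

# three replicate values with exactly the requested mean and SD
exact_group <- function(m, s) c(m - s, m, m + s)

# closed-form OLS slope/intercept, independent of lm()
ols_slope <- function(x, y) sum((x - mean(x)) * (y - mean(y))) /
  sum((x - mean(x))^2)
ols_intercept <- function(x, y) mean(y) - ols_slope(x, y) * mean(x)
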