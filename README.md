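# thermokin

Thermal degradation kinetics, activation thermodynamics and
enzyme-inhibition dose-response analysis for plant bioactives.

## What it is for

Heat treatment degrades the anthocyanins and antioxidant capacity of
plant extracts (the motivating system is a red onion skin extract heated
at 75–155 °C). Food chemists summarise that degradation with a standard
chain of models, and `thermokin` implements the whole chain as classed,
testable R objects:

* **First-order kinetics per temperature** — `first_order_fit()` fits
  `C/C0 = exp(−k t)` by log-linear OLS (per replicate, mean ± SD of `k`),
  and derives the half-life `t½ = ln2/k` and decimal reduction time
  `D = ln10/k`.
* **Secondary models across temperatures** — `arrhenius_fit()` regresses
  `ln k` on `1/T` for the activation energy `Ea = −slope·R`;
  `z_value_fit()` regresses `log10 D` on temperature for the z-value
  `z = −1/slope`.
* **Eyring activation thermodynamics** — `thermo_table()` computes, per
  temperature, `ΔH‡ = Ea − RT`, `ΔG‡ = RT ln(kB·T/(h·k_s))` (with `k_s`
  in s⁻¹) and `ΔS‡ = (ΔH‡ − ΔG‡)/T`.
* **Bioassay inference** — `ic50_loglinear()` interpolates the IC50 from
  percent inhibition vs log10 concentration; `tukey_letters()` rebuilds a
  one-way ANOVA + Tukey HSD compact letter display from group
  mean/SD/n summaries.
* **Spectrophotometric helpers** — pH-differential total anthocyanins
  (`tac_ph_differential()`), standard-curve calibration and
  quantification for Folin–Ciocalteu / DPPH assays.
* **Synthetic data** — `simulate_degradation()`,
  `simulate_dose_response()` and `arrhenius_rates()` generate data with
  the statistical structure the estimators assume, so every stage is
  testable without laboratory data; `reference_kinetics()` and
  `reference_ic50()` ship published red onion skin extract parameter
  tables as reference inputs.
* **Pipeline** — `thermal_study()` runs the full kinetic chain on a tidy
  time-series; `run_thermal_analysis()` adds file I/O, CSV reports and a
  provenance log.

## Worked example

Simulate a noiseless triplicate heating experiment at the packaged
reference rate constants and run the full analysis:

```r
library(thermokin)
k_ref <- reference_kinetics("TAC")
sim <- simulate_degradation(degradation_design(noise_cv = 0),
                            k = setNames(k_ref$k_per_min, k_ref$temperature_C))
study <- thermal_study(sim)
study
#> Thermal degradation study: 1 analyte(s), 5 temperature(s)
#>
#>  analyte temperature_C      k k_sd k_se r2 t_half_min d_value_min ...
#>      TAC            75 0.0069    0    0  1    100.500      333.70
#>      TAC            95 0.0138    0    0  1     50.230      166.90
#>      TAC           115 0.0253    0    0  1     27.400       91.01
#>      TAC           135 0.0737    0    0  1      9.405       31.24
#>      TAC           155 0.1865    0    0  1      3.717       12.35
#>
#> TAC: Ea = 50.83 +/- 4.885 kJ/mol (R^2 = 0.973), z = 55.69 +/- 3.512 degC (R^2 = 0.9882)
```

The fitted rate constants equal the generating ones (noiseless round
trip); the derived columns are the familiar thermal-processing numbers —
e.g. at 155 °C the anthocyanin half-life is 3.7 min and a tenfold loss
takes 12.3 min, while at 75 °C the half-life is over 100 min. The
activation energy (~51 kJ/mol) and z-value (~56 °C) quantify how steeply
the degradation accelerates with temperature.

```r
study$thermo$TAC
#> Activation thermodynamics (Ea = 50.831 kJ/mol)
#>  analyte temperature_C    T_K      k     dH     dG      dS ...
#>      TAC            75 348.15 0.0069 47.936 111.97 -183.92
#>      TAC            95 368.15 0.0138 47.770 116.45 -186.56
#>      TAC           115 388.15 0.0253 47.604 120.99 -189.07
#>      TAC           135 408.15 0.0737 47.437 123.77 -187.02
#>      TAC           155 428.15 0.1865 47.271 126.70 -185.51
```

Positive `dH` and `dG` with negative `dS` read as an endothermic,
non-spontaneous activation step with an entropy-ordered transition
state. For the bioassay side:

```r
ref <- reference_ic50("alpha_amylase")
tukey_letters(mean = ref$ic50_ug_mL, sd = ref$sd, n = ref$n,
              labels = ref$sample)
#> One-way ANOVA from summary statistics: F = 127.4, p = 0.0003512
#>     label mean   sd n letter
#>   extract 1.02 0.30 3      a
#>  acarbose 4.49 0.44 3      b
```

The extract's IC50 against alpha-amylase is significantly lower
(letter `a`) than the acarbose control (`b`): a stronger inhibitor at
equal mass concentration.

See `vignettes/degradation-kinetics.Rmd` for the models, assumptions and
design decisions in detail.

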