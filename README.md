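# csckinetics

Kinetic modelling of tumor regression during fractionated radiotherapy,
with an explicit cancer stem-like cell (CSC) compartment.

Daily cone-beam CT (CBCT) imaging during a course of radiotherapy yields a
per-day record of gross tumor volume. `csckinetics` resolves that regression
curve into the dynamics of three cell compartments — self-renewing,
radio-resistant CSCs (`u`), non-stem tumor cells (`v`) and dead cells still
occupying imaged volume (`w`) — and estimates patient-specific
radiobiological parameters from it: the CSC proportion `p`, the probability
of symmetric (self-renewing) CSC division `δ`, the per-fraction surviving
fractions `SF_u`/`SF_v`, and the dead-cell clearance half-time `T_h`. It is
aimed at radiation-oncology modellers working with longitudinal volume
series from locally advanced lung cancer and similar settings.

## The model

Between imaging days the compartments evolve as a linear ODE system

    u̇ = δ m_u u − γ_u u
    v̇ = (1 − δ) m_u u + m_v v − (m_a + γ_v) v
    ẇ = γ_u u + (m_a + γ_v) v − γ_w w

with division rates `m_x = ln2 / T_x`, programmed-death rate
`m_a = ln2 / T_a`, clearance `γ_w = ln2 / T_h`, and radiation kill rates
`γ_u = −ln SF_u`, `γ_v = −ln SF_v` on treated days (zero otherwise; dose is
fixed at 2 Gy/fraction, so dose-response is not modelled). The system is
solved in closed form; one calendar day is one application of a 3×3
propagator (`advance_one_day()`), iterated across a weekday-fraction
treatment calendar (`standard_course()`, `simulate_course()`). A forward
Euler integrator (`euler_integrate()`) provides an independent numerical
check of the closed form and is excluded from the fitting path.

Fitting minimizes

    R = sqrt( mean_i | M_i / M_0 − G_i / G_0 | )

over the imaging days, where `M_i` are measured volumes, and
`G_i = U_i + V_i + W_i` is the modelled total (volume is assumed
proportional to total cell count). The free parameters are
`(δ, p, SF_u, T_h)`; the tumor-cell surviving fraction is tied to the
histology's population value through the mixing relation
`SF_T = p SF_u + (1 − p) SF_v`, with `SF_T = 0.90` (squamous) or `0.62`
(adenocarcinoma) at 2 Gy, and `T_u = T_v = T_a` fixed at the histology's
potential doubling time (6.2 d squamous, 7.1 d adenocarcinoma).

A companion module analyses clonogenic-style two-arm cell-count assays:
exponential growth fits, day-0 extrapolation, the surviving fraction
`SF_2 = N0_irradiated / N0_control`, and the division time `ln2 / k`.

## Worked example

Generate a synthetic squamous patient (the study's S1 fitted parameters as
ground truth, 33 weekday fractions, 3% lognormal measurement noise) and
refit it:

```r
library(csckinetics)

spec   <- synthetic_spec(patient = "S1", noise_sd = 0.03, seed = 42)
course <- generate_volumes(spec)
fit    <- fit_parameters(course, preset = "squamous")
fit
#> <rt_fit>  kinetic-model fit to 33 volume measurements
#>   preset: squamous (SF_T = 0.90), shared doubling time 6.2 d
#>   delta = 0.199  p = 0.232  SF_u = 0.958  SF_v = 0.883  T_h = 0.96 d
#>   R = 0.125   fit error % = 1.56 +/- 1.62
```

The CSC proportion is recovered well (`p` = 0.232 against a ground truth of
0.242) and the per-day fit error is below the 3% measurement noise. The
self-renewal probability `δ` is the weakly identified direction under noise
— here it drifts to its search bound — mirroring the sensitivity of the
objective to `δ` that `stability_scan(fit, "delta")` makes visible;
`autoplot(fit)` overlays the measured and modelled regression curves, and
`tidy(fit)` / `glance(fit)` return the estimates and the one-row summary.

The packaged NCI-H2170 assay analysis:

```r
assay_analysis()
#> <assay_report>
#>   count ratios (irradiated / control):
#>     day 2: 0.78
#>     day 6: 0.56
#>     day 9: 0.44
#>   day-0 extrapolates: control 1.489 M, irradiated 1.391 M
#>   SF2 = 0.93;  division time 2.41 d (57.8 h)
```

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "csck.R", package = "csckinetics")`, with subcommands
`simulate | fit | scan | compare-doubling | synth | assay | validate`.

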