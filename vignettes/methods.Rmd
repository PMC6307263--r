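---
title: "Methods: compartmental kinetics of tumor regression under fractionated radiotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartmental kinetics of tumor regression under fractionated radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csckinetics)
```

## The model and its assumptions

The imaged gross tumor volume is treated as proportional to the total
number of cells it contains, split into three compartments: cancer
stem-like cells (CSCs, `u`), which self-renew with probability `δ` per
division and are comparatively radio-resistant; non-stem tumor cells
(`v`), produced by asymmetric CSC division; and dead cells (`w`), which
still occupy imaged volume until cleared. Between observations the
compartments follow the linear system

$$
\begin{aligned}
\dot u &= \delta m_u u - \gamma_u u\\
\dot v &= (1-\delta) m_u u + m_v v - (m_a + \gamma_v) v\\
\dot w &= \gamma_u u + (m_a + \gamma_v) v - \gamma_w w
\end{aligned}
$$

with all rates per day: division rates $m_u = \ln 2/T_u$,
$m_v = \ln 2/T_v$, programmed tumor-cell death $m_a = \ln 2/T_a$,
dead-cell clearance $\gamma_w = \ln 2/T_h$, and radiation kill rates
$\gamma_u = -\ln SF_u$, $\gamma_v = -\ln SF_v$ active only on treated
days. Key assumptions:

* **Dose enters only as a per-fraction surviving fraction.** Every
  fraction is 2 Gy; there is no dose-response (linear-quadratic) model,
  no accumulation, and no re-planning.
* **A treated day is one linear system.** Division, kill and clearance
  act simultaneously over the day ($t = 1$), not as an instantaneous kill
  followed by growth. The day-$i$ state is pre-treatment of day $i$; the
  transition to day $i+1$ uses day $i$'s fraction flag.
* **Volume proportionality.** Normalizing both measured volumes and the
  modelled total $G = U + V + W$ to their first-day values removes the
  absolute scale, so states are tracked per unit initial volume with
  $U_0 = p$, $V_0 = 1 - p$, $W_0 = 0$.
* **Shared doubling time.** For fitting, $T_u = T_v = T_a$ is pinned at
  the histology's potential doubling time $T_{pot}$ (6.2 d squamous,
  7.1 d adenocarcinoma), the proliferation index that accounts for
  quiescent cells. The in-vitro division time $T_{div}$ (60 h / 22 h) and
  the clinical volume doubling time $T_{vol}$ (115.2 d / 221.6 d) are
  retained as deliberately worse alternatives for the model comparison in
  `doubling_time_comparison()`.

## The sign of the net tumor-cell rate

The closed-form solution is a sum of exponentials with rates
$A = \delta m_u - \gamma_u$ (net CSC), $C$ (net TC) and $-\gamma_w$.
Some write-ups of this solution print $C = m_v + m_a - \gamma_v$ and a
dead-cell inflow $m_v + \gamma_v$, which contradicts the ODE system above
(programmed death *drains* `v`, and the `v`-to-`w` flux is
$m_a + \gamma_v$). This package implements the ODE-consistent forms
$C = m_v - m_a - \gamma_v$ and inflow $m_a + \gamma_v$ — the choice the
Euler integrator, which knows only the differential equations, validates
directly — and exposes the other convention behind `legacy = TRUE` /
`legacy_c = TRUE`. Under the shared-doubling-time assumption
$T_a = T_v$ the two inflow forms coincide, and the untreated-day
ODE-consistent $C$ is exactly zero, so the fitted results do not hinge on
the switch.

## Numerical evaluation of the propagator

Because one day at constant treatment status is a linear map, the daily
update is a lower-triangular $3\times3$ propagator built from the
analytic solution; a course of $n$ days costs two propagators (treated /
untreated) and $n$ matrix–vector products. The exponential-difference
quotients $(e^{At}-e^{Ct})/(A-C)$ and their time-weighted relatives are
evaluated through `expm1()` and short series expansions, so the resonant
denominators $A \approx C$, $A \approx -\gamma_w$, $C \approx -\gamma_w$
never blow up; below an absolute difference of $10^{-9}$/day the exact
analytic limit ($t e^{At}$-type terms) is used. Outputs are clipped at
zero to remove negative floating-point dust; the exact solution is
non-negative.

The forward Euler integrator (default 1000 substeps/day; the
equivalence checks in the test-suite use $10^4$) integrates the ODEs
directly and serves purely as an independent oracle — by construction it
is excluded from the fitting path.

## The objective and its optimization

The fit criterion is
$R = \sqrt{\tfrac1n \sum_i |M_i/M_0 - G_i/G_0|}$ over imaging days —
the square root of the mean *absolute* deviation, which is how the
objective is defined for this model, although it is conventionally
described as least squares. A true root-mean-square variant is available
(`variant = "rms"`) but is not the default. Two observations from
implementing both:

* The published per-patient residues are numerically consistent with the
  RMS variant (for the first adenocarcinoma patient,
  $\sqrt{0.026^2 + 0.0233^2} \approx 0.035$, the tabulated value),
  not with the printed absolute-value form (which would give
  $\approx 0.16$ for the same per-day errors). The printed definition is
  nevertheless kept as the default, as the stated form of the method.
* Near a perfect fit $R$ behaves like the square root of the error, so
  "R = 0" assertions on noiseless data are made at $10^{-7}$, not
  machine epsilon.

The objective is non-smooth (absolute values under a root), so the search
is derivative-free and fully deterministic: the four free parameters
$(\delta, p, SF_u, T_h)$ are mapped to an unconstrained scale by logit
transforms of their boxes ($\delta \in [0.001, 0.2]$,
$p \in [0.001, 0.999]$, $SF_u \in [0.001, 1]$, $T_h \in [0.1, 20]$ d,
the documented scan/fit ranges), a coarse Cartesian grid of feasible
candidates (720 points) is evaluated, Nelder–Mead runs from the best 8,
and the incumbent is polished by up to 8 fresh-simplex restarts (stopping
early when an iteration improves by less than $10^{-14}$) — restarting
the simplex is what lets Nelder–Mead finish traversing the narrow curved
$\delta$–$SF_u$ valley. $SF_v$ is not a free parameter: it is implied by
the histology's population surviving fraction through
$SF_T = p\,SF_u + (1-p)\,SF_v$, and candidates whose implied $SF_v$
leaves $(0, 1]$ are rejected via a continuous penalty. No randomness
enters the fit, so results are reproducible without a seed.

One-parameter stability scans (`stability_scan()`) deliberately do *not*
re-tie $SF_v$ when scanning $p$ or $SF_u$: they are pure one-dimensional
slices of the objective, the procedure that makes identifiability
visible. On noiseless synthetic data the slices in $p$ and $SF_u$ have a
single grid minimum at the generating value; per unit parameter change
the objective rises fastest along $\delta$, which is also the direction
that drifts under measurement noise.

## The treatment calendar

Fractions are weekday-only, weekends untreated, imaging on every fraction
day; 33 fractions from a Monday span 45 calendar days, from a Friday
47 days. A treatment interruption is modelled by skipping a configurable
number of weekdays after a configurable fraction: missing 5 weekdays (one
treatment week) shifts a rigid weekday calendar by exactly 7 days. The
one-week-interruption patient analogue therefore starts on a Friday and
misses 6 consecutive weekdays (a calendar week of treatment, Monday
through the following Monday) after fraction 5, reproducing the reported
55-day course span; both the placement and the length are configurable
since neither is recorded. Public holidays are not modelled.

## The synthetic-data generator

The study's raw daily volume series were never deposited, so end-to-end
validation runs on data the forward model generates
(`synthetic_spec()`, `generate_volumes()`, `patient_like_suite()`):

* ground truth = a published per-patient parameter set (or any feasible
  one), histology-matched preset, baseline volume defaulting to that
  patient's gross tumor volume (162.5, 177.1, 115.9, 77.6, 91.8 cm³);
* one volume per imaging day,
  $M_i = V_0 \cdot (G_i/G_0) \cdot e^{\varepsilon_i}$ with
  $\varepsilon_i \sim N(0, \sigma^2)$ i.i.d. — multiplicative lognormal
  noise, chosen because volumes are positive and contouring error scales
  with size. The default $\sigma = 0.03$ represents contouring-level
  uncertainty (the 3–5% band); the lognormal mean is $e^{\sigma^2/2}$, a
  documented ~0.05% upward bias at that level. Generation is
  deterministic given the seed and restores the global RNG state.

What passing tests on such data do show: the estimation machinery
recovers the generating parameters (to near machine precision without
noise; median $p$ error well inside ±0.05 at 3% noise over 20 seeded
replicates), the analytic and numerical solvers agree, and the
qualitative identifiability findings reproduce. What they cannot show:
anything about real CBCT series — systematic contouring bias, day-to-day
observer variability, inflammation or atelectasis masquerading as tumor,
and model misspecification are all absent by construction.

## The cell-count assay

The two-arm growth assay (unirradiated control vs a single 2 Gy dose) is
analysed by fitting $N(t) = N_0 e^{kt}$ to each arm and reading the
surviving fraction off at day 0, $SF_2 = N_0^{irr}/N_0^{ctrl}$, which
frees the count ratio from repopulation. The default fit is ordinary
least squares on log counts with the seeded day-0 count included for the
control arm: with the packaged counts this reproduces the reported
extrapolates (control $N_0$ 1.489 vs 1.476 reported, rate 0.2879 vs
0.2865, division time 57.8 h vs 58.1 h), whereas nonlinear least squares
on raw counts — which the day-9 count dominates — lands visibly lower
($N_0 \approx 1.32$). Both the method and the seed-inclusion are exposed
toggles. The irradiated arm excludes the seed point by default: radiation
kills part of the seed, so the pre-irradiation count does not lie on the
irradiated growth curve. Replicate-level input is averaged per day before
fitting; only per-day means are available for the packaged assay.

## Problem sizes and runtime choices

The default test-suite and validation runs use: 33-fraction courses
(45–55 day spans); $10^4$ Euler substeps/day for solver-equivalence
checks and $10^3$ elsewhere; 100 random parameter sets for the
one-day-oracle property; 20 noisy replicates for the recovery study;
100-point grids for stability scans. These sizes keep the full suite
around a minute on a single core while leaving every check far from its
tolerance.

## Known limitations

* `δ` is weakly identified from a single regression curve with
  measurement noise; fits can pin it at a search bound while `p`, `SF_u`
  and `T_h` remain stable. The stability scans are the diagnostic.
* No uncertainty quantification beyond the scans (no bootstrap or
  profile intervals).
* No transitional progenitor compartments, quiescence, hypoxia, immune
  or microenvironment effects; no chemotherapy term even though the study
  patients received chemoradiation.
* Dose is a fixed 2 Gy/fraction surviving fraction: the model cannot
  extrapolate to other fractionation schemes without new `SF` values.
* The published per-patient estimates cannot be re-derived here because
  the underlying volume series are unavailable; they are used as
  consistency references and synthetic ground truths instead.
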