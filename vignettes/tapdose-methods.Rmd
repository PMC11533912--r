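---
title: "Methods and design of tapdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of tapdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tapdose)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the parameters that matter, what the
synthetic-data generators emulate, and the choices made where the design
was genuinely open.

## The ²¹²Pb decay chain

²¹²Pb (half-life 10.64 h in the bundled constants) beta-decays to ²¹²Bi,
which branches 64.06 % by beta decay to ²¹²Po (an alpha emitter with a
0.3 µs half-life) and 35.94 % by alpha decay to ²⁰⁸Tl (3.05 min), both
ending at stable ²⁰⁸Pb. `decay_chain()` loads a versioned plain-text
constants table (`inst/extdata/pb212_nuclide_data.csv`) with half-lives,
branching fractions and mean emission energies per decay mode, derived from
ICRP-107/NNDC-style compilations. Bundling the constants keeps every
computation reproducible without network access; a user can point
`decay_chain()` at an alternative table, and values from other
compilations may differ in the third significant figure.

`bateman_activities()` evaluates the analytic Bateman solution for the
branched chain. Two numerical choices:

* **²¹²Po is treated as decaying instantaneously with its ²¹²Bi parent**
  (any nuclide under 3.6 ms). Its activity is reported as the branching
  share of the parent's. This avoids a stiffness ratio of ~10¹¹ between
  chain members at an error far below anything measurable on the hours
  timescale.
* **Repeated decay constants** (impossible in the bundled chain, possible
  in user chains) are perturbed by one part in 10⁹ so the closed form
  stays usable.

The suite verifies the solution against an independent `deSolve` ODE
integration to better than 10⁻⁶ relative error over 0–72 h, along with
number conservation (one ²¹²Bi decay per ²¹²Pb decay; 35.94 % of them via
²⁰⁸Tl).

`chain_emission_summary()` gives mean energies per ²¹²Pb decay under the
equilibrium assumption — every daughter decays where and when its parent
does, the standard preclinical assumption for a chain whose daughters live
minutes, not hours. With the bundled constants:
E<sub>α</sub> = 7.802, E<sub>e</sub> = 0.882, E<sub>γ</sub> = 1.461 MeV per
decay.

## Biodistribution quantities

`percent_id_per_gram()` implements the counting-standard arithmetic: organ
counts and standard counts are decay-corrected to the common injection
reference, the standard is scaled by the dose fraction it represents
(default 1; diluted standards supported), and

%ID = 100 · counts<sub>corr</sub> / (standard<sub>corr</sub> / fraction),
%ID/g = %ID / organ mass.

Reported %ID/g is therefore **decay-corrected to injection time**. This
convention is deliberate and recorded here because the dosimetry layer
must re-apply physical decay when building time-activity curves. Background
subtraction happens upstream in the counter; the data model stores net
counts. Group summaries use the sample SD (n−1); single-sample cells report
`NA`.

Group comparisons (`compare_uptake_groups`) default to the two-sided
Welch unequal-variance t test, with Student's pooled test available via
`var_equal = TRUE`. Welch is the robust default when variances differ
between dose groups; the choice matters little at n = 5 per group but is
stated explicitly rather than hidden.

Radiochemical purity (`chromatogram_purity`) is the fraction of counts in
the main-peak window. When no window is supplied, a Gaussian is fitted to
the tallest peak and ±3σ used; this clips 0.27 % of a truly Gaussian peak,
so supplied windows are preferred for calibrated comparisons.

## MIRD-style dosimetry

`build_time_activity_curves()` converts decay-corrected %ID/g means back
to the fraction of injected activity physically in each organ,
A(t) = (%ID/g · m<sub>g</sub>/100) · e^(−λt). Choices:

* **t = 0 anchoring.** A point A(0) = 0 is prepended to each tissue curve
  before integration (configurable off). Nothing is known about the
  pre-first-timepoint interval; the zero anchor is bounded and
  conservative for tissues that fill from blood. The dense-sampling
  round-trip test quantifies the cost.
* **Tail model.** After the last observation the curve is extrapolated by
  **pure physical decay**: TIAC = trapezoid + A(t_last)/λ. A
  biological-plus-physical tail would be smaller; physical-only is the
  stated analysis convention and is conservative.

TIAC bounds worth knowing: the trapezoid **overestimates** any convex
decaying curve, so a sparse 4-point sampling of a pure e^(−λt) gives
16.49 h against the closed-form 1/λ = 15.29 h (for a 10.6-h half-life).
TIACs of coarsely sampled curves can therefore legitimately exceed 1/λ;
the package does not clamp them.

**Mouse-to-human projection** uses the relative-concentration method: the
organ-to-whole-body concentration ratio R(t) measured in the mouse is
assumed to hold in the human, and the human whole-body fraction curve is
taken equal to the mouse one. The mouse whole-body curve defaults to the
mass-weighted sum of measured organ curves (the generator includes a
carcass/remainder compartment so this sum is meaningful); phantoms are
plain CSV tables (25-g mouse; ICRP-89-style human male/female, female
kidneys 0.275 kg) and fully overridable. The projection preserves R(t)
exactly — the suite checks the round trip to 10⁻⁹.

**Dose coefficients.** For each organ,

coefficient = TIAC[s] · (RBE·E<sub>α</sub> + E<sub>e</sub> + φ·E<sub>γ</sub>)[J/decay] / m[kg],

reported in Gy/GBq. RBE weights the alpha component only; electrons and
photons carry weight 1; any positive RBE is accepted with 3 and 5 the
usual presets. The photon absorbed fraction φ defaults to **0**: photons
mostly escape organ-scale volumes while the alpha component dominates the
weighted sum, and this choice is validated end-to-end by the consistency
of the RBE-5/RBE-3 kidney-limited activity pair (8.29 → 13.6 GBq) computed
from the bundled emission constants. Red marrow is treated as a generic
organ with a user-supplied activity surrogate; there is no specialized
marrow model.

**Published coefficients as inputs.** The program's published organ-dose
table reports human-projected doses at reference activities, but the raw
biodistribution behind it is not public. `reference_dose_coefficients()`
therefore loads those printed values (bundled, RBE 5, female reference)
and the reproducible surface is the arithmetic on top: linear dose
scaling, `activity_limit()` (minimum over organs of limit/coefficient),
`safety_margin()` (limit/dose) and `rescale_rbe()`. One caveat: printed
doses are rounded to 3 decimals, so 5× scaling of the reference column can
differ from an independently rounded print by one unit in the last place
(1.435 vs 1.434 for the pancreas at 0.555 GBq); tests allow exactly that
propagated-rounding slack and no more.

## One-site binding

`specific_binding()` subtracts matched cold-block means per concentration;
negative specific values are retained (clipping would bias the fit) and
flagged. `fit_one_site()` fits B(c) = Bmax·c/(Kd+c) by Levenberg–Marquardt
least squares with Bmax₀ = max observed binding, Kd₀ = concentration
nearest half-maximum, positivity bounds, and up to 20 jittered restarts on
failure. Standard errors come from the Jacobian-based covariance;
`confint()` gives Wald intervals on n−2 degrees of freedom. Nonspecific
binding is modeled as *measured*, not fitted; radioligand depletion is
ignored (incubation volumes unknown at the assay design). The fit is
invariant to count rescaling (Kd unchanged, Bmax scales), verified in the
suite, and simulation at the assay design (8 concentrations 0.5–64 nM,
triplicates, 5 % CV) shows mean Kd recovery within 2 % and ~95 % Wald
coverage.

## Survival and welfare endpoints

`km_curve()` wraps the product-limit estimator (the `survival` package)
and applies these conventions: events before censorings at tied times; the
**median is the earliest time with S(t) ≤ 0.5** and is undefined if the
curve never reaches 0.5; `survival_at()` evaluates the right-continuous
step function. An enumeration oracle confirms equality with the empirical
survival fraction on all no-censoring cohorts up to n = 8. No
between-group test is run by default; `survival::survdiff` is available to
users who want a log-rank comparison.

Termination criteria (`evaluate_termination`): tumor volume ≥ 1000 mm³
(volume = length × width × height), weight loss > 15 % from initial weight
on two consecutive measurements, ≥ 20 % loss from initial weight, or an
externally recorded welfare code. Thresholds are parameters with those
defaults.

## What the generators emulate — and what they do not

The generators exist so that every pipeline stage has statistically
realistic, fully known inputs.

* `gen_biodist()`: 5 animals per timepoint at 1/4/24 h (defaults), organ
  kinetics as bi-exponential biological retention times physical decay,
  lognormal count noise (CV 10 %), dose conservation through a
  carcass/remainder compartment. Calibration targets are the study's
  summary kinetics: tumor plateau ≈ 5 %ID/g from 1 h through 24 h,
  pancreas > 30 %ID/g at 1 h with fast washout, predominantly renal
  clearance. Receptor self-blocking scales blocked-organ uptake by
  1/(1 + m/K_block); K_block = 560 ng is the closed-form solution of a
  30 % pancreas reduction from 28 → 280 ng. This is a calibration, not a
  mechanistic occupancy model.
* `gen_tumor_size_cohort()`: volumes 150/300/600/900 mm³ (n = 5/6/4/3)
  where necrosis mildly reduces whole-tumor %ID but %ID/g falls steeply
  through the mass denominator — the signature that uptake-vs-size
  correlations are visible per gram but not per tumor.
* `gen_binding_plate()`: one-site specific signal plus a linear
  nonspecific component (5 % of Bmax at the top concentration); cold-block
  wells carry only the nonspecific part.
* `gen_survival()`: Weibull event times per group (shape 2.5, a
  realistically steep xenograft failure curve), medians set to the study's
  reported group medians (9.4/10.5/18.9/16/14.7 wk), administrative
  censoring at 22 wk, group sizes 10–15. The published per-timepoint
  survival percentages are not calibration targets — they are mutually
  inconsistent with the printed medians, and medians win.
* `gen_chromatogram()`: Gaussian main peak (360 s, σ 15 s) and an
  earlier-eluting oxidation satellite (180 s, σ 10 s) on a 6-s fraction
  grid with Poisson noise; the emitted window separates the peaks so a
  noiseless 96 %-area trace reads exactly 96 % pure.

Not emulated: inter-animal kinetic hierarchies, physiologically based PK,
receptor internalization kinetics, daughter redistribution after decay,
plate-edge effects, and detector dead time. Passing tests on synthetic
data therefore demonstrate the *analysis* is correct under the stated
noise model, not that real data will satisfy the model.

## Problem sizes and numerical checks in the suite

The test suite fixes all seeds. Sampling designs used by the TIAC
round-trip checks are the package's own: dense = every 0.1 h over 0–72 h
(recovery of every organ's analytic integral to < 0.5 %), study-like =
five timepoints {1, 4, 8, 16, 24} h, log-spaced over about two half-lives
as a dosimetry study of a 10.6-h emitter would choose (recovery within
10 %; the blood compartment, with a 30-min fast phase, is the worst case
at ~9.7 %). Monte Carlo sizes: 500 replicates for Kd bias, 200 for CI
coverage, 300 cohorts for the survival-median calibration check.

## Known limitations

* Absolute dose coefficients cannot be derived from public data; only the
  scaling/limit/margin identities on the published table are reproducible.
* φ = 0 is an assumption validated solely through the RBE-pair consistency
  check; organ-specific photon absorbed fractions would change sub-percent
  to few-percent details.
* The t = 0 zero anchor underestimates the first-interval integral for
  fast-filling organs exactly as quantified above; users with an early
  timepoint should include it rather than rely on the anchor.
* The Bateman solver targets linear chains with branching (trees); it is
  not a general burnup code.
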