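---
title: "A four-compartment model of liver regeneration after partial hepatectomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A four-compartment model of liver regeneration after partial hepatectomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liverregen)
```

## The model

After a 70% partial hepatectomy (PHx) the remaining mouse liver lobes
regrow to restore the organ's mass within about three weeks. The
regrowth is not a single-cell-type process: hepatocytes proliferate,
monocyte-derived macrophages are recruited from the circulation,
angiogenic activity of the endothelium rises early and decays, while
the tissue-resident Kupffer cell population stays essentially
constant. `liverregen` implements a deliberately simple dynamical
description of this interplay: four well-mixed cell compartments —
hepatocytes $H$, Kupffer cells $K$, recruited macrophages $M$, and
endothelial cells $E$ — expressed as dimensionless fractions of the
healthy liver, whose healthy proportions are fixed at

$$ (H_0, K_0, M_0, E_0) = (0.8,\; 0.06,\; 0.06,\; 0.08). $$

Each compartment's growth rate is a weighted sum of relaxation toward
homeostasis and linear responses to the lack or excess of other
compartments:

$$
\begin{aligned}
dH/dt &= k_{\mathrm{homeostasis}}\,(1 - H/0.8) + k_{EH}\,(0.8/0.08 - H/E)\\
dK/dt &= k_{\mathrm{homeostasis}}\,(1 - K/0.06) + k_{HK}\,(0.8 - H)\\
dM/dt &= k_{\mathrm{homeostasis}}\,(1 - M/0.06) + k_{HM}\,(0.8 - H)\\
dE/dt &= k_{\mathrm{homeostasis}}\,(1 - E/0.08) + k_{HE}\,(0.8 - H)
        + k_{ME}\,\bigl(M/(H{+}K{+}M{+}E) - 0.06\bigr)
\end{aligned}
$$

The six coefficients (units day⁻¹) are stimulation strengths:
$k_{EH}$ ties hepatocyte growth to endothelial supply (nutrition and
structural alignment), $k_{HK}$ and $k_{HM}$ let a hepatocyte deficit
stimulate Kupffer-cell growth and macrophage recruitment, $k_{HE}$ and
$k_{ME}$ drive vessel growth by hepatocyte lack and macrophage excess,
and $k_{\mathrm{homeostasis}}$ lumps everything the explicit couplings
leave out, pulling all compartments slowly back to their healthy
proportions. All six are constrained nonnegative: the direction of each
effect lives in the printed lack/excess expressions, and a negative
"strength" would silently change the biology. The homeostatic state is
a fixed point of the dynamics for *every* admissible coefficient set —
the package tests assert this to $10^{-15}$.

Two readings of the equations deserve a note, since they are design
decisions of this package:

* The hepatocyte equation's coupling coefficient is $k_{EH}$
  (endothelium limiting hepatocytes), distinct from $k_{HE}$ in the
  endothelial equation. Only this reading yields six distinct
  coefficients matching the six described effects.
* The coupling term is grouped as $k_{EH}(0.8/0.08 - H/E)$, i.e., the
  deviation of the hepatocyte-to-endothelium ratio from its healthy
  value 10. This is the only grouping under which homeostasis is a
  fixed point.

Surgery is modeled by the operator
`apply_partial_hepatectomy(state, remnant_fraction)`: every
compartment is multiplied by the remnant fraction (default 0.3 for a
70% resection), leaving compartment ratios untouched. A useful
consequence: immediately after surgery both ratio-based coupling terms
vanish exactly, so the very first dynamics are driven purely by
relaxation and absolute hepatocyte lack.

## Integration

Simulations use classical fixed-step fourth-order Runge–Kutta with a
60-minute step ($\Delta t = 1/24$ day) over 100 days — 2,400 steps,
all stored. The integrator is deliberately minimal: no adaptivity, no
interpolation, bit-for-bit deterministic. The step-halving order test
in the suite confirms the expected $O(\Delta t^4)$ convergence (error
ratios within [12, 20] per halving), and a cross-check against
`deSolve`'s fixed-step RK4 agrees to $10^{-10}$. States with a
non-positive compartment are refused rather than clamped — a
parameterization that drives the system out of the biological region
surfaces as an error with the failing time attached, not as a silently
altered trajectory.

Internal time is in days throughout; days 4/8/14/21 and the 100-day
horizon are all integer multiples of the step, so measurement-day
lookup on the default grid is exact (nearest-sample lookup, ties
toward the earlier sample, matters only on non-default grids).

## Observables and measurement scales

Four simulated measurement curves are derived from a trajectory:
volume ($H+K+M+E$), total macrophages ($M+K$), Kupffer cells ($K$),
and angiogenesis, defined as the endothelial growth rate $dE/dt$. The
angiogenesis curve is evaluated analytically from the rate equations
at each stored state instead of finite-differencing $E(t)$; both agree
to $O(\Delta t^4)$ but the analytic form has no grid artifacts.

The experiments the model mirrors report volume as % of control,
macrophage densities as % of nucleated cells, and angiogenic activity
as a VEGFR2⁺/CD31⁺ area ratio. The model-to-measurement conversion is
affine per observable (`observable_mapping()`): volume is frozen at
scale 100 (model volume 1 ↔ 100% of control), while the other three
scales/offsets are estimated during calibration, because no unit
conversion between compartment fractions and stain percentages is
available — those curves are compared by shape. During fitting the
affine mappings are not searched but *profiled out*: for fixed
coefficients the optimal scale and offset are a weighted linear
regression of cell means on model values, in closed form. Profiled
scales are kept positive and clamped to a broad plausibility box
(scale ≤ 2000, |offset| ≤ 100); without the clamp, a degenerate
parameterization with a nearly flat macrophage curve can fake a good
fit by stretching that flat curve with a scale of several thousand.

## Calibration

The measured facts the calibrated model must reproduce are encoded
twice, deliberately:

* as *target means* (`default_calibration_targets()`) entering a
  weighted least-squares objective — the sum over (observable, day)
  cells of squared residuals standardized by the cell SD (falling back
  to the observable's pooled SD, then to 1);
* as a *constraint set* (`default_constraints()`): volume ≥ 70% at
  day 4 and ≥ 80% at day 8, a transient overshoot above 100% at day 14
  with normalization to within 10% by day 21, total macrophages
  peaking at day 8 and renormalized by day 21, Kupffer cells within
  10% of homeostatic at every measurement day, and angiogenic activity
  maximal at day 4 and strictly decreasing thereafter.

The published record gives summary facts, not per-animal values, so
the target means are this package's own plausible encodings of those
facts (e.g. volume 75/88/105/100% at days 4/8/14/21). They are
declared as such everywhere; nothing shipped here is a published
coefficient estimate. The Kupffer constancy tolerance of 10% and the
day-21 normalization band of ±10% are likewise this package's
quantitative encodings of "not significantly altered" and
"comparable to control".

Minimization is a deterministic Nelder–Mead simplex over the six
coefficients with box bounds (default [0, 2] day⁻¹) enforced by
reflecting proposals back into the box. The search is multi-start:
starts are drawn from the bounds by a seeded generator, alternating
uniform and log-uniform draws, because the interesting dynamics live
across orders of magnitude in the coefficients and uniform draws alone
essentially never land in the slow-relaxation regime. Each converged
simplex is restarted from its optimum (default twice) — the standard
remedy for premature simplex collapse. A `constraint_weight` adds
hinge penalties for violated constraints to the objective; the default
calibration uses it so the fit cannot trade the day-14 overshoot away
against a slightly better least-squares score. For parameter-recovery
fits the coefficients are optimized on the log scale, which fixes the
scaling problem outright when all true coefficients are positive.
Convergence uses a relative objective-spread tolerance of $10^{-10}$
with a 5,000-evaluation budget per start.

The shipped coefficient set,

```{r}
calibrated_parameters()
```

satisfies all ten constraints:

```{r}
check_constraints(calibrated_parameters())[, c("description", "value", "pass")]
```

With these coefficients the simulated liver reaches 70.7% of control
volume at day 4 and 92.6% at day 8, overshoots to 103.3% at day 14,
and relaxes back toward 100%; the macrophage curve peaks at day 8
(model value 0.157 against a homeostatic 0.12) while the dense
angiogenesis maximum lies near day 1, well before the macrophage
peak. A single joint model is fitted across all observables; fitting
separate parameter sets per observable was considered and rejected —
the point of the model is that one interaction structure explains all
four curves.

## The synthetic cohort generator

No per-animal measurements are deposited for this study, so the
package generates them. `study_design()` reproduces the study's
structure: a pool of 10 untreated control mice (labeled day 0), PHx
groups of 5/4/4/4 mice at days 4/8/14/21, and sham groups of 3/3/3/6.
PHx animals receive the mapped model curve at their day; sham and
untreated animals receive mapped homeostatic values, following the
finding that sham surgery leaves the measured quantities unchanged (a
sham-specific perturbation hook is deliberately not implemented).
Per-animal noise is additive Gaussian on the measurement scale with
SD = CV × true mean, independent across animals and truncated at zero;
the default CV of 0.15 is this package's choice of a realistic
between-animal spread for imaging and immunohistochemistry readouts —
the study shows error bars but publishes no per-animal variance. The
published record also contains slightly different group sizes for
some immunohistochemistry endpoints; the macrophage-density sizes were
adopted as the single default design.

What the generator emulates — group sizes, measurement days, scale
conversions, mean-proportional noise — is enough to test calibration
and parameter recovery end to end. What it does not emulate: imaging
physics (probe pharmacokinetics, fluorescence reconstruction error,
blood-pool background), inter-animal kinetic heterogeneity (every
synthetic animal shares one true curve), non-Gaussian outliers, and
any real sham-surgery response. Passing recovery tests therefore shows
the estimation machinery is sound, not that real data of this design
would identify the coefficients equally well.

## Parameter recovery

`recover_parameters()` closes the loop: generate a cohort from known
coefficients, refit from a deliberately wrong start (2× the truth),
and report per-coefficient relative errors. Noise-free and densely
sampled (days 2–21), all six coefficients return to within 5% — in the
shipped configuration, within 1%. Under the study's actual design and
noise, the median error rises from about 8% at CV 0.05 to about 18% at
CV 0.15, and the suite asserts this monotone degradation. The mapping
is held fixed at the generating one during recovery: the experiment
validates coefficient estimation, not joint identifiability of mapping
and dynamics (which the four-day design cannot support).

## Problem sizes and numerical choices

The defaults used throughout the tests and reports: 100-day
simulations at a 60-minute step (2,401 stored samples) for headline
curves, 21-day simulations inside objective evaluations (504 steps,
under a millisecond via the compiled RK4 core), 1,000 seeded draws for
the global-minimum spot check, and 20 replicates per noise level for
recovery summaries. Integer seeds control every random element (start
draws, cohort noise); identical seeds give byte-identical fits and
datasets, and the generator restores the caller's RNG state.

## Known limitations

The model is a caricature by design: no stellate cells, bile duct
cells or lymphocytes, no hepatocyte activation states, no spatial
structure, blood flow, or portal pressure, and linear couplings
throughout. The calibration targets are reconstructions of published
summary statements, so the shipped coefficients inherit their
coarseness; with four measurement days the data cannot pin down six
coefficients and six mapping parameters jointly, which is why the
constraint set, not the least-squares score alone, defines an
acceptable calibration. Uncertainty quantification (bootstrap,
profile likelihood) is out of scope, matching the absence of any
published coefficient uncertainties.
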