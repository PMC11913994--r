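---
title: "Design-of-experiments optimization of ESI and collision-cell parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design-of-experiments optimization of ESI and collision-cell parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionopt)
```

## The problem

Triple-quadrupole LC--MS/MS quantification of oxylipins (prostaglandins,
lipoxins, leukotrienes, HETEs, HODEs) is limited by how efficiently each
analyte is ionized in the electrospray source and fragmented in the
collision cell.  The adjustable instrument parameters -- interface voltage
(IntV, kV), interface temperature (IntT, °C), heating and drying gas flows
(HG, DG, L/min), heating block (HB, °C), desolvation line (DL, °C) and CID
gas pressure (kPa) -- interact, and one-factor-at-a-time (OFAT) tuning both
wastes runs and can miss joint optima.  `ionopt` implements the
design-of-experiments alternative as a reusable pipeline:

1. **Screening** — a resolution-IV fractional factorial over seven factors
   separates main effects from two-factor interactions at 19 runs.
2. **Optimization** — a central composite design (CCD) over the surviving
   factors supports a full quadratic response-surface model per analyte.
3. **Design space** — Monte-Carlo simulation maps the factor region where
   the probability of any analyte missing its target response stays below a
   risk threshold, and a weighted optimum is selected inside it.
4. **Collision-energy check** — a multilevel D-optimal design over CE and
   CID validates that the collision energy needs no re-optimization after
   the CID change, cross-checked against an OFAT CE scan.
5. **Sensitivity evaluation** — 1/x-weighted calibration with S/N- and
   accuracy-based limits of quantification compares the optimized method
   with the baseline settings.

Because no raw instrument data are deposited anywhere, every stage is
exercised against a seeded synthetic instrument whose ground-truth surfaces
encode the effect structure reported for this chemistry (see below).  That
makes the whole pipeline testable end to end, and makes clear what passing
tests mean: they validate the *statistical machinery and its calibration to
the reported effect sizes*, not any new measurement.

## Designs and coded units

All models are fitted in coded units: factor `f` with nominal range
`[low, high]` maps to $x = (f - \mathrm{mid})/\mathrm{halfrange}$, so the
design centre is the origin.  Natural settings are decoded with clipping to
*hard* instrument bounds followed by rounding to the settable step
(round-half-to-even), e.g. a CID star point at coded $-1.35$ decodes to
$195 - 1.35\cdot 55 = 120.75 \to 120$ kPa with the 5 kPa step.

The screening design is the regular $2^{7-3}_{IV}$ fraction with the
standard minimum-aberration generators $E = ABC$, $F = BCD$, $G = ACD$,
plus three centre points (19 runs, duplicate injections).  The defining
relation (7 words, shortest length 4) gives the alias structure exposed by
`alias_structure()`; every two-factor interaction is confounded with two
others, which the modelling layer reports by name when a user requests an
inestimable term pair.

The CCD uses $\alpha = 1.35$ star points and three centres: $8 + 6 + 3 =
17$ runs.  The IntT $+\alpha$ point (417.5 °C) exceeds the 400 °C hardware
ceiling; the run is kept, clipped to 400 °C, re-coded at its achieved
level and annotated `clipped`.  Keeping the run preserves the 17-run
design; models are always fitted at achieved, not nominal, levels.

The CE×CID stage uses an exact D-optimal design (14 runs) selected from
the CE 12–28 eV × CID 190–250 kPa candidate grid by Fedorov coordinate
exchange with 20 seeded restarts.  Rows are distinct candidates; the
objective $\log\det(X^TX)$ is non-decreasing within every exchange pass,
and on grids small enough to enumerate the result equals the exhaustive
optimum (tested).

## Response-surface models and diagnostics

`rsm_fit()` fits ordinary least squares on the coded model matrix to
*replicate-level* data.  Fitting replicates (not their means) keeps pure
error estimable; run means would make the lack-of-fit test impossible.
Reported diagnostics:

* $R^2 = 1 - SS_{res}/SS_{tot}$ (corrected);
* $Q^2 = 1 - PRESS/SS_{tot}$ with $PRESS = \sum_i (e_i/(1-h_{ii}))^2$ —
  exact leave-one-out, always $\le R^2$;
* reproducibility $= 1 - MS_{pure\,error}/MS_{total}$ (mean-square
  convention, both corrected);
* lack of fit: $SS_{res}$ split into pure error (within-run replicate
  scatter) and lack of fit, $F = (SS_{lof}/df_{lof})/(SS_{pe}/df_{pe})$.

Significance of a term is judged by its 95 % confidence interval excluding
zero — the coefficient-plot reading — and `refine_rsm()` removes the least
significant removable term (largest p) one at a time, refitting after each
removal, until all unprotected terms are significant.  Weak heredity
protects a main effect while any retained quadratic or interaction term
contains it; refinement is idempotent.  With α = 0.05 each truly inactive
term survives with roughly the test size, so refinement of pure noise
yields the intercept-only model in most but not all seeds — the tests
assert that distributional behaviour rather than a per-seed certainty.

In the screening stage, per-factor quadratics are inestimable from
two-level points plus centres; the model instead carries a single lumped
`curvature` contrast (centre-point indicator).  This matters numerically:
the true surfaces are curved, and without the contrast the centre offset
inflates the residual variance enough to mask real factor effects.

**Factor selection.** `screen_factors()` carries a factor forward when its
main effect is significant for at least 3 of the 5 panel analytes.  A
majority vote across analytes is used instead of "significant for any
analyte" because, with four inert factors and a 5 % per-term test size, an
any-analyte rule would drag a spurious factor into the optimization stage
in a fifth to a third of experiments; the cross-analyte rule reduces that
to well under 5 % while the genuinely active factors (IntT, CID, IntV) are
significant for essentially all analytes.

The default response transform in the pipeline is the natural logarithm of
peak height: instrument gains compound multiplicatively and replicate
noise is close to a constant CV, so the log scale makes both additive.
`rsm_fit()` also supports the identity scale.

## Monte-Carlo design space

For grid setpoints $x$, `design_space_map()` estimates
$p_{fail}(x) = P(\exists a: \hat{H}_a(x + \delta)\,e^{\varepsilon_a} <
m_a)$ where $\delta$ is setpoint jitter (SD = 2 % of each factor's range,
in natural units), $\varepsilon_a$ a residual draw at the model's residual
SD, and $m_a$ the analyte's minimum acceptable response.  Defaults: $m_a$
is 70 % of the analyte's own predicted maximum over the grid, and weights
prioritize the low-abundance prostaglandins and lipoxins (PGE2-d4 = LXA4-d5
= 2, LTB4-d4 = 1.5, HODE/HETE = 1).  The optimum maximizes the weighted
log-margin $\sum_a w_a \log(\hat H_a/m_a)$ over grid points with
$p_{fail} \le 1\,\%$; ties break toward the gentler source settings (lowest
IntV, then lowest IntT).  The optimum is invariant to rescaling all
weights.

Implementation note: jitter and residual draws are *common random numbers*
shared across grid points (each point's estimate stays unbiased).  Because
the surfaces are quadratic, $\eta(x+\delta) = \eta(x) + \nabla\eta(x)^T
\delta + \delta^T B \delta$, so the grid × samples evaluation is a single
matrix product per analyte; a 27 000-point map at 2 000 draws takes
seconds.  The default map (CID 120–270 × IntT 282–400, step 2, six IntV
slices, 2 000 draws per point) is the problem size used throughout the
tests and the acceptance script; single-setpoint checks (`pfail_at`) use
20 000+ draws.

## Calibration and LOQ

Calibration lines are 1/x-weighted least squares over ten 2-fold dilution
levels (31.25 pg down to 0.061 pg on column, duplicate injections).
Back-calculated accuracy at each level is computed from the mean response
via the global fit (a single fit for the whole series — no refitting after
candidate-LOQ exclusion).  S/N is peak height over the baseline noise SD;
vendor peak-to-peak conventions differ by a constant factor exposed as a
multiplier.  The LOQ is the lowest level whose S/N ≥ 5 (boundary passes)
*and* whose accuracy, together with all higher levels, stays within
80–120 % — requiring the higher levels too keeps the quantifiable range
contiguous.  The LOQ is monotone: degrading noise or narrowing the
accuracy window can only raise it.

## The synthetic instrument

Ground truth for the five-analyte optimization panel is a log-quadratic
surface per analyte, $H(x) = H_0 e^{f(x)}$, with multiplicative lognormal
replicate noise at 4 % CV and duplicate injections — the committed
coefficients live in `inst/extdata/ground_truth_surfaces.csv` and were
solved (once, by constrained least squares) to satisfy simultaneously: a
51 % analyte-average gain for CID 140→250 kPa at IntT 400 °C; a 32 %
average gain for IntT 300→400 °C at CID 250 kPa; a weighted joint optimum
at exactly (222 kPa, 380 °C, 2 kV); analyte-specific marginal optima
(PGE2-d4 near 230 kPa/377 °C, 5-HETE-d8 near 200 kPa with a temperature
plateau above 390 °C); positive IntT×CID interactions only for LTB4-d4 and
9-HODE-d4, a positive IntT×IntV term only for LXA4-d5, and negative IntV
effects throughout, strongest for the polar analytes.  The voltage optimum
sits at the lower feasibility bound (2 kV), so the design-space search is
exercised on a boundary optimum.  The four inert factors carry
coefficients far below the noise floor.  Anchors are verified by direct
evaluation of the committed table in the test suite.

The CE×CID truth gives each analyte an interior CE optimum on the even-eV
grid (16–24 eV) with curvature placing a 2 eV miss at a 7–15 % height
loss; only LXA4-d5 and 5-HETE-d8 carry small CID terms, so refinement
should prune CID elsewhere — which is exactly what the fitted models do.

The calibration generator is anchored to the printed 14-analyte LOQ/S-N
comparison: per-analyte response factors are scaled so the pre-optimization
S/N at the printed LOQ level matches the printed S/N; post-optimization
series apply height gains of 1.66–2.15 and the correspondingly reduced
baseline noise.  Trace-level behaviour is modelled as a cooperative
adsorptive loss $s(L) = L^2/(L^2+K^2)$ with per-analyte $K$ chosen so the
accuracy gate fails exactly where the printed LOQ says it must; replicate
heights carry 2 % proportional noise plus an absolute component of 0.2×
the baseline noise SD.  What this generator does *not* emulate: real
chromatographic peak shapes and integration, matrix effects, drift,
carry-over, inter-day variance.  Passing tests therefore demonstrate that
the analysis pipeline recovers what was put in at realistic noise — not
that the instrument settings are transferable to another laboratory.

## Numerical choices and edge cases

* Rounding of natural levels is round-half-to-even at the factor's step
  (CID 5 kPa, IntT 1 °C, IntV 0.1 kV); optima are reported at 1 kPa /
  1 °C / 0.1 kV grid resolution.
* Rank-deficient model requests raise a typed error naming the confounded
  term groups from the design's alias structure.
* `q2_press()` refuses saturated fits ($h_{ii}=1$); lack of fit and
  reproducibility refuse series without replicate degrees of freedom.
* Predictions outside a coded ±1.5 box warn (extrapolation) but do not
  fail.
* All generators and Monte-Carlo routines take explicit integer seeds,
  restore the caller's RNG state, and are bit-reproducible; the pipeline
  derives per-stage seeds from one root seed.

## Known limitations

* The disturbance model (2 % range jitter, residual resampling) is a
  package default, not a published value; design-space probabilities are
  only as good as that model.
* Reproducibility uses the mean-square convention; software using a
  sum-of-squares variant will report slightly different values.
* The weighted-optimum fraction (70 % of per-analyte maximum) and the
  95 %-of-maximum definition of the "optimal CE region" are package
  conventions, configurable but not externally anchored.
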