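---
title: "Models and methods behind toxiquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind toxiquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxiquant)
```

toxiquant implements the quantification–validation–kinetics chain of a
targeted MRM LC–MS/MS assay for six anticoagulant rodenticides in blood and
faeces. This vignette records the models, the tunable parameters and the
design choices made where the design was genuinely open. It states no
empirical result that the package's tests and acceptance script do not
themselves compute.

## The panel and units

Each analyte carries two MRM transitions (one quantifier, one qualifier),
a calibration range stated both in mass units and in µM, and an average
molecular weight from its molecular formula. Unit conversion uses the
identity 1 µM × 1 g/mol = 1 ng/mL. Blood (ng/mL) and lyophilized-faeces
(ng/g dry matter) concentrations share one numeric scale tagged by matrix:
calibrators in both matrices are prepared against the same analyte masses,
so no density correction is applied or wanted.

Printed range endpoints follow a half-up rounding convention: integers at
or above 100, one decimal below 10. With the bundled molar masses, the µM
and mass endpoints of every analyte agree exactly after rounding; the
loader enforces agreement within 1% so third-party panel files cannot
smuggle in inconsistent units.

## Calibration

The response ratio $y = H_\text{analyte}/H_\text{IS}$ is modelled as
$y = ax^2 + bx + c$ over a range spanning nearly three decades; the
quadratic term absorbs mild detector saturation at the top of the range.
The fit minimises $\sum_i w_i (y_i - \hat y_i)^2$ with $w_i = 1/x_i$ and
the origin excluded. Constant-CV (multiplicative) noise is the regime in
which $1/x$ weighting is the right variance model, and it is exactly the
noise the synthetic generator produces.

Two deliberate reporting choices:

* **R² is computed on the weighted scale** ($1 - SSE_w/SST_w$ with the
  weighted mean in $SST_w$), because that is the scale on which the fit is
  optimal; the unweighted value is reported alongside, since assay
  software differs and the source convention is not stated.
* **Monotonicity is verified, not assumed.** The derivative $2ax + b$ is
  linear, so positivity at the range endpoints is necessary and
  sufficient. A non-monotone fit is flagged with a warning and
  quantification remains defined on the monotone branch.

**Back-calculation** solves the quadratic for $x$ with this root policy:
the real root inside $[0, 1.2 \cdot x_\text{top}]$; when both roots
qualify, the one on the monotone branch containing the calibration range.
The 20% head-room above the top calibrator is a package convention: beyond
it a sample signals *above range* rather than extrapolating a saturating
curve. Responses below the attainable minimum signal *below range* and are
treated downstream as detected-below-LOQ.

**LOQ policy.** The LOQ sits at the lowest calibrator, accepted when
signal-to-noise ≥ 10, with S/N defined as peak height over the standard
deviation of a peak-free baseline segment (the acceptance criterion is
stated in the source method; the S/N denominator definition is ours).

## Censoring and aggregation

Four censoring states are first-class: `quantified` (≥ LOQ),
`below_loq_detected` (signal present, back-calculated value below LOQ —
"trace amounts"; the value is retained for inspection but never treated as
quantified), `not_detected` (zero quantifier height) and `above_range`.
A concentration equal to the LOQ up to 1e-9 relative counts as quantified,
so the lowest calibrator cannot censor itself on floating-point round-off.

Ion-ratio identity QC compares the qualifier/quantifier ratio with the
batch expectation (mean over calibrators) at a ±30% relative tolerance —
a conventional confirmation tolerance, configurable, since the source
method states no acceptance rule.

Faecal specimens measured as parallel aliquots aggregate as the arithmetic
mean of the quantified aliquots, with the $n-1$ RSD; censored aliquots are
counted and excluded, not substituted (LOQ/2 substitution exists behind an
off-by-default flag). An all-censored specimen inherits the most
informative state in the order above.

## Validation battery

* Within-day precision: $100 \cdot s/\bar x$ over same-day replicates.
* Between-day precision: one-way ANOVA intermediate precision,
  $s^2_\text{tot} = MS_w + \max(0, (MS_b - MS_w)/n_0)$, RSD against the
  grand mean. With one replicate per day this degenerates gracefully to
  the RSD of the daily values; the naive all-observations RSD is attached
  as an attribute for comparison. Both replicated-day and
  one-replicate-per-day designs are supported because the source design is
  ambiguous.
* Bias: $100(\bar x - x_\text{nom})/x_\text{nom}$ (negative =
  under-recovery).
* Matrix effect and extraction recovery follow the post-extraction spike
  design from set means per level — $ME\% = 100\,\bar B/\bar A$,
  $RE\% = 100\,\bar C/\bar B$ — not per-lot ratios averaged (that is the
  original formulation; process efficiency $ME \cdot RE/100$ is also
  reported).
* Acceptance: $|bias| \le 20$ and both precisions $\le 20$ at every level
  including the LOQ (the blanket rule; no LOQ-specific relaxation).
  ME/RE are reported, not gated.

QC levels default to 3×LOQ, the geometric mid-range and 80% of the top
calibrator; the geometric mid is chosen because the range is sampled
geometrically.

## Elimination kinetics

Phase windows are **user-supplied**, mirroring how phases are chosen by
inspection in sparse case data; automatic breakpoint detection is a
non-goal. Within a window, quantified points enter an OLS fit of
$\ln C$ on day; $\lambda = -\text{slope}$, $t_{1/2} = \ln 2/\lambda$.
Faecal observations are the per-day aggregate means, unweighted (1/RSD²
weighting exists as an option).

The **lower-bound flag** encodes when the estimate should be read as
"at least": (i) any point in or after the window is censored below the
LOQ, or (ii) the gap before the last in-window point exceeds twice the
median in-window spacing, so the tail hangs on a single remote
observation. On the bundled case schedule, the terminal window (64, 422)
triggers rule (ii) through the 204→422 gap — which is precisely why a
terminal half-life from such data is a floor, not a point estimate.
"Trailing" is read as *after the window start*: any later sub-LOQ point
leaves open the possibility of a slower tail, so the flag is deliberately
conservative. Censored points never enter fits and are never substituted.

Non-decaying windows return a flagged result with no half-life rather than
a negative one; the two-point estimator refuses non-decaying pairs for the
same reason.

## The synthetic world

The generator emulates, under explicit seeds and with no global RNG state:

* **Instrument response**: mean response $s(a_2x^2 + a_1x + a_0)$ with set scale
  $s$ = 1 (neat), $m$ (post-spike), $mr$ (pre-spike/routine), and
  multiplicative lognormal noise with stated CV (mean preserved). Lot
  effects in the matrix experiment are drawn once per lot and shared
  between the post- and pre-spike sets so the ME/RE estimators see
  realistic pairing.
* **Calibration/QC series**: 7 geometric levels endpoint-inclusive;
  QC replicates with an optional shared per-day factor giving a true
  between-day variance component.
* **The case**: a two-compartment disposition curve
  $C(t) = A_\alpha 2^{-t/t_{1/2,\alpha}} + A_\beta 2^{-t/t_{1/2,\beta}}$
  sampled on the fixed 16-day schedule (day 6–513), faeces
  $= \text{scale} \cdot C(t)(1 + \text{bump}(t))$ with a Gaussian bump
  (centre day 32, width 6 d, height 0.8) standing in for
  enterohepatic-recirculation second peaks. The bump is generative only:
  estimators exclude it via phase windows, they never model it.

Default parameter choices, made once and documented here:

| parameter | default | why |
|---|---|---|
| $t_{1/2,\alpha}$, $t_{1/2,\beta}$ | 1.8 d, 81 d | the case's reported phases |
| LOQ | 1.5 ng/mL·ng/g | lowest calibrator (coumatetralyl) |
| aliquot RSD | 0.25 | centre of the reported 4–41% band |
| $A_\alpha, A_\beta$ | 121, 0.05 ng/mL | true blood ≈12 ng/mL at day 6 and 1.8 at day 11, so the observed 9.8→1.5 pair is a plausible noisy draw and blood falls below LOQ just after day 11 |
| faeces_scale | 2500 | not identifiable from any paired data; chosen so the faecal series stays quantifiable through day 470 with day 513 at the LOQ boundary |
| parallels per day | drawn from 3–6 | the stated faecal protocol |

For the half-life *recovery* Monte-Carlos (tests and acceptance script)
the design fixes **six parallels per day** — the count used in the source
protocol when a sample was re-checked — because a design-time error
analysis shows the α window (three sampling days, five-day span) sits
exactly at the 90%-of-seeds boundary under random 3–6 parallels, i.e. the
criterion would then test the luck of the draw rather than the estimator.

What a green test does **not** establish: real faeces are inhomogeneous in
ways lognormal aliquot noise does not capture (plant material, aliquot
composition); real calibration residuals are not exactly constant-CV;
real matrix effects vary by lot in structured ways; blood LOQ-hovering
("varies around and below the LOQ for months") is reproduced only
qualitatively. The generator validates estimator correctness and pipeline
plumbing, not instrument physics.

## Numerical choices

* Weighted fits via `stats::lm`; tests cross-check every fit path against
  an independent normal-equations oracle to 1e-6 and the unweighted path
  against standard polynomial regression.
* Back-calculation uses the closed-form quadratic root, checked against a
  bisection oracle; round-trip identity holds to 1e-9 across 1000 random
  curves.
* Degenerate flat calibrations fit as $a = b = 0$ with a monotonicity
  warning; quantification against such a curve fails loudly.
* Boundary ties: LOQ equality counts as quantified (1e-9 relative slack);
  an ion ratio exactly on the ±30% edge passes.
* Endpoint rounding is half-up (`floor(x·10^d + 0.5)`), not banker's
  rounding — required to reproduce printed endpoints like 1318.5 → 1319.

## Known limitations

* No peak integration, chromatogram simulation or vendor-format reading:
  peak heights are the inputs.
* No carryover correction or within-batch re-calibration.
* No compartmental ODE fitting, absorption modelling or AUC/clearance
  suite; kinetics is deliberately noncompartmental and window-based.
* The faeces/blood scale of the synthetic case is a stated convention;
  conclusions that depend on absolute faecal levels should not be drawn
  from the generator.
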