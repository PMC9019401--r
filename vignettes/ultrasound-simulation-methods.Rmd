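---
title: "Methods: gradient-driven B-mode simulation and the evaluation toolbox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gradient-driven B-mode simulation and the evaluation toolbox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonosim)
```

## The acoustic model

B-mode ultrasound brightness arises from partial reflection of the beam
wherever acoustic impedance Q = ρV changes. sonosim works on a volumetric
surrogate: a per-voxel attenuation value δ(x) whose spatial gradient takes
the role of the impedance jump. Three kernels share one normalizer, the
global maximum max δ of the volume:

* reflection toward the probe,
  R = max(0, d·∇δ/‖∇δ‖) · (‖∇δ‖ / 2 max δ)ⁿ;
* interface transmittance, t = 1 − (‖∇δ‖ / 2 max δ)²;
* cumulative depth attenuation,
  I(X)/I₀ = exp(−∫ (‖∇δ‖ / 2 max δ)² dλ) along the ray.

The classical impedance forms (Q = ρV, the squared mismatch ratio
K = ((Q₂−Q₁)/(Q₂+Q₁))², and the diffuse variant cosⁿθ·K) are exposed as
standalone functions; the volumetric kernels are what the renderer uses.

Assumptions worth stating plainly:

* **Straight rays.** No refraction, no multiple scattering, no speckle
  interference; the simulator models echo amplitude, not RF signals.
* **Intensity bookkeeping only.** The echo at sample *k* composites the
  attenuation integral with the transmittance of every interface already
  crossed, Iₖ = (I/I₀)(λk)·Π_{j<k} tⱼ, echoₖ = IₖRₖ. The three factors
  each follow the model above; the compositing rule itself is this
  package's design choice, following standard ray-cast ultrasound
  practice — the factors are defined pointwise, and turning them into a
  pixel requires exactly such a rule.
* **Global normalizer.** "max δ" is read as the global volume maximum,
  computed once and cached. A per-neighbourhood maximum would be an
  alternative reading; global was chosen for determinism and O(1) cost,
  and because it makes the three kernels exactly consistent
  ((‖∇δ‖/2 max δ)² = 1 − t at every point, a tested invariant).
* **Transmittance exponent.** t uses the squared term of the model's
  n = 1 case. Whether it should generalize to another exponent for
  n ≠ 1 is left open; the squared form is the shipped behaviour for
  every n, and only the reflection kernel carries n.
* **Back-facing interfaces.** The model as stated does not fix a sign
  convention for d·∇δ; sonosim clamps negative cosines to zero so interfaces
  facing away from the probe reflect nothing toward it. Without the
  clamp, reflection coefficients would go negative, which has no physical
  reading in an intensity model.

## The gray mapping and the shadow rule

Echoes are log-compressed: gray = clamp(round(scale·log(1 + gain·echo)),
0, 255). The only pinned rendering constant is the acoustic-shadow rule:
wherever the accumulated intensity ratio falls below **0.92**, the pixel
is overwritten with gray **50**. The rule is applied after the log
mapping, as a floor, and the boolean shadow mask is returned with the
image — the gray value 50 can also arise from the log map itself, so the
mask is what makes the rule testable.

`gain = 100` and `scale = 40` are display defaults chosen once so that a
mid-strength reflector (echo ≈ 0.3) lands in the mid-gray range and echo
0 maps to black; they shape contrast only and carry no model content.

## Numerical choices

* **Gradients**: central differences in the grid interior, one-sided on
  boundary faces (zero-padding would fabricate an interface at the volume
  edge). Central differences are exact for linear fields, which the tests
  exploit.
* **Off-grid sampling**: trilinear interpolation of the precomputed
  per-voxel gradient field; the field is memoized per volume.
* **Attenuation integral**: midpoint rule at the ray's marching step λ
  (default 0.3 mm, half the finest default voxel pitch). Tests check a
  closed form on constant-gradient phantoms and 1% agreement between λ
  and λ/10 on smooth phantoms.
* **Degenerate gradients**: ‖∇δ‖ below 1e-12 returns reflection 0,
  avoiding 0/0 in the cosine factor.
* **Clamps**: reflection to [0, 1] and transmittance to [0, 1] — a very
  sharp interface relative to max δ can push ‖∇δ‖ beyond 2 max δ, and the
  clamp keeps the intensity interpretation.
* **Unit directions**: enforced to 1e-9; marching steps must be positive.
* **Exact plateau recursion**: the PCR model computes (1+E)^n by repeated
  multiplication rather than `pow`, so the per-cycle recursion
  Yₙ = Yₙ₋₁(1+E) holds bit-exactly below the plateau — a tested contract,
  not an optimization.

## The phantom generator

`phantom_spec()`/`make_phantom()` build the synthetic volumes every
acoustic test runs on: constant background, axis-aligned layers applied
in order, spherical/ellipsoidal inclusions, then optional additive
Gaussian texture noise clipped at zero (δ is non-negative by contract).
Noise is seeded and the seed is part of the spec, so phantoms are
bitwise reproducible; generation saves and restores the caller's RNG
state.

Defaults mirror the clinical volumes this generator stands in for: grid
521 × 512 × 344 voxels with 0.6 mm slice spacing and 0.59 mm in-plane
pitch. Two oddities of that convention are deliberately preserved rather
than corrected: 521 is plausibly a transcription artifact of 512 but is
kept, and the 0.59 in-plane pitch is conventionally quoted unitless —
mm is assumed to match the slice spacing. Tests and examples use small
grids (up to 64³); the vignette-scale problem sizes keep the whole suite
in seconds on one CPU while still spanning multi-interface geometry.

What the phantoms emulate: piecewise-constant tissue compartments, sharp
interfaces, texture-scale heterogeneity. What they do not: anatomical
shapes, frequency-dependent attenuation, speckle statistics of real
ultrasound. Passing tests therefore establish the internal consistency
of the acoustic model and renderer, not fidelity to clinical images.

## Quantitation layer

The PCR model Yₙ = X(1+E)^min(n, n_plateau) constrains E to [0, 1] and
caps amplification with a hard plateau. Real reactions stay exponential
for a limited run — generally 20 to 30 cycles — before plateauing; 30 is
the default cap (the upper end, configurable) and no smooth logistic
roll-off is attempted, since the modelled feature is simply that
amplification stops.

Relative quantification uses the standard 2^−ΔΔCt rule with its implicit
perfect-doubling assumption — the field-standard choice where no
alternative is specified.

ELISA standard series are two-fold geometric dilutions ending in a blank;
plates with irregular series (e.g. 5000, 2500, 1000, …) use the explicit
constructor. Calibration interpolates log-concentration against
log-signal between bracketing standards — a signal at the geometric mean
of two standards' responses maps to the geometric mean of their
concentrations. Responses below the blank floor at 0 (`below_blank`);
the blank-to-lowest-standard segment interpolates linearly because
log(0) is undefined (`below_curve`); responses above the top standard
are flagged out of range rather than extrapolated. Four-parameter
logistic fitting is deliberately omitted: the interpolation contract is
exact at the nodes, which is what the tests and fixtures need, and no
dose–response shape is specified for these assays.

## Evaluation statistics

`roc_analysis()` computes the AUC as the Mann–Whitney probability
(pair counting with ties ½, implemented via midranks; the test suite
re-derives it with an exhaustive pair loop and a trapezoid integration
of the empirical ROC). The standard error is Hanley–McNeil; the 95% CI
is auc ± 1.96·SE truncated to [0, 1] — the normal approximation, chosen
for transparency and stated rather than hidden.
Cut-off candidates are midpoints between adjacent distinct pooled values
plus ±∞ sentinels; the Youden index is maximized, ties broken toward
higher specificity and then toward the higher threshold, making the
result deterministic. Sensitivity is defined on the cases, and the
caller must state the marker's direction (`"lower"` for markers
depressed in cases, such as longitudinal strain).

`welch_test()` is the unequal-variance t statistic with
Welch–Satterthwaite degrees of freedom, coded from the formulas;
`stats::t.test` serves as an independent oracle in the tests, never as
the implementation. Two equal constant groups return t = 0, p = 1.

The bundled per-subject surfactant-protein table (50 COPD, 50 control
subjects for SP-A and SP-D) ships as plain CSV and is checksum-verified
on load. It is the package's worked fixture: no reference AUC accompanies
it, so its ROC and Welch results are validated by oracle equivalence —
exhaustive pair counting, trapezoid integration, a from-scratch
evaluation of the Welch formulas, and `pROC`/`stats::t.test` as
library-grade cross-checks.

## Known limitations

* Linear-array geometry only; no sector scan conversion.
* No speckle, no RF simulation, no time-gain compensation beyond the
  gray map, no registration to CT.
* The attenuation integral's accuracy degrades for marching steps larger
  than the voxel pitch; the default keeps λ at half the finest pitch.
* Statistical results are only as trustworthy as their oracles: every
  test value asserted in the suite is either computed by an independent
  in-test implementation or verified analytically; no external summary
  statistic is taken on faith.
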