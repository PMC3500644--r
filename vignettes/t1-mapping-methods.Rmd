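---
title: "Models and methods behind cmrt1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cmrt1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmrt1)
```

# Scope

cmrt1 implements the quantitative chain of a contrast-enhanced CMR T1
study: saturation-recovery and Look-Locker (MOLLI) T1 estimation, contrast
relaxivity from dilution series, myocardial partition coefficient and ECV,
and two-exam reproducibility statistics, together with a synthetic-data
generator that reproduces the statistical structure these analyses assume.
This vignette records the models, the defaults and why they were chosen,
the numerical decisions, and what the synthetic validation does and does
not establish.

# Signal models

**Saturation recovery (in vitro).** Multi-TR spin-echo signal is modelled
as $S(\mathrm{TR}) = S_0\,(1 - e^{-\mathrm{TR}/T_1})$. Echo-time decay is
deliberately omitted: TE is constant across the TR series, so the factor
$e^{-\mathrm{TE}/T_2}$ is absorbed into $S_0$ and does not bias $T_1$.

**Inversion recovery (in vivo).** MOLLI series are fitted with the
canonical three-parameter model $S(\mathrm{TI}) = A - B\,e^{-\mathrm{TI}/T_1^*}$
followed by the Look-Locker correction $T_1 = T_1^* (B/A - 1)$. Fits with
$A \le 0$ or $B/A \le 1$ have no physical inversion-recovery
interpretation and are flagged as not converged; at the map level such
pixels are excluded from ROI statistics rather than raising errors.

**Magnitude polarity.** Reconstructed magnitude data lose the sign of the
early, inverted samples. `fit_molli()` restores it by refitting with the
first $k$ samples negated for every $k \in \{0, \dots, n\}$ and keeping
the lowest residual; ties (to a relative tolerance of $10^{-12}$) are
broken toward fewer flipped points, and physically valid fits always beat
invalid ones. The exhaustive search matters: near the zero crossing, and
for tissues whose crossing lies beyond the last TI, neighbouring flip
candidates can fit deceptively well.

# Fitting engine

Both models are linear in their amplitude parameters once the time
constant is fixed, so the package fits them by variable projection: the
profiled residual sum of squares is evaluated on a 120-point log-spaced
grid of time constants between 1 ms and 10 s, and the bracketed minimum is
refined by Brent's method (`optimize`, tolerance $10^{-7}$ of the local
grid value). This is an exact separable nonlinear least-squares solution;
by construction its residual can never exceed that of a dense grid search
over the same bounds, a property the test suite asserts against an
independent brute-force oracle and against `minpack.lm::nlsLM`.
Convergence is reported honestly per pixel: estimates on a search bound or
with non-physical amplitudes are flagged, not silently dropped. For
saturation-recovery maps the grid stage is vectorised across all pixels of
the mask (one matrix product), which keeps 50-vial pixelwise fits below a
second.

# In-vitro model and defaults

Vial ground truth follows
$1/T_1 = 1/T_{1,\mathrm{solvent}} + r_1(\mathrm{albumin}, \mathrm{ibu}) \cdot [\mathrm{Gd}]$
with $r_1 = r_{1,\mathrm{arm}} + \beta_\mathrm{ibu} [\mathrm{ibu}]$. Defaults:

| parameter | default | unit | rationale |
|---|---|---|---|
| `r1_albumin` | 9.24 | mmol⁻¹ s⁻¹ l | literature relaxivity of gadobenate dimeglumine at 1.5 T with physiological albumin |
| `r1_no_albumin` | 7.22 | mmol⁻¹ s⁻¹ l | same, protein-free saline |
| `t1_solvent` | 3000 | ms | long-T1 aqueous solvent at 1.5 T |
| `noise_sd` | 0.01 | fraction of $S_0$ | typical SNR of a phantom spin-echo acquisition |
| `ibuprofen_effect_slope` | 0 | mmol⁻¹ s⁻¹ l per mmol/l | the null hypothesis; set negative to simulate competitive displacement |

The relaxivity regression is ordinary (unweighted) least squares of
$1/T_1$ (s⁻¹) on concentration with a free intercept per dilution series —
nothing in the design forces a common intercept, so none is imposed.
Pearson p-values use the exact $t$ transform on $n-2$ degrees of freedom
and are two-sided; with $n = 5$ ibuprofen levels per arm they are
approximate and reported as such, never dichotomised by the package.

The degenerate paired t-test (zero variance of differences with nonzero
mean, as happens on noise-free simulations) reports $p = 0$ with a warning
flag instead of raising, so batch pipelines complete; exactly identical
arms give $t = 0$, $p = 1$.

# In-vivo model and defaults

Per subject, blood relaxation follows
$1/T_{1,\mathrm{blood}}(t) = 1/T_{1,\mathrm{blood,pre}} + r_{1,\mathrm{blood}} C(t)$
and the myocardium follows
$\Delta R_{1,\mathrm{myo}}(t) = \lambda(t)\, \Delta R_{1,\mathrm{blood}}(t)$ with a
linear drift $\lambda(t) = \lambda_0 + \dot\lambda t$. The drift is linear
because the empirical observation being emulated is a monotone increase,
not a specific functional form. Defaults $\lambda_0 = 0.3755$,
$\dot\lambda = 0.0013091\,\mathrm{min}^{-1}$ place $\lambda$ at 0.382 at
5 min and 0.454 at 60 min, the package's reference operating point
(`reference_exam_summary()`).

The washout curve $C(t) = 1.307\,e^{-t/3.935} + 0.640\,e^{-t/86.75}$
mmol/l (minutes) was calibrated once, with $r_{1,\mathrm{blood}} = 6.3$
mmol⁻¹ s⁻¹ l, so that simulated blood T1 rises from ≈148 ms at 5 min to
≈373 ms at 60 min after a 0.15 mmol/kg bolus — the reference exam-1 blood
column. The 15-minute entry of that reference table (255 ms) is not
monotone with its neighbours and is inconsistent with its own printed
λ; the calibration smooths through it and the tests skip that row when
comparing recomputed against printed λ.

`between_subject_sd` (default 32 ms) is the SD of subject pre-contrast
myocardial T1; blood T1 is scattered proportionally to its larger mean
(≈48 ms), approximating the typical spread of both tissues with a single
knob. Exam 2 is generated from *identical* truth with independent noise —
the null hypothesis of no between-exam effect — so any rejection by the
reproducibility statistics on default simulations is a false positive.

MOLLI series are generated with $B = 2A$ (ideal inversion), under which
$T_1^* = T_1$; imperfect inversion efficiency can be simulated via the
`b_over_a` pathway of the signal model but is not the default, since the
readout-driven reduction of apparent $T_1^*$ is scanner-specific. The
generator samples the ideal recovery curve at the 11 nominal TIs; it does
not model heart-rate-dependent TI jitter, readout perturbation of the
recovery, motion, or coil bias fields. Geometry is deliberately minimal:
circular vials on a grid, an annular myocardium with circular endo/epi
contours, and a concentric blood ROI eroded 3.8 px inward from the
endocardium (blood area ≈3.5 cm², papillary-avoidance by construction).
Consequently, passing tests validate the *estimation chain* — fitting,
segmentation bookkeeping, λ arithmetic, statistical calibration — not
robustness to realistic cardiac image structure.

Noise is Gaussian on the signed signal by default, with a Rician option
(magnitude of a complex Gaussian) for magnitude-reconstruction realism;
Gaussian is the default because it keeps analytic expectations exact in
tests. Magnitude output (`magnitude = TRUE`) exercises polarity
restoration; signed output is available for large simulation studies where
the 12-candidate flip search would dominate runtime.

# Segmentation and extraction

The six mid-cavity AHA segments (7–12) are equal 60° wedges anticlockwise
from the reference angle (default 90°, the anterior direction in the
package's pixel convention); the convention is explicit because wedge
numbering differs between vendors. Segment exclusion for "severely
impaired image quality" is operationalised as a pixel-fit failure fraction
above 30% within the segment, plus any a-priori exclusions; the slice mean
is the unweighted mean of included segment means. Heart-rate correction is
not applied anywhere.

Exam-level λ can be formed as the ratio of subject-mean ΔR1 values
(default) or the mean of per-subject ratios; both are computed because
published tables rarely state which was used, and on group-mean input the
two coincide. The difference on the reference table is ≤0.002.

# Reproducibility statistics

- **ICC:** fixed to ICC(2,1) — two-way random effects, absolute agreement,
  single measures — computed from the ANOVA decomposition and verified
  against an independent `aov`-based oracle. "Two-way random" alone
  underdetermines the estimator; this choice is the conventional one for
  test–retest agreement of a measurement method.
- **Bland-Altman:** bias ± 1.96·SD of differences, with the per-pair
  (mean, difference) data returned for plotting.
- **Mixed model:** `log(response) ~ exam * factor(time) + (1|subject) +
  (1|subject:time)`, Satterthwaite tests via lmerTest. The natural log is
  used; the exam test is invariant to the base and to rescaling of the
  response. The subject-by-time random interaction is a deliberate
  modelling choice: with two exams measuring the same subject at the same
  nominal time, subject-specific washout curves generate subject×time
  variance that a pure random-intercept model dumps into the residual,
  making the exam test severely conservative. With the interaction term
  the exam contrast
  is evaluated within subject×time cells and the test suite verifies its
  type-I error is consistent with the nominal 5% over 200 null
  replicates.

# Problem sizes used in validation

The test suite and acceptance script choose simulation sizes as follows:
relaxivity recovery uses the full default phantom (vial radius 3 px, ≈29
pixels per vial) over 10 seeds; the p-value-uniformity study uses 200
phantoms with 2-px vials (the per-vial pixel count affects only estimator
variance, not the null distribution being tested); the mixed-model
calibration uses 200 two-exam studies of 10 subjects at all 13 time
points, generated at ROI resolution with signed signals. Image-resolution
tests run 48×48 slices with one to two subjects and a reduced time grid,
which is sufficient to verify the pixelwise chain against ground truth to
0.1–0.5%.

# Known limitations

- Contours are inputs; there is no automatic segmentation of the blood
  pool or myocardium from images.
- No T2*, magnetisation-transfer, inversion-efficiency or heart-rate
  corrections; no scheme-specific MOLLI conditioning (e.g. 5(3)3
  grouping).
- The Pearson p-values at five points per arm, and the ICC at ten
  subjects, carry the usual small-sample caveats; the package reports
  them without gating decisions on them.
- The synthetic heart is geometric; conclusions about motion, partial
  volume, or off-resonance behaviour cannot be drawn from these
  simulations.
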