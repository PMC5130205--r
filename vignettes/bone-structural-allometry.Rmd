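---
title: "Cross-sectional bone geometry and comparative allometry with bonexs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-sectional bone geometry and comparative allometry with bonexs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bonexs)
```

## What the package models

Long-bone diaphyses remodel in response to mechanical loading, so the
distribution of cortical bone in a cross section records how a limb was
used during life. Two kinds of quantity carry that signal:

* **cross-sectional geometric properties** — areas, second moments of
  area (SMA) and section moduli of a segmented section image; and
* **comparative allometric position** — where an individual falls
  relative to a reference sample's scaling relationship between two
  such properties (e.g. femoral vs humeral strength), expressed in
  standard-error units and against a prediction band.

`bonexs` implements both, plus the supporting machinery: femoral-neck
cortical thickness ratios, bilateral asymmetry, and conversions between
properties or section locations used to harmonize older comparative
datasets.

## Section geometry

A `section_mask` is a binary raster (nonzero = cortical bone) with a
physical pixel size in mm. The default anatomical convention maps image
columns to mediolateral (M-L) and rows to anteroposterior (A-P),
anterior up; left-side sections are mirrored into right-side
orientation before computation so the medial direction is consistent.

**Pixel model.** Each cortical pixel contributes an area element
`p²` concentrated at its center, plus a self-moment `p⁴/12` to each
planar SMA (the exact second moment of a square about its own center).
Without the self-moment term the planar SMAs are biased low by exactly
the summed self-moments, which dominates the discretization error at
coarse resolutions; with it, the raster error is governed by boundary
effects that vanish as the pixel shrinks. Whether legacy section-macro
implementations included this term is not documented; the convergence
suite (raster vs closed-form, error strictly decreasing as the pixel
halves) is the check that our choice behaves correctly.

**TA and CA.** Total subperiosteal area is the area of the periosteal
envelope: the cortical region plus every enclosed cavity (medullary
canal, intracortical voids), obtained by hole-filling the cortical
component (`fill_periosteal()`, built on EBImage). Cortical area counts
cortical pixels only. A disconnected cortex raises an error; an *open*
periosteal contour is topologically indistinguishable from a solid
section at this stage, so contour closure is a precondition on the
segmentation, which — like endosteal boundary identification — is the
caller's responsibility.

**True section moduli.** `Zx = Ix / max|y|`, `Zy = Iy / max|x|`,
`Zp = J / rmax`, with maximum distances measured from the cortical-area
centroid to the periosteal contour (evaluated over the filled region,
whose maxima lie on the boundary). These are *true* moduli, as opposed
to power-law surrogates (`J^0.75`, `SMA^0.73`) provided separately by
`power_convert()` for comparative datasets lacking contour distances.

**Principal axes.** `theta` is the angle (degrees, in (−90, 90],
counterclockwise from the M-L axis) of the axis maximizing the SMA,
from the eigen-structure of the planar moment tensor; rotationally
symmetric sections report 0 by a tie-break toward zero.

**Numerical behavior.** On rasterized hollow-ellipse ground truth (10
shapes including eccentric canals and rotated sections) all eleven
scalar properties agree with closed forms to better than 1% at 0.05 mm
pixels and 0.2% at 0.02 mm pixels; these two pixel sizes are the grid
the automated suites use. The binding term at fine pixels is the
half-pixel quantization of the maximum contour distances in the moduli.

## Femoral-neck cortices

`measure_neck_cortices()` measures superior and inferior cortical
thickness along a vertical (superoinferior) line, by default through
the cortical-area centroid (`axis_x` shifts it), as the summed
contiguous cortical intercepts on each side, with boundaries resolved
at pixel edges. The superior/inferior ratio is the comparative
quantity: low ratios (thin superior cortex) characterize modern human
femoral necks. The exact anatomical placement of the measurement plane
is defined only graphically in the comparative literature, so the plane
is a caller-visible parameter rather than something inferred from the
image; mid-neck vs neck-base is metadata only.

## RMA allometry

`rma(y ~ x, data)` fits a reduced major axis on log10 scale (raw
positive inputs are transformed; `log10 = FALSE` accepts pre-logged
data). The fit object carries slope, intercept, `r`, SEE, %SEE =
`(10^SEE − 1)·100`, n, x̄ and Σ(x − x̄)², with the usual methods
(`print`, `summary`, `coef`, `predict`, `residuals`, `plot`,
`simulate`).

**SEE convention.** SEE is the standard deviation of *vertical*
(y-direction) residuals about the RMA line with n − 2 df. Orthogonal
residuals would be an alternative; vertical residuals are conventional
in the comparative literature this package serves and are dimensionally
consistent with scoring fossils in "SEE units" on the y variable, so
they are used throughout.

**Prediction interval.** The band halfwidth at xᵢ is

\[ t_{\alpha(2),\,n-2} \cdot \sqrt{2\,\mathrm{SEE}^2\left[1 +
\tfrac1n + \tfrac{(x_i-\bar x)^2}{\Sigma(x-\bar x)^2}\right]} \cdot |b| . \]

Published renderings of this formula often collapse the radical's scope
typographically. We place the bracket inside the radical (so the
halfwidth scales with SEE, not SEE²), read "Σx²" as the *corrected* sum
of squares (so the band widens away from x̄ rather than depending on
the absolute location of the data), and take |b| so the band has
positive width for negative allometries. The band is symmetric about
x̄, narrowest there, and tends to `t·√2·SEE·|b|` as n → ∞ — all
property-tested.

**Known bias.** The RMA slope estimate inflates as
`sqrt(1 + σ²/var(x))` under residual noise σ; with σ = 0.05 log10 units
this is +1.5% over a 1-log-unit x-range and +0.7% over 1.5 log units.
Parameter-recovery tests use the wider range so the tolerance reflects
Monte-Carlo error rather than this structural bias.

## Group comparison tests

**Quick Test** (elevation): a pooled RMA line is fitted to both
samples, each point is classified above/below it, and the 2×2
group-by-side table goes to Fisher's exact test, two-sided. The source
describing the original test is not fully prescriptive; this
operationalization matches its standard description. Points exactly on
the pooled line (a zero-measure event with continuous data) are
excluded and tallied. Because Fisher's exact test is conservative, the
realized null size sits slightly below nominal; the calibration suite
uses 200 specimens per group — comparable to the mid-sized comparative
samples the test is applied to — where the discreteness effect is
small, and checks the rejection rate over 1000 seeded null replicates
against a ±2 SD Monte-Carlo band around α = 0.05.

**Slope equality**: a seeded permutation test on `|b₁ − b₂|` under
group-label shuffling (default 999 permutations; the calibration suite
uses 95 per group, matching the smaller comparative samples, with 199
permutations). Permutation is assumption-light and exactly reproducible
under a seed, which we prefer to the likelihood machinery of dedicated
SMA packages; rejection at `p ≤ α` with `(n_perm + 1)·α` integral makes
the test exact under exchangeability.

Fossil individuals are scored against *each* reference group's fit
separately (`see_units()`), with an inside/outside flag for the 95%
prediction band; `run_comparative_analysis()` orchestrates this over
any set of variable pairs and groups, pairwise-complete per fossil
because comparative fossil tables are sparse.

## Derived indices and conversions

* `bilateral_asymmetry()` — `((R − L)/((R + L)/2))·100`, positive =
  right-dominant; `asymmetry_sensitivity()` enumerates asymmetry over
  all pairings of section offsets (e.g. ±1–3 mm) when right/left
  section concordance is uncertain, summarizing min/median/max.
* `power_convert()` — `J^0.75` (polar) and `SMA^0.73` (planar)
  surrogate moduli. In proximal-femur shape analyses the planar
  conversion is applied to *every* specimen, including those with true
  moduli available, so that all groups share one convention
  (`al288_record()` follows this).
* `fit_conversion()` / `apply_conversion()` — power-law (log10,
  through-origin), log-linear (OLS) and mean-ratio transfer models,
  reporting r and %SEE; the mean-ratio kind is the mechanism behind
  published location transfers such as a 35%/40% section ratio of
  0.975.

## Synthetic data: what it emulates and what it does not

`ellipse_section_spec()` + `render_section()` +
`closed_form_properties()` generate rasterized hollow-ellipse sections
with exact analytic ground truth (composite areas and parallel-axis
terms for eccentric canals, tensor rotation for oblique sections,
contour distances from a dense parameterization of the exact outer
boundary). `simulate_group()` draws comparative samples from a
log10-linear allometry with chosen slope, intercept, residual SD and
x-range; `simulate_fossil_at_deviation()` plants a point exactly k
residual SDs off the generating line.

`default_synthetic_groups()` ships a "human" group (n = 1000, slope 1,
intercept 0.45, σ = 0.06, log10 x in [2.4, 3.4]) and a "chimpanzee"
group (n = 95, slope 1, intercept 0.05, σ = 0.06, x in [2.6, 3.4]).
The sample sizes mirror the published comparative samples (hundreds to
~1800 humans, ~95 chimpanzees); slope 1 reflects the near-isometry of
log-log comparisons between same-dimension variables and keeps the
prediction band's slope multiplier benign; σ = 0.06 log10 units (≈ 15%
SEE) is typical of diaphyseal strength scatter; and the 0.40 elevation
gap separates the groups' 95% bands as the published femoral/humeral
comparisons do.

What the generator does **not** emulate: real endosteal/periosteal
contour irregularity beyond optional radial jitter, trabecular
structure, taphonomic damage, CT greyscale physics, and — most
importantly — the actual published human and chimpanzee samples, whose
raw data are not deposited. Passing tests therefore demonstrate that
the machinery is correct on data of realistic size and structure, not
that it reproduces the published fits; the packaged fossil tables are
the only verbatim published numbers.

## Degenerate inputs and tie-breaks

Empty masks, disconnected cortices, missing pixel sizes, nonpositive
measurements, zero-variance samples, n < 3, SEE = 0 (for SEE-unit
scoring), and measurement lines that miss the section or cross the
cortex in an uninterpretable pattern all raise immediate, specific
errors. Principal-axis ties break toward θ = 0. Fossils missing a
variable for a comparison are skipped with a warning and logged, not
errored, because sparse fossil tables are the norm.

## Problem sizes in the automated suites

The test and acceptance suites run at desk scale chosen to exercise
each claim meaningfully: geometry grids of 10 shapes at 0.05 and
0.02 mm pixels, reference-sample fits at n = 1000, deviation recovery
against n = 1000 fits, and 1000-replicate null calibrations of both
group tests. The full suite completes in well under a minute per
component on a single CPU.

## Limitations

* Segmentation is out of scope: the package consumes masks, and the
  quality of endosteal boundaries is the caller's problem, as it is in
  practice.
* The Quick Test inherits Fisher-exact conservatism; its realized size
  is slightly below nominal at small n.
* RMA slope estimates carry the `sqrt(1 + σ²/var(x))` inflation
  inherent to the estimator; over narrow x-ranges with noisy y this is
  material.
* Published comparative fits cannot be reproduced from this package
  alone — the machinery is validated on synthetic data and the
  packaged fossil values only.
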