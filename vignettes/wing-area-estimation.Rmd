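---
title: "Estimating avian wing area and aspect ratio from folded-wing measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating avian wing area and aspect ratio from folded-wing measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingplan)
```

## The problem

The aspect ratio of a bird's wings,

$$AR = \frac{WS^2}{A},$$

with $WS$ the wingspan and $A$ the projected area of both wings plus the
intervening body, is the morphological quantity most strongly tied to
long-distance flight efficiency, and through it to dispersal ability.
Wingspans are routinely recorded on specimen labels, but $A$ traditionally
requires a spread-wing preparation: the wing is photographed, segmented to
a binary image, its area measured at a known scale, and the total
reconstructed from two extra linear measurements. Each step can introduce
error, and suitable spread-wing specimens exist for only a small fraction
of collections.

`wingplan` implements an alternative that needs just three linear
measurements available from ordinary study skins: the wingspan $WS$, the
wing length $WL$ (wrist joint to tip of the longest primary), and the wing
width $S1$ (wrist joint to tip of the first secondary). It also
re-implements the traditional image-based workflow, the statistics used to
compare the two methods, and a phylogenetic regression engine for
interspecific validation, plus synthetic ground-truth generators that make
every stage testable against exact geometry.

## Geometric planform models

The folded-wing estimators model the planform as a medial rectangle (the
"medial box", spanning the body and proximal wings) flanked by two
hand-wings of an assumed shape:

$$A = \underbrace{h(WL, S1)}_{\text{both hand-wings}} +
      \underbrace{(WS - 2\,WL)\,S1}_{\text{medial box}}.$$

The hand-wing area $h$ depends on the assumed shape:

| model            | hand-wing shape                          | $h(WL, S1)$ |
|------------------|------------------------------------------|-------------|
| triangle         | right triangle, legs $WL$ and $S1$       | $WL \cdot S1$ |
| ellipse          | half-ellipse (axes $WL$, $S1$) or quarter-ellipse (semi-axes $WL$, $S1$) | $\tfrac{\pi}{2} WL \cdot S1$ |
| ellipse-triangle | quarter-ellipse over $\tfrac{2}{3} S1$ stacked on a triangle | $\tfrac{\pi + 1}{3} WL \cdot S1$ |

The half- and quarter-ellipse assumptions yield the same area formula, so
the ellipse model covers a continuum of wing outlines between them. For
the triangle model the total collapses algebraically to $(WS - WL)\,S1$,
which `total_wing_area()` reproduces to machine precision.

All three are members of a one-parameter family indexed by the *ellipse
fraction* $f \in [0, 1]$, the proportion of $S1$ occupied by the
elliptical portion of the shape:

$$h_f(WL, S1) = WL \cdot S1\left(f\,\tfrac{\pi}{2} + (1 - f)\right),$$

with $f = 0, \tfrac{2}{3}, 1$ giving the named models. Fractions outside
those three are supported (`planform_model("mixture", f = ...)`) but are
flagged as an extension in the model object, since only the named shapes
have been validated against specimen data. For fixed measurements the
totals are strictly ordered, triangle < ellipse-triangle < ellipse,
because $1 < \tfrac{\pi+1}{3} < \tfrac{\pi}{2}$.

```{r}
total_wing_area("ellipse-triangle", WS = 40, WL = 10, S1 = 5)
aspect_ratio(40, total_wing_area("ellipse", 40, 10, 5)$total_area)
```

**Units.** The canonical internal unit is cm (areas in cm²).
`read_morphometrics()` accepts a per-file or per-column unit declaration
(mm or cm) and converts on ingest; nothing downstream ever rescales.

**Degenerate geometry.** A wingspan shorter than $2\,WL$ would make the
medial box negative. This can arise in pointed-winged species through
measurement error. The default policy is a hard error naming the
offending specimens; `policy = "clamp"` instead zeroes the box and flags
the record. Silent negative areas would corrupt every downstream ratio,
which is why clamping is opt-in.

**Missing values.** Rows lacking any of $WS$, $WL$, $S1$ are skipped with
a warning; nothing is imputed.

## The traditional spread-wing workflow

`binarize()`, `fill_holes()`, and `largest_component_area()` reproduce
the digital measurement chain: threshold the photograph to a binary
image, fill enclosed gaps (broken feather vanes), and measure the area of
the wing particle at the ruler-derived scale (pixels per cm). The total
is then reconstructed from the root chord $c$ and wing extent $e$:

$$A_{spread} = 2a + c\,(WS - 2e),$$

where $a$ is the single-wing area and the second term is the root box
between the two wing roots.

Choices the interactive original leaves open are fixed deterministically
here:

* **Threshold.** `threshold = "auto"` uses Otsu's between-class variance
  criterion. Interactive thresholding is not reproducible; a published,
  deterministic criterion is substituted and the resolved threshold is
  recorded on the mask.
* **Connectivity.** Foreground components are 4-connected and background
  flood-fill is 8-connected — the standard complementary pair, which
  prevents a diagonal pixel chain from leaking a hole to the border.
* **Pixel model.** A pixel is counted entirely inside or outside; there
  is no partial-coverage weighting. The discretization error is on the
  order of perimeter/(px per cm), which is far below measurement error at
  practical scales (tests verify recovery within 2 % at 50 px/cm and
  convergence as resolution doubles).
* **Manual repairs.** Brush/eraser-style editing is out of scope; an
  externally edited mask can be supplied via `mask_overlay`.

## Comparison statistics

For paired estimates on the same specimens, the package computes:

* **Discrepancy** `log10_discrepancy()`: the sum over specimens of
  $\log_{10}(folded) - \log_{10}(spread)$. The log scale removes
  body-size scaling; the folded-minus-spread orientation makes a model
  that underestimates area come out negative. Because $AR = WS^2/A$ with
  a shared wingspan, the discrepancy of aspect ratios is exactly the
  negative of the discrepancy of areas — a sign mirror the test suite
  asserts.
* **Percent difference** `percent_difference()`:
  $100\,(\bar{A}_{folded} - \bar{A}_{spread})/\bar{A}_{spread}$. Whether
  a cohort difference should be the ratio of means (default) or the mean
  of per-specimen ratios is ambiguous at 1-dp rounding for small-bodied
  series; both are implemented (`diff_mode`). Note the two orientations
  of the measure are reciprocal ratios — $(1 + p_1/100)(1 + p_2/100) = 1$
  exactly — so it is orientation-fixed, not antisymmetric.
* **Coefficient of variation** `coefficient_of_variation()`:
  $100\,s/\bar{x}$ with the sample ($n-1$) standard deviation, the
  standard choice for specimen samples. Because the specimens are
  identical across methods, a lower CV for one method indicates higher
  measurement precision.

Report-time rounding is 1 decimal place, half away from zero
(`round_half_away()`); formulas themselves never round. A reference table
of published intraspecific summary statistics for three specimen series
(hummingbird, pigeon, jay; `reference_summaries()`) ships with the
package so these definitions can be checked for internal consistency
against printed means and SDs. One printed cell (the jay-series ellipse
percent difference) disagrees with its own printed means by one unit in
the last decimal, evidently because it was computed before rounding; the
tests document this rather than hiding it.

## Phylogenetic GLS

Interspecific validation regresses one method's (log) estimates on the
other's across species. Species are not independent samples, so the
residual covariance is modeled on a phylogeny: under Brownian motion the
covariance of two tips is the shared root-to-ancestor path length
(`phylo_vcv()`), and Pagel's λ multiplies the off-diagonal entries
(`lambda_transform()`), measuring the strength of phylogenetic signal
(0 = none, 1 = Brownian).

`gls_fit()` solves the generalized normal equations
$\hat\beta = (X^\top V^{-1}X)^{-1}X^\top V^{-1}y$ through a Cholesky
whitening, with standard errors from
$\hat\sigma^2 (X^\top V^{-1}X)^{-1}$, $\hat\sigma^2 = RSS_V/(n - p)$.
`fit_pgls_ml()` profiles λ on $[0, 1]$ by bounded scalar optimization
with explicit endpoint checks and returns the fit at $\hat\lambda$,
with AICc $= -2\ell + 2k + 2k(k+1)/(n-k-1)$.

Design choices that the standard presentation leaves open:

* **Regression through the origin** is the default for method-comparison
  fits: the slope is then read directly as a bias factor (1 = unbiased).
* **$r^2$ for through-origin GLS** is uncentered: $1 - RSS_V/TSS_V$ with
  $TSS_V$ computed about zero in the $V$-metric. A centered total sum of
  squares is incoherent without an intercept. With an intercept, $TSS_V$
  is the residual sum of squares of the GLS intercept-only model.
* **ML vs REML.** ML is the default (`reml = TRUE` available); the
  fixed-λ likelihood is verified in the tests against an independent GLS
  implementation to 8 decimal places.
* **AICc parameter count.** $k$ defaults to the regression coefficients
  plus one for $\sigma^2$ and one for λ, the common comparative-methods
  convention; `k` is exposed as an argument because published df
  accounting varies between sources.
* **Log base.** Base-10 throughout (discrepancy, trait transforms), so
  slopes and discrepancies share one scale.
* **Name matching.** Species names are matched after normalizing spaces
  to underscores; unmatched tips are pruned with a message rather than
  silently dropped.

## Synthetic ground truth

Every stage is validated against generators whose truth is exact:

* `make_planform()` builds the composite planform polygon (straight
  leading edge, elliptical-fraction trailing edge — the two are
  interchangeable for area) with closed-form component areas attached;
  its shoelace area agrees with the closed forms to < 1e-4 relative at
  10⁴ vertices, and the estimator family is exact on noiseless planforms
  for every $f$.
* `rasterize_planform()` renders an anti-alias-free stencil plus a
  grayscale "photograph" (dark wing on light ground), so the image
  pipeline can be checked end-to-end: segmentation equals the stencil,
  and the reconstructed total converges to the generator's area.
* `make_paired_dataset()` emulates paired folded/spread cohorts.
  Between-specimen variation is multiplicative log-normal with a stated
  CV — the choice keeps lengths positive and mimics proportional
  measurement error. Defaults (6 % specimen CV, 0 measurement CV) give
  area CVs in the mid-single digits, the range observed in real
  intraspecific series. With the estimator matched to the generating
  fraction and no measurement error, the two methods agree exactly.
* `simulate_lambda_brownian()` draws tip traits from
  $\mathcal{N}(\mu, \sigma^2 V_\lambda)$ for λ-recovery experiments.

What the generators deliberately do not model: feather slotting (wingtip
gaps), camber, posture error in spread wings, and photographic
distortion. Passing tests therefore demonstrate correctness of the
geometry, segmentation, and statistics — not that a given live species'
wing is well described by any particular $f$.

## Problem sizes and numerical choices

The validation suite uses 100 random geometries for the estimator-vs-
polygon oracle, three shapes at 50 px/cm (plus a doubled-resolution
refinement check) for the raster pipeline, and 200 seeded replicates on a
50-tip coalescent tree for slope recovery (100 per λ endpoint for signal
detection). These sizes give Monte-Carlo noise comfortably below the
assertion tolerances while keeping the full suite in the tens of
seconds. π enters formulas at machine precision; covariance solves use
Cholesky factorization and report a condition diagnostic on failure;
λ optimization tolerance is 1e-6 with endpoint checks because the
profile is frequently maximized at the λ = 1 boundary.

A note on the ±2·SE slope-recovery check: for a through-origin fit at
n = 50 the nominal coverage of ±2·SE is $P(|t_{49}| \le 2) \approx
94.9\,\%$, so observed rates hover around 95 % and vary a few points with
the simulated tree; that is the statistic behaving as theory predicts,
not an implementation defect.

## Reproducing the headline validation

`scripts/acceptance.R --seed N --out results.json` recomputes, from a
fresh run of the package: the estimator-vs-polygon worst relative error,
the CVs and percent differences recomputed from the published
intraspecific summary table, the raster-pipeline recovery error, the
PGLS slope/λ recovery rates, and the discrepancy antisymmetry residual.
Reproducing the full interspecific regression table (through-origin
slopes near 1, r² above 0.9, λ = 1) additionally requires the original
specimen appendix and an external phylogeny, which are not bundled; the
recipe is: `read_morphometrics()` → `estimate_wing_areas()` →
`aspect_ratio()` → `fit_pgls_ml(log10(folded), log10(spread),
through_origin = TRUE)`, exactly as exercised on synthetic stand-ins in
the test suite.
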