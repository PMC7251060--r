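---
title: "Quantitative CO histochemistry brain mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative CO histochemistry brain mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohmap)
```

## Scope and scientific background

Cytochrome oxidase (CO) is the terminal enzyme of the mitochondrial
electron transport chain; its histochemical activity integrates the
recent metabolic history of a brain region and is widely used as a
metabolic brain-mapping signal. `cohmap` implements the complete
quantitative analysis chain for a 2x2 (surgery x drug) rodent cohort in
which chronic cerebral hypoperfusion (permanent bilateral common carotid
artery occlusion, "2VO") is crossed with daily low-dose methylene blue
(MB) treatment:

1. **Densitometric calibration** — 8-bit gray levels to optical density
   (OD) via a step tablet, OD to CO activity (umol/min/g) via
   thickness-graded brain-homogenate standards.
2. **ROI densitometry** — polygon region-of-interest mean OD on section
   images, background correction, aggregation over three adjacent
   sections and both hemispheres.
3. **Per-ROI factorial statistics** — Type III two-way ANOVA with
   Cohen's d effect sizes, and brain-behavior correlations against a
   composite visual-water-task (VWT) score.
4. **Interregional correlation networks** — within-group Pearson
   correlation matrices over all 44 ROIs ("metabolic covariance"),
   compared edge-wise between groups via Fisher's z.
5. **Lesion volumetry** — white-matter-referenced OD thresholding,
   serial-section volume, type/laterality classification.
6. **Synthetic cohort generation** — every input above can be generated
   with known ground truth, so the full pipeline is testable without any
   external data.

The reference cohort (`co_cohort_reference()`) carries published-style
cell means and SEMs for 44 atlas-defined ROIs in four groups —
sham+saline, sham+MB, 2VO+saline, 2VO+MB — with group sizes (9, 9, 9, 8),
N = 35 and error df 31. The 2VO group sizes are fixed by the design; the
sham 9/9 split is the natural inference from N = 35 and remains
configurable in `cohort_spec()`.

## Calibration models

**Gray to OD.** The camera calibration is the logarithmic family

\[ \mathrm{OD}(g) = \alpha + \beta \log_{10}\!\frac{256}{g + 1}, \qquad
   g \in [0, 255], \; \beta > 0, \]

fitted by least squares to a step tablet of known densities
(`fit_gray_to_od()`). This form is monotone decreasing in gray, finite at
`g = 0`, and anchored so that a saturated bright field (`g = 255`) maps
to OD `alpha`; with `alpha = 0, beta = 1` it is the standard uncalibrated
OD of an 8-bit camera. Only the logarithmic *family* is fixed; the two
coefficients are always estimated from the tablet at hand. A fit
r-squared below 0.99 warns but does not fail — a noisy tablet is a data
quality problem, not a programming error.

The synthetic step tablet (`generate_step_tablet()`) inverts the same
family. One subtlety: the default tablet density range 0.06–3.05 exceeds
what an 8-bit sensor can span at unit slope (OD
\(\log_{10} 256 \approx 2.408\) at gray 0). When the requested range
fits, the generator uses the pure reference model, so noiseless tablets
invert exactly; when it does not, \(\beta\) is scaled so the full range
maps onto gray \([0, 255]\), which keeps gray levels strictly decreasing
and in range — the refit then recovers the scaled coefficients.

**OD to activity.** Ordinary least squares of spectrophotometric CO
activity on mean OD across standards cut at 10–80 um
(`fit_od_to_activity()`). The calibration-quality rule *r* ≥ 0.95 is
promoted to a pipeline contract: a fit below threshold raises an error
rather than silently propagating a bad calibration (threshold
configurable, `-Inf` disables). Conversions outside the fitted OD domain
are returned with an `extrapolated` flag, never clamped.

Default standards parameters: specific activity 6.25 umol/min/g per um
(≈250 umol/min/g at the 40 um working thickness, the magnitude of the
cortical values in the reference table), OD affine in thickness with
intercept 0.10 and slope 0.0075 OD/um (so the 10–80 um ladder spans OD
0.175–0.70, comfortably inside the 8-bit range), Gaussian OD noise with
sd 0.01. Under these defaults the linearity gate passes in ≥99% of
seeds, as the property suite verifies.

## ROI densitometry

Pixel membership uses **pixel centers under the even-odd rule** with
0-based (row, col) polygon coordinates and implicit closure; the scanline
rasteriser is checked exhaustively against an independent point-in-polygon
oracle in the test suite. Background correction subtracts the mean OD of
a blank slide region (constant flat-field model — the minimal faithful
treatment of slide and light-box artifacts), clamping at zero and logging
the subtracted constant.

ROI means deliberately include lesioned pixels: the ROI is atlas-defined,
not lesion-defined, so degeneration lowers the regional mean rather than
shrinking the region. A lesion mask, when supplied, only annotates the
overlap fraction. Aggregation over up to six measurements (three adjacent
sections x two hemispheres) is an unweighted mean — equal weighting
matches the stated measurement protocol; pixel-count weighting was
considered and rejected because hemispheric outlines of the same
structure should count equally.

**Quantisation.** The synthetic renderer quantises continuous gray
levels with deterministic 8x8 ordered (Bayer) dithering rather than
rounding. Plain rounding biases a uniform region's mean OD by up to half
a gray level, which at typical working ODs is a ~0.5% activity error —
the same order as the round-trip accuracy the pipeline promises.
Dithering makes the spatial mean track the continuous target to ~1/64
gray level, so the noiseless render → measure → convert loop recovers
every ROI activity to well under 0.5% (the suite measures ≈0.05%).

## Factorial statistics

Each ROI is analysed as a separate 2x2 ANOVA with **Type III sums of
squares under sum-to-zero contrasts** (via `car::Anova` behind
`two_way_anova()`). Type III is the appropriate default for this
unbalanced design (9, 9, 9, 8) and matches the convention of the
commercial statistics packages used in this literature. The test suite
verifies the implementation against an independent full-vs-reduced
residual-sum-of-squares oracle on 1000 random small designs, and the
balanced-case orthogonal decomposition as a special case.

**Cohen's d.** `d = (m_a - m_b) / s_pooled` with df-weighted pooled SD.
For a surgery main effect, the two "groups" are the pooled sham and
pooled 2VO samples (pooling the two drug arms, including the
between-drug-arm spread in each pooled SD). This choice was validated by
reconstruction: for secondary visual cortex the pooled-group d from the
reference cell moments is 0.8228, matching the published 0.82 to the
printed precision. A main-effect d is not uniquely defined in the
literature (an F-derived d gives a different number); the pooled-group
reading is the one consistent with the reference values, so it is the
default. For interactions the package reports the simple-effect d
(2VO+saline vs 2VO+MB) — the scientifically meaningful contrast when the
interaction is of the "treatment rescues the deficit" form — alongside
the surgery d, both labelled.

**Moment reconstruction.** `moment_matched_cells()` builds a dataset
whose cells match given means and SDs exactly (the F statistics depend on
the data only through these moments, which the suite also verifies).
Reconstruction from the reference table reproduces the published
perirhinal interaction F within ~4% and the primary-visual interaction
within ~5%, which validates the machinery; the published V2 surgery F
(4.491) and M2 interaction F (5.883) are **not** consistent with the
printed cell moments under any group-size assignment or SS type we
examined (reconstruction gives 5.92 and 4.78). Since F is a deterministic
function of the cell moments, the package reports the reconstructed
values as computed; the discrepancy presumably reflects analyses run on
unrounded or per-hemisphere data upstream of the printed table.

**Brain-behavior correlations.** Pearson r per ROI with exact-t
two-tailed p values, over the full cohort or excluding lesioned subjects;
n is always reported explicitly (avoiding the r(N) vs r(df) ambiguity).
No correction across the 44 ROIs is applied by default, mirroring the
field's practice; a Benjamini–Hochberg column can be *added* (never
substituted) with `fdr = TRUE`, and the run report prints a prominent
note about multiplicity.

The composite VWT score is the arithmetic mean of the two final probe
percent-correct scores (elemental and transverse discrimination), bounded
[0, 100]; scores are analysed as raw percentages (no arcsine/logit
transform, none being standard here).

## Interregional correlation networks

Within each group, all pairwise Pearson correlations of ROI activities
across subjects form the metabolic covariance matrix
(`group_correlation_matrix()`; symmetric, unit diagonal, built only for
n ≥ 4 and non-degenerate columns). Group differences per edge use
Fisher's z:

\[ Z = \frac{\operatorname{atanh} r_1 - \operatorname{atanh} r_2}
   {\sqrt{1/(n_1 - 3) + 1/(n_2 - 3)}} . \]

The default reference distribution is the standard normal — the
z-difference has *known* variance, so normal theory is the classical
choice — but a t reference with `n1 + n2 - 6` df is available
(`method = "t"`) because descriptions of this comparison in the applied
literature sometimes phrase it as a two-sample t test; neither variant is
guessed to be "the" original intent, and the suite verifies the normal
version holds its nominal 5% size (measured 4.8–5.2% at n = 20 per
group). Edges where either group shows |r| = 1 (possible at small n, or
from exactly collinear columns) are excluded and listed rather than
infinitely weighted; a numerical guard snaps correlations within 1e-12 of
±1 to exactly ±1 so collinearity is detected reliably.

`difference_map()` compares all 44·43/2 = 946 pairs at uncorrected
alpha 0.05 by default (the convention this analysis family uses), with
optional FDR columns reported alongside. Heat maps are exported as
device-free raster PNGs (diverging blue–white–red over [-1, 1], ROI order
fixed to the reference-table order for comparability) and always with a
CSV twin that round-trips bit-exactly — the CSV, not the image, is the
canonical output.

## Lesion segmentation and volumetry

Lesion pixels are those inside a user-supplied approximate outline whose
OD falls in the **white-matter-referenced band [0.85, 0.98] x WM OD** —
darker than unstained fibre tracts, lighter than healthy gray matter.
The band is applied only inside the outline (never whole-image), which is
what keeps striatal white-matter speckle from being counted. In
tissue-loss mode the upper bound is set equal to the white-matter OD and
the lower bound dropped, so missing tissue (brighter than WM) is still
captured. No morphological cleanup is applied by default — the procedure
is pure thresholding.

The serial-section volume formula \(V = \sum A \times d\) admits two
readings of d, and the source description is internally inconsistent
("distance between collected sections" vs an explicit
\(d = T \times (n_\text{sections} - 1)\)). The default is the standard
Cavalieri estimator `d = T` (80 um), which extrudes each profile over one
spacing; `literal_d = TRUE` applies the printed formula instead. Outputs
always name the mode and carry the alternative value, so neither reading
is silently chosen. Volumes are mm³ internally with an explicit cm³
column (axis labels in this literature vary).

Type labels (neocortical, striatal, hippocampal, perirhinal) attach when
the mask overlaps the corresponding atlas ROI group by more than 5% of
the ROI's area on any section (configurable); laterality comes from ROI
polygon membership, not the image midline, so oblique sections cannot
mislabel a hemisphere.

## The synthetic cohort generator

`generate_cohort()` draws each group's subjects from a multivariate
normal with mean equal to the reference cell means, marginal SDs
`SEM x sqrt(n)` (so group means have the stated SEMs in expectation), and
a within-group inter-ROI correlation matrix — the simplest model
matching the reported first and second moments. Inter-ROI correlations
are not published, so the default is an explicit assumption: a
block-structured matrix (`block_correlation()`) with background r = 0.15
and +0.45 within the visual ({V1, V2, SC}), hippocampal ({CA1–CA3, DG,
subiculum}) and prefrontal blocks, chosen to emulate the qualitative
block structure of the published heat maps. The construction (sums of
scaled indicator outer products plus a positive diagonal remainder) is
PSD by construction; arbitrary user matrices are validated, and repair is
only ever explicit via `nearest_psd()`.

Lesion flags are planted in `round(n/3)` subjects of each 2VO group
(3/9 and 3/8, matching the observed incidence); sham subjects never carry
lesions. The pipeline's rendered lesions are placed unilaterally in the
caudate/putamen cell with MB-treated lesions drawn smaller — the
dominant observed pattern.

**Behavior scores.** `generate_behavior()` builds the VWT score as a
linear blend of standardized target-ROI activities plus Gaussian noise,
with blend weights \(w = R^{-1}\rho\) solved from the empirical ROI
correlation matrix so the realized cohort-level correlations approach the
targets \(\rho\); the residual variance is \(1 - \rho' R^{-1}\rho\), and
target vectors outside the feasible ellipsoid
(\(\rho' R^{-1} \rho > 1\)) are refused with an explicit error. Scores
are centred at 65 with spread 12 (a plausible mean percent-correct for a
learnable discrimination, keeping [0, 100] clipping rare) and clipped
after noise. Because the default target ROIs (perirhinal, motor, visual,
hippocampal) are themselves depressed in the 2VO+saline cell, the group
ordering of scores — 2VO+saline lowest — emerges from the ROI coupling
without explicit group shifts; additive `group_effects` remain available
but perturb realized correlations and are off by default. Over repeated
cohorts the realized perirhinal correlation averages 0.527 against a
0.526 target.

All randomness flows from one explicit integer seed per call, evaluated
in a local RNG stream that restores the caller's state — no function
touches global RNG state, and identical seeds give bit-identical tables
and images.

**What the generator does not emulate.** Polygons are schematic grid
rectangles, not anatomy; staining chemistry, optics (vignetting,
point-spread), section-to-section registration error, and trial-level
swim behavior are all out of scope. Passing tests therefore demonstrate
that the *analysis chain* is correct and calibrated under the stated
statistical model — not that the model captures every feature of real
histochemical images.

## Numerical choices and degenerate inputs

* Polygon vertices at half-integer coordinates in fixtures keep pixel
  centers off edges, making rasteriser/oracle comparisons exact.
* Collinear ROI columns: correlation snapped to ±1 (guard 1e-12) and the
  edge excluded from z comparison.
* Step-tablet noise is clipped to 0.4x the smaller adjacent gray gap, so
  monotonicity survives noise by construction.
* Degenerate inputs fail loudly with specific messages: empty factorial
  cells, all-zero within-cell variance, zero-width OD ranges, under-
  determined standards, empty ROIs/scopes, infeasible behavior targets,
  non-PSD correlation inputs.

## Problem sizes used in the shipped checks

The property suites run at sizes chosen to make the statistical checks
informative while keeping the whole suite interactive: 1000 random small
designs for the ANOVA oracle, 5000 replicates for the edge-test size,
200 cohort seeds for moment recovery and for network power (planted
r = 0.9 vs 0 at n = 30 per group, detected in every seed; false-positive
load at its binomial expectation), 400 seeds for behavior-target
recovery, 128x128 images for the exhaustive segmentation oracle, and the
full 44-ROI render for the noiseless round trip.

## Known limitations

* The published V2 surgery F and M2 interaction F cannot be reproduced
  from the printed cell moments (see above); the package reports the
  reconstructed values rather than the printed ones.
* Lesion areas are exact pixel counts of a thresholded mask; no partial-
  volume handling at lesion edges (the suite's rendered-fixture checks
  bound the resulting error at the ~one-pixel-row level).
* ROI outlines are inputs; no atlas registration or automatic ROI
  detection is provided or planned.
* The behavior generator calibrates correlations in-sample; very small
  cohorts (n < ~10) will show noticeable shrinkage of realized vs target
  correlations.
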