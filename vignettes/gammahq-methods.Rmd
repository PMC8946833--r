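---
title: "Quantifying gamma-H2AX positivity under co-stress: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gamma-H2AX positivity under co-stress: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gammahq)
```

## The measurement problem

Phosphorylated histone H2AX (gamma-H2AX) accumulates in nuclei within
minutes of DNA double-strand breaks and is the standard immunofluorescence
readout of DNA damage. In a co-stress design, keratinocytes are
pre-conditioned under hyperosmotic medium (NaCl) or normal medium, then
challenged with UV irradiation or hydrogen peroxide; the question is whether
osmotic pre-stress blunts the damage response. The quantity of interest is
the *fold change* of the percentage of gamma-H2AX-positive cells between
challenged and unchallenged wells, computed separately within each
pre-stress arm — fold changes rather than raw percentages, because baseline
positivity drifts considerably between experiments done on different days.

`gammahq` implements the full computational chain for this readout:

1. nuclei are segmented from the DAPI channel and used to crop the
   gamma-H2AX channel (`segment_nuclei()`);
2. both channels are background-corrected and each cell is scored by its
   *brightest* background-corrected signal pixel (`assign_max_signal()`);
3. a positivity threshold is derived once per experiment from the untreated
   control and applied, unchanged, to every image of that experiment
   (`derive_threshold()`, `count_positive()`);
4. treated/untreated fold changes are computed per arm, Grubbs outliers
   excluded, normality checked, and the two arms compared by a paired
   t-test across replicate experiments (`compute_fold_changes()`,
   `grubbs_exclude()`, `paired_t_test()`, `compare_arms()`);
5. a separate module performs 2^-ddCt relative quantification of qPCR Cq
   tables with reference-gene (18S) normalization (`analyze_qpcr()`).

## The per-cell score and its threshold

The per-cell statistic is deliberately simple: the maximum
background-corrected signal intensity anywhere inside the nucleus mask. A
maximum is sensitive to segmentation truncation at image borders, which is
why border-touching nuclei are excluded by default
(`segmentation_params(exclude_border = TRUE)`), and to residual background,
which is why background subtraction precedes scoring on both channels with
identical settings. A configurable within-cell percentile
(`max_percentile`) exists for sensitivity analysis but the default, 100, is
the readout itself. A cell is *positive* when its score strictly exceeds
the threshold; a score exactly at the threshold is negative. Percent
positive per condition pools the cells of all fields of that condition
(one percentage per condition per experiment); per-field percentages are
emitted alongside for dispersion diagnostics.

Anchoring the threshold to the untreated control of *one* experiment, and
reusing it for all images of that experiment, makes conditions within an
experiment directly comparable while letting the threshold track
between-day staining differences. What "an appropriate threshold" means is
genuinely open, so the method is pluggable:

* `mean_k_sd` (default, k = 2): the classic control-anchored rule. Note a
  structural property, not a defect: if the control's negative scores are
  approximately normal, a mean + 2 SD cut labels about 2.3% of negative
  cells positive by construction.
* `otsu_on_scores`: maximizes between-class variance over the score
  distribution; preferable when the dim and bright populations are well
  separated, because the cut then falls in the gap and misclassification is
  essentially zero. The package's own recovery studies use this method for
  exactly that reason — they measure pipeline error, not the irreducible
  tail mass of the mean + k SD rule.
* `percentile` and `fixed` for completeness and reproduction of external
  choices.

Every threshold is recorded (value, method, parameters, source condition)
in the outputs, so provenance survives into the result tables.

By default one threshold per experiment is derived from the normal-medium
untreated control and applied to both arms; `per_arm_thresholds = TRUE`
derives one per arm for sensitivity analysis.

## Statistics

Fold change is the plain ratio of percent-positive values
(treated/untreated) within an experiment and arm; an untreated percentage
of zero flags the ratio undefined and it is excluded downstream with a
recorded reason. Arms are compared per treatment by a two-sided paired
t-test across replicate experiments, pairing the two arms' fold changes by
experiment. Before the test, iterated two-sided Grubbs exclusion
(alpha = 0.05) is applied to the paired differences, removing whole pairs;
iteration was chosen because more than one aberrant replicate can occur,
and each exclusion is logged with its G statistic and critical value. The
critical value uses the closed form
G = ((n-1)/sqrt(n)) * sqrt(t^2/(n-2+t^2)) with t the upper alpha/(2n)
quantile of Student's t on n-2 degrees of freedom; the test suite verifies
it against a 100,000-sample Monte-Carlo null. Normality of the differences
is checked by Shapiro-Wilk; failure warns but does not switch to a
nonparametric test, since the readout of record is the t-test. NaCl doses
(e.g. 100 mM and 200 mM arms) are analyzed as separate arms by default;
pooling is the caller's choice of manifest labels.

For qPCR, technical duplicates are averaged at the Cq level, each sample's
target Cq is normalized to its 18S Cq (delta Ct), Grubbs exclusion is
applied per gene and condition to the delta-Ct values, and
ddCt = mean(treated) - mean(control) gives fold change 2^-ddCt. PCR
efficiency is fixed at 2 (no efficiency correction), matching the standard
Livak/Schmittgen workflow.

## What the simulator emulates — and what it does not

Because the pipeline's raw microscopy cannot be redistributed, validation
rests on a generator with exact ground truth. `generate_field()` renders:

* round nuclei with Gaussian-perturbed radius (default 12 +/- 1.5 px in a
  1024 x 1024 field of ~150 cells — field size and density are plausible
  defaults for a 20x objective, configurable and not claims about any
  particular instrument), placed by rejection sampling with a minimum
  center separation, disks fully inside the field;
* a DAPI channel with one bright disk per nucleus over background;
* a signal channel in which each cell draws a peak intensity from a dim
  (negative, 500 +/- 80) or bright (positive, 3000 +/- 300) distribution on
  a 16-bit scale, paints 70% of that value across the nucleus disk and the
  full value on the single center pixel — so the per-cell maximum has
  *exact* ground truth;
* a planar illumination ramp (default amplitude 100) plus additive
  Gaussian read noise (default SD 40), clipped to the bit range.

Positivity labels are independent Bernoulli draws, so realized condition
fractions are binomial around the configured ones — which is what makes
"recovered within 3 binomial standard errors" a meaningful acceptance
property. The default experiment layout crosses two arms with three
treatments at multiplicative effects 2.4/4.7 (control arm, UV/H2O2) and
1.2/1.9 (osmotic arm) on a 10% baseline, the pattern the co-stress readout
is designed to detect.

Deliberately *not* modeled: optical point-spread functions, punctate
per-focus structure (the readout is whole-cell, not focus counting),
irregular or overlapping nuclei, cell-cycle heterogeneity, Poisson shot
noise (additive Gaussian only), and day-to-day baseline drift beyond a
configurable baseline. Passing recovery tests therefore demonstrates the
correctness of the computational chain under the stated statistical
structure, not robustness to every real-microscopy artifact. The
`simulate_costress_scores()` fast path draws per-cell scores directly from
the same distributions (perfect-imaging limit) and is used where only the
classification and statistics stages are under study, e.g. the power
study over 100 repeated 8-replicate experiments.

## Numerical choices

* **Coordinates** are `[row, col]`, 1-based, R's native matrix convention;
  centers are real-valued and rasterized by a center-in-pixel test.
* **Background subtraction** defaults to grayscale morphological opening
  with a disc ("rolling-ball"): it is exact on constant and planar-ramp
  backgrounds (erosion/dilation return actual pixel values, with no
  intensity quantization), which is what makes the simulator's noise-free
  score-fidelity check exact to floating-point. The median filter is
  available but internally quantizes intensities, and `none` disables
  correction. The radius (default 50 px, ~4 nucleus radii) must exceed the
  nucleus radius comfortably or nuclei leak into the background estimate.
* **Thresholding DAPI** uses Otsu on the background-corrected image by
  default; connected components use 8-connectivity (4 available);
  touching nuclei can be split by watershed on the distance transform
  (`split_touching`), off by default since the simulator's default
  geometry keeps nuclei separated and whether the original workflow split
  touching cells is unknowable.
* **Area filter** defaults to `min_area = 40` px^2 (about a third of the
  default nucleus area) to drop noise specks; filtering re-indexes labels
  consecutively and can only reduce the count.
* **Degenerate inputs**: empty images segment to zero labels (not an
  error); zero segmented cells in a condition flag the summary rather than
  aborting the run; zero-variance samples make Grubbs a no-op and the
  t-test a flagged degenerate result; an empty untreated control is a hard
  error because nothing can anchor the experiment.
* **Determinism**: every stochastic routine takes an integer seed; one
  experiment consumes a single RNG stream, so identical seeds give
  bit-identical images, manifests and result tables.

## Problem sizes used in the validation suite

The test and acceptance studies run on reduced geometries chosen to keep
the statistical guarantees intact: 256 x 256 fields of 20 nuclei for the
50-field segmentation studies; 512 x 512 fields of 80 nuclei, pooled to
2,000-10,000 cells per condition, for positivity and fold-change recovery
(at ~9,600 cells per condition the binomial relative error of a recovered
ratio is ~4%, comfortably inside the 10% recovery criterion); 400 cells
per condition in each of 8 replicate experiments, repeated 100 times, for
the paired-test power study, where the configured effect sizes put the
expected power near 1.

## Known limitations

* Nucleus masks stand in for whole cells; since gamma-H2AX is nuclear this
  is the biologically appropriate crop, but an optional dilation is the
  only concession to cytoplasmic signal.
* The mean + k SD threshold inherits its false-positive tail from
  normality of the control; use `otsu_on_scores` when the score
  distribution is clearly bimodal.
* No mixed-effects modeling of plate or day effects and no multiple-testing
  correction across treatments; the paired design absorbs day effects into
  pairs, which is exactly what it is for.
* The qPCR module assumes perfect doubling per cycle; no standard-curve
  efficiency estimation and no multi-reference-gene normalization.
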