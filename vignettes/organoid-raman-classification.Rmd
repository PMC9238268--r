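---
title: "Classifying organoid differentiation states from Raman spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying organoid differentiation states from Raman spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanoid)
```

## The problem

Salivary gland organoids grown from embryonic progenitor cells differentiate
along distinct paths depending on the growth factor in the medium: FGF2
drives branching morphogenesis and proacinar differentiation, EGF drives
proliferation, and control medium leaves a duct-enriched phenotype. For
quality control and screening one wants to read the differentiation state
off intact, unlabeled, hydrated organoids. Confocal Raman microspectroscopy
provides that readout: point spectra collected from the cell-dense epithelial
regions carry vibrational fingerprints (protein, lipid, nucleic-acid bands
over ~500--2000 cm^-1) that differ between treatment classes.

`ramanoid` implements the complete analysis chain for such data: spectral
post-processing, diagnostic peak statistics, SVD scatter analysis with a
perpendicular-bisector separation statistic, a robust (ramp-loss) SVM
evaluated over repeated stratified splits, and two blinded-assignment
procedures. Because raw instrument data of this kind are rarely public, the
package also ships a synthetic spectrum generator that reproduces the data
properties every stage relies on, so the whole chain is testable end to end.

## The data model

Spectra live on a wavenumber grid (fixed-mode acquisitions: 500--2000 cm^-1,
750 points; live-mode: 600--2000 cm^-1). The central container is the
`spectra_matrix`: the n x m stacked matrix with one spectral point per row
and one spectrum per column, treatment blocks contiguous (e.g. control in
columns 1--50, EGF in 51--100, an unknown batch last). On disk this is a
wavenumber-indexed wide TSV plus a metadata table; vendor binary formats are
deliberately out of scope -- users export to text first.

## Preprocessing

The chain applies, in order:

1. **Matrigel rejection.** Spectra dominated by the embedding matrix are
   removed before anything else: in fixed mode any spectrum with a point at
   the detector ceiling (saturation), in live mode any spectrum whose fitted
   fluorescence-background integral exceeds twice the dataset median.
2. **Despiking.** A point is a cosmic-ray candidate when it exceeds 3.5x the
   spectrum mean. The pipeline adds a narrow-artifact guard: a candidate
   must also exceed twice the larger of its two shoulders (the points two
   grid steps away). A cosmic ray is one point wide, so its shoulders sit at
   the background; even the narrowest real band here (phenylalanine,
   half-width ~5 cm^-1 ~ 2.5 grid steps) spans several points and is spared.
   Without the guard, re-running the pipeline on cleaned, background-free
   spectra would flag the phenylalanine peak itself, because the spectrum
   mean of a baseline-subtracted spectrum is far below its strongest bands.
   Manual despiking, which this stage emulates, is isolation-aware in
   exactly this sense. Flagged points are bridged by linear interpolation
   between the nearest clean neighbours (for an isolated point, the average
   of the two connecting points).
3. **Denoising.** Savitzky--Golay local polynomial smoothing, order 1 over a
   5-point window (the nearest odd window to the vendor software's printed
   "size 4"; the semantics of that parameter are unpublished, so both order
   and window are configurable).
4. **Background subtraction.** Fluorescence is modeled as a low-order
   polynomial fitted to evenly spaced anchor points and refined by
   iterative clipping: each anchor value is replaced by the minimum of its
   current value and the fitted value, and the polynomial is refitted.
   Defaults: degree 2 with 256 anchors (fixed), degree 5 with 100 anchors
   (live). The clipping update decays like a power law, so the convergence
   tolerance is 1e-4 of the intensity scale (tolerances much below that are
   unreachable in a practical iteration budget and would change the baseline
   by an amount immaterial against band amplitudes); a pure polynomial of
   matching degree converges in one iteration to machine precision.
   Negative residuals are kept -- clipping them would bias peak ratios --
   and counted in the processing log.
5. **Normalization.** Division by the maximum intensity in the 995--1011
   cm^-1 window around the ~1003 cm^-1 phenylalanine band, a strong, stable
   protein reference; afterwards the window maximum is exactly 1.

Two spec-level caveats are worth stating. First, the pipeline is not exactly
idempotent: despiking and normalization are (re-running them is a bitwise
no-op on cleaned data), but smoothing a spectrum twice is not the same as
smoothing it once, and on the narrow reference band the second pass moves
points by up to ~10% of the spectrum maximum. Second, with the smoothing and
baseline stages enabled the pipeline output cannot equal the analytic
noiseless band sum to high precision (smoothing lowers a Lorentzian apex by
a few percent; the clipped baseline rides on the band-tail floor). Both
stages are individually skippable (`denoise_window = NA`,
`baseline_degree = NA`), and the exactness tests run with them off.

## Peak statistics and the blinded vote

Diagnostic intensities are extracted as the window maximum (half-window
6 cm^-1) at nine panel bands: 569, 621, 676, 1124, 1248, 1335, 1446, 1654
and 1926 cm^-1. (Two printed sources disagree by 1 cm^-1 on the last band --
1926 vs 1927; they describe the same CO-stretch band and the panel uses
1926.) Group statistics per band: one-way ANOVA, Dunnett's post hoc against
control (delegated to `multcomp`, which implements the multivariate-t
single-step adjustment), and all pairwise pooled-variance t-tests with
Bonferroni correction.

The blinded procedure averages an unknown batch's spectra, normalizes the
average, extracts the panel intensities, assigns each band to the known
group with the nearest mean, and takes a simple majority. Exact per-band
ties are flagged ambiguous and cast no vote. A secondary annotation lists
other groups whose 95% confidence interval contains the unknown mean
("overlapping ranges"); it never affects the vote. Whether "mean ratios"
should be read from the averaged spectrum or as averages of per-spectrum
intensities is not settled by the description; the averaged spectrum is the
default (`average_first = TRUE`), the alternative is one flag away.

## SVD analysis

The stacked matrix is decomposed as M = U S V^T without prior centering --
the stacked description operates on raw spectra, and with non-negative data
the first component is then the shared mean shape, which is itself useful in
the component report. Scores for scatter plots are rows of V scaled by their
singular values (so they carry variance weight; unscaled is an option), and
the default plotted pair is components (2, 3) for the reason above. Signs
are fixed deterministically (each U column's largest-magnitude element made
positive). Which components the original scatter plots used, and whether
scores were variance-scaled, is not stated anywhere; these defaults are
recorded in the output.

Separation between two groups is quantified by the line perpendicular to and
equidistant from the two cluster means in score space. Assigning each point
to the side it falls on is algebraically the two-class nearest-centroid
rule, which is how the tests oracle it. Points exactly on the boundary are
counted in an explicit on-line bucket rather than silently assigned --
zero-measure on real data, but reproducible behaviour on constructed integer
cases matters for testing.

For blinded batches, the unknown block is stacked after the two known
blocks, participates in the decomposition, but is excluded from the
mean/boundary computation (whether the original analysis excluded it from
the decomposition too is not stated; including it matches the stacked-input
description). The verdict is the known side holding the majority of the
unknown population; across the three known pairs the overall winner is the
label taking the most pairwise verdicts.

## Robust SVM

Features are the min-max-normalized intensities: at each wavenumber the
minimum across spectra is subtracted and the difference divided by the
range, so values lie in [0, 1]. Following the published protocol the
statistics are computed on the full assembled comparison before splitting;
a leakage-free train-only variant (test values clipped to [0, 1]) is
provided and recommended for new studies.

The classifier is a linear ramp-loss (truncated hinge) SVM: the loss
min(max(0, 1 - yf), 1 - s) caps the penalty of far-side points, which is
what makes the learned classifier resistant to outliers. The original
formulation is cited, not restated, in the source study, so this package
implements the standard concave--convex procedure: the ramp splits into a
hinge minus a shifted hinge, each iteration solves a convex weighted
hinge-loss SVM (a box-constrained dual solved by coordinate descent in
compiled code; the bias is an augmented, regularized constant feature), and
iterations stop when the outlier set -- the points with y f(x) < s -- stops
changing. Defaults: C = 1, s = -1, linear kernel only (none of these values
is printed in the source; all are configurable). The ramp objective is
non-increasing across iterations, which the tests assert per fit.

Evaluation repeats a stratified random split (default train fraction
100/120, inside the stated 83--90% band) `n_reps` times (default 4000;
the worked examples use 200) and reports the full accuracy distribution
with mean, standard deviation and a kernel-density violin summary.

One calibration subtlety: for a fixed finite dataset the split-averaged
accuracy converges to a dataset-conditional value, not to the population
value, so at zero effect size the mean accuracy fluctuates around 0.5 with
the dataset realization (about +-0.05 at 60 spectra per class) no matter how
many repetitions are run. The null-calibration check therefore uses the
accuracy distribution's own standard deviation (~0.1) as its yardstick, not
a standard error.

## The synthetic generator

`simulate_dataset()` emulates the study conditions: 50 spectra per treatment
class (the reported 40--60 per treatment), three organoids per class in the
metadata, Lorentzian bands at the library positions (Gaussian available for
robustness checks), a low-order polynomial fluorescence background (steeper
and higher in live mode, mirroring the reported live-organoid background),
additive Gaussian noise (sd 0.02 relative to a unit phenylalanine amplitude;
defaults chosen once as a realistic mid-range since no noise model is
printed), rare single-point spikes (Poisson, set to a multiple of the
spectrum mean), and Matrigel-contaminated spectra -- saturating in fixed
mode, high-background/low-signal in live mode -- at a configurable fraction.

Class structure: all classes share the phenylalanine anchor and two
non-diagnostic bands; the nine diagnostic bands rotate (high, mid, low)
roles in triples, so every pair of classes differs at every diagnostic band
and the maximum per-pair relative amplitude difference equals the
`effect_size` parameter exactly. Real class differences are only reported
through figures, so effect size is a user parameter, not a literature value;
0.5 is the package default for worked examples.

What the generator does *not* model, and what passing tests therefore do not
show about real data: Poisson shot noise and detector read noise, organoid-
level random effects (spectra within an organoid are treated as exchangeable),
wavenumber calibration drift, water/quartz background structure, and any
Matrigel chemistry beyond its two rejection cues. Synthetic results
calibrate the machinery, not the biology.

## Numerical choices and degenerate inputs

* Baseline fitting uses a Vandermonde basis on the grid scaled to [-1, 1]
  with a single QR factorization reused across clipping iterations.
* `group_statistics()` reports F = 0, p = 1 when the between-group sum of
  squares is zero (identical group means), where the raw F ratio is 0/0.
* An exact nearest-mean tie in `assign_peak()` is flagged ambiguous and
  casts no vote; a tied majority sets the tie flag and no winner.
* A decision value of exactly 0 predicts the positive (second) class.
* Duplicated spectra produce identical SVD score points; duplicating a
  separable training set leaves the (zero-loss) SVM optimum unchanged.
* Problem sizes in the tests and the acceptance script -- 200 SVM
  repetitions, 10 blinded rounds, 100 oracle matrices -- were chosen as the
  package's own worked-example scale; the published protocol's 4000
  repetitions remain the function default.

## Known limitations

* The vendor software's exact parameter semantics ("size 4", "256 points")
  are unpublished; this package documents one faithful reading and exposes
  the knobs.
* The ramp-SVM CCCP is a local method: started from the plain hinge
  solution, it resists moderate outlier contamination (asserted in tests)
  but cannot recover once the hinge solution is fully flipped.
* Dunnett p-values rely on multivariate-t quadrature; agreement across
  platforms is at quadrature precision (~1e-4), not machine precision.
* No multiclass SVM, nonlinear kernels, or hyperparameter search; the
  analysis always compares class pairs, as the study design does.
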