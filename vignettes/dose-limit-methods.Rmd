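---
title: "Determining the lower dose limit for automated CT fat quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining the lower dose limit for automated CT fat quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipoCT)
```

## The question

CT is the reference method for measuring visceral (VAT) and subcutaneous
(SAT) adipose tissue, but routine fat monitoring is only defensible at very
low radiation dose. As dose falls, image noise rises as
$\sigma \propto 1/\sqrt{\text{dose} \times \text{slice thickness}}$, and at
some point automated fat segmentation stops being trustworthy. adipoCT
implements the full procedure for locating that point: simulate (or load)
repeat abdominal scans across a dose grid, quantify fat automatically,
compare against ground truth, and test - dose bin by dose bin - whether
accuracy is still compatible with the accuracy level that unavoidable
positioning differences impose anyway.

The core quantities are:

* **Fat volume per unit scan length** $V_u = \frac{1}{N}\sum_i S_i$, the mean
  per-slice fat area. Unlike the total volume $V_t = \sum_i S_i I$, $V_u$
  is invariant to slice interval and scan-length differences between
  reconstructions, which would otherwise dominate the error budget.
* **Accuracy** $= (1 - |V_{true} - V_{meas}|/V_{true}) \times 100\%$. The
  absolute value makes over- and under-segmentation both count against the
  method; the value can be negative when the error exceeds 100%.
* **SSDE**, the size-specific dose estimate: CTDIvol times a conversion
  factor indexed by the patient's AP+LAT dimension sum (32-cm phantom
  convention), and **SSDE$_{5.25}$ = SSDE x thickness / 5.25**, which puts
  images of different slice thickness on an equal-noise dose scale.

## The statistical ladder

1. **Confounder screens.** Two-sided Mann-Whitney U tests check whether (a)
   field-of-view truncation and (b) an acquisition gap of 15+ days between
   the compared scans shift measurement accuracy. The interval screen
   decides, per compartment, which records may define the acceptable
   accuracy.
2. **Acceptable accuracy.** The mean accuracy of ground-truth-vs-ground-truth
   comparisons between repeat scans - the error floor set by positioning
   alone. If the interval screen flags day-gap drift (typically SAT), only
   short-interval records qualify; otherwise all records qualify after a
   3-sigma outlier screen. A `fixed` mode bypasses derivation with reference
   values 94.5% (SAT) and 85.2% (VAT).
3. **Dose-bin tests.** Automated-measurement records (denoised, finest slice
   thickness) are binned on SSDE$_{5.25}$ (default edges 0.35, 0.40, 0.45,
   0.50, Inf; half-open `[low, high)`), and each bin is tested one-sided for
   *inferiority* to the acceptable-accuracy reference sample. A large
   p-value supports acceptability. Bins with fewer than `small_n_min = 6`
   records are flagged.
4. **The limit.** The lowest dose $d$ such that every bin at or above $d$
   shows no inferiority at $\alpha = 0.05$, with at least one unflagged bin
   among them (a small-n bin never qualifies alone). If no fine bin
   qualifies, the lowest passing coarse-thickness fallback level (default:
   5.25-mm denoised records pooled at SSDE$_{5.25} \ge 1.5$ mGy) is used.
   The effective dose at the limit is SSDE x scan length x 0.015
   mSv/(mGy cm).

Note one deliberate literalism: with this rule, a passing bottom bin lowers
the limit to the lowest tested edge. A more conservative reading would
require the bin's p-value to be "almost 1" before extending the limit
downwards; we do not implement that discretionary step, so on borderline
data this package may report one bin lower than a cautious human reader
would.

### The Mann-Whitney implementation

The U statistic is computed from midranks. For untied data with
$\min(n_1,n_2) \le 20$ the p-value is exact, from the full permutation
distribution via the standard count recurrence
$c(u;m,n) = c(u-n;m-1,n) + c(u;m,n-1)$. Otherwise a normal approximation
with midrank tie correction of the variance and a 0.5 continuity correction
is used, and the method is recorded in the result. One-sided alternatives
follow the inferiority convention ("sample stochastically smaller").

At $n_1=n_2=8$ the exact null CDF is a step function with central jumps
near 0.02, so *no* continuous approximation can track it to 0.01
everywhere; the tie-corrected normal path is accurate to roughly one such
jump (worst case ~0.02-0.03 for ordinary tie intensities). Tests that need
better than that at small n should use the exact path, which is why the
automatic method selection prefers it whenever the data are untied.

### 3-sigma outlier exclusion

The screen is single-pass, with mean and SD computed *leave-one-out* for
each candidate. With the candidate included, the largest attainable z-score
in a group of $n$ is $(n-1)/\sqrt{n}$ - below 3 for $n \le 10$ - so an
include-the-candidate rule could never discard even a gross outlier from a
small group. Leave-one-out preserves the intent (discard only values more
than 3 SD from the rest) at every group size.

## The synthetic cohort

No patient data ship with the package; the phantom module generates a
cohort whose *statistical structure* matches what the analysis assumes.

**Anatomy.** An extruded elliptical abdomen (default 400 mm LAT x 250 mm
AP): a SAT ring of constant thickness (20 mm) bounded by two ellipses, a
10-mm muscle wall, and an organ interior with equal-radius circular VAT
deposits filling 25% of the cavity. Because the regions are defined by
exact ellipse/disk equations, every ground-truth area has a closed-form
value against which rasterised label counts are verified. HU means: fat
-100, muscle +50, organ +30, air -1000, with 3 HU within-tissue texture.
Fat HU sit inside the conventional adiposity window (-190, -30); muscle and
organ sit outside it, so segmentation of a noiseless phantom is exact by
construction - a green segmentation test establishes correct plumbing, not
clinical performance.

**Dose-dependent noise.** Additive, white, Gaussian in HU, with
$\sigma = 33.8 \sqrt{(1.9 \times 5.25)/(\text{SSDE} \times T)}$ HU,
anchored at the measured low-dose fat-ROI noise (33.8 HU at SSDE 1.9 mGy,
5.25 mm). The standard-dose anchor reported alongside it (12.7 HU at 20.4
mGy) deviates from the square-root law (predicting 10.3 HU) because real
reconstructions differ in kernel; the model follows the stated law and this
discrepancy is documented, not fitted. Only the sigma scaling is modelled -
no noise correlation, beam hardening, or kernel texture - so conclusions
about spatially-correlated-noise behaviour are out of reach of this
generator.

**Repeat-scan variation.** Each acquisition draws positioning jitter
(rotation U(-5deg, 5deg), translation U(-10, 10) mm per axis, anterior
compression U(0, 5%)) and a *tissue rearrangement* factor: a zero-mean
Gaussian fractional change of SAT ring thickness (SD 3.5%) and VAT fill
(SD 13%). The rearrangement term exists because rigid in-plane motion
preserves cross-sectional areas almost exactly, which would put the
truth-vs-truth repeat accuracy near 99% for both compartments - unlike real
repeat scans, where visceral contents redistribute substantially. The two
SDs are anchored once to the reference positioning-effect means (about
94.5% SAT, 85.2% VAT repeat accuracy) and are configuration-exposed; no
canonical physical values exist.

**Day-gap drift.** Subjects carry random linear drift slopes (SAT
0.075 +/- 0.05 %/day, VAT 0 +/- 0.02 %/day), active only for scans at a
nonzero day offset; offsets are exponential (mean 55 d, capped at 180 d,
matching a 6-month enrollment window and putting roughly a quarter of
subjects under the 15-day cutoff). This reproduces the observed asymmetry:
the interval screen flags SAT, not VAT.

**Truncation.** With probability 17/46 a low-dose acquisition is clipped to
a FOV of 0.97 x the lateral body diameter, removing lateral SAT; the flag
is set exactly when labelled voxels were removed.

**Seeding.** A master seed spawns named substreams (per subject, per
acquisition, per noise field), so enlarging the cohort never changes
existing subjects, and identical specs give bit-identical cohorts.

## Segmentation stand-ins

The deep-learning segmenter and the commercial noise-reduction product the
procedure was designed around are proprietary; adipoCT substitutes
deterministic classical components with the same interfaces:

* **Denoiser:** 2-D bilateral filter, spatial sigma 2.5 mm (calibrated at
  the 2-mm default grid so that 33.8 HU of noise becomes ~11-13 HU,
  matching the reported noise-reduction effect size), with an *adaptive*
  range sigma of 2.2 x the slice's estimated noise SD (Immerkaer Laplacian
  estimator, floored at 20 HU). A fixed range sigma cannot serve both the
  34 HU (5.25 mm) and 69 HU (1.25 mm) operating points - the filter
  collapses at the higher noise level. Gaussian and median filters are
  available alternatives; strength 0 is the identity.
* **Fat detection:** HU window (-190, -30), then removal of in-plane
  connected components below 9 voxels.
* **SAT/VAT split:** per slice, body = largest connected component above
  -500 HU (hole-filled); wall = non-fat-window body tissue, morphologically
  closed with a 5-mm radius and hole-filled; fat inside the closed wall is
  VAT, fat outside is SAT. Processing is slicewise (2-D), matching the
  slice-area statistic; no 3-D regularisation.

These stand-ins degrade much faster with noise than a trained network
(without denoising at 1.25 mm the split can fail grossly); the package's
claims are therefore about the *procedure* - screens, thresholds, binned
tests, limit rule - not about the performance of any particular segmenter.

## Numerical choices and degenerate inputs

* Areas are label-voxel counts x pixel spacing squared; no partial-volume
  weighting. Rasterisation tolerance is one pixel-perimeter per region.
* Labels are resampled nearest-neighbour, images bilinearly; an exact
  identity transform returns its input unchanged.
* The slice-thickness ratio in SSDE$_{5.25}$ uses the exact 1.25/5.25, not
  the rounded 1/4.
* The SSDE conversion table is generated from the published exponential fit
  $f = 3.704369\, e^{-0.01835969 (AP+LAT)}$ (cm), 16-90 cm, and verified
  against the paper-printed dose pairs (1.7 -> 1.9 mGy and 18.0 -> 20.4 mGy
  both imply AP+LAT ~ 65 cm for the same patient). Out-of-range sums raise
  an error; there is no extrapolation.
* Effective dose follows the SSDE-based convention (SSDE x length x k); a
  `ctdivol` argument switches to the conventional CTDIvol DLP.
* Empty dose bins are skipped with a message; an all-identical sample gives
  a saturated (p = 1) normal-path test rather than 0/0.
* HU are clipped to [-1024, 3071] after noise injection, so air voxels have
  slightly truncated noise; soft-tissue ROIs are unaffected.

## What a green test establishes - and what it does not

The simulation reproduces the *direction and topology* of the published
findings at the package defaults: raw low-dose SAT fails its acceptable
accuracy at 5.25 mm while denoising lifts it above; VAT passes without
denoising at 5.25 mm; SAT's fine-thickness bins fail so its limit comes
from the 5.25-mm fallback at 1.5 mGy (0.38 mSv at a 16.8-cm scan); VAT's
limit comes from the fine bins. Absolute per-bin means differ from any
clinical cohort because phantom anatomy, a threshold segmenter and white
noise are all idealisations. The end-to-end planted-threshold experiment
(a known crossing dose recovered within one bin in >= 90% of replicates)
is the package's own calibration of the limit rule, not a clinical claim.

## Known limitations

* No projection-domain physics: truncation is modelled in image space, and
  noise is uncorrelated.
* The phantom has no bone, no organs with HU inside the fat window, and no
  vertebral-level localisation; slices are statistically identical copies.
* The 1.25-mm and 5.25-mm "reconstructions" share geometry and differ only
  in noise level (and independent noise draws), whereas real thin-slice
  reconstructions differ in sampling and partial volume.
* Dose limits reported by `run_study()` inherit every stand-in above; for
  real data, replace the phantom with measured volumes and re-run only the
  metrics and statistics stages (`replay_stats()`).
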