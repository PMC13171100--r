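---
title: "duraCa: models and methods for meningeal macrophage Ca2+ imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{duraCa: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duraCa)
```

## The analysis problem

Meningeal macrophages imaged through a closed cranial window in awake,
head-fixed mice show sparse, slow intracellular Ca2+ events (dominant
spectral content well below 0.05 Hz). The pipeline in this package turns
two-channel two-photon movies (GCaMP Ca2+ channel plus an intravascular
tracer channel), a wheel-encoder velocity trace, and ROI masks into:

1. motion-corrected, temporally downsampled dF/F0 traces per cell;
2. spatiotemporally segmented Ca2+ *events* with morphology
   (area, perimeter, circularity), peak dF/F0, per-pixel onset-time maps,
   and a propagating/stationary label;
3. perivascular vs. non-perivascular niche labels per cell;
4. frequency-domain features and a k-means clustering of cell activity;
5. pairwise event-synchronization statistics;
6. a two-state locomotion decoding from wheel velocity;
7. normalized vessel-diameter traces by Radon-profile width;
8. lagged elastic-net GLMs coupling vasomotion to locomotion, and
   macrophage Ca2+ to vasomotion;
9. rule-based classification of acute and persistent Ca2+ responses to a
   cortical spreading depolarization (CSD).

Every stage is exercised against synthetic data with planted ground truth;
no raw imaging data is required anywhere in the test suite.

## Acquisition geometry and rates

All defaults reflect the acquisition this pipeline targets: 0.49 um/pixel,
15.5 Hz acquisition, analysis at 1.03 Hz after non-overlapping block
averaging with the integer block `round(15.5 / 1.03) = 15` (the effective
rate 15.5/15 ~= 1.033 Hz is recorded on the output). Block averaging is
exactly mean-preserving per pixel, which the tests check literally.

## Registration

Rigid translation is estimated per frame by phase correlation: the
normalized cross-power spectrum of frame and reference peaks at the
negative of the displacement. The reference defaults to the temporal median
image, which is robust to transient Ca2+ events; integer displacements are
recovered exactly, and an optional local matrix-DFT upsampling refines the
estimate to subpixel precision (0.5-px planted shifts are recovered within
0.1 px). Shifts are applied as rounded integer translations with
replicate padding so no interpolation smooths the data; the subpixel
estimate is still reported for QC.

## dF/F0

F0 is the 10th percentile of the cell's full-recording trace. The
percentile definition was an open choice; the full-recording percentile
keeps dF/F0 invariant to global gain and makes the baseline independent of
event timing. A sliding-window percentile (`f0Method = "sliding"`) is
available for recordings with slow drift. Cells with F0 <= 0 are excluded
and named in a message rather than silently dropped.

## Event detection

The detector is a deliberately simple, fully documented stand-in for
machine-learning event-segmentation platforms: per-pixel robust z-scores
(median and 1.4826*MAD over time), a threshold of z >= 3, 26-connected
spatiotemporal component labelling, then two hard filters taken from the
study conditions: minimum duration 1 s and a footprint size window of
523-3140 pixels (125-750 um^2 at 0.49 um/px). Durations use the inclusive
frame-span convention `(last - first + 1) / rate`; a single frame at
1.03 Hz (0.97 s) therefore fails the 1-s minimum.

Per-pixel onset is the first frame crossing 50% of that pixel's event peak
(the fraction is configurable). An event is *propagating* when the onset
map spans at least one frame of lag **and** the centroids of the
earliest- and latest-onset pixels are at least 5 um apart; degenerate maps
are stationary.

**Perimeter estimator.** Digital perimeters are biased: the raw boundary
chain of a disk converges to ~1.05x the true circumference, and the crack
boundary to 4/pi x. We measure the boundary polygon through boundary-pixel
centres, smooth it with a 5-point circular moving average, and add pi for
the half-pixel centre-to-edge offset. On digital disks circularity
`4*pi*A/P^2` then converges to 1 from above (1.01 at r = 10 px, 1.005 at
r = 100 px), and a 1x100 px rod measures within a few percent of the
closed-form rectangle perimeter 202 px. Circularity is validated against
(0, 1.15] to absorb the residual small-footprint bias; single-pixel
footprints take perimeter 4 px by convention and are flagged.

**Niche rule.** A cell is perivascular when its mask comes within 5 um of
the vessel mask (distance transform; touching counts). Manual labels can
override the rule wherever curated annotations exist.

## Spectral features and clustering

Traces are detrended by subtracting a wide Savitzky-Golay baseline
(order 2, window 301 samples ~ 5 min; wide enough that a 0.01 Hz tone
passes nearly untouched), then smoothed with the (order, window) pair
maximizing `SNR = var(filtered)/var(residual)` over orders 2-5 and odd
windows 5-101. Pairs with `order >= window - 1` reproduce the input
exactly and are excluded, otherwise the criterion would always select
them; by construction the search still favours light smoothing, which is
harmless for the downstream argmax-based features. Noiseless inputs cap
the SNR at 1e6 and flag the cell.

Dominant frequency is the periodogram argmax excluding the DC bin,
reported at bin centres (`k * rate / N`); a 900-s recording at 1.03 Hz has
bin width 1/900 Hz, putting a 0.01 Hz tone exactly on bin 9. Peaks are
counted with a topographic-prominence threshold of 10% of the signal range.

Cells are clustered by k-means on z-scored (dominant frequency, peak
count, SNR) features, 20 restarts under a fixed seed. k is chosen by the
elbow rule on the within-cluster-sum-of-squares curve: the largest k whose
second difference is a genuine elbow, i.e. strength
`d2(k)/WSS(k-1) >= 0.5`. At a true cluster count the strength is ~1
(the WSS above it collapses), while on the smooth single-blob decay
(WSS ~ k^(-2/d)) it stays near 0.2; taking the *largest* qualifying k
rather than the global argmax of d2 keeps three well-separated blobs from
being read as two. No qualifying k -- a flat curve -- returns k = 1.
Cluster-niche association uses Pearson chi-square without continuity
correction.

## Synchronization

Two events in different cells are synchronous when their `[t0, t1]`
intervals overlap after symmetric dilation by a tolerance (default 0 s --
the co-occurrence window was an open choice and is a first-class knob).
The implementation is a sorted sweep join; tests compare it exhaustively
against a brute-force O(n^2) oracle. Latency is reported as `t0_A - t0_B`
with A the lexicographically smaller cell id. Distances are
centroid-to-centroid in micrometres.

## Locomotion HMM

A two-state Gaussian-emission hidden Markov model is fitted by EM (scaled
forward-backward, k-means initialization, 5 jittered restarts, fixed seed)
on the concatenated velocity of one mouse, then each run is decoded with
Viterbi. States are relabelled so "run" always has the larger emission
mean. Bouts are maximal run-state stretches lasting at least 2 s
(inclusive; a run of n samples at rate r lasts n/r s), with edges snapped
to analysis-rate samples. Zero-variance speed traces abort with advice to
use a threshold rule: EM cannot identify two states there.

## Vessel diametry

Within an ROI, pixel intensities (after subtracting the ROI median as
background, robust while the vessel fills less than half the ROI) are
integrated parallel to the vessel axis as a function of perpendicular
offset -- a Radon projection at the axis angle. The axis angle is chosen to
maximize the projection variance, and near-isotropic ROIs error out with
advice to set the angle manually. The per-frame diameter is the full width
at half maximum of this profile with linear interpolation at the
crossings (the width fraction is configurable; FWHM is our declared
convention, as the source convention is not stated), normalized by the
frame-1 width so the series starts at exactly 1. Frames with an empty
profile are interpolated from neighbours and flagged.

## Lagged coupling GLMs

Both coupling questions use the same machinery: a design matrix with one
column per lag of the predictor over -60..+60 s at 1.03 Hz (125 columns:
round(60 * 1.03) = 62 per side plus lag 0), rows with undefined lags
trimmed. The first 75% of rows (temporally contiguous, avoiding leakage)
train a Gaussian elastic-net GLM (alpha = 0.01, ~100-value penalty path)
whose penalty is chosen by 10-fold cross-validation over contiguous
temporal blocks; deviance explained `1 - SSE/SST` is reported on the
held-out final 25%, with the null prediction being the training mean (the
null model is fit on the training block too; the exact held-out formula
was an open choice and is recorded in the fit metadata). Fits with
held-out deviance explained >= 0.1 are well-fit.

Step 1 regresses vessel diameter on the decoded locomotion state: well-fit
vessels with a negative coefficient at the largest-|coefficient| lag are
dural (constrict during running), positive are pial. Step 2 regresses
perivascular macrophage dF/F0 on dural vessel diameter and labels the
coupling sign the same way. The centre-of-mass delay
`sum(lag * |coef|) / sum(|coef|)` summarizes response timing. Sign
classification is invariant to positive rescaling of either series since
the sign is read off a single coefficient of a linear model.

## CSD response classification

Recordings are split into half-open phases anchored at the CSD time:
PreCSD (30 min), DuringCSD (1 min), PostCSD (30 min); an event at exactly
the anchor belongs to DuringCSD. Persistent classes use strict ratio
inequalities -- increased when post > 2x pre, decreased when post < 0.5x
pre, boundaries unchanged -- which extend naturally to a zero baseline
(pre = 0, post > 0 is increased; 0/0 unchanged). The acute rule defaults
to the same ratio test on the 1-min during-phase rate (one event in that
window is 1 event/min); an any-event variant is provided because, at these
baseline rates, a single event during one minute is already far above
chance. Contingency summaries report counts and one-decimal percentages;
Pearson chi-square is used when all expected counts are >= 5, Fisher's
exact test otherwise. Baseline-rate comparisons use the two-sided
Mann-Whitney U test with tie correction.

## The synthetic-data module

The generators plant exactly the structure each stage assumes:

- `makeVelocityTrace`: a Markov-switching Gaussian speed series (rest/run
  transition probabilities 0.02/0.05 per sample by default, means
  0/10 cm/s, noise 0.5 cm/s) returning both the observable speed and the
  hidden states.
- `makeCoupledDiameter`: `baseline * (1 + gain * state) + noise`; negative
  gain emulates dural constriction. With zero smoothing the noiseless
  trace dips exactly `|gain|` in every bout, which tests exploit.
- `makeCoupledCaTrace`: `gain * (lagged, mean-centred diameter) + offset`,
  rectified at zero. The offset `-min(gain * centred diameter)` makes the
  noiseless trace an exact affine image of the diameter, so rectification
  never clips the signal component, only noise excursions; this preserves
  the analytic noiseless limit (deviance explained = 1).
- `makeEventTable`: Poisson event trains per cell at the configured rate
  with morphology drawn per footprint shape (rod-shaped perivascular
  cells, rounded non-perivascular cells).
- `renderMovie`: two-channel movies; Ca2+ events follow a
  difference-of-exponentials kernel (rise 2 s, decay 8 s -- slow
  GCaMP6s-like kinetics that survive 1.03 Hz sampling; the true kinetic
  constants for these cells are unreported, so the defaults are exposed in
  the config), propagating events get a linear onset gradient at 5 um/s,
  and the vessel tube is rendered with a 1-px anti-aliased edge so that
  profile widths interpolate to subpixel accuracy. Integer per-frame
  jitter is supported so registration recovery is exact.

What the generators deliberately do **not** emulate: optics (PSF,
scattering, depth attenuation), bleaching, non-rigid tissue deformation,
spatially correlated noise, and overlapping cells. Passing tests therefore
demonstrate algorithmic correctness on data with the assumed statistical
structure, not robustness to every nuisance of real recordings.

## Problem sizes and numerical choices

The test and demonstration problem sizes are chosen to be decisive yet
desk-scale: 900-s traces at 1.03 Hz (927 samples, the scale at which the
+/-60 s lag design leaves ~700 training rows), cohorts of 86 vessels and
35 macrophages matching the analyses they mirror, 100-seed null batteries
for the well-fit threshold, and movies up to ~200x200 px. Tolerances in
tests come from the constructions themselves (exact for closed forms,
sampling-error bounds for Monte-Carlo checks). Degenerate inputs
(constant traces, all-zero movies, zero-variance speeds, empty ROIs,
all-zero coefficient vectors) raise errors or flags rather than producing
silent numbers.

## Known limitations

- The event detector is intentionally simpler than learned segmentation;
  heavily overlapping events in one cell merge into single components.
- ~1 Hz analysis cannot resolve fast Ca2+ transients; this is inherited
  from the downsampling convention, not a bug.
- The SNR-maximizing smoother-selection criterion degenerates toward light
  smoothing by construction (see above); it is kept because it is the
  declared, reproducible rule, and downstream features are insensitive
  to it.
- The co-occurrence tolerance strongly affects synchronization fractions;
  published co-activation percentages cannot be pinned down without
  knowing that window, so the package treats it as a parameter rather
  than asserting a value.

## A worked CSD example

```{r csd-demo}
out <- tempfile("duraCa_demo_")
man <- runPipeline(list(simulate = list(duration_s = 3660, n_cells = 24)),
                   outdir = out, seed = 1)
resp <- read.csv(file.path(out, "responses.csv"))
table(resp$persistent)
summ <- summarizeContingency(resp, "persistent", "niche")
summ$pooled
```

The pooled percentages above are computed by the same operation the
acceptance tests use for per-niche bookkeeping.
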