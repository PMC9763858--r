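---
title: "Counting receptor subunits and quantifying their clustering: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting receptor subunits and quantifying their clustering: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchstoich)
```

# What this package computes

Membrane receptors such as chemokine receptors assemble into oligomers, and
two complementary single-cell measurements constrain how. First,
single-molecule fluorescence imaging (Slimfield-type illumination with a
partially TIRF-coupled HILO beam) of GFP-tagged receptors records image
sequences in which each diffraction-limited focus is one assembly whose
integrated brightness is proportional to the number of GFP tags it carries.
Stepwise photobleaching then provides an internal ruler: the brightness of a
single GFP. Second, super-resolution (SIM) images of immunolabelled
receptors give the positions of receptor puncta across the membrane, whose
spatial statistics distinguish clustering from uniform or dispersed
organisation.

`patchstoich` implements both analysis branches end to end, plus a
synthetic-data generator that produces image stacks, intensity traces and
point patterns with known ground truth, so that every stage is testable
without microscope data.

# Single-molecule branch

## Detection and localization

Candidate foci are local maxima that are the strict maximum within a disk of
radius 8 px and exceed the mean of their 17 x 17 px local background window.
Candidates are searched on a matched-filtered copy of each frame (Gaussian
smoothing with the PSF sigma): for a diffraction-limited spot this is the
optimal linear detector, and it makes the candidate gate photon-limited
rather than limited by integer-count quantisation at low background.
All quantitative measurements are made on the raw frame.

Each candidate is refined by iterative Gaussian masking: the centroid is
updated to the Gaussian-weighted mean of background-subtracted pixel
positions, with the mask (sd fixed at the PSF sigma, 76.4 nm at a 180 nm
FWHM) re-centred each iteration, to a tolerance of 0.01 px (at most 50
iterations). On noiseless data this estimator agrees with a full nonlinear
least-squares Gaussian fit to better than 0.05 px (tested against that
oracle).

The local background level and noise sd are estimated per focus from a
25 x 25 px region around the seed, excluding the 8 px detection disk, with
iterated 3-sigma clipping to reject pixels lit by neighbouring spots. A
large background sample matters: the variance of the integrated intensity
contains a term `n_disk^2 * var(bg_estimate)`, which with a small background
sample would dominate and push false positives to single-GFP brightness.

The background-subtracted intensity is summed over an integration disk of
radius 6 px (about 4 PSF sigma, capturing more than 99.9 % of the spot mass
while collecting far less background noise than the full 8 px detection
disk), and

```
snr = I / (bg_sd * sqrt(n_disk))
```

with `n_disk` the integration-disk pixel count. Two acceptance gates follow:

* a width gate — foci whose second-moment width exceeds 1.8 x the nominal
  PSF sigma are rejected as not diffraction-limited (noise blobs fit to
  wide, flat profiles; true spots, even at the detection limit, stay below
  this bound);
* an SNR threshold, default 3.2. The threshold was calibrated once on blank
  synthetic frames under the default noise model so that at most one false
  positive survives per 100 blank frames, and is exposed in the
  configuration together with `calibrate_snr_threshold()` so users can
  recalibrate for their own noise model.

## Track linking

Foci in adjacent frames link when the disks of radius one PSF FWHM centred
on their centroids overlap by 75-100 % of a disk area and their intensity
ratio lies within 50-200 %. "Overlap" is interpreted as the fractional area
intersection of two equal disks; a centre-distance gate at the equivalent
distance is available (`link_mode = "distance"`). Ambiguities resolve
greedily by decreasing overlap, then intensity ratio closest to one, then
lexicographic order, so linking is fully deterministic and invariant to
input ordering. There is no gap closing: a missed detection ends the track.
Consequently track counts exceed assembly counts on long bleaching
sequences — fragments are expected and harmless, because stoichiometry uses
only tracks that start within the first 10 frames of laser exposure.

## Single-fluorophore calibration

The unitary brightness `I_1` is estimated two independent ways:

* **Modal post-bleach brightness.** Frames after "sufficient
  photobleaching" are defined as those after the summed focus intensity
  first falls below a fraction (default 5 %) of its initial value. At that
  knee the mean number of surviving fluorophores per assembly is roughly
  the fraction times the mean initial stoichiometry, so the fraction must
  stay below `1 / mean(S)` for post-knee foci to be predominantly single
  fluorophores; 5 % covers mean stoichiometries up to about 20 molecules.
  `I_1` is the mode of a KDE over the post-knee focus intensities.
* **Photobleaching step intervals.** Track intensity traces are filtered
  with the Chung-Kennedy edge-preserving filter (variance-weighted forward/
  backward window means; window 5 samples, exponent 2) and downward steps
  larger than half the current `I_1` estimate are extracted. For this
  calibration the foci are re-linked with a wide intensity-ratio gate,
  because bleaching steps larger than 50 % are exactly the transitions the
  calibration must traverse and the tracking-oriented gate would cut them.
  Step sizes are only trusted where both flanking plateaus span at least
  one filter window, plateau levels are medians of the *raw* trace (the
  filter's residual edge leakage would bias filtered-trace medians toward
  each other), and a guard band around each change point is excluded.
  `I_1` is the modal step size.

The two estimates agree to within 15 % on data matching the model
assumptions; this consistency is asserted in the test suite.

## Stoichiometry and periodicity

The initial intensity `I0` of each track is the ordinary least-squares line
through its first five focus intensities, evaluated at the first
laser-exposed frame (tracks whose early intensities rise fall back to the
mean; length-1 tracks are excluded). `S = I0 / I_1`, and only tracks
starting within the first 10 frames of exposure enter population
estimates, to avoid undercounting from photobleaching before detection.

The stoichiometry distribution is summarised by a Gaussian KDE with kernel
sd 0.6 molecules — the measurement uncertainty of a single-molecule
stoichiometry, not a statistical bandwidth.

**Periodicity** is the modal spacing between stoichiometry states; a value
near 2 indicates dimeric building blocks. Two interval definitions are
implemented:

* `kde_peaks` (default): nearest-neighbour differences between adjacent
  modes of the stoichiometry KDE — the spacings of the characteristic
  peaks of the distribution. With many tracks per state this is the
  estimator that recovers a known period: it is insensitive to how many
  tracks populate each peak.
* `raw_intervals`: nearest-neighbour differences of the sorted
  stoichiometry values themselves. When states are sampled more than once,
  these differences are dominated by within-state spacings (which shrink
  as sampling grows), so the interval mode collapses toward zero. We keep
  this form available because it is the more literal transcription of the
  procedure, but it is only meaningful when states are sparsely sampled.

The intervals are themselves summarised by a KDE (kernel sd 0.6 molecules)
and the modal peak is quoted, with standard error
`0.6 * sqrt(mean(S) / n_extrap) / n_under_peak`, where `n_extrap` is the
number of extrapolation points (5) and `n_under_peak` counts intervals
within one kernel width of the modal peak. The grouping of the error
formula is ambiguous in prose; the left-to-right reading above is the
default and the alternative (with `n_under_peak` inside the square root)
is reported as `error_alt`.

# Clustering branch

SIM z-planes can be corrected for acquisition photobleaching by fitting an
exponential decay to a reference series of repeated images and scaling
plane k by `exp(k / tau)` (`bleach_correct_zstack()`).

Puncta are binarized by the AND of a global Otsu threshold and a per-pixel
local Otsu threshold computed in a rolling disk of radius 25 px (evaluated
by quantising to 64 levels and accumulating per-level disk counts with FFT
convolutions), then components smaller than 4 px are removed. Connected
components are 8-connected. Object centroids are intensity-weighted;
circularity is `4*pi*A / P^2` with the perimeter from Moore tracing of the
outer boundary using Vossepoel-Smeulders step weights (0.980 axial, 1.406
diagonal), which is close to unbiased for smooth digitised contours (a
digitised disk measures 0.93-0.95). Discretisation can push the
circularity of small axis-aligned shapes above 1; values up to ~1.3 should
be read as "compact at the resolution limit".

Number densities use a 2D Gaussian KDE with kernel sd 180 nm (the
widefield lateral resolution), scaled to integrate to the point count and
reported per square micrometre.

**Ripley statistics.** For a pattern of n points in a region of area A,

```
K(r) = (A / n^2) * sum_i sum_{j != i} e_ij * 1(d_ij <= r)
L(r) = sqrt(K(r) / pi),   H(r) = L(r) - r
```

H is 0 under complete spatial randomness, positive for clustering,
negative for dispersion. Edge corrections: `none` (matches a brute-force
pair count exactly; used for oracle tests), `translation` (closed form,
rectangular regions), and `isotropic` (Ripley's weight `1/p_ij`, the
fraction of the circle through j centred on i that lies inside the region,
evaluated by angular sampling so arbitrary mask regions work; it agrees
with the `spatial` package's implementation to sub-nanometre level on
rectangles). The default radius grid runs from 0 to half the equivalent
region radius (at most 10 um) in 20 nm steps.

The **modal clustering gradient** is the peak of a KDE (kernel width
0.001) over the gradients between adjacent H(r) grid points, with r and H
both in micrometres so the gradient is dimensionless. Two properties
matter in practice. The statistic needs dense patterns: with fewer than a
few hundred points the pair-arrival jumps in H dominate and the mode is
noise (our CSR calibration uses patterns at SIM-like puncta densities of
~6 per square micrometre). And it is range-dependent: it reports the slope
of the flattest regime of H within the analysed radius range, so the range
must match the structure of interest — for a clustered pattern that means
radii up to the cluster scale, while beyond the cluster size the decaying
tail of H dominates and the mode turns negative even for strongly
clustered patterns.

The **nearest-neighbour distance** is the radius of the minimum of H over
the initial negative region (H equals -r below the smallest pair distance,
so every pattern starts negative, and the initial minimum marks where
pairs begin to accumulate). The initial region ends where H turns positive
for at least 5 consecutive grid points; isolated single-pair blips at very
small radii flip the sign of H without evidence of clustering and are
ignored. Per-cell estimates are noisy for weakly structured patterns;
condition-level estimates average over cells.

# Statistics

Condition comparisons use the Brunner-Munzel test of the relative effect
`P(X < Y) + 0.5 P(X = Y)` against one half, computed from pooled midranks
with the rank-based variance estimator and a t reference with Welch-type
degrees of freedom, two-sided by default. The completely degenerate case
(zero rank variance: all values tied, or complete separation) is a hard
error rather than a silent NaN; in power simulations complete separation
should be counted as a rejection. Multiple comparisons across the family
of readouts (intensity/stoichiometry, periodicity, cluster density) use a
Bonferroni-adjusted level, `alpha = 0.05 / 5 = 0.01`.
`compare_conditions()` additionally tests the stoichiometry
sub-populations below and at-or-above 15 molecules, a split at which small
and large assemblies respond differently to ligand.

# The synthetic-data generator

`simulate_assembly_stack()` renders immobile assemblies as pixel-integrated
2D Gaussians (sd = PSF sigma; 53 nm pixels and a 180 nm FWHM by default)
whose integrated intensity is (surviving molecules) x `I_1`, with
per-molecule, single-step, irreversible photobleaching at a constant
per-frame probability (geometric survival; all molecules emit in frame 0).
Noise is Poisson shot noise on signal plus background with additive
Gaussian read noise, rounded to non-negative integer counts as a camera
digitises. The default background (1 count/px) and read noise (0.5
counts) place a single GFP at an integrated SNR of ~9, consistent with an
instrument whose localization precision is ~40 nm and which resolves
single-GFP photobleaching steps; the pipeline's operating point
(calibrated SNR threshold 3.2) keeps single fluorophores detectable while
holding false positives at or below 1 per 100 blank frames.

`simulate_point_pattern()` generates homogeneous Poisson (CSR) patterns,
square lattices with isotropic Gaussian jitter whose rms displacement
defaults to half the spacing (per-axis sd `a / (2*sqrt(2))`), and
Thomas-type clustered patterns (Poisson parents, Poisson-many Gaussian
offspring). `simulate_intensity_trace()` produces piecewise-constant
traces with Gaussian noise for step-detection validation.

What the generator deliberately does not emulate: diffusing or moving
emitters, fluorophore blinking and incomplete maturation, EMCCD excess
noise, 3D PSF structure, cell-shaped regions with autofluorescence
gradients, and SIM reconstruction artefacts. Passing tests therefore
demonstrate correctness of the estimators under the stated model — not
robustness to motion blur, blinking-induced undercounting or
reconstruction artefacts, which on real data are handled by experiment
design (fixed cells, 1:1 labelling, reconstruction QC).

# Problem sizes and reproducibility

The test suite and the acceptance script exercise the full pipeline at
the scale of a complete experiment: nine synthetic cells of 256 x 256 px and 300 frames with
~50 assemblies each of true stoichiometry `2k`, k = 1..18 (about 450
tracks pooled), calibration fixtures of 25 low-stoichiometry assemblies
over 300 frames, spatial calibration over 100 CSR seeds with envelopes
from 199 simulations, and 5000-replicate type-I-error checks. Every
simulation takes an explicit integer seed; re-running any stage with the
same configuration and seed reproduces outputs byte-identically, and every
output table carries the hash of the configuration that produced it.

# Known limitations

* Stoichiometries above ~40 molecules blur into a quasi-continuum at
  kernel width 0.6; periodicity evidence comes from the resolved
  low-stoichiometry peaks.
* The modal clustering gradient is meaningful only with dense patterns and
  an analysis range matched to the structure scale (see above).
* The isotropic edge correction uses angular sampling (72 angles); for
  extreme radii relative to a very irregular mask the weight saturates at
  the sampling resolution.
* No gap closing in tracking: estimates that need long traces (step
  calibration) rely on re-linking with a relaxed ratio gate rather than on
  bridging detection dropouts.
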