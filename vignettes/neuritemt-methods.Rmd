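---
title: "Quantifying microtubule polarity and minus-end dynamics in neurites"
author: "neuritemt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microtubule polarity and minus-end dynamics in neurites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuritemt)
```

## The scientific problem

Young neurites start life with microtubules of mixed orientation and end up,
in mature axons, with almost all plus-ends pointing toward the tip
("plus-end-out").  Live imaging reads this sorting process out in two ways:

* **EB1 comets.** End-binding protein 1 forms a bright punctum on every
  growing microtubule plus-end; the travel direction of a comet therefore
  reports the orientation of its microtubule.  Classifying hundreds of comet
  trajectories per axon as tipward or somaward gives the fraction of
  plus-end-out microtubules.
* **CAMSAP/Patronin puncta.** These minus-end binders mark where microtubule
  minus-ends sit.  Whether they scatter along the shaft, pile up at the
  process tip, or stream back toward the soma after a perturbation reports on
  the machinery (cortical dynein) that clears minus-ends from the tip.

`neuritemt` implements both read-outs as a reusable, fully tested pipeline,
together with a synthetic movie generator that provides ground truth for
every stage.  Real movies of this kind are rarely shared; the generator is
therefore a first-class module, not a test fixture: it defines the study
conditions under which the pipeline's accuracy claims are made.

## The polarity classifier

The classifier is deliberately simple and mirrors standard practice:

1. **Cell center.**  Either supplied manually or estimated from a membrane
   channel: threshold at median + k·MAD, take the largest connected
   component, narrow it to its thickest core (pixels whose distance to
   background is ≥ 60% of the maximum — the soma body, which is thicker than
   any neurite), and return the intensity-weighted centroid.
2. **Segment subdivision.**  Curved trajectories are greedily split into
   approximately linear segments: a segment grows until the next step's
   bearing deviates from the segment's running mean bearing by more than
   `straightness_tol` (default 30°).  This keeps the angle measurement
   meaningful on bent neurites.
3. **Trajectory angle.**  For each segment, the angle between the outward
   radial direction (center → segment midpoint) and the segment's net
   displacement, counter-clockwise in [0°, 360°).  0° is motion straight
   away from the center.
4. **Thresholds.**  A segment is *plus-end-out* if its angle is < 70° or
   > 290°, *plus-end-in* if strictly between 110° and 250°.  The two 40°
   dead zones ([70°, 110°] and [250°, 290°], boundaries included) carry no
   label: near-perpendicular motion is ambiguous and excluded.
5. **Track label.**  Majority vote over labelled segments; ties and tracks
   with no labelled segment are excluded.

Referencing angles to the *outward radial* direction makes the printed
thresholds symmetric about the neurite axis for a radially growing process.
Excluded comets never enter a fraction's denominator: the reported
`f_out` is n_out / (n_out + n_in).  Both the per-axon average of `f_out`
(with s.d. across axons, "n axons with m comets") and the pooled fraction are
reported; which one drives downstream comparison is the
`classify.aggregation` config flag, since published bar plots are ambiguous
about the pooling convention.

Enumerating all 360 integer angles yields exactly 139 plus-end-out, 139
plus-end-in and 82 excluded — a fixed point of the threshold definition that
the test suite asserts.

## Detection and linking

The detector is a standard band-pass pipeline: difference-of-Gaussians at
the PSF scale (σ and 1.6σ), local maxima above median + k·MAD of the
filtered frame (k = 5), non-maximum suppression within 2 px, and sub-pixel
refinement by the intensity-weighted centroid of the positive band-pass
response in a window of radius 2σ.  Comet shape anisotropy is ignored:
polarity depends on displacement direction, not on comet tails.

Linking solves, per consecutive frame pair, the linear assignment problem
that minimizes total squared displacement, with a hard cutoff
`link_radius` and birth/death alternatives priced at `link_radius`².
The solver is an exact O(n³) Jonker–Volgenant/Hungarian implementation;
ties resolve to the lowest spot index, so linking is deterministic.  A
second assignment pass closes gaps of up to `max_gap` frames (cutoff scaled
by the elapsed time).  The default `link_radius` is three times the
expected per-frame comet displacement (3 × 0.15 µm/s × 2 s = 0.9 µm);
`max_gap` = 1; tracks shorter than 3 spots are dropped.  Only tracks whose
median position lies within half a neurite width of an ROI polyline are
analyzed — the process-inclusion rule — and each kept track is annotated
with its neurite.

## Minus-end read-outs

* **Tip tracking.**  Per frame, the membrane channel is thresholded at
  median + k·MAD within a corridor around the neurite ROI (k = 5 by
  default, which lands near the half-maximum of the tube profile, where a
  Gaussian-blurred edge crosses at the true boundary); the connected
  component attached to the soma end defines the neurite, and the tip is
  the maximal arc length it covers.  Frames without an attached component
  are invalid and never interpolated.
* **Growth events** are maximal runs of non-negative smoothed tip velocity
  with cumulative advance ≥ `min_growth` (1 µm).  Pauses (zero velocity) do
  not split an event; true retractions do.  This matters downstream: the
  colocalization fraction is measured over event frames, and pauses are
  exactly the frames where, under the coupling hypothesis, the punctum has
  left the tip — splitting on pauses would bias the fraction toward 1.
* **Tip colocalization** is binary per frame — is any punctum within
  `coloc_radius` (1 µm) of the tip? — averaged over event frames.
* **Tip accumulation** is the time-averaged fraction of punctum intensity
  mass within `tip_zone` (2 µm of arc length) of the tip; ≥ 0.5 calls the
  neurite *tip_accumulated*, else *scattered*.  The ratio is invariant to
  uniform intensity rescaling.
* **Retrograde clearing** seeds a cluster from the pre-treatment tip-zone
  puncta and then follows the cluster's intensity-weighted arc-length
  centroid frame by frame (each frame, puncta within `tip_zone` of the
  previous centroid).  This deliberately avoids relying on particle
  identities surviving the whole movie, which linking cannot guarantee
  when a dense cluster starts moving.  The call is positive when the
  centroid moves ≥ `min_displacement` (2 µm) toward the soma between the
  pre-treatment mean and the final frame.

None of these radii and thresholds are dictated by published protocols;
all are config-exposed, logged per run, and chosen once at scales natural
to the geometry (a ~1 µm-wide neurite imaged at 0.1 µm/px).

## Kymographs

`make_kymograph()` samples intensity by bilinear interpolation at
arc-length steps of one pixel along the ROI polyline, taking the maximum
over `width_px` (5) transverse samples — max rather than mean projection so
dim comets survive.  Sampling positions are bin centres
s_i = (i − 0.5)·L/n, which makes polyline reversal mirror the kymograph
exactly (to floating-point precision).  `kymograph_speed()` fits the
per-row intensity centroid against time; on synthetic single-comet movies
the fitted slope is within 5% of the generative speed.

## Statistics

Group comparisons use the tests conventional for this kind of data:

* **Mann–Whitney U** (two-sided) on per-axon fraction distributions.  U is
  computed from midranks.  Tie-free samples use the exact null distribution
  of U; tied samples with choose(n_a+n_b, n_a) ≤ 2×10⁵ (every split of a
  combined sample of 20) are enumerated exactly over all group assignments;
  larger samples fall back to the normal approximation with tie and
  continuity corrections, and the method used is recorded in the result.
  The two-sided p is the symmetric tail P(|U − n_a·n_b/2| ≥ observed),
  which reduces to the familiar doubled one-tail for tie-free data.
* **Fisher's exact test** (two-sided) on 2×2 phenotype count tables: the
  sum of hypergeometric probabilities of all tables with the observed
  margins no more probable than the observed one.

"95% confidence" in the conventions this package follows is interpreted as
significance at α = 0.05; no interval procedure is attached to the tests,
and no multiple-testing correction is applied (comparisons are reported
with raw p-values, one row each).

## The synthetic generator: what it emulates, and what it does not

Geometry: a soma disk (radius 2.5 µm) with neurites laid out at evenly
spaced, jittered base angles; `curvature` bends each path by a Gaussian
random walk of bearing.  Comets: born anywhere along the neurite as a
Poisson process (default 0.01 comets·µm⁻¹·s⁻¹, matching the comet
densities visible in published kymographs), plus a steady-state population
alive at frame 1; each comet is independently plus-end-out with probability
`f_plus_end_out`, moves at a constant 0.15 µm/s, and dies after an
exponential lifetime (mean 15 s) or on reaching a path end.  Movies: 31
frames at 2 s for comets; punctum movies use 60 s intervals.  Optics and
camera: isotropic Gaussian PSF (σ 0.15 µm at 0.1 µm/px), Poisson shot
noise, additive Gaussian read noise, integer counts.  SNR is defined as
comet peak amplitude over background noise s.d.; `peak_for_snr()` inverts
it.

Tip dynamics: the punctum visits the tip under a 2-state Markov chain with
stationary at-tip fraction `tip_dwell_fraction` (0.85 in `camsap_growth`,
0.3 in `eb1_like`) and mean visit length `dwell_mean_frames` (2 frames;
when the implied return rate exceeds 1 the leave rate is rescaled so the
stationary fraction is preserved exactly).  In `camsap_growth` the tip
advances by `elongation_rate × frame_interval` exactly in the frames where
the punctum sits within `coupling_radius` of the tip — total advance equals
rate × interval × number of coupled frames, an identity the tests assert.
The default elongation rate of 0.005 µm/s (0.3 µm/min) is a typical slow
neurite outgrowth speed and keeps a 16-minute movie inside a 20–25 µm path.
`tip_accumulated` parks a 4-punctum cluster at a static tip; `scattered`
places 8 puncta uniformly; `retrograde_clearing` moves the tip cluster
somaward at `clearing_speed` from `treatment_frame` on.

What the generator does **not** emulate: comet shape anisotropy and
photobleaching; out-of-focus light and 3-D optics; autofluorescent debris
and neighbouring cells; stage drift; comet pausing/catastrophe kinetics;
EMCCD excess noise.  Passing tests therefore demonstrate correctness of the
measurement machinery under a faithful but idealized image-formation model —
they do not certify performance on adversarial real data, where detector
and threshold settings would need tuning against manual annotation.

## Numerical choices and degenerate inputs

* Coordinates: 0-based pixel convention; a particle at pixel (i, j) center
  is at ((j+0.5)·px, (i+0.5)·px) µm, x = column, y = row.  All tables are
  in micrometres, never pixels.
* Movies are integer camera counts in [0, 65535], stored as 16-bit TIFF;
  round-trips are bit-exact, and calibration lives in a mandatory JSON
  sidecar (a missing sidecar is an error, never a silent default).
* Zero-length trajectory steps are absorbed during segment subdivision;
  zero net displacement of a whole segment contributes no angle; a track
  whose segments all degenerate is excluded.
* Boundary angles (exactly 70°, 110°, 250°, 290°) are excluded — the
  threshold inequalities are strict.
* Assignment ties in linking break to the lowest spot index; every stage
  consumes an explicit seed, and (config, seed) determine every output
  byte-exactly.
* Axons with zero classified comets are flagged undefined and skipped in
  aggregation; a single-axon condition reports an undefined (NA) s.d.

## Problem sizes used by the test suite and acceptance script

Polarity recovery uses 30 single-neurite cells per condition
(f ∈ {0.5, 0.8, 0.95}) at SNR 8, about 450 true comets per condition;
tracking quality uses 10 movies; colocalization uses 30 neurites per mode
at 31 frames; phenotype discrimination uses 20 neurites per mode; the
Mann–Whitney null calibration uses 1000 replicates of n = 10 vs 10.  These
sizes keep every accuracy estimate's sampling error comfortably below the
tolerance it is compared against while remaining desk-scale.

## Known limitations

* The linker has no motion model (no Kalman prediction); at comet densities
  far above the defaults, crossing trajectories in a thin neurite will
  occasionally swap, which inflates the excluded fraction before it biases
  the polarity fraction.
* Tip tracking assumes the ROI polyline traces the neurite beyond its
  maximal extent and that the neurite stays attached to the soma component;
  a fragmented membrane signal invalidates frames rather than guessing.
* `estimate_center` assumes the soma is the thickest object in the membrane
  channel; for cells whose soma leaves the field, pass a manual center.
* The statistics module implements exactly the two tests this analysis
  needs; it is not a general nonparametric toolbox.
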