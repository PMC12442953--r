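---
title: "Methods: stimulus-locked ganglion imaging, ISH alignment and reflex metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stimulus-locked ganglion imaging, ISH alignment and reflex metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dentsense)
```

`dentsense` reimplements, as a tested pipeline, the quantitative machinery
used to characterize tooth-innervating mechano-nociceptors from in vivo
trigeminal ganglion Ca²⁺ imaging, with a synthetic-data generator standing
in for raw recordings that are not publicly deposited. This vignette
records the models, the tunable parameters and their defaults, what the
generator does and does not emulate, and the numerical choices a
maintainer would want stated explicitly.

## The experimental setting being modeled

A widefield fluorescence camera images the exposed dorsal surface of the
trigeminal ganglion at 5 Hz while a molar tooth is stimulated. The
identification stimulus is a low-voltage square-pulse train (2–4 V,
0.6 Hz, 200 ms pulses, i.e. 12% duty) delivered in three independent
rounds with different cathode placements; a cell is called *intradental*
when it responds in at least 2 of the 3 rounds. Subsequent stimuli (force,
cold, enamel cutting, friction, vibration) are applied in known windows.
After imaging, the ganglion is processed for multiplexed in situ
hybridization (ISH); a sparse mCherry "guidepost" channel imaged both in
vivo and post hoc anchors the alignment between the two image spaces.
Separate experiments record the digastric electromyogram and jaw
kinematics following optogenetic activation.

## Motion correction

Frames are registered to a reference image — the mean projection of the
unregistered stack by default (robust to single-frame noise; the
protocol's reference choice is not stated), or the first frame. Each
frame passes through two stages, both minimizing the mean-squares metric
over the overlap domain with regular-step gradient descent:

1. **Translation rough pass.** Parameters start at the previous frame's
   estimate (movie motion is temporally smooth, so the warm start keeps
   the search inside the metric's capture range). Defaults: initial step
   2 px, minimum step 0.01 px, 200 iterations, relaxation 0.5.
2. **Affine fine-tune.** All six parameters, scaled so a unit optimizer
   step moves the image comparably through matrix entries and offsets
   (offset scale `1/max(H, W)`). Defaults: initial step 0.1, minimum
   step 1e-4. The coarser 0.01 minimum used for translation is far too
   coarse here — in scaled units it corresponds to a 1% scale change,
   the same magnitude as the effects being estimated.

The optimizer tracks the best-seen parameters, so the reported final
metric never exceeds the initial one; a frame whose fine-tune would
worsen the full-grid metric falls back to the identity with a warning
attached to the frame index, and the stack is never aborted. During
optimization the metric is evaluated on a strided pixel subsample (at
least ~4000 pixels); reported metrics always use the full grid.

Registration to an internal reference leaves one global translation
undetermined (the reference's own position), so recovered-vs-true shift
errors are reported after removing the common offset.

Interpolation is bilinear, with nearest-neighbour reserved for label
masks. Coordinates are 0-based (row, col) with pixel centers at integer
positions; transforms act about the image center.

## ΔF extraction and morphometrics

For each somatic ROI a neuropil annulus is constructed between Euclidean
dilations by 2 px and 8 px (defaults; the protocol says only "local"),
excluding the pixels of every somatic ROI. The trace is
`ΔF(t) = mean(soma, t) − mean(annulus, t)` per frame: a spatially uniform
contaminant cancels exactly, and a smooth one approximately. Traces are
kept in ΔF units (difference of means, matching the "20 ΔF" scale-bar
convention), not ΔF/F; the neuropil term is subtracted with factor 1.0
(no r-factor scaling — the published script's behaviour is not stated).
A cell whose annulus is emptied by the exclusions falls back to the
global out-of-ROI background mean, with a warning.

AUC is the *total* trapezoidal area (no peak detection, no thresholding)
of the normalized trace over the stimulation window, frames 40–120
(0-based, inclusive) by default — 8–24 s at 5 Hz, which makes frames
0–39 the natural pre-stimulation baseline. "Normalized" is not further
specified in the protocol; the default is ΔF/F₀ with F₀ the baseline
mean, with `baseline_z` and `none` modes provided.

Somal size is Feret's diameter: the maximum distance between boundary
pixel centers plus one pixel (measuring across pixel areas, the ImageJ
convention), times the pixel size.

## Responder classification

Electrical rounds are periodic, so detection uses the pulse-triggered
average (PTA) on `[0, 1 s]` after each pulse. Each segment is first
baselined to the mean of its two preceding frames; without this, a
slowly drifting neuropil residual shifts the whole PTA and converts
drift into spurious "entrainment" (the global baseline mean no longer
describes the trace level at stimulation time). The round is positive
when the PTA peak exceeds `threshold_sd` (default 3) baseline SDs.
Aperiodic stimuli (cutting, friction, cold, force) use a persistence
rule instead: at least `min_consecutive_frames` (default 2) consecutive
supra-threshold frames inside the known stimulation window. Thresholds,
windows and the persistence count are not stated in the protocol; the
defaults are conventional Ca²⁺-imaging practice and all are exposed in
`response_criterion()`.

Pooled proportions use all intradental cells as denominator. Integer
percentages round half away from zero; one-decimal output truncates —
that is the convention under which 22/27 prints as 81.4%.

## ISH alignment

Both guidepost images are normalized by mapping their 0.1st and 99.9th
intensity percentiles to 0 and 1 (clipped). Renormalizing a normalized
image changes values only at the ~1e-6 level (tail clipping shifts the
anchor percentiles slightly; exact idempotence would require unclipped
tails).

The initial alignment is a second-order polynomial fit (least squares on
the basis `{1, r, c, r², rc, c²}`) to at least six control-point pairs;
a rank-deficient design (points on a conic, e.g. a line) is rejected
with an explanatory error. Control points are supplied as JSON — the
original interactive picking GUI is out of scope; only the data contract
is kept.

Refinement is classic intensity-driven Demons on a Gaussian pyramid:
four levels, factor 2, iterations `[5, 1, 1, 1]` assigned coarse→fine
(the stated "decreasing iterations" fixes the otherwise ambiguous list
order). Three implementation choices matter and are the package's own:

* **Symmetric forces**: the update uses the average of the fixed and
  warped-moving gradients, `u += d·J/(|J|² + d²)` with
  `J = (∇F + ∇M∘φ)/2` — consistently more accurate than fixed-only
  forces on the synthetic pairs.
* **Fluid-like regularization**: the Gaussian smoothing (σ = 1.5 px per
  level) is applied to the incremental update rather than the
  accumulated field. Diffusion-style field smoothing erodes the
  coarse-level structure that the `[5,1,1,1]` schedule depends on, and
  measurably degrades landmark recovery.
* **Per-level trust check**: after each level the full-resolution metric
  is evaluated; a level that worsened it is reverted. This guarantees
  the recorded per-level metric sequence is non-increasing and that the
  final model never does worse than its polynomial initialization (a
  failure to improve returns the polynomial-only model with zero
  displacement and a warning).

The composed mapping is fixed-grid `p → poly(p) + disp(p)`; the ISH
stack is resampled through it channel by channel onto the fixed grid.
ROI transfer to the moving grid forward-maps 2×2-supersampled ROI pixels
with nearest-neighbour placement and fills residual rasterization holes;
transferred areas track the warp's local Jacobian up to a sub-pixel
boundary band.

Positivity is scored per cell and channel as ROI mean above the
out-of-ROI background mean plus 2 SD (the protocol scores "visible
presence of signal above background"; the 2-SD operationalization is the
package's). Efficiency is the percent of neurons carrying the reporter;
specificity the percent of reporter-positive neurons carrying the
marker, undefined (NA) when no cell is reporter-positive.

## Immune-cell fluorescence

The DAPI channel is thresholded (Otsu by default — parameter-free and
reproducible; a fixed threshold can be supplied), components smaller
than 50 px are removed, holes filled, and an optional exclusion mask
zeroes bright out-of-tissue areas; an error names whichever stage
emptied the mask. The signal channel has the scalar mean of its non-ROI
pixels subtracted everywhere; where a thresholded noise channel is
positive, its intensity is additionally subtracted (a masking mode
exists for excising those pixels instead — the protocol wording admits
both readings); the result is clamped at 0. Brightness is total
corrected fluorescence over the ROI mask divided by its area. Adding a
constant to the signal channel leaves the result unchanged up to the
clamp.

## Reflex metrics

EMG is band-passed 100–3000 Hz with a 4th-order Butterworth applied
forward-backward (zero phase; the filter family is not stated —
Butterworth filtfilt is standard EMG practice), then full-wave rectified
and leaky-integrated with τ = 0.1 s. Latency is the time from stimulus
onset to the first sample whose rectified amplitude exceeds the baseline
mean + 3 SD; the burst ends at the last supra-threshold sample before a
sub-threshold run of ≥ 5 ms; duration is end − onset; peak-to-peak is
taken on the *filtered, unrectified* trace over the burst (peak-to-peak
of an integrated trace is ill-defined). The search is capped at 100 ms
post-stimulus, generous for the 5–15 ms protective-reflex latencies.

One deliberate deviation: `reflex_metrics()` consumes a trace that is
already band-limited and does **not** re-filter internally. A zero-phase
IIR filter spreads burst energy acausally; with a noiseless baseline
(SD → machine epsilon, as the degenerate-baseline rule requires) any
near-zero threshold would fire on that pre-ringing and latency could
never be recovered to ±1 sample. The pipeline therefore filters
explicitly with `bandpass_emg()` before computing metrics, and the
synthetic bursts are generated band-limited (a half-sine-windowed tone
at the geometric band center, where the filter gain is exactly 1).

Jaw kinematics: the per-frame Euclidean distance between the two incisor
keypoints, with frame times quantized to the 10 kHz trigger clock
(nearest sample, worst-case error 0.05 ms — the sub-millisecond
alignment property). Deflection per pulse is the maximum rise of the
distance above its pre-pulse baseline mean, converted to μm via the
required pixels-per-μm scale (the conversion is rig-specific and is not
defaulted).

## The synthetic world

Each generator states the recording conditions and records every
generative value as ground truth, so every downstream number can be
checked against its cause. Conditions taken from the experimental
setting: 5 Hz acquisition, somata 7–52 μm in diameter, 18 cells per
field (within the 12–22 identified per trial), 0.6 Hz / 200 ms
three-round electrical trains starting at frame 40, 170 Hz video with a
10 kHz trigger, 0.83 mV digastric peak-to-peak, 305 μm deflection,
5–15 ms latencies. Values the source does not state are nominal choices,
made once: transient amplitude 20 ΔF with instant rise and 0.4 s
single-exponential decay (GCaMP6f-like), neuropil amplitude 10, pixel
noise SD 1, pixel size 1.625 μm (a 6.5 μm sensor behind a 4× objective).

Model specifics worth knowing:

* Somata are isotropic Gaussian blobs truncated at 2σ with σ =
  diameter/4, placed without overlap (large cells first); transients are
  added as a flat top-hat over the somatic mask, so the generative
  ROI-mean amplitude equals `transient_amplitude` exactly.
* The neuropil contaminant is a Gaussian-smoothed (σ = 30 px) random
  field standardized to spatial mean 0 / SD 1, scaled per frame by a
  slow clamped random walk. The zero spatial mean is what makes the
  per-frame scene sum conserved outside transient windows even though
  the contaminant varies in time.
* Motion is a smooth random walk clamped at ±10 px (±3° rotation for the
  affine model). The scene is rendered on a padded canvas and cropped
  after warping, so motion brings real tissue into the field of view
  rather than zero-filled borders — without this the borders dominate
  the registration metric and corrupt shift recovery.
* The ISH pair renders the scene in the moving (post hoc) frame —
  non-overlapping cells plus a smooth tissue texture — and observes the
  fixed image through the true warp (a mild quadratic polynomial
  composed with a band-limited random displacement, smoothness 20 px,
  scaled to the requested RMS). The texture gives the non-rigid
  refinement gradient information across the whole field, as real
  ganglion images do. Guideposts are laid out on a jittered golden-ratio
  lattice: control points "distributed across the full surface" are part
  of the stated protocol, and a quadratic fitted to clustered points
  extrapolates badly at the field edges. Fixed-frame coordinates come
  from fixed-point inversion of the near-identity map and are exported
  exactly consistent with it.
* EMG bursts are half-sine-windowed tones at √(100·3000) ≈ 548 Hz,
  rescaled so max − min equals the programmed peak-to-peak exactly; jaw
  deflections are trapezoids with a 10% ramp so the plateau carries the
  programmed amplitude exactly.

What the generator does **not** emulate: photon (Poisson) noise —
additive Gaussian only, a Poisson option being deliberately out of the
default path; bleaching; vascular artifacts or occlusions; non-rigid
within-movie motion; cell-to-cell amplitude heterogeneity; ISH
chemistry variability beyond a per-cell Bernoulli positivity. A green
test therefore establishes that the algorithms recover the stated
generative structure at realistic SNR — not that they are robust to
every artifact of real recordings.

## Reproducibility and budgets

All generators take explicit seeds and are bit-deterministic;
`run_pipeline()` derives per-stage sub-seeds from one master seed and
produces byte-identical reports for identical configs. The test suite
and the acceptance tests run scaled-down instances (e.g. 60–200 frames
rather than 300, 96–128 px fields) purely for runtime; each scaling is
stated where it happens. The full-size demo
(`pipeline demo`, 256×256×300) runs in a few minutes on one CPU.

## Known limitations

* The affine stage is single-resolution (a deliberate match to the
  two-stage translation+affine description); very large rotations would
  need the pyramid flag that exists but defaults off.
* Transferred ROI masks gain a sub-pixel dilation band from the forward
  splat; areas are faithful only up to ~10% plus the warp's Jacobian.
* `pool_proportions`'s truncating one-decimal mode exists to match the
  printed convention; callers wanting conventional rounding should use
  the integer mode or round the raw ratio themselves.
* The minimal TIFF reader/writer supports exactly the subset the
  pipeline emits (uncompressed little-endian grayscale, one strip per
  page, 8/16-bit unsigned or 32-bit float) — it is not a general TIFF
  library.
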