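---
title: "Models and methods behind cloudpoint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cloudpoint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cloudpoint` determines apparent protein cloud-point temperatures
(T~Cloud,app~) and ice-nucleation temperatures (T~Nuc~) from time-lapse
images of microtiter-plate wells on a cooling ramp, and ships a synthetic
plate generator whose ground truth makes every stage of that pipeline
testable. This vignette explains the models, the tunable parameters, the
numerical choices, and what the synthetic validation does and does not
demonstrate about real data.

```{r setup}
library(cloudpoint)
```

## The measurement model

A cryogenic device cools a sealed 96-well plate from 15 °C to −40 °C at a
programmed rate while a camera photographs the wells at a fixed interval.
Three per-frame statistics turn each well's image stack into a trace
aligned to the temperature log:

* **TID** (total intensity difference): the sum over pixels and channels of
  the absolute difference to the well's first frame. Clouding — the loss of
  transparency at liquid–liquid phase separation — produces a sharp rise.
* **TWP** (total white pixels): the count of pixels whose gray value
  (BT.601 luminance, rounded, as the classic `rgb2gray`) exceeds a white
  level after binarization. Five levels are supported: fixed 0.50, 0.75,
  0.85, and two data-dependent levels resolved per well from its first
  frame (its Otsu threshold, or its mean gray intensity / 255).
* **MGL/MRL/MGrL/MBL**: mean gray and per-channel levels, carried for
  comparison; their clouding signal is small (a few gray levels out of 255)
  and no event definition is attached to them here.

Event definitions on smoothed traces:

* T~Cloud,app~ from TID is the temperature at which the sharp increase
  *flattens* — where clouding is concluded. Flattening is operationalized
  as the first frame after the peak first-difference at which the first
  difference drops below `flatten_fraction` (default 0.10) of that peak.
  The fraction is a reconstruction — the qualitative notion "the increase
  flattened" admits no unique formula — so it is a configuration key and is
  recorded in run metadata.
* T~Cloud,app~ from TWP is the trace minimum (earliest frame on ties): the
  well is darkest once turbidity has removed the specular reflection.
* T~Nuc~ is the maximum TWP gradient. Freezing turns protein and buffer
  wells abruptly white (gradient up) while water wells freeze to gray ice
  (gradient down); `detect_tnuc(direction = "auto")` takes whichever
  magnitude is larger.

Reported event temperatures are **device** temperatures — the instrument's
own reading — because that is what any user of such a device obtains. The
gap between that reading and the true sample temperature is precisely what
makes the detected cloud point *apparent*; see below.

## The thermal-lag model

The sample relaxes toward the device temperature at a rate k (1/s):

$$\frac{dT_{sample}}{dt} = k\,(T_{device} - T_{sample})$$

On a linear ramp of rate r (°C/s) the solution settles at a constant offset
r/k above the device. Two consequences follow immediately and are the
package's central reproduction targets:

* faster ramps increase the offset proportionally to r, and
* larger volumes (thermal mass) decrease k, increasing the offset —

so the device-reported cloud point is depressed by r/k in both sweeps,
while detection against the sample-temperature grid shows no trend. At
nucleation the latent heat of fusion appears as an additive exponential
pulse on the sample temperature (default magnitude 5 °C, e-folding time
60 s; only the phenomenon, a transient re-warming spike, is modeled — its
parameters are free).

When k is not given it is derived from the volume as k = c/V with
c = 1/15 µL/s, calibrated so a 24 µL sample on a 0.5 °C/min ramp sits
about 3 °C above the device. This scaling is illustrative — real plates
add adapter and plate layers with their own lags, and observed deviations
reach ~7 °C — it is not a fitted thermal model.

**Integration.** Explicit Euler on the capture grid. The scheme is
monotone and accurate here because k·Δt ≪ 1 for realistic parameters
(k ≤ 0.013 1/s at 5 µL, Δt ≤ 30 s gives k·Δt ≤ 0.4); the integrator
refuses to run beyond its monotone-stability bound k·Δt ≤ 1.

## The synthetic optical model

Each well renders as a 64×64 8-bit RGB raster (achromatic by default —
every described signal is a luminance phenomenon; a `tint` option exists to
exercise the per-channel means) in three regimes:

| regime | background | specular spot | noise |
|---|---|---|---|
| clear (above T~Cloud~) | 0.45 | 0.95 over 5 % of the area | σ = `noise_sd` |
| turbid (between events) | 0.44 | removed | σ grows with depth |
| frozen (below T~Nuc~) | 0.92 protein/buffer, 0.35 water | removed | σ = `noise_sd` |

Values are intensity fractions of 255. The defaults were chosen to satisfy
three constraints that real data imposes on the *relationships* between
traces, not to mimic any specific image:

1. the mean gray level changes by only ~9 gray levels at clouding (the
   observed MGL signal is of order 1–10), so most of the TID signal comes
   from losing the bright specular reflection rather than from background
   darkening;
2. the TWP trace must have a well-defined minimum at clouding completion.
   A perfectly uniform turbid state would produce an exact-zero plateau on
   which the minimum is arbitrary; physically, the coarsening dense phase
   scatters ever more light as cooling proceeds. This is modeled as pixel
   *speckle*: in the turbid regime the noise σ is multiplied by
   1 + `speckle_gain`·depth (default 0.075/°C, saturating 20 °C below the
   transition), which slowly raises the count of stray bright pixels and
   pins the smoothed minimum at the plateau entry;
3. the resulting post-clouding TID drift must stay below the 10 %
   flattening threshold, or the TID cloud point would never be declared.

The clouding transition is rendered over a finite width (default 1 °C,
linear interpolation of the optical state) so the detectors see a ramp, not
a step; `transition_width = 0` is available for step-response tests. The
frozen state is latched at the first nucleation crossing of the
*unperturbed* lag solution — the latent-heat pulse may lift the sample
temperature back above T~Nuc~, but ice does not re-melt on a cooling ramp.
The ground-truth table records the clouding onset frame, the completion
frame (onset minus transition width — the event the detectors are defined
to report), and the latched nucleation frame, each with its device
temperature.

Noise is Gaussian per pixel, shared across channels, clipped to 0–255;
with `noise_sd = 0` rendering is fully deterministic, and all per-well
noise streams derive from the plate seed.

What the generator does **not** emulate: real well texture, menisci,
sealing-tape reflections, illumination drift, condensation, the optics of
oil-covered wells, or the heating phase. Passing the recovery tests
therefore shows that the detectors are correct *for signals with the
modeled structure* (sharp monotone events under stationary noise with a
known thermal lag); it does not certify performance on artifact-laden real
imagery, where cropping quality and illumination stability dominate.

## Numerical and design choices

**Smoothing.** Centered moving mean, window = max(1, round(fraction·n)),
truncated (not padded) at the edges; the standard fraction is 0.05 with
0.025 as the documented fallback for noisier runs. For a window of W
points the mean at frame i covers i − ⌊(W−1)/2⌋ … i + ⌊W/2⌋.

**Window-delay compensation.** A box mean has no phase delay for symmetric
features, but the events defined above are one-sided: a plateau entry (TWP
minimum) or a slope collapse (TID flattening) of the *smoothed* trace
occurs ⌊(W−1)/2⌋ frames after the underlying feature. At study-scale data
sizes this matters: 5 % of a 661-frame trace is a 33-point window, i.e.
~1.3 °C at 0.08 °C/frame — larger than the events' own detection
uncertainty. `smooth_trace()` therefore records its window geometry on the
trace, and the detectors subtract the known delay from plateau-entry and
flattening frames (diagnostics expose the frames actually used). For the
maximum-gradient event the compensation is structural instead: a one-frame
step smoothed by a W-box yields a W-frame run of near-equal gradients, and
the reported frame is the midpoint of the run within 90 % of the peak —
unbiased for the step location, exact on unsmoothed traces, and robust to
noise reordering ties.

**Noise floors.** All "absent" decisions compare against multiples
(default 5×) of the median absolute successive difference of the
*unsmoothed* trace, which `smooth_trace()` carries along. For
gradient-peak tests the floor is divided by the window, since box
smoothing divides the first difference of signal and noise alike. Flat or
featureless traces return NA rather than an arbitrary frame.

**Search restriction.** The freezing signal is far sharper than clouding,
so both cloud-point detectors accept a `search_end` and the pipeline
restricts the clouding search to frames whose smoothing window stays clear
of the detected nucleation frame. For TWP this also prevents the gray-ice
state of water wells from supplying a spurious minimum. Whether the
original minimum definition was likewise restricted is not determinable
from its one-line description; restriction is the only choice that keeps
the definition meaningful for wells that freeze.

**TID artifact guard.** TID is identically zero at the reference frame, so
the step from 0 up to the noise baseline right after t₀ looks like a sharp
increase; gradients whose smoothing window touches the first frame are
excluded from peak searches.

**TID arithmetic.** The default is the sum of absolute per-channel
differences versus frame 0 — non-negative, sign-free, and satisfying the
triangle bound used in the tests. A signed grayscale variant
(`variant = "signed_gray"`) exists for comparison with mean-level-style
analyses; the absolute form is the package's definition.

**Binarization convention.** A pixel is white iff gray/255 > level,
strictly; 8-bit values are normalized by 255 before comparison. Boundary
pixels flip between conventions (128 is white at level 0.50; 127 is not),
so the convention is fixed and documented.

**Otsu degenerate case.** A constant image has no separation; its own
normalized value is returned so blank wells do not error. Ties in the
between-class variance break toward the lower threshold.

**Quartiles and MAD.** Tukey fences use linear interpolation between order
statistics (`stats::quantile` type 7); at n = 6 the fences shift
materially between quartile conventions, so the convention is part of the
method. The MAD is unscaled (no 1.4826 factor) — a raw spread measure, not
a normal-σ estimate. Fewer than 4 replicates: no filtering, with a
warning.

**"Total" vs "average" RMSE.** Strategy comparisons report the per-series
RMSEs, their sum (the "total") and their mean (the "average"); the sum
convention is what makes a total an order of magnitude larger than the
average over ~9 series. Which series enter is the caller's grouping
choice.

**ANOVA.** `stats::oneway.test(var.equal = TRUE)` supplies the classical
F and p; the two degenerate zero-variance cases are defined (F = 0, p = 1
when groups are identical; F = ∞, p = 0 when within-variance is zero but
means differ). No significance labels are attached — values are reported,
interpretation is left to the analyst.

**Sampling plans.** Image counts use floor (unobservable on the standard
ramps, which divide exactly); reported degrees-per-image round half away
from zero to two decimals, matching the conventional 0.02/0.03/0.05/0.07/
0.08 series; interval choice minimizes |rate/60 · s − target| over the
camera's supported set {1, 5, 10, 20, 30, 60} s with ties toward the
larger interval (less data).

## Validation scale

The test suite exercises the full study geometry where it matters and
smaller fixtures elsewhere: event recovery runs 100 noisy 64×64 wells on
the 661-frame standard ramp (both strategies and both events within 0.5 °C
of ground truth in ≥95 % of wells), strategy agreement uses a 12-well
noise-free plate, the rate (0.1–0.5 °C/min at the matched camera
intervals) and volume (5–24 µL) sweeps use one noise-free well per
condition, and the brute-force oracle comparisons (Otsu, smoothing, Tukey
fences, MAD, RMSE, R², ANOVA F) run 50 random fixtures each. Unit tests
use short ramps (≈ 350–900 frames) and 16–32 px rasters.

## Known limitations

* The optical model is a stylized luminance field; parameters are stated
  defaults, not fits to any image corpus.
* The lag model is single-compartment; real setups are multi-layered
  (device → adapter → plate → sample) and their offsets need not be linear
  in volume.
* Detection covers the cooling phase only; re-melting and the heating
  phase are out of scope.
* Well cropping is assumed done: synthetic frames are single wells, and
  user imagery is read from per-well directories. Automatic plate
  registration is not provided.
* If the lagged sample never reaches T~Nuc~ before the ramp ends (fast
  rate, large volume, shallow ramp), there is no freeze to detect and the
  TWP clouding drop itself becomes the largest gradient; detections in
  that regime should be interpreted with the ground-truth table or a
  deeper ramp.
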