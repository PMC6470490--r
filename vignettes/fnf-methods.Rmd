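---
title: "Flash/no-flash compositing and color-blob detection: models and methods"
author: "pepperFNF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flash/no-flash compositing and color-blob detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The acquisition model

A scene pixel under two illuminants obeys, up to sensor clipping and
noise,

$$ I_{\text{flash}}(x) \;=\; I_{\text{ambient}}(x) + I_{\text{artificial}}(x), $$

so subtracting a no-flash (ambient-only) frame from a flash frame
recovers the scene as if lit by the artificial source alone. Three
practical complications shape the implementation:

* **Saturated pixels.** Where any flash channel reaches the sensor
  ceiling the linearity is broken and the difference is meaningless.
  Such pixels are *excluded from subtraction*: `composeFNF()` passes the
  flash value through unchanged. We prefer passthrough over zeroing
  because it keeps overexposed fruit visible to the detector rather than
  punching black holes into it; the pixel's color is still tainted by
  ambient light, which is the physically honest outcome. A pixel counts
  as saturated when *any* channel is at or above `saturationLevel`
  (default 255), the conservative choice — partial clipping already
  distorts hue.
* **Negative differences.** Noise makes `flash − noflash` dip below zero
  on dark pixels; results are clamped at 0 so the composite is a valid
  8-bit image.
* **Pair identification.** The camera alternates the LED trigger, but
  dropped frames and variable frame rate can desynchronize the stream.
  `scanStream()` compares the mean brightness of consecutive frames and
  accepts a pair only when the difference *strictly exceeds*
  `brightnessDeltaThreshold` (default 10 mean-intensity units; the
  field-calibrated value of the original rig is unpublished, so the
  default is deliberately conservative and exposed in the config) and
  the brighter frame comes first — the rig fires on the first frame of
  each pair, so a dark-to-bright transition spans two different pairs.
  A delta exactly at the threshold is rejected (strict inequality).

## The detector

`detectPeppers()` chains five stages, all parameterized by
`DetectorParams`:

| parameter | default | unit | rationale |
|---|---|---|---|
| `hueMin`, `hueMax` | 20, 50 | degrees | ripe-yellow band, inclusive at both ends |
| `satMin`, `satMax` | 90, 255 | 8-bit saturation | rejects washed-out background |
| `minAreaRef` | 400 | px at 320×240 | suppresses speckle; scales ∝ pixel count at other resolutions |
| `morphCloseSize` | 5 | px (square element) | bridges specular holes and thin occlusions |
| `connectivity` | 8 | — | merges diagonally touching fruit pixels |

The value channel is deliberately unconstrained: on a composite,
distance alone darkens out-of-range objects, and the original threshold
set bounds only hue and saturation.

Morphological cleanup is closing followed by hole filling (via
*EBImage*). The operators behind the published system are not specified
anywhere; closing is chosen because it reproduces the documented
behavior that adjacent fruit merge into a single blob. Connected
components are labeled through an adjacency graph handed to *igraph*;
components are reported in raster-scan order of their first pixel so
detection lists are deterministic.

`calibrateThresholds()` replaces the original interactive calibration
(a human adjusting sliders over 3 sample images) with a reproducible
rule: hue band = 1st–99th percentile of hue over the labeled fruit
pixels, widened outward by one whole degree; saturation floor = 1st
percentile; ceiling stays 255. This keeps the attractive property that
adapting to a new cultivar or greenhouse needs only a handful of labeled
frames.

## The evaluation protocol

Matching uses the bounding-box overlap ratio (intersection over union)
with a 50 % criterion. Because no matching algorithm is prescribed for
the original protocol, we match greedily by descending overlap with ties
broken by (truth index, detection index); greedy matching is exact here
because every candidate pair already exceeds the threshold and each side
may be used once.

Matched pairs are classified by the truth's maturity into the six-way
taxonomy: TP (mature), FP2 (partially mature detected as mature — a TP
under the *flexible* scheme), FP1 (immature detected), DC (distant,
out-of-range fruit — ignored entirely), FP (no fruit at the detected
location), FN (countable fruit missed). Precision and recall fold FP1
and FP2 into the false positives; DC never enters either measure. A
zero denominator yields an explicit `NA`, never 0 or 1.

**Cluster credit.** Harvesters re-detect continuously while approaching
the target (visual servoing), so a cluster of fruit merged into one blob
is not a practical miss. The second measure counts every labeled fruit
with at least `containmentThreshold` (default 50 %) of its pixels inside
a single detection blob as detected. A detection covering only
non-countable truths is classified by its best-covered truth; one
covering nothing is a plain FP.

Hue/saturation stability statistics (`labeledPixelStats`) collect all
labeled ripe-fruit pixels, normalize hue by 1/360 and saturation by
1/255, and report population standard deviations and 100-bin histograms.
Hue is treated as linear on [0, 1]: yellow fruit sits far from the
wrap point, and the printed magnitudes of the original comparison are
only consistent with a linear [0, 1] normalization.

## The scene simulator

The generator exists so that every claim above is testable without the
field database. It emulates the acquisition *physics* the method relies
on, not photorealism:

* fruit and leaves are depth-ordered ellipses; reflectance hue encodes
  maturity (ripe ≈ 35°, immature ≈ 100°, partial maturity as a hue
  gradient along the fruit axis whose mature fraction is the maturity
  level, drawn U(0.5, 0.95) — fruit with less color break would be
  labeled immature by a grower);
* the flash term is exactly inverse-square in depth. Flash power
  defaults to 0.018 m², placing the nearest working distance (0.17 m) at
  ~60 % of full scale — a rig tuned this way leaves headroom so moderate
  ambient light does not immediately saturate the flash frame;
* ambient light = intensity × frame gradient × per-object directional
  shading × per-channel tint, plus an illuminant-colored specular lobe
  on each fruit (waxy skin reflecting the sky/sun). All ambient terms
  are linear, so the noiseless unclipped composite is exactly invariant
  to them — the core claim, testable to ±1 intensity unit of rounding.
  The flash's own centered specular lobe survives in the composite, as
  it does in reality;
* `ambientIntensity` is expressed against a quarter-scale reference
  exposure: 1.0 lights a perfect reflector to 25 % of full scale, so the
  default scene-to-scene range 0.2–2.0 spans dusk to strong daylight at
  a short exposure, and clipping (with its hue corruption) appears on
  the sun-lit side of fruit in the strongest scenes rather than
  everywhere. Tints are mean-normalized so they carry chromaticity only;
* sensor noise is additive Gaussian per channel (σ = 0.5 DN, read noise
  below the 8-bit quantization step, as for an industrial sensor at base
  gain), applied independently to both frames before clipping and
  rounding;
* the background plane sits at 2.5 m (the adjacent crop row), where the
  flash term rounds to zero; fruit beyond 0.6 m is labeled *distant*
  and, receiving flash below the detector's saturation threshold, stays
  dark and small enough for the minimum-size filter;
* scenes hold 1–4 fruit (clusters with probability 0.3), 0–2 occluding
  leaves placed just in front of an anchor fruit, at working depths
  0.17–0.26 m.

What the simulator does **not** model: real fruit shape and texture,
specular highlights on leaves, inter-reflections, motion between the
two frames, rolling-shutter artifacts, and the LED rig's spectral or
vignetting profile. Passing tests therefore demonstrate the
correctness of the algorithms and the direction and rough magnitude of
the illumination-invariance effect, not field performance figures.

## Numerical and interface choices

* Bounding boxes are 0-based half-open `(x0, y0, x1, y1)` throughout,
  including JSON serialization; frame indices from `scanStream()` are
  1-based, following R convention.
* Thresholds written in fractional notation (20/360, 90/255) in a YAML
  config are rescaled at the config boundary; internally hue is always
  degrees and saturation 8-bit.
* Degenerate inputs fail loudly: zero-area boxes in `boxIoU`, empty
  calibration masks, unlabeled scenes in `evaluateDataset` (the error
  names the scene), unknown YAML keys, unmapped label codes.
* All randomness is seed-scoped (`rngSeed` per scene, per-scene seeds
  derived from one master seed by a fixed linear-congruential step) and
  the caller's RNG state is restored; dataset generation is
  byte-reproducible.
* The per-object masks needed by cluster credit cannot be reconstructed
  from the class-label raster when same-class fruit touch, so scene
  directories carry an `instances.png` id raster next to `labels.png`.

## Problem sizes

The test suite and the acceptance script work at deliberately modest
sizes: 50 simulated 320×240 scenes for the dataset-level claims
(detection precision/recall ≥ 0.90 under the flexible cluster-credit
scheme on composites; composite hue std below half the flash-only hue
std), 20 scenes for the simulator/compositor consistency check, 1 000
random 32×32 pairs for the compositing oracle, and 100 random 32×32
masks per connectivity for the component-labeling oracle. The full
suite runs in about one minute on a single CPU.

## Known limitations

Clipped (saturated) pixels remain the method's blind spot: their color
is ambient-contaminated in the composite too, and with the value channel
unconstrained, a heavily overexposed non-fruit region with an in-band
hue would be detected. The detector inherits every bias of a pure color
threshold — camouflaged (immature) fruit is invisible by design and
counted accordingly. The evaluation's greedy matching can differ from
optimal assignment when detections overlap several truths near the
50 % criterion; ties are broken deterministically so results are at
least reproducible.
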