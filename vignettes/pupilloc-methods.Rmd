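---
title: "Pupil localisation by adaptive-kernel template matching: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pupil localisation by adaptive-kernel template matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilloc)
```

## The problem and the model

Pupil-centre localisation gets hard exactly where it matters most: eye
frames cropped from ordinary face images are often only 20–80 px wide, and
illumination, gaze direction and sensor noise vary from frame to frame.
Global appearance models and intensity thresholds degrade badly in this
regime; static-size templates either latch onto noise (too small) or smear
across the frame (too large).

`pupilloc` implements a coarse-to-fine template-matching localiser that
leans on two robust geometric facts: the iris is approximately circular and
dark against the sclera, and the pupil is its darkest part. The search is
decomposed into two one-dimensional cascades:

* a **horizontal pass** over the full-height eye frame *E* that finds the
  iris column position R~x~,
* a **vertical pass** restricted to the iris rectangle *I* (the
  kernel-width strip at R~x~) that finds the pupil row position R~y~.

Each pass slides an adaptively resized iris template *K* with a 1-pixel
stride along its one axis only — there is no nested 2D sliding — and scores
every overlap with the normalised correlation coefficient

$$S = \frac{\sum_{x',y'} K'(x',y')\,E'(x+x',y+y')}
{\sqrt{\sum K'^2 \cdot \sum E'^2}},$$

with $K'$, $E'$ the mean-centred template and patch. Mean-centring makes the
score a true correlation coefficient in $[-1, 1]$, invariant to positive
affine changes of either input — so a darker image or a global illumination
shift does not move the estimate. The un-centred variant is available via
`localiser_config(centred = FALSE)` for comparison, but the centred form is
the default precisely because of that invariance.

Instead of taking the single arg-max — which is brittle in low resolution,
where local maxima abound — each pass computes a **dynamic threshold**: the
90th percentile of its score vector. All positions scoring strictly above it
become candidates, and their mean coordinate (rounded half-to-even) gives
R~x~ or R~y~. The centre is then the rectangle midpoint,
$C_x = R_x + \lfloor w_k/2\rfloor$, $C_y = R_y + \lfloor h_k/2\rfloor$.

Before each pass the frame is padded with a **white rim** (255) of half the
kernel extent along the stride axis — the smallest rim that lets the kernel
centre reach the frame edges. Without it, an iris at an extreme left/right
gaze position could never be the centre of any full overlap; with it, rim
positions compete on equal terms. White is the right padding colour because
it matches the template's own light field, so a rim match is rewarded
rather than penalised.

## Parameters

| parameter | default | units | why |
|---|---|---|---|
| `width_fraction` | 0.4 | fraction of eye-frame width | iris diameter is ≈ 0.4 of the corner-to-corner eye-frame width in typical face imagery; a kernel at this width straddles the iris without smearing across the whole frame |
| `height_fraction` | 0.4 | fraction of iris-rectangle height | same reasoning vertically: the squashed kernel brackets the dark core where the pupil sits |
| `quantile` | 90 | percentile | keeps roughly the top tenth of stride positions; low enough to average out single-position noise, high enough to stay on the main peak |
| `centred` | TRUE | — | mean-centred correlation; see above |
| crop `margin` | 0 | px | eye frames are the exact landmark bounding boxes; a margin is configurable because some annotation conventions place corners conservatively |

The percentile uses linear interpolation between order statistics
(`quantile type 7`), and candidates must be **strictly** greater than the
threshold. When every score ties (e.g. a blank frame region), the fallback
candidate set is all positions attaining the maximum, so aggregation never
sees an empty set. Zero-variance patches — which the white rim produces by
construction — score 0 rather than raising, and only a fully constant eye
frame is an error (`pupilloc_localisation_error`).

The default template is an analytic dark disc (intensity 20, diameter
0.9 × min dimension, on a 235 field). `build_custom_kernel()` instead
averages user-supplied iris patches (each bilinearly resized to the
element-wise median patch size, then pixel-wise averaged and rounded),
which generalises better across iris colour and texture when example
patches are available; the analytic disc is the default because it requires
no data and captures the geometry the method actually uses.

## The synthetic generator

`render_eye()` draws, in order: sclera background, iris disc, concentric
pupil disc, an optional eyelid band from the top, an additive horizontal
illumination ramp, and Gaussian noise clipped to [0, 255]. Discs are
rasterised by centre-of-pixel inclusion (a pixel belongs to a disc iff its
centre is within the radius) — an unambiguous rule that makes ground truth
exact. Noise is applied last and clipped, not wrapped, mimicking sensor
saturation. Rendering is bit-reproducible given the spec (the seed is part
of the spec).

The default sampling distribution spans the low-resolution regime the
method targets: frame width uniform on 24–80 px at 2.5:1 aspect, iris
radius 0.12–0.22 × width, gaze offset uniform over the visible span (the
disc stays inside the left/right edges, down to tangency), pupil radius
0.4 × iris radius (mid human range), noise sigma uniform on 0–10 and
gradient amplitude 0–20 intensity units, with intensity orderings
pupil ≤ iris < sclera enforced. `render_face_mock()` composes two rendered
eye regions at a fixed 100 px interocular distance into a skin-toned frame
with 68-point-style landmarks and a rigid per-face position jitter (±15 px),
because head position varies between frames in real footage — without that
variation, per-axis R² against truth would be computed on a near-constant
series and be meaningless.

What the generator does **not** emulate: iris texture, specular glints,
eyelashes, skin around the frame interior, motion blur, compression
artefacts, or correlated (non-Gaussian) sensor noise. Passing tests
therefore demonstrate that the implementation realises the method correctly
and that the method's geometry works at these scales — not that real-world
benchmark accuracy is attained; for that, run `detect`/`eval` on a real
annotated dataset.

## Evaluation metrics

* **wec / bec**: worst (max) and best (min) of the two per-eye Euclidean
  errors divided by the interocular distance. Scale-free across images;
  wec ≤ 0.05 corresponds roughly to an estimate within the pupil diameter
  and wec ≤ 0.1 within the iris. Accuracy curves count frames with error ≤ t
  (inclusive) across thresholds.
* **S_ED**: per-eye error as a percentage of the eye frame's diagonal —
  the largest error the frame geometry permits. It needs no second eye and
  is invariant to uniform scaling and translation, so it compares fairly
  across resolutions. The geometry used is the same crop the eye frame came
  from.
* **Per-axis MAE and R²**: R² is computed as $1 - SS_{res}/SS_{tot}$ of the
  estimates against the actual series directly (no refitted regression
  line), so a constant offset costs R² rather than being absorbed. A
  zero-variance actual series leaves R² undefined (`NA`). Per-axis
  aggregates pool both eyes; wec/bec are per frame. This pooling choice is
  recorded in the report metadata.

## Numerical choices and degenerate inputs

* Adapted kernel dimensions round half-up and clamp to ≥ 1 px; candidate
  means round half-to-even (bias-free ties); the centre formula uses floored
  halves. All outputs are integer pixel coordinates in a 0-based,
  x-rightward, y-downward convention used everywhere in the package.
* Bilinear resampling (via EBImage) handles all kernel resizing, up or
  down. Resizing to the kernel's own size is exactly the identity. One
  mathematically unavoidable corner: downsampling the centrally symmetric
  disc template to 2×2 yields four equal samples under *any* symmetric
  interpolation scheme; the kernel constructor rejects that degenerate
  (constant) template with a classed error rather than returning it. At
  every practical size (≥ 3 px) non-constancy is preserved.
* A rim match can place the iris rectangle partly outside the frame; the
  rectangle is clipped, and the vertical-pass kernel follows the clipped
  width. The centre formula still uses the unclipped kernel width, then
  clamps into the frame.

## Behaviour at extreme gaze, and a known limitation

The white rim exists for extreme left/right gaze. Across the generator's
distribution with the disc tangent to a frame edge (centre one iris radius
from the edge — the extreme of the visible gaze span), noiseless recovery
within 2 px succeeds in ≈ 95% of frames; the residual failures are frames
whose iris diameter exceeds the frame height, where the vertical strip is
dark nearly everywhere and the vertical score profile carries little
information (see below).

Template matching fundamentally estimates the position of the *visible*
dark mass. If the disc is pushed past tangency so that the frame edge clips
it, the matching peak shifts toward the visible centroid and, for a
half-clipped disc, the estimate can be several pixels inside the true
centre — this is a property of the estimator, verified against a literal
stride-by-stride scoring oracle, not an implementation artefact. The same
applies vertically: when the iris is taller than the frame and sits
off-centre, the visible mass midpoint is displaced from the true centre and
the vertical estimate inherits part of that displacement. Applications that
need unbiased centres for heavily clipped irises should treat such frames
the way closed or half-closed eyes are treated: filter them upstream, or
fit an explicit clipped-disc model, which is outside this package's scope.

## Problem sizes used in the bundled checks

The test suite and `scripts/acceptance.R` use 50 frames (≤ 64×32 px)
for oracle agreement, 200 generator-distribution frames for centre
recovery, 50 two-eye mock faces for the interocular-normalised metrics and
100 noiseless renders for the extreme-gaze check — sizes at which the
sampling error of the reported rates is a few percent, which is adequate
for the pass/fail bands being checked, while a full run stays interactive.
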