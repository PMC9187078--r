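---
title: "Topographic severity mapping for colon capsule endoscopy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topographic severity mapping for colon capsule endoscopy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccemap)
```

## The problem

Ulcerative colitis (UC) is a diffuse, chronic inflammation of the colonic
mucosa whose endoscopic activity is conventionally graded with the Mayo
endoscopic subscore (MES, 0–3). Second-generation colon capsule endoscopy
(CCE-2) records the whole colorectum non-invasively with two cameras
(forward and backward), producing hundreds of 576×576-pixel still pictures
per examination — far too many for routine expert reading, and with severity
that often varies *within* a single frame during the resolution phase of the
disease.

`ccemap` implements an automated pipeline that grades severity at
sub-frame resolution and aggregates it into a positional, per-segment
**topographic map** of disease activity:

1. **Tiling.** Each still is tiled into overlapping 128×128 patches at a
   32-pixel stride over the effective (optical) region — 225 windows for a
   full 576×576 frame.
2. **Exclusion.** Patches that are uninterpretable are removed by exact
   intensity rules: a patch is a *blackout* when more than 1% of its pixels
   have intensity below 70, and *overexposed* when more than 5% are above
   230 (strict inequalities on the Rec.601 luma; at 16384 pixels per patch
   the rules flip exactly at 164 dark and 820 bright pixels).
3. **Classification.** Each remaining patch is assigned one of six
   categories: MES0, MES1, MES2, MES3, inadequate quality, or ileal mucosa.
   White scars and inflammatory polyps count as MES0 (inactive findings).
4. **Severity profile.** For one still, the class-k area is the *pixel
   union* of all windows labelled k, so overlapping same-class windows are
   not double-counted:
   areaₖ = |S₁ ∪ S₂ ∪ … ∪ Sₙ|, total = area₀+area₁+area₂+area₃, and the
   still's profile is the stacked fractions areaₖ/total. A still whose
   total is zero (only inadequate/ileal patches) is excluded and appears as
   a blank column.
5. **Topographic map.** Profiles are ordered per camera along the four
   colorectal segments (cecum+ascending → transverse → descending+sigmoid →
   rectum) and rendered as a serial stacked-bar figure (MES0 light gray,
   MES1 yellow, MES2 magenta, MES3 red).

## Contracts and numerical choices

**Tiling geometry.** Windows are half-open `[r, r+128) × [c, c+128)` with
0-based offsets; enumeration is left-to-right, then top-to-bottom. The count
per axis is `floor((dim − 128)/32) + 1`. The suite checks `tile_grid()`
against a brute-force enumeration on 1000 random geometries.

**Intensity channel.** The exclusion thresholds are applied to the Rec.601
luma (0.299 R + 0.587 G + 0.114 B, rounded), the standard single-channel
reading of "intensity" for RGB frames; `exclusion_rule(channel=)` exposes the
single-colour channels for sensitivity analyses. Thresholds are strict
(`< 70`, `> 230`, share strictly greater than the cut) and the boundary
cases are unit-tested explicitly.

**Mask participation.** A patch must lie entirely inside the effective
region (`min_inside = 1`); the knob exists because partial-overlap policies
are a genuine design freedom, but full inclusion is the default and the only
tested mode. The effective-region mask itself is estimated by labelling
near-black (luma < 30) connected components touching the image corners and
taking their complement; degenerate frames (no dark corners, or entirely
dark) fall back to an all-true mask and rely on patch-level exclusion. A
user-supplied mask file always overrides estimation.

**Cross-class overlap.** The total area is the *sum* of the four per-class
unions, not the union of unions: a pixel covered by both an MES0 window and
an MES1 window contributes to both area₀ and area₁. This is the literal
reading of the definition above, and it is what the implementation does; an
"exclusive assignment" mode is deliberately out of scope. Union areas are
computed exactly by a scanline interval sweep (integer arithmetic); the test
suite cross-checks 1000 random grids against an independent boolean-canvas
rasterization.

**Rounding.** Reported accuracies use half-up rounding to 3 decimals;
exported severity percentages use half-up to 1 decimal. Rows of the percent
table may sum to 99.9 or 100.1; raw fractions are exported alongside, so
nothing is lost.

**Ordering and blanks.** Map assembly is order-independent in its input and
stable in its output; duplicate (camera, segment, index) positions are an
error. Excluded stills keep their position and render as blank, full-width
columns so the x-axis remains a faithful positional axis along the colon.
Whether serial position should encode transit time instead of still index is
unknowable from the inputs; still index is used.

## The classifier interface

Classification is pluggable behind `predict_patches()`: a model handle maps
patches to six scores summing to 1; the label is the argmax with ties broken
to the lowest class index.

Two handles are provided:

* **Oracle** (`make_oracle_classifier()`): decodes the synthetic texture
  signature (below) by per-pixel nearest-offset assignment and majority
  vote. It exists so the severity and mapping stages can be verified
  end-to-end with exactly known ground truth. Patches in which fewer than
  half the pixels carry a decodable signature fall back to *inadequate*
  with a warning.
* **Trainable** (`train_classifier()`): a compact feed-forward network —
  bilinear resize to 224×224, scale to [0,1], 8×8 per-channel average
  pooling (192 features), one ReLU hidden layer (64 units), softmax output —
  trained with minibatch Adam on the cross-entropy loss. Defaults follow the
  conventional recipe for this task family: Adam, learning rate 2.5e-4,
  50 epochs, batch size 256, six output classes, 224-pixel input. Training
  is bit-deterministic for a fixed seed and fixed data ordering, logs loss
  and accuracy per epoch, and refuses single-class data. Class imbalance is
  not reweighted by default; inverse-frequency weights sit behind
  `class_weights = "inverse-frequency"`.

The bundled network is intentionally small: it is the reference
implementation of the training contract and a benchmark vehicle, not a
clinical-grade model. Deep CNN backbones (and any reproduction of
clinically trained weights, which require patient videos) are out of scope;
users with such a model can wrap it in a handle honouring the predict
contract and reuse every downstream stage unchanged.

**Preprocessing note.** Resize interpolation is bilinear and input
normalization is plain scale-to-[0,1]; both are recorded in the model handle
so predictions are self-describing.

## The synthetic-study generator

Clinical capsule images cannot ship with a package, so `ccemap` generates
stills whose ground truth is known by construction:

* **Texture signature.** A pixel of class *k* is painted `R = g + δₖ`,
  `G = g`, `B = g − δₖ` with class offsets δ = (−25, −15, −5, 5, 15, 25) and
  a shared luminance field `g` (base 150, a 32-pixel-period ripple of
  amplitude 12, clamped Gaussian noise of σ = 3). The 32-pixel period means
  every stride-aligned window sees the same phase; offsets are 10 apart
  while the per-pixel decoding tolerance is 4, so decoding is reliable but
  the trainable network still has a non-trivial (easy) learning task.
  Channel values stay within [72, 228], so clean textures can never trip
  the intensity exclusion rules.
* **Defects.** Blackout regions are painted gray in [0, 30] and overexposed
  regions in [240, 255] (achromatic, hence carrying no class signature), so
  generated defects always trigger the intended exclusion rule — a
  self-consistency the suite asserts.
* **Field of view.** An optional circular disc; outside is black. The mask
  estimator recovers a radius-280 disc with Jaccard overlap > 0.98.
* **Scripted studies.** `generate_study()` paints each scripted still as
  vertical class strips with widths proportional to the target fractions
  (stills scripted "excluded" are painted entirely with the
  inadequate-quality texture). Scripted studies default to full-frame
  geometry (no FOV disc): the scripted-recovery guarantee is about patch
  quantisation, and a disc would convolve it with boundary effects that the
  FOV-specific tests already cover separately.

**Quantisation tolerance ±0.05.** With a 32-pixel stride, a class boundary
can shift each class's window union by up to ±64 pixels (half a window on
either side, plus the tie rule), i.e. roughly 64/576 ≈ 0.11 of one axis
split across the two adjacent classes — in practice at most ≈ 0.05 of the
per-still fraction for axis-aligned strip layouts, which is the tolerance
the end-to-end recovery tests assert (observed maximum error ≈ 0.042).

**What passing tests do and do not show.** The generator emulates geometry
(patch grids, unions, FOV, defects) and the label-to-severity arithmetic
exactly, but its textures are nothing like mucosa: no vascular patterns,
erosions, residue, bubbles or motion blur, no correlation between
neighbouring stills, no class imbalance. Green end-to-end tests therefore
validate the *pipeline machinery*, not classification performance on real
capsule images.

## Evaluation module and the packaged reference tables

`confusion_matrix()`, `per_class_accuracy()`, `overall_accuracy()` and
`composition_report()` implement the evaluation bookkeeping for a six-class
classifier. The package ships two plain-CSV fixtures from the published
clinical validation of this pipeline design: the 6×6 validation confusion
matrix and the per-class training/validation composition. The suite
recomputes from them, exactly: overall validation accuracy 0.983 (251126 of
255377), per-class accuracies 0.994 / 0.948 / 0.913 / 0.952 / 0.986 / 0.892,
grand total 739021 patch images, training total 483644, validation total
255377, and the 52.4% inadequate-quality share — and checks that the
confusion-matrix row sums equal the composition's validation column. (The
published abstract quotes 0.973 for validation overall; the results tables
give 0.983, and the fixtures follow the tables.) The training-data confusion
matrix was published only as supplementary material and is not fabricated
here; only the validation matrix ships.

## Problem sizes used by the default runs

Chosen so a full check runs comfortably on a laptop core: the geometry
oracles use 1000 random cases each; the end-to-end recovery study is 4
segments × 2 cameras × 2 stills (16 stills, 3600 windows); the training
benchmark is 3000/600 patches at ≤10 epochs with batch size 32 — roughly
940 Adam steps, at which the run is fully converged (batch 64 at the same
epoch cap is only marginally converged and noticeably seed-dependent, which
is why the benchmark fixes 32).

## Known limitations

* MPEG capsule videos must be decoded to frames upstream;
  `extract_stills()` consumes frame sequences (lists of arrays or image
  files) and applies the uniform endpoint-inclusive sampling rule
  `round(i·(L−1)/(n−1))`. How the 50 stills per segment are best chosen from
  a real recording is an open question; uniform sampling is the
  least-assumption default.
* The segment partition is taken as a declarative manifest (the
  human-in-the-loop step of a capsule study), not inferred from telemetry.
* The bundled trainable classifier is a benchmark-scale network; clinical
  use requires an externally trained model wrapped in the predict contract.
* Severity fractions are geometric statistics of patch labels; they inherit
  any classifier bias, and the cross-class overlap convention (sum of
  unions) can make the total exceed the physically covered area when grades
  mix within an overlap.
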