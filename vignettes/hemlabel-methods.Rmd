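---
title: "Molecular label transfer from IHC to H&E: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular label transfer from IHC to H&E: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Training a tile classifier for cancer detection on H&E histology normally
requires pathologist annotations, which are slow to obtain, coarse, and
variable between observers. When an adjacent section of the same tissue
block has been stained by immunohistochemistry (IHC) with a cancer-specific
marker — here p53, visualized by brown DAB deposition — the IHC stain
itself can label the H&E image at pixel resolution. `hemlabel` implements
that label-transfer pipeline: stain-normalize the H&E slides, register the
IHC image onto its H&E partner, threshold the DAB signal into a
cancer-positive mask, transfer the mask into tile-level labels, train a
transfer-learning tile classifier on those labels, and summarize
predictions as a tissue-area-weighted tumor-purity estimate per slide.

## The model, stage by stage

### Stain normalization

Stains mix additively in optical density (Beer–Lambert). With
`od = -log10(max(I, 1) / I0)` per channel (`I0 = 255` after luminosity
standardization), an H&E image factorizes as `OD = C S`, where the rows of
the 2×3 matrix `S` are unit-norm stain color vectors and `C` holds
per-pixel stain concentrations. A slide is re-colored to a template by
estimating its own `S`, solving the non-negative least-squares problem for
`C`, rescaling each concentration channel so its 99th percentile matches
the template's, and reconstructing with the template's `S`.

Two estimators for `S` are provided. Macenko: SVD of the tissue OD cloud,
stain vectors at the 1st/99th percentile angles in the leading plane.
Vahadane (default): sparse non-negative dictionary learning with two atoms,
alternating exact NNLS steps with an L1 penalty (`lambda = 0.1`) on the
concentrations, initialized from the Macenko estimate. The dictionary fit
runs internally on natural-log OD, the scale that `lambda = 0.1` is
conventionally calibrated for; stain directions are unaffected by the
scale change. Reinhard normalization (per-channel mean/sd matching in
CIELAB) is available as a simpler alternative.

Pixels enter the stain fit when their mean OD across channels exceeds
`beta = 0.15`. A per-channel cutoff would silently drop eosin-dominant
pixels — eosin barely absorbs red light — and make the eosin direction
unidentifiable. For the same physical reason the hematoxylin row is
identified as the vector with the larger red/green OD ratio: hematoxylin
absorbs red and green about equally, eosin absorbs green but almost no
red. Red/blue is not a reliable discriminant once stain colors vary.

The template is the cancer-status slide whose mean (R, G, B) vector is
closest to the componentwise median of all slides' mean vectors; ties go
to the lowest index.

### Registration

Both images are converted to Rec. 601 grayscale and reduced by block
averaging to the working scale (default 1/5; user-adjustable). An affine
transform, then optionally a cubic B-spline free-form deformation, is
fitted by maximizing the mutual information (natural log, 50-bin joint
histogram, each image binned over its own range) through a
multi-resolution pyramid (shrink 4/2/1, levels dropped below 32 px). Only
the IHC image is ever resampled; out-of-field pixels are filled white, and
the final transform is applied identically to each RGB channel.

The optimizer is a deterministic compass (pattern) search with step
halving and one restart per level, initialized at the coarsest level by an
exhaustive translation × rotation scan. A hard-binned MI surface is
piecewise flat at fine scales, which defeats gradient and simplex methods;
a compass search with restarts is robust there and exactly reproducible.
The coarsest level is rigid-only; finer levels free all six affine
parameters. The B-spline phase (control-point spacing 64 px, displacement
bounds ± one spacing, small quadratic penalty) is optimized on an internal
half-resolution image to keep the search affordable. The deformation is
kept only if it does not reduce MI. The displacement field is only
identifiable where tissue exists: residual-error statements are made over
tissue pixels, because outside the tissue (white background, out-of-field
fill) the metric carries no signal.

### Stain separation and masks

Registered IHC images are deconvolved into hematoxylin/eosin/DAB OD
channels with the published Ruifrok–Johnston unit vectors
(config-overridable) by a per-pixel linear solve. Thresholding is
two-stage Otsu, computed independently per slide: the hematoxylin channel
of the whole image separates tissue from slide background; the DAB channel
restricted to tissue pixels separates DAB-positive from faintly stained
tissue. Otsu uses 256 bins over the observed range with ties broken toward
the lower threshold; thresholds operate on OD, which is monotone in stain
amount. A guard declares the positive mask empty (with a warning) when the
fitted DAB threshold sits below 0.15 OD — in that regime the "positive"
class is indistinguishable from unstained background noise, which is what
a p53-negative slide produces.

### Label transfer

The H&E image is split into 224×224 px tiles (defaults; all sizes
configurable); labels are computed on the registered IHC at the working
scale, where a tile covers `round(224/5) = 45` px. A tile is *cancer* when
more than 2% of its pixels are DAB-positive (the fraction uses all pixels
of the tile, not only tissue), otherwise *normal*. An uncertainty band on
the mean DAB OD of the tile's tissue pixels (defaults 0.05–0.15 OD, both
user-selectable) takes precedence: a tile inside the band is *uncertain*
regardless of the fraction, so an uncertain tile is never labeled cancer.
Partial tiles at image edges are dropped rather than padded, because
padding would distort the DAB-fraction statistic.

Two quality filters follow. The tissue-presence check discards a tile when
exactly one of the H&E/IHC tiles contains tissue (registration-error
guard) or when neither does (background). Tissue here is segmented by Otsu
on the *total* OD — H&E stroma is nearly hematoxylin-free, so a
single-channel rule would miss it. The slide-level training filter keeps
only cancer tiles from cancer slides and only normal tiles from normal
slides; everything else is excluded from training. In evaluation mode no
filtering occurs.

### Tile classifier

The classifier is a frozen feature backbone plus a trainable head: one
dense hidden layer (default 256 units, ReLU) and a single sigmoid output,
trained with binary cross-entropy and minibatch Adam (lr 1e-4, batch 32,
100 epochs, all defaults). Training augments each tile with its four
rotations and flips, every copy inheriting the source label. The bundled
`"tiny"` backbone pools color, stain (H/E/DAB) and gradient statistics
into a 32-dim vector; it has no weights, so the frozen-backbone guarantee
is structural, and the test suite needs no pretrained networks. ImageNet
backbones (VGG16's 512-dim pooled output and friends) plug in as
user-supplied feature functions. Training and prediction are exactly
reproducible from the spec seed.

### Evaluation and purity

Predictions are scored against p53-derived labels (or pathologist
annotation masks rasterized to tile labels at ≥50% area coverage) with
accuracy, a truth-by-prediction confusion matrix (positive class: cancer),
and ROC AUC computed by the rank/Mann–Whitney formula with half-credit
ties. Because cancer and normal tiles are imbalanced, the dominant class
is subsampled to the minority count (seeded) before scoring. Tumor purity
per slide is the tissue-area-weighted cancer fraction: tiles are binarized
at 0.5 (probabilistic weighting available behind a flag) and each tile
contributes its tissue fraction worth of area, so a half-background tile
counts half.

## The synthetic generator

Every stage is validated against synthetic paired slides with exact ground
truth. Tissue is drawn as thresholded smooth Gaussian fields (no attempt
at histologic realism); hematoxylin is concentrated in a fine nuclear
speckle whose areal density doubles in cancer regions (0.25 → 0.5 of
tissue area), eosin fills the stroma between nuclei, and the IHC section
adds a uniform hematoxylin counterstain floor plus DAB (0.8 OD) on the
cancer mask over a faint 0.03 OD tissue background. The misalignment is a
known affine (defaults: 5°, (10, −6) px) with an optional sinusoidal warp,
applied by inverse resampling so the stored transform is exactly the one
registration should recover. Noise is additive Gaussian in OD (sd 0.02),
i.e. multiplicative in intensity, matching stain physics. Default canvas
1024×1024 px; tests run smaller (192–512 px) so the suite finishes in
about a minute and the acceptance script in a few minutes.

Three generator choices deserve emphasis because they are what make the
pipeline's properties *testable*:

- Cancer is encoded as nuclear **density**, not stain brightness. The
  99th-percentile concentration used for normalization scaling is then
  slide-invariant, so normalization cannot erase (or fake) the cancer
  signal, and the classifier must learn a texture/density cue — loosely
  analogous to real morphology.
- Both stains have near-pure pixels (nuclei vs stroma). Without them the
  stain directions are simply not identifiable by any estimator.
- The IHC counterstain floor keeps the hematoxylin histogram cleanly
  bimodal, which is what the first Otsu stage assumes.

What the generator does *not* emulate: real nuclear/glandular morphology,
scanner optics, tissue folds and artifacts, section-to-section anatomical
differences (the paired slides are pixel-identical up to the known
transform and stain), or biological label noise (p53-positive normal
tissue, p53-negative cancer). Passing tests therefore demonstrate the
pipeline's internal correctness and recoverability under its own model
assumptions, not clinical performance.

## Numerical choices and degenerate inputs

- OD uses `log10` with intensities clamped to ≥1; the RGB round trip is
  exact for intensities ≥1.
- The concentration NNLS for two stains is solved in closed form
  (unconstrained solve, then the better single-stain fit where a
  coefficient goes negative) — exact, not iterative.
- The Vahadane alternation runs 30 iterations on at most 20,000
  subsampled tissue pixels (seeded subsample). The L1 penalty leaves a
  small systematic rotation of the estimate relative to an unpenalized
  fit; at the defaults it stays within the 0.05 rad the tests assert.
- Constant inputs: Otsu and MI both treat them explicitly (error and
  zero, respectively). All-black images are rejected by luminosity
  standardization; all-white (blank) slides pass through normalization
  unchanged.
- Ties: Otsu breaks toward the lower threshold; template selection toward
  the lowest index; AUC counts ties half.
- Manifests store doubles with 17 significant digits so the CSV round
  trip is lossless.

## Known limitations

- The per-slide Otsu on DAB assumes a genuinely stained slide; the 0.15 OD
  floor guard handles marker-negative slides but a nearly-unstained slide
  with a few artifacts could still pass it.
- The purity estimate inherits the 2%-rule's asymmetry: boundary tiles
  with little cancer are still counted fully cancer, which biases purity
  upward at small tile counts (visible as a slope slightly above 1 on
  synthetic cohorts). The bias shrinks with tile count and does not affect
  ordering.
- GrabCut-based tissue segmentation is not offered; the deterministic
  total-OD Otsu rule is the only presence-check segmenter.
- The B-spline phase is deliberately conservative (coarse grid, bounded
  displacements, kept only when it improves MI); it corrects smooth
  low-frequency warps, not tears or folds.

## Problem sizes used by the tests

Unit tests run on 64–384 px synthetic slides; the acceptance checks use
512 px slides for registration recovery (20 random rigid misalignments),
a 10-slide 256 px cohort for normalization variance reduction, and a
5-slide 512 px training cohort plus a 10-slide 384 px purity cohort for
the end-to-end property, with 64 px tiles at a 4× working scale. These
sizes were chosen so each stage still has the geometry it needs (several
tiles per slide, several nuclei per tile) while a full run completes in
minutes on a laptop.
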