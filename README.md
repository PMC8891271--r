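# hemlabel

Molecular label transfer from IHC to H&E histopathology images, in R.

Pathologist annotation of whole-slide images is slow, coarse and variable,
yet it is what most deep-learning cancer classifiers train on. When an
adjacent section of the same tissue block carries an immunohistochemistry
(IHC) stain for a cancer marker — such as p53, visualized as brown DAB —
that stain can label the matched H&E image at pixel resolution instead.
`hemlabel` implements the full label-transfer pipeline for researchers in
computational pathology:

1. **Stain normalization** — every H&E slide is re-colored to a template
   slide's stain profile through the Beer–Lambert factorization
   `OD = C · S` (`OD = -log10(I / I0)`), with Vahadane (sparse
   non-negative dictionary learning), Macenko (SVD / percentile angles)
   or Reinhard (CIELAB moment matching) estimators.
2. **Registration** — the IHC image is aligned onto its H&E partner by
   maximizing grayscale mutual information,
   `I(A, B) = Σ p(a,b) log[ p(a,b) / (p(a) p(b)) ]`,
   with an affine then B-spline transform over a multi-resolution
   pyramid, at a user-set working scale (default 1/5). Only the IHC image
   is ever resampled; out-of-field pixels become white.
3. **Stain separation** — Ruifrok–Johnston color deconvolution into
   hematoxylin / eosin / DAB optical densities, then two-stage Otsu:
   hematoxylin separates tissue from background, and Otsu on the DAB of
   tissue pixels separates marker-positive from faintly stained tissue,
   independently per slide.
4. **Label transfer** — the H&E image is tiled (224 px default; 45 px on
   the 1/5-scale registered IHC); a tile is *cancer* when more than 2% of
   its pixels are DAB-positive, with a user-selectable uncertainty band on
   mean DAB OD, a tissue-presence check against registration errors, and a
   slide-level filter that keeps only status-consistent tiles for
   training.
5. **Tile classifier** — a frozen feature backbone plus a trainable dense
   head (256 units + sigmoid, binary cross-entropy, Adam, rotation/flip
   augmentation). A deterministic 32-feature `"tiny"` backbone is bundled;
   ImageNet backbones plug in as feature functions.
6. **Evaluation & purity** — accuracy, confusion matrix and ROC AUC with
   class balancing by subsampling, and slide-level tumor purity as the
   tissue-area-weighted cancer-tile fraction (a half-background tile
   contributes half a tile of area).

A first-class synthetic generator (`generate_pair()`, `generate_cohort()`)
renders paired pseudo-H&E / pseudo-IHC slides from known stain matrices,
known misalignment and known cancer masks, so every stage can be checked
against exact ground truth.

## Worked example

```r
library(hemlabel)

cfg <- pipeline_config(
  out_dir = "demo_run", seed = 11,
  simulate = list(n_cancer = 3L, n_normal = 2L,
                  image_shape = c(384L, 384L), purity_grid = c(0.3, 0.5, 0.7)),
  registration = list(downscale = 4L),
  labeling = list(tile_px = 64L),
  classifier = list(hidden = 32L, epochs = 40L, lr = 1e-2)
)
res <- run_pipeline(cfg)
#> [hemlabel] simulate: wrote 5 slide pairs
#> [hemlabel] normalize: template slide synthetic_13
#> [hemlabel] register synthetic_12: MI 0.553 -> 1.118
#> ...
#> [hemlabel] evaluate: accuracy 1.000, AUC 1.000
#> [hemlabel] purity: 5 slides

res$purity
#>       slide_id cancer_tissue_area total_tissue_area    purity true_purity
#> 1 synthetic_12           6.117188          11.57031 0.5286968   0.3000011
#> 2 synthetic_13           8.785156          12.15234 0.7229187   0.4999943
#> 3 synthetic_14          11.648438          13.19922 0.8825096   0.6999989
#> 4 synthetic_15           0.000000          13.88672 0.0000000   0.0000000
#> 5 synthetic_16           0.000000          13.64844 0.0000000   0.0000000
```

Reading the output: registration raised the mutual information of every
pair (better alignment); the trained tiny-backbone classifier separated
cancer from normal tiles perfectly on this easy synthetic cohort (AUC
1.0); and the purity estimates rank the slides correctly — they sit above
the true area fractions because the 2% labeling rule counts boundary
tiles fully, a bias that shrinks with tile count. Normal slides are
correctly estimated at zero purity.

The same stages are available as plain functions
(`normalize_to_template()`, `register_pair()`, `deconvolve_hed()`,
`compute_masks()`, `build_dataset()`, `hem_classifier()`,
`estimate_purity()`, ...) for use on your own images, and a thin
command-line wrapper lives at `inst/cli/hemlabel.R`.

## Scope

The package operates on flat lossless rasters (PNG/TIFF) at desk scale;
pyramidal WSI formats are supported through a pluggable reader interface.
It does not ship pretrained clinical weights, does not implement genomic
purity estimators, and its synthetic slides make no claim to histologic
realism — see the methods vignette (`vignettes/hemlabel-methods.Rmd`) for
the model, its assumptions, and known limitations.
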