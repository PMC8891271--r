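# Synthetic paired pseudo-H&E / pseudo-IHC slides with full ground truth.
#
# Tissue is drawn as smoothed random blobs (thresholded Gaussian fields);
# stains are rendered through the Beer-Lambert forward model from known
# stain matrices and concentration fields, so every downstream stage can be
# checked against exact truth: tissue and cancer masks, the misalignment
# transform, concentrations and the area-fraction purity. Cancer regions
# carry DAB on the IHC slide and an elevated hematoxylin concentration on
# the H&E slide (emulating increased nuclear density), which is what makes
# cancer learnable from the H&E appearance alone.

#' Specification of one synthetic slide pair
#'
#' @param image_shape (H, W) in pixels (default 1024 x 1024, roughly 16
#'   full 224-px tiles).
#' @param seed Mandatory RNG seed; generation is bit-reproducible.
#' @param status `"cancer"` or `"non_cancer"`.
#' @param tissue_coverage Fraction of the image covered by tissue
#'   (default 0.6).
#' @param cancer_region_fraction Target fraction of tissue that is cancer
#'   (default 0.5 for cancer slides; forced to 0 for non-cancer slides).
#' @param blob_scale Correlation length of the tissue blobs in pixels
#'   (default 128).
#' @param stain_he 2 x 3 unit-row H&E stain matrix for rendering.
#' @param stain_ihc 3 x 3 unit-row H/E/DAB stain matrix for rendering.
#' @param dab_concentration DAB OD level inside cancer regions (default 0.8).
#' @param dab_background Faint background DAB OD in all tissue
#'   (default 0.03).
#' @param rotation_deg,translation_px Misalignment of the IHC slide:
#'   rotation about the image centre (default 5 degrees) and (x, y)
#'   translation (default c(10, -6) px).
#' @param warp_amplitude_px Amplitude of an additional smooth sinusoidal
#'   warp (default 0, none).
#' @param noise_sd Additive Gaussian noise in OD space (default 0.02).
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(image_shape = c(1024L, 1024L), seed,
                           status = c("cancer", "non_cancer"),
                           tissue_coverage = 0.6, cancer_region_fraction = 0.5,
                           blob_scale = 128, stain_he = rj_stain_matrix()[1:2, ],
                           stain_ihc = rj_stain_matrix(),
                           dab_concentration = 0.8, dab_background = 0.03,
                           rotation_deg = 5, translation_px = c(10, -6),
                           warp_amplitude_px = 0, noise_sd = 0.02) {
  status <- match.arg(status)
  if (missing(seed)) stop("seed is mandatory for synthetic generation")
  if (cancer_region_fraction < 0 || cancer_region_fraction > 1)
    stop("cancer_region_fraction must be in [0, 1]")
  if (status == "non_cancer") cancer_region_fraction <- 0
  structure(as.list(environment()), class = "synthetic_spec")
}

# Smooth random field in [0,1]-ish: white noise on a coarse grid, bilinear
# upsample to (H, W).
smooth_field <- function(H, W, scale) {
  ch <- max(2L, ceiling(H / scale) + 1L)
  cw <- max(2L, ceiling(W / scale) + 1L)
  g <- matrix(stats::rnorm(ch * cw), ch, cw)
  mapx <- matrix(rep(seq(0, cw - 1.001, length.out = W), each = H), H)
  mapy <- matrix(rep(seq(0, ch - 1.001, length.out = H), W), H)
  warp_bilinear(g, mapx, mapy, fill = 0)
}

#' Generate one synthetic slide pair with ground truth
#'
#' @param spec A [synthetic_spec()].
#' @return List with `pair` (fields `slide_id`, `he`, `ihc`, `status`,
#'   `magnification`) and `truth` (fields `tissue_mask`, `cancer_mask`,
#'   `true_affine` — the full-resolution 2 x 3 fixed-to-moving transform —
#'   `warp_amplitude_px`, `concentrations`, `true_purity`).
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  H <- spec$image_shape[1]; W <- spec$image_shape[2]
  withr::with_seed(spec$seed, {
    f_tissue <- smooth_field(H, W, spec$blob_scale)
    tissue <- f_tissue > stats::quantile(f_tissue, 1 - spec$tissue_coverage)
    cancer <- matrix(FALSE, H, W)
    if (spec$cancer_region_fraction > 0) {
      f_cancer <- smooth_field(H, W, spec$blob_scale)
      thr <- stats::quantile(f_cancer[tissue], 1 - spec$cancer_region_fraction)
      cancer <- tissue & f_cancer > thr
    }
    # Hematoxylin lives in nuclei: a fine-scale speckle whose areal density
    # doubles in cancer regions (nuclear crowding). The per-nucleus OD does
    # not depend on the slide or on purity, so concentration-percentile
    # matching during normalization is amplitude-neutral and cancer remains
    # recognizable as density/texture, as in real tissue. Eosin fills the
    # stroma between nuclei. Near-pure pixels of both stains (nuclei /
    # stroma) keep the stain directions identifiable.
    u1 <- stats::pnorm(1.4 * (smooth_field(H, W, spec$blob_scale / 8) +
                                smooth_field(H, W, spec$blob_scale / 32)))
    u2 <- stats::pnorm(1.4 * (smooth_field(H, W, spec$blob_scale / 8) +
                                smooth_field(H, W, spec$blob_scale / 32)))
    fine <- smooth_field(H, W, 3)
    u_f <- stats::pnorm(fine / stats::sd(fine))
    nuc_density <- 0.25 + 0.25 * cancer
    nuclei <- tissue & (u_f > 1 - nuc_density)
    s_n <- 0.7 + 0.6 * u1                 # per-nucleus stain uptake
    c_h <- tissue * (0.04 + 1.25 * nuclei * s_n)
    c_e <- tissue * (0.08 + 0.65 * u2) * (1 - 0.45 * nuclei)
    noise <- function() matrix(stats::rnorm(H * W, sd = spec$noise_sd), H, W)

    od_he <- array(0, c(H, W, 3))
    for (ch in 1:3)
      od_he[, , ch] <- pmax(c_h * spec$stain_he[1, ch] + c_e * spec$stain_he[2, ch] +
                              tissue * noise(), 0)
    he <- array(od_to_rgb(od_he), c(H, W, 3))

    # the IHC section carries a hematoxylin counterstain with a substantial
    # uniform floor (unlike H&E, where stroma is eosin-dominant and nearly
    # hematoxylin-free), which is what makes tissue separable from slide
    # background on the hematoxylin channel
    # IHC hematoxylin counterstain: strong uniform floor (so tissue is
    # separable from slide background on the hematoxylin channel) plus the
    # same nuclear speckle, which also gives registration its texture
    c_h_ihc <- tissue * (0.50 + 0.20 * u1) + nuclei * 0.45 * s_n
    c_d <- tissue * spec$dab_background + cancer * spec$dab_concentration
    od_ihc <- array(0, c(H, W, 3))
    for (ch in 1:3)
      od_ihc[, , ch] <- pmax(c_h_ihc * spec$stain_ihc[1, ch] + c_d * spec$stain_ihc[3, ch] +
                               tissue * noise(), 0)
    ihc_aligned <- array(od_to_rgb(od_ihc), c(H, W, 3))
  })

  center <- c((W - 1) / 2, (H - 1) / 2)
  A <- affine_from_params(c(spec$translation_px, spec$rotation_deg, 0, 0, 0), center)
  ihc <- misalign_image(ihc_aligned, A, spec$warp_amplitude_px)

  truth <- list(tissue_mask = tissue, cancer_mask = cancer,
                true_affine = A, warp_amplitude_px = spec$warp_amplitude_px,
                concentrations = list(hematoxylin = c_h, eosin = c_e, dab = c_d),
                true_purity = if (any(tissue)) sum(cancer) / sum(tissue) else 0)
  pair <- list(slide_id = sprintf("synthetic_%d", spec$seed),
               he = he, ihc = ihc, status = spec$status, magnification = 10)
  list(pair = pair, truth = truth)
}

# The truth transform T maps fixed (H&E) coordinates to moving (raw IHC)
# coordinates: T(x) = A x + w(x), with w an optional smooth sinusoidal
# displacement. The raw IHC image is rendered by sampling the aligned IHC
# at T^{-1}(y), found by fixed-point iteration (the warp is small).
misalign_image <- function(aligned, A, warp_amplitude = 0) {
  d <- dim(aligned)
  Ainv <- solve(rbind(A, c(0, 0, 1)))[1:2, ]
  X <- matrix(rep(0:(d[2] - 1), each = d[1]), d[1])
  Y <- matrix(rep(0:(d[1] - 1), d[2]), d[1])
  px <- Ainv[1, 1] * X + Ainv[1, 2] * Y + Ainv[1, 3]
  py <- Ainv[2, 1] * X + Ainv[2, 2] * Y + Ainv[2, 3]
  if (warp_amplitude > 0) {
    for (i in 1:8) {
      w <- sinusoid_warp(px, py, d, warp_amplitude)
      qx <- X - w$dx; qy <- Y - w$dy
      px <- Ainv[1, 1] * qx + Ainv[1, 2] * qy + Ainv[1, 3]
      py <- Ainv[2, 1] * qx + Ainv[2, 2] * qy + Ainv[2, 3]
    }
  }
  pmin(pmax(warp_bilinear(aligned, px, py, fill = 255), 0), 255)
}

sinusoid_warp <- function(x, y, shape, amplitude) {
  list(dx = amplitude * sin(2 * pi * y / shape[1]),
       dy = amplitude * cos(2 * pi * x / shape[2]))
}

#' Ground-truth tile labels from synthetic masks
#'
#' Converts the generator's pixel-level tissue and cancer masks into
#' tile-level labels, under one of two membership rules:
#' `"coverage"` — cancer when at least `cover` of the tile's tissue is
#' cancer (area-faithful; the right oracle for purity); `"fraction"` —
#' cancer when cancer pixels exceed `frac` of the whole tile (the
#' pipeline's own 2% rule; the right oracle for label agreement). Tiles
#' without tissue get `NA`.
#'
#' @param truth A `truth` element from [generate_pair()].
#' @param tile_px Tile size in pixels at the mask resolution.
#' @param rule `"coverage"` or `"fraction"`.
#' @param cover Tissue-coverage cut for the coverage rule (default 0.5).
#' @param frac Tile-fraction cut for the fraction rule (default 0.02).
#' @return data.frame with `tile_row`, `tile_col`, `tissue_fraction`,
#'   `label`.
#' @export
truth_tile_labels <- function(truth, tile_px, rule = c("coverage", "fraction"),
                              cover = 0.5, frac = 0.02) {
  rule <- match.arg(rule)
  g <- tile_grid(dim(truth$tissue_mask), tile_px)
  g$tissue_fraction <- NA_real_
  g$label <- NA_character_
  for (i in seq_len(nrow(g))) {
    rows <- (g$tile_row[i] * tile_px + 1):((g$tile_row[i] + 1) * tile_px)
    cols <- (g$tile_col[i] * tile_px + 1):((g$tile_col[i] + 1) * tile_px)
    tis <- mean(truth$tissue_mask[rows, cols])
    can <- mean(truth$cancer_mask[rows, cols])
    g$tissue_fraction[i] <- tis
    if (tis > 0) {
      hit <- if (rule == "coverage") can / tis >= cover else can > frac
      g$label[i] <- if (hit) "cancer" else "normal"
    }
  }
  g
}

# Evaluate the truth displacement map at fixed coordinates (used by tests to
# measure residual registration error).
truth_map <- function(truth, shape) {
  X <- matrix(rep(0:(shape[2] - 1), each = shape[1]), shape[1])
  Y <- matrix(rep(0:(shape[1] - 1), shape[2]), shape[1])
  A <- truth$true_affine
  mx <- A[1, 1] * X + A[1, 2] * Y + A[1, 3]
  my <- A[2, 1] * X + A[2, 2] * Y + A[2, 3]
  if (truth$warp_amplitude_px > 0) {
    w <- sinusoid_warp(X, Y, shape, truth$warp_amplitude_px)
    mx <- mx + w$dx; my <- my + w$dy
  }
  list(x = mx, y = my)
}

# Rescale a full-resolution fixed-to-moving affine to the registration
# working scale s (block-mean pixel centres at i*s + (s-1)/2).
affine_at_scale <- function(A, s) {
  o <- (s - 1) / 2
  L <- A[, 1:2]
  t_new <- (L %*% c(o, o) + A[, 3] - o) / s
  cbind(L, t_new)
}

#' Generate a synthetic cohort of slide pairs
#'
#' Emulates the training design of a handful of cancer and normal slide
#' pairs: per-slide stain matrices are randomly perturbed (to exercise
#' stain normalization), cancer slides draw their cancer-area fraction from
#' `purity_grid`, and every slide is generated from its own derived seed.
#'
#' @param n_cancer,n_normal Number of cancer / normal slide pairs.
#' @param seed Cohort seed; slide seeds are derived from it.
#' @param purity_grid Cancer-area fractions cycled over the cancer slides
#'   (default 0.5).
#' @param image_shape,... Passed through to [synthetic_spec()].
#' @param vary_stains Perturb each slide's rendering stain vectors
#'   (default TRUE).
#' @return List with `slides` (list of `generate_pair()` results) and
#'   `manifest` (data.frame: slide_id, status, true_purity).
#' @export
generate_cohort <- function(n_cancer, n_normal, seed, purity_grid = 0.5,
                            image_shape = c(1024L, 1024L), vary_stains = TRUE,
                            ...) {
  stopifnot(n_cancer >= 0, n_normal >= 0)
  statuses <- c(rep("cancer", n_cancer), rep("non_cancer", n_normal))
  slides <- vector("list", length(statuses))
  for (i in seq_along(statuses)) {
    # only the H&E stain vectors vary across slides (that is what stain
    # normalization has to correct); IHC slides are never normalized, so
    # they render with the standard profile the deconvolution assumes
    s_he <- rj_stain_matrix()[1:2, ]
    s_ihc <- rj_stain_matrix()
    if (vary_stains) {
      pert <- withr::with_seed(seed + 1000L + i, matrix(stats::rnorm(6, sd = 0.05), 2))
      s_he <- normalize_rows(pmax(s_he + pert, 0.01))
    }
    frac <- purity_grid[(i - 1) %% length(purity_grid) + 1]
    sp <- synthetic_spec(image_shape = image_shape, seed = seed + i,
                         status = statuses[i],
                         cancer_region_fraction = frac,
                         stain_he = s_he, stain_ihc = s_ihc, ...)
    slides[[i]] <- generate_pair(sp)
  }
  manifest <- data.frame(
    slide_id = vapply(slides, function(s) s$pair$slide_id, character(1)),
    status = statuses,
    true_purity = vapply(slides, function(s) s$truth$true_purity, numeric(1)),
    stringsAsFactors = FALSE
  )
  list(slides = slides, manifest = manifest)
}
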