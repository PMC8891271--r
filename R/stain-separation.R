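# Color deconvolution of IHC images into hematoxylin / eosin / DAB optical
# densities (Ruifrok-Johnston), and two-stage Otsu thresholding: hematoxylin
# separates tissue from slide background, then Otsu on the DAB channel of
# tissue pixels only separates DAB-positive (p53-positive) pixels from faint
# background staining.

#' Deconvolve an RGB image into H, E and DAB channels
#'
#' Per-pixel solve of `od = c %*% M` where `M` is a 3 x 3 unit-row stain
#' matrix (rows: hematoxylin, eosin, DAB). The default matrix is the
#' published Ruifrok-Johnston vector set.
#'
#' @param img H x W x 3 RGB array.
#' @param M 3 x 3 invertible stain matrix with unit-norm rows.
#' @return Object of class `channel_stack`: list with `hematoxylin`,
#'   `eosin`, `dab` (H x W OD matrices) and `deconv_matrix`.
#' @export
deconvolve_hed <- function(img, M = rj_stain_matrix()) {
  stopifnot(is.matrix(M), all(dim(M) == 3))
  if (abs(det(M)) < 1e-8) stop("rank error: stain matrix is singular")
  if (any(abs(sqrt(rowSums(M^2)) - 1) > 1e-6))
    stop("stain matrix rows must be unit norm")
  assert_rgb(img)
  d <- dim(img)
  od <- matrix(rgb_to_od(img), ncol = 3)
  C <- od %*% solve(M)
  structure(list(
    hematoxylin = matrix(C[, 1], d[1], d[2]),
    eosin = matrix(C[, 2], d[1], d[2]),
    dab = matrix(C[, 3], d[1], d[2]),
    deconv_matrix = M
  ), class = "channel_stack")
}

# Forward Beer-Lambert remix: concentrations (N x 3 or H x W x 3) back to
# RGB through the same stain matrix. Used by the synthetic generator and by
# round-trip checks.
remix_hed <- function(C, M = rj_stain_matrix(), shape = NULL) {
  Cm <- matrix(C, ncol = 3)
  rgb <- od_to_rgb(Cm %*% M)
  if (is.null(shape)) rgb else array(rgb, c(shape, 3))
}

#' Otsu threshold of a sample of values
#'
#' Histogram threshold maximizing the between-class variance over `bins`
#' uniform bins spanning the observed range. Deterministic; ties are broken
#' toward the lower threshold. Returns the bin edge separating the two
#' classes.
#'
#' @param values Numeric vector with at least two distinct values.
#' @param bins Number of histogram bins (default 256).
#' @return Threshold scalar (values strictly above it fall in the upper
#'   class).
#' @export
otsu_threshold <- function(values, bins = 256L) {
  values <- values[is.finite(values)]
  r <- range(values)
  if (length(values) < 2 || r[2] - r[1] < 1e-12)
    stop("degenerate input: need at least two distinct values for Otsu")
  h <- tabulate(pmin(as.integer(floor((values - r[1]) / (r[2] - r[1]) * bins)),
                     bins - 1L) + 1L, nbins = bins)
  p <- h / sum(h)
  mids <- r[1] + (seq_len(bins) - 0.5) * (r[2] - r[1]) / bins
  w <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[bins]
  k <- seq_len(bins - 1)
  denom <- w[k] * (1 - w[k])
  sigma_b <- ifelse(denom > 0, (muT * w[k] - mu[k])^2 / denom, -Inf)
  kstar <- which.max(sigma_b)     # which.max takes the first (lowest) maximum
  r[1] + kstar * (r[2] - r[1]) / bins
}

#' Tissue and DAB-positive masks from a channel stack
#'
#' Stage one: Otsu on the hematoxylin channel of the whole image separates
#' tissue from slide background. Stage two: Otsu on the DAB channel
#' restricted to tissue pixels separates DAB-positive (high OD) pixels from
#' faintly stained background tissue. Thresholds are computed independently
#' for each slide. A slide whose tissue DAB histogram is degenerate (no DAB
#' anywhere) yields an empty positive mask with a warning.
#'
#' @param stack A `channel_stack` from [deconvolve_hed()].
#' @param bins Histogram bins for both thresholds (default 256).
#' @param dab_floor Minimum OD the DAB threshold must exceed for the
#'   positive class to count as stained (default 0.15); below it the DAB
#'   histogram is treated as unstained noise and the positive mask is empty.
#' @return Object of class `mask_set`: list with logical `tissue` and
#'   `dab_positive` masks and the two thresholds.
#' @export
compute_masks <- function(stack, bins = 256L, dab_floor = 0.15) {
  stopifnot(inherits(stack, "channel_stack"))
  hthr <- otsu_threshold(as.vector(stack$hematoxylin), bins)
  tissue <- stack$hematoxylin > hthr
  if (!any(tissue)) stop("insufficient tissue: no pixels above the hematoxylin threshold")
  dab_t <- stack$dab[tissue]
  dthr <- tryCatch(otsu_threshold(dab_t, bins), error = function(e) NA_real_)
  if (is.na(dthr) || diff(range(dab_t)) < 0.05 || dthr <= dab_floor) {
    warning("degenerate DAB histogram: no DAB-positive pixels detected")
    dab_positive <- tissue & FALSE
    dthr <- NA_real_
  } else {
    dab_positive <- tissue & stack$dab > dthr
  }
  structure(list(tissue = tissue, dab_positive = dab_positive,
                 otsu_tissue_threshold = hthr, otsu_dab_threshold = dthr),
            class = "mask_set")
}

# Deterministic tissue segmentation of an RGB tile/image by Otsu on the
# total optical density (any stain marks tissue; H&E stroma is nearly
# hematoxylin-free, so thresholding a single channel would miss it).
# Returns a logical mask; near-blank images (degenerate histogram) give all
# FALSE.
segment_tissue <- function(img, method = c("otsu"), bins = 256L) {
  method <- match.arg(method)
  od <- rgb_to_od(img)
  tot <- od[, , 1] + od[, , 2] + od[, , 3]
  if (diff(range(tot)) < 0.05) return(matrix(FALSE, nrow(tot), ncol(tot)))
  tot > otsu_threshold(as.vector(tot), bins)
}

#' Write a binary mask as a single-channel PNG
#'
#' @param mask Logical matrix.
#' @param path Output PNG path (0 = FALSE, 255 = TRUE).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask)), path)
  invisible(path)
}
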