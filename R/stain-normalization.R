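# Stain color normalization.
#
# All H&E slides are re-colored to a template slide's stain profile by
# factorizing the optical-density image OD = C * S (Beer-Lambert), where the
# rows of S are unit-norm stain color vectors in OD space and C holds the
# per-pixel stain concentrations, then reconstructing with the template's S.

#' Standardize slide luminosity
#'
#' Corrects overall image brightness so the slide background is near white:
#' the image is converted to CIELAB, lightness is divided by its 95th
#' percentile (clipping at the maximum), and converted back to RGB. Applying
#' the operation twice is equivalent to applying it once (to within one
#' intensity unit).
#'
#' @param img H x W x 3 array in \[0, 255\].
#' @return H x W x 3 array in \[0, 255\] with near-white background.
#' @export
standardize_luminosity <- function(img) {
  assert_rgb(img)
  d <- dim(img)
  rgb <- matrix(img, ncol = 3) / 255
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  p95 <- stats::quantile(lab[, 1], 0.95, names = FALSE)
  if (p95 <= 0) stop("degenerate input: image is black, cannot standardize luminosity")
  lab[, 1] <- pmin(lab[, 1] / p95 * 100, 100)
  out <- grDevices::convertColor(lab, from = "Lab", to = "sRGB")
  array(round(pmin(pmax(out, 0), 1) * 255), d)
}

#' RGB to optical density
#'
#' Beer-Lambert transform `od = -log10(max(I, 1) / I0)` applied per channel.
#' Intensities are clamped to at least 1 before the log so the transform is
#' finite everywhere; a pixel equal to `I0` in all channels has zero OD.
#'
#' @param img H x W x 3 array in \[0, 255\].
#' @param I0 Incident (white) intensity, default 255.
#' @return H x W x 3 array of non-negative optical densities.
#' @export
rgb_to_od <- function(img, I0 = 255) {
  stopifnot(I0 > 0)
  assert_rgb(img)
  -log10(pmax(img, 1) / I0)
}

#' Optical density to RGB
#'
#' Inverse of [rgb_to_od()]: `I = I0 * 10^-od`, rounded and clipped to
#' \[0, 255\].
#'
#' @param od H x W x 3 array (or N x 3 matrix) of optical densities.
#' @param I0 Incident intensity, default 255.
#' @return Array of the same shape with values in \[0, 255\].
#' @export
od_to_rgb <- function(od, I0 = 255) {
  out <- round(pmin(pmax(I0 * 10^(-od), 0), 255))
  out
}

#' Ruifrok-Johnston stain color matrix
#'
#' The published hematoxylin / eosin / DAB unit color vectors in OD space,
#' row-normalized. Used as the default deconvolution matrix and as the
#' default rendering matrices of the synthetic generator.
#'
#' @return 3 x 3 matrix with unit-norm rows (hematoxylin, eosin, dab).
#' @export
rj_stain_matrix <- function() {
  m <- rbind(
    hematoxylin = c(0.650, 0.704, 0.286),
    eosin       = c(0.072, 0.990, 0.105),
    dab         = c(0.268, 0.570, 0.776)
  )
  m / sqrt(rowSums(m^2))
}

# Pixels used for stain estimation: mean OD across channels above the
# background cutoff beta. A per-channel cutoff would systematically drop
# eosin-dominant pixels (eosin barely absorbs red), making the eosin
# direction unidentifiable.
tissue_od_pixels <- function(od, beta = 0.15) {
  m <- matrix(od, ncol = 3)
  m[rowMeans(m) > beta, , drop = FALSE]
}

normalize_rows <- function(S) S / sqrt(rowSums(S^2))

# Order stain rows so hematoxylin is first. Hematoxylin (blue-purple)
# absorbs red and green about equally, while eosin (pink) absorbs green
# but hardly any red, so the red/green OD ratio separates them robustly.
order_h_first <- function(S) {
  ratio <- S[, 1] / pmax(S[, 2], 1e-8)
  S[order(-ratio), , drop = FALSE]
}

macenko_fit <- function(V, angle_percentiles = c(0.01, 0.99)) {
  sv <- svd(V, nu = 0, nv = 2)
  if (sv$d[2] / sv$d[1] < 1e-3)
    stop("rank error: tissue OD is effectively one-dimensional (single stain?)")
  E <- sv$v                       # 3 x 2 basis of the leading OD plane
  # orient basis so projections are mostly positive
  if (sum(V %*% E[, 1]) < 0) E[, 1] <- -E[, 1]
  if (sum(V %*% E[, 2]) < 0) E[, 2] <- -E[, 2]
  proj <- V %*% E
  phi <- atan2(proj[, 2], proj[, 1])
  q <- stats::quantile(phi, angle_percentiles, names = FALSE)
  if (diff(q) < 1e-3)
    stop("rank error: stain angles are degenerate (single stain?)")
  S <- rbind(
    as.vector(E %*% c(cos(q[1]), sin(q[1]))),
    as.vector(E %*% c(cos(q[2]), sin(q[2])))
  )
  S[S < 0] <- 0
  order_h_first(normalize_rows(S))
}

# Exact two-stain non-negative least squares: minimizes ||V - C S||^2 with
# C >= 0, where B is the (possibly L1-shifted) right-hand side V S' and G
# the Gram matrix S S'. Closed form: unconstrained solve, then the better
# of the two single-stain fits wherever that leaves the feasible region.
nnls_two_stain <- function(B, G, V, S) {
  C <- B %*% t(solve(G))
  neg <- C[, 1] < 0 | C[, 2] < 0
  if (any(neg)) {
    c1 <- pmax(B[neg, 1] / G[1, 1], 0)
    c2 <- pmax(B[neg, 2] / G[2, 2], 0)
    r1 <- rowSums((V[neg, , drop = FALSE] - outer(c1, S[1, ]))^2)
    r2 <- rowSums((V[neg, , drop = FALSE] - outer(c2, S[2, ]))^2)
    use1 <- r1 <= r2
    C[neg, 1] <- ifelse(use1, c1, 0)
    C[neg, 2] <- ifelse(use1, 0, c2)
  }
  C
}

# Sparse non-negative dictionary learning V ~ C S with an L1 penalty on the
# concentrations (2 atoms), by alternating exact NNLS steps; initialized
# from the Macenko estimate for stability. The factorization runs on
# natural-log OD (the scale the canonical implementations use and that
# lambda = 0.1 is calibrated for); the stain directions are unaffected by
# the scale change.
vahadane_fit <- function(V, lambda = 0.1, n_iter = 30) {
  V <- V * log(10)
  S <- macenko_fit(V)
  for (i in seq_len(n_iter)) {
    G <- S %*% t(S)
    B <- V %*% t(S) - lambda / 2          # L1 subgradient shift
    C <- nnls_two_stain(B, G, V, S)
    CtC <- crossprod(C)
    if (rcond(CtC) < 1e-10) break
    S_new <- solve(CtC, crossprod(C, V))
    S_new[S_new < 0] <- 1e-8
    S <- normalize_rows(S_new)
  }
  order_h_first(S)
}

#' Estimate the H&E stain matrix of a slide
#'
#' Fits the 2 x 3 unit-row stain matrix in OD space, either by the Macenko
#' SVD/percentile-angle method or by Vahadane sparse non-negative dictionary
#' learning (2 atoms, L1 sparsity on concentrations). Only pixels with OD
#' above `beta` in every channel are used. Rows are ordered so hematoxylin
#' (the bluer vector) is row 1.
#'
#' @param img H x W x 3 RGB array, or an OD array from [rgb_to_od()] when
#'   `is_od = TRUE`.
#' @param method `"vahadane"` (default) or `"macenko"`.
#' @param beta Background OD cutoff (default 0.15).
#' @param lambda Sparsity weight for the Vahadane fit (default 0.1).
#' @param min_pixels Minimum number of tissue pixels required (default 200).
#' @param max_pixels Subsample cap for the fit, for speed (default 20000).
#' @param is_od Set `TRUE` if `img` is already an OD array.
#' @param seed Seed controlling the pixel subsample.
#' @return 2 x 3 matrix with unit-norm rows (hematoxylin, eosin).
#' @export
estimate_stain_matrix <- function(img, method = c("vahadane", "macenko"),
                                  beta = 0.15, lambda = 0.1,
                                  min_pixels = 200, max_pixels = 20000,
                                  is_od = FALSE, seed = 1L) {
  method <- match.arg(method)
  od <- if (is_od) img else rgb_to_od(img)
  V <- tissue_od_pixels(od, beta)
  if (nrow(V) < min_pixels)
    stop("insufficient tissue: only ", nrow(V), " pixels above the OD cutoff")
  if (nrow(V) > max_pixels)
    V <- V[withr::with_seed(seed, sample.int(nrow(V), max_pixels)), , drop = FALSE]
  switch(method,
    macenko = macenko_fit(V),
    vahadane = vahadane_fit(V, lambda = lambda)
  )
}

#' Per-pixel stain concentrations
#'
#' Solves `od ~ C %*% S` for the non-negative concentration matrix C by
#' exact per-pixel non-negative least squares (closed form for two stains).
#'
#' @param od H x W x 3 OD array or N x 3 matrix.
#' @param S 2 x 3 stain matrix with full row rank.
#' @return List with `C` (N x 2 matrix, non-negative) and `residual`
#'   (root-mean-square reconstruction error).
#' @export
estimate_concentrations <- function(od, S) {
  if (qr(S)$rank < nrow(S)) stop("rank error: stain matrix is rank deficient")
  V <- matrix(od, ncol = 3)
  C <- nnls_two_stain(V %*% t(S), S %*% t(S), V, S)
  resid <- sqrt(mean((V - C %*% S)^2))
  list(C = C, residual = resid)
}

#' Fit a stain template
#'
#' Captures everything needed to normalize other slides to this slide's
#' stain appearance: its stain matrix, the 99th percentile of each stain
#' concentration channel (used to match concentration scales), and the
#' CIELAB channel statistics used by the Reinhard method.
#'
#' @param img Template slide, H x W x 3 RGB.
#' @param method Stain estimation method, `"vahadane"` or `"macenko"`.
#' @inheritParams estimate_stain_matrix
#' @return Object of class `stain_template`.
#' @export
fit_stain_template <- function(img, method = c("vahadane", "macenko"),
                               beta = 0.15, lambda = 0.1, seed = 1L) {
  method <- match.arg(method)
  img <- standardize_luminosity(img)
  S <- estimate_stain_matrix(img, method, beta = beta, lambda = lambda, seed = seed)
  od <- rgb_to_od(img)
  C <- estimate_concentrations(od, S)$C
  c99 <- apply(C, 2, stats::quantile, 0.99, names = FALSE)
  lab <- grDevices::convertColor(matrix(img, ncol = 3) / 255, "sRGB", "Lab")
  structure(
    list(S = S, c99 = c99, method = method, beta = beta, lambda = lambda,
         lab_mean = colMeans(lab), lab_sd = apply(lab, 2, stats::sd)),
    class = "stain_template"
  )
}

#' @export
print.stain_template <- function(x, ...) {
  cat("Stain template (", x$method, ")\n", sep = "")
  cat("  stain matrix (rows H, E):\n")
  print(round(x$S, 4))
  cat("  concentration 99th percentiles:", round(x$c99, 3), "\n")
  invisible(x)
}

#' Normalize a slide to a template's stain appearance
#'
#' For `"vahadane"`/`"macenko"`, decomposes the source into stain
#' concentrations with its own fitted stain matrix, rescales each
#' concentration channel so its 99th percentile matches the template's, and
#' reconstructs with the template stain matrix (`OD_norm = C_source *
#' S_template`). For `"reinhard"`, matches per-channel mean and standard
#' deviation in CIELAB. Luminosity is standardized first in all cases. An
#' image with no tissue pixels at all (blank background) is returned
#' unchanged.
#'
#' @param img Source slide, H x W x 3 RGB.
#' @param template A `stain_template` from [fit_stain_template()].
#' @param method `"vahadane"`, `"macenko"` or `"reinhard"`.
#' @inheritParams estimate_stain_matrix
#' @return Normalized H x W x 3 RGB array, same shape as the input.
#' @export
normalize_to_template <- function(img, template,
                                  method = c("vahadane", "macenko", "reinhard"),
                                  beta = 0.15, lambda = 0.1, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(template, "stain_template"))
  img <- standardize_luminosity(img)
  d <- dim(img)
  od <- rgb_to_od(img)
  if (nrow(tissue_od_pixels(od, beta)) == 0) return(img)  # blank slide
  if (method == "reinhard") {
    lab <- grDevices::convertColor(matrix(img, ncol = 3) / 255, "sRGB", "Lab")
    mu <- colMeans(lab); sdv <- apply(lab, 2, stats::sd)
    sdv[sdv == 0] <- 1
    lab <- sweep(sweep(lab, 2, mu), 2, template$lab_sd / sdv, "*")
    lab <- sweep(lab, 2, template$lab_mean, "+")
    out <- grDevices::convertColor(lab, "Lab", "sRGB")
    return(array(round(pmin(pmax(out, 0), 1) * 255), d))
  }
  S_src <- estimate_stain_matrix(img, method, beta = beta, lambda = lambda, seed = seed)
  C <- estimate_concentrations(od, S_src)$C
  c99 <- apply(C, 2, stats::quantile, 0.99, names = FALSE)
  scale <- ifelse(c99 > 0, template$c99 / c99, 1)
  C <- sweep(C, 2, scale, "*")
  od_norm <- C %*% template$S
  array(od_to_rgb(od_norm), d)
}

#' Select the template slide of a cohort
#'
#' Chooses the slide whose mean (R, G, B) intensity vector is closest in
#' Euclidean distance to the componentwise median of all slides' mean
#' vectors. When slide statuses are supplied, only cancer slides are
#' eligible (the median is still taken over all slides). Ties go to the
#' lowest index.
#'
#' @param slides List of H x W x 3 RGB arrays.
#' @param statuses Optional character vector, `"cancer"` / `"non_cancer"`,
#'   one per slide.
#' @return Integer index into `slides`.
#' @export
select_template <- function(slides, statuses = NULL) {
  if (length(slides) == 0) stop("no slides supplied")
  means <- t(vapply(slides, function(s) apply(s, 3, mean), numeric(3)))
  med <- apply(means, 2, stats::median)
  dist <- sqrt(rowSums(sweep(means, 2, med)^2))
  cand <- seq_along(slides)
  if (!is.null(statuses)) {
    stopifnot(length(statuses) == length(slides))
    if (any(statuses == "cancer")) cand <- which(statuses == "cancer")
  }
  cand[which.min(dist[cand])]
}
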