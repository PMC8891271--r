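# Intensity-based registration of IHC onto H&E.
#
# Both images are converted to grayscale and reduced to a working scale
# (default 1/5); an affine transform and then a B-spline free-form
# deformation are fitted by maximizing the mutual information of the joint
# grayscale histogram, each phase using a multi-resolution pyramid. Only the
# IHC image is ever resampled; the H&E image stays untouched.

#' Mutual information of two images
#'
#' Evaluates `I(A, B) = sum p(a,b) log( p(a,b) / (p(a) p(b)) )` (natural
#' log, in nats) on the joint histogram of pixel intensities. Each image is
#' binned uniformly over its own intensity range; a constant image occupies
#' a single bin and yields zero.
#'
#' @param a,b Numeric matrices (grayscale images) of identical shape.
#' @param bins Number of histogram bins per image (default 50).
#' @return Mutual information in nats (non-negative, symmetric).
#' @export
mutual_information <- function(a, b, bins = 50L) {
  if (!identical(dim(a), dim(b))) stop("images must have the same shape")
  if (bins < 2) stop("bins must be >= 2")
  bin_index <- function(v) {
    r <- range(v)
    if (r[2] - r[1] < 1e-12) return(rep(1L, length(v)))
    pmin(as.integer(floor((v - r[1]) / (r[2] - r[1]) * bins)), bins - 1L) + 1L
  }
  ia <- bin_index(as.vector(a))
  ib <- bin_index(as.vector(b))
  joint <- tabulate((ia - 1L) * bins + ib, nbins = bins * bins)
  p <- joint / sum(joint)
  pm <- matrix(p, bins, bins)       # rows: b bins, cols: a bins
  pa <- colSums(pm); pb <- rowSums(pm)
  nz <- which(pm > 0)
  outer_ab <- outer(pb, pa)
  sum(pm[nz] * log(pm[nz] / outer_ab[nz]))
}

# Affine 2x3 matrix from parameters p = (tx, ty, theta_deg, log_sx, log_sy,
# shear), composed about `center` (0-based x, y). Maps fixed-frame (x, y)
# to moving-frame coordinates.
affine_from_params <- function(p, center) {
  th <- p[3] * pi / 180
  S <- diag(c(exp(p[4]), exp(p[5])))
  Sh <- matrix(c(1, 0, p[6], 1), 2, 2)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  A <- R %*% Sh %*% S
  tr <- center + p[1:2] - A %*% center
  cbind(A, tr)
}

affine_map <- function(A, shape) {
  X <- matrix(rep(0:(shape[2] - 1), each = shape[1]), shape[1])
  Y <- matrix(rep(0:(shape[1] - 1), shape[2]), shape[1])
  list(x = A[1, 1] * X + A[1, 2] * Y + A[1, 3],
       y = A[2, 1] * X + A[2, 2] * Y + A[2, 3])
}

# Cubic B-spline interpolation of a control-point displacement grid.
# grid: gy x gx x 2 array of (dx, dy) displacements in pixels; control point
# (i, j) sits at position ((i-2) * spacing, (j-2) * spacing) so one ring of
# controls lies outside the image on every side.
bspline_displacement <- function(grid, spacing, shape) {
  H <- shape[1]; W <- shape[2]
  gy <- dim(grid)[1]; gx <- dim(grid)[2]
  bw <- function(u) list((1 - u)^3 / 6,
                         (3 * u^3 - 6 * u^2 + 4) / 6,
                         (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6,
                         u^3 / 6)
  tx <- (0:(W - 1)) / spacing; ty <- (0:(H - 1)) / spacing
  ix <- floor(tx); iy <- floor(ty)
  wx <- bw(tx - ix); wy <- bw(ty - iy)
  dx <- matrix(0, H, W); dy <- matrix(0, H, W)
  gdx <- grid[, , 1]; gdy <- grid[, , 2]
  for (a in 1:4) {
    rows <- pmin(iy + a, gy)        # control row index, 1-based
    wya <- wy[[a]]
    for (b in 1:4) {
      cols <- pmin(ix + b, gx)
      w <- outer(wya, wx[[b]])
      idx <- outer(rows, (cols - 1L) * gy, "+")
      dx <- dx + w * gdx[idx]
      dy <- dy + w * gdy[idx]
    }
  }
  list(dx = dx, dy = dy)
}

#' Construct a transform chain
#'
#' @param affine 2 x 3 matrix mapping H&E (fixed) pixel coordinates to IHC
#'   (moving) coordinates, 0-based (x, y) convention.
#' @param bspline Optional list with `grid` (gy x gx x 2 displacement array)
#'   and `spacing` (control-point spacing in pixels at the working scale).
#' @param downscale Integer working-scale factor the transform was fitted at.
#' @param fixed_shape (H, W) of the fixed image at the working scale.
#' @return Object of class `transform_chain`.
#' @export
transform_chain <- function(affine, bspline = NULL, downscale = 1L,
                            fixed_shape = NULL) {
  if (abs(det(affine[, 1:2])) < 1e-12) stop("transform error: affine is singular")
  if (!is.null(bspline) && any(!is.finite(bspline$grid)))
    stop("transform error: non-finite B-spline displacements")
  structure(list(affine = affine, bspline = bspline,
                 downscale = as.integer(downscale), fixed_shape = fixed_shape),
            class = "transform_chain")
}

#' @export
print.transform_chain <- function(x, ...) {
  cat("Transform chain (fitted at 1/", x$downscale, " scale)\n", sep = "")
  cat("  affine:\n"); print(round(x$affine, 4))
  if (is.null(x$bspline)) cat("  B-spline: none\n")
  else cat("  B-spline: ", dim(x$bspline$grid)[1], "x", dim(x$bspline$grid)[2],
           " control grid, spacing ", x$bspline$spacing, " px\n", sep = "")
  invisible(x)
}

chain_map <- function(chain, shape) {
  m <- affine_map(chain$affine, shape)
  if (!is.null(chain$bspline)) {
    d <- bspline_displacement(chain$bspline$grid, chain$bspline$spacing, shape)
    m$x <- m$x + d$dx
    m$y <- m$y + d$dy
  }
  m
}

#' Apply a fitted transform to an image
#'
#' Resamples every channel of `img` with the same transform (bilinear
#' interpolation); pixels falling outside the moving image are filled with
#' white, matching the slide background.
#'
#' @param img RGB array or grayscale matrix at the transform's working scale.
#' @param chain A `transform_chain`.
#' @param target_shape (H, W) of the output (the H&E shape at the working
#'   scale); defaults to the chain's stored fixed shape.
#' @param fill Fill value for out-of-field pixels (default 255, white).
#' @return Resampled image of shape `target_shape`.
#' @export
apply_transform <- function(img, chain, target_shape = chain$fixed_shape,
                            fill = 255) {
  stopifnot(inherits(chain, "transform_chain"), !is.null(target_shape))
  m <- chain_map(chain, target_shape)
  out <- warp_bilinear(img, m$x, m$y, fill = fill)
  pmin(pmax(out, min(0, fill)), max(255, fill))
}

# Derivative-free compass (pattern) search with step halving: robust on the
# piecewise-flat surfaces a binned MI metric produces, and fully
# deterministic. Only the parameters in `idx` move.
pattern_search <- function(par, fn, idx, steps, min_step, max_evals = 2000) {
  best <- fn(par)
  evals <- 1
  step <- steps
  while (any(step[idx] > min_step[idx]) && evals < max_evals) {
    improved <- FALSE
    for (j in idx) {
      if (step[j] <= min_step[j] / 2) next
      for (sgn in c(1, -1)) {
        cand <- par; cand[j] <- cand[j] + sgn * step[j]
        v <- fn(cand); evals <- evals + 1
        if (v < best - 1e-12) { best <- v; par <- cand; improved <- TRUE; break }
      }
    }
    if (!improved) step <- step / 2
  }
  par
}

neg_mi <- function(p, fixed, moving, bins, center) {
  A <- affine_from_params(p, center)
  m <- affine_map(A, dim(fixed))
  w <- warp_bilinear(moving, m$x, m$y, fill = 255)
  v <- mutual_information(fixed, w, bins)
  if (!is.finite(v)) stop("registration error: non-finite metric value")
  -v
}

#' Register an IHC image onto its H&E counterpart
#'
#' Converts both images to grayscale, reduces them to the working scale
#' (`downscale`), and fits an affine transform followed (optionally) by a
#' cubic B-spline free-form deformation by maximizing mutual information
#' with a multi-resolution pyramid. The optimization is fully deterministic.
#'
#' @param he Fixed H&E image (H x W x 3, full resolution).
#' @param ihc Moving IHC image (H x W x 3, full resolution).
#' @param downscale Working-scale factor applied before fitting (default 5).
#' @param bins Histogram bins for the MI metric (default 50).
#' @param shrink Pyramid shrink factors per level, coarse to fine
#'   (default `c(4, 2, 1)` relative to the working scale).
#' @param maxit Optimizer iterations per pyramid level (default 200).
#' @param init_search_px Half-width of the exhaustive translation search
#'   used to initialize the coarsest level, in working-scale pixels
#'   (default 30).
#' @param do_bspline Fit the B-spline phase after the affine phase
#'   (default TRUE).
#' @param bspline_spacing Control-point spacing in working-scale pixels
#'   (default 64).
#' @param bspline_maxit L-BFGS iterations for the B-spline phase (default 15).
#' @param bspline_reg Quadratic penalty weight on control displacements
#'   (default 1e-4 per px^2).
#' @return List with `chain` (a [transform_chain()]) and `report` (an
#'   `mi_report` with `mi_before`, `mi_after_affine`, `mi_after_bspline`,
#'   `histogram_bins`).
#' @export
register_pair <- function(he, ihc, downscale = 5L, bins = 50L,
                          shrink = c(4L, 2L, 1L), maxit = 200L,
                          init_search_px = 30, do_bspline = TRUE,
                          bspline_spacing = 64, bspline_maxit = 15L,
                          bspline_reg = 1e-4) {
  stopifnot(downscale >= 1)
  gf <- downscale_mean(to_grayscale(he), downscale)
  gm <- downscale_mean(to_grayscale(ihc), downscale)
  fshape <- dim(gf)
  center <- c((fshape[2] - 1) / 2, (fshape[1] - 1) / 2)
  id_chain <- transform_chain(cbind(diag(2), c(0, 0)), downscale = downscale,
                              fixed_shape = fshape)
  mi_before <- mutual_information(gf, apply_transform(gm, id_chain), bins)

  # drop pyramid levels that would leave too few pixels to support the
  # histogram metric
  shrink <- shrink[pmin(fshape[1], fshape[2]) / shrink >= 32]
  if (length(shrink) == 0) shrink <- 1L

  p <- c(0, 0, 0, 0, 0, 0)
  free <- list(1:3, 1:6, 1:6)     # rigid at the coarsest level, affine after
  for (lev in seq_along(shrink)) {
    s <- shrink[lev]
    f <- downscale_mean(gf, s); m <- downscale_mean(gm, s)
    # few pixels support few histogram bins: cap bins by sample size
    bins_l <- max(16L, min(bins, as.integer(sqrt(length(f) / 2))))
    ctr <- c((ncol(f) - 1) / 2, (nrow(f) - 1) / 2)
    scale_t <- function(q, k) { q[1:2] <- q[1:2] * k; q }
    pl <- scale_t(p, 1 / s)
    if (lev == 1L) {
      # exhaustive translation x rotation initialization on the coarsest level
      r <- max(1, round(init_search_px / s))
      steps <- seq(-r, r, by = max(1, round(r / 6)))
      rots <- seq(-12, 12, by = 3)
      best <- Inf
      for (rot in rots) for (dx in steps) for (dy in steps) {
        v <- neg_mi(c(dx, dy, rot, pl[4:6]), f, m, bins_l, ctr)
        if (v < best) { best <- v; pl[1:3] <- c(dx, dy, rot) }
      }
    }
    idx <- free[[min(lev, length(free))]]
    obj <- function(q) neg_mi(q, f, m, bins_l, ctr)
    for (round in 1:2)   # a restart with fresh steps escapes shallow plateaus
      pl <- pattern_search(pl, obj, idx,
                           steps = c(2, 2, 2, 0.04, 0.04, 0.04),
                           min_step = c(0.05, 0.05, 0.05, 1e-3, 1e-3, 1e-3),
                           max_evals = maxit * 12)
    p <- scale_t(pl, s)
  }
  A <- affine_from_params(p, center)
  chain <- transform_chain(A, downscale = downscale, fixed_shape = fshape)
  mi_affine <- mutual_information(gf, apply_transform(gm, chain), bins)
  mi_bspline <- mi_affine

  if (do_bspline) {
    gy <- floor((fshape[1] - 1) / bspline_spacing) + 4L
    gx <- floor((fshape[2] - 1) / bspline_spacing) + 4L
    par0 <- numeric(gy * gx * 2)
    # the deformation is optimized on a half-resolution image (same physical
    # control grid, displacements scaled) to keep the finite-difference
    # L-BFGS affordable, then carried back to the fitting resolution
    bs <- 2L
    f2 <- downscale_mean(gf, bs); m2 <- downscale_mean(gm, bs)
    A2 <- affine_at_scale(A, bs)
    bobj <- function(q) {
      grid <- array(q / bs, c(gy, gx, 2))
      ch <- transform_chain(A2, list(grid = grid, spacing = bspline_spacing / bs),
                            downscale, dim(f2))
      -mutual_information(f2, apply_transform(m2, ch), bins) +
        bspline_reg * mean(q^2)
    }
    np <- length(par0)
    par_b <- pattern_search(par0, bobj, seq_len(np),
                            steps = rep(2, np), min_step = rep(0.25, np),
                            max_evals = bspline_maxit * 2L * np)
    grid <- array(par_b, c(gy, gx, 2))
    chain <- transform_chain(A, list(grid = grid, spacing = bspline_spacing),
                             downscale, fshape)
    mi_bspline <- mutual_information(gf, apply_transform(gm, chain), bins)
    if (mi_bspline < mi_affine) {   # keep the deformation only if it helps
      chain <- transform_chain(A, downscale = downscale, fixed_shape = fshape)
      mi_bspline <- mi_affine
    }
  }
  report <- structure(list(mi_before = mi_before, mi_after_affine = mi_affine,
                           mi_after_bspline = mi_bspline,
                           histogram_bins = as.integer(bins)),
                      class = "mi_report")
  list(chain = chain, report = report)
}

#' @export
print.mi_report <- function(x, ...) {
  cat(sprintf("MI before: %.4f  after affine: %.4f  after B-spline: %.4f (%d bins)\n",
              x$mi_before, x$mi_after_affine, x$mi_after_bspline, x$histogram_bins))
  invisible(x)
}

#' Serialize / deserialize a transform chain to JSON
#'
#' @param chain A `transform_chain`.
#' @param path Output (input) JSON file path.
#' @return `transform_from_json` returns a `transform_chain`.
#' @export
transform_to_json <- function(chain, path) {
  obj <- list(affine = as.vector(t(chain$affine)),   # row-major
              downscale = chain$downscale, fixed_shape = chain$fixed_shape)
  if (!is.null(chain$bspline))
    obj$bspline <- list(spacing = chain$bspline$spacing,
                        dim = dim(chain$bspline$grid),
                        displacements = as.vector(chain$bspline$grid))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname transform_to_json
#' @export
transform_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bspline <- NULL
  if (!is.null(obj$bspline))
    bspline <- list(grid = array(obj$bspline$displacements, obj$bspline$dim),
                    spacing = obj$bspline$spacing)
  transform_chain(matrix(obj$affine, 2, 3, byrow = TRUE), bspline,
                  obj$downscale, obj$fixed_shape)
}
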