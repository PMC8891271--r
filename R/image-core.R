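# Images are plain numeric arrays, H x W x 3 for RGB (values 0..255) or
# H x W matrices for grayscale / single channels.  Pixel (0,0) is top-left;
# transform code uses 0-based (x = col, y = row) pixel-centre coordinates.

assert_rgb <- function(img, arg = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(arg, " must be an H x W x 3 array", call. = FALSE)
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop(arg, " must contain values in [0, 255]", call. = FALSE)
  invisible(img)
}

#' Read an RGB image
#'
#' Reads a lossless flat raster (PNG or TIFF) into an H x W x 3 array of
#' 8-bit intensities in \[0, 255\]. Pyramidal whole-slide formats are
#' supported through a pluggable reader: pass a function as `reader` that
#' returns the requested level as an H x W x 3 array in \[0, 1\] or
#' \[0, 255\]. For flat files only level 0 exists.
#'
#' @param path Path to a PNG or TIFF file.
#' @param level Pyramid level; must be 0 for flat PNG/TIFF.
#' @param reader Optional function `(path, level)` implementing a custom
#'   (e.g. whole-slide) reader.
#' @return Numeric H x W x 3 array in \[0, 255\].
#' @export
read_image <- function(path, level = 0L, reader = NULL) {
  if (!is.null(reader)) {
    img <- reader(path, level)
  } else {
    if (!file.exists(path)) stop("cannot read image: no such file: ", path)
    if (level != 0L)
      stop("level ", level, " not available: flat PNG/TIFF images only have level 0")
    ext <- tolower(tools::file_ext(path))
    img <- switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = tiff::readTIFF(path),
      stop("unsupported image format: .", ext)
    )
    img <- img * 255
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  img <- round(img)
  assert_rgb(img, "decoded image")
  img
}

#' Write an RGB image losslessly
#'
#' @param img H x W x 3 array in \[0, 255\] (or an H x W matrix, written as
#'   a single-channel image).
#' @param path Output path; format chosen by extension (.png or .tif/.tiff).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  x <- pmin(pmax(img / 255, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(x, path),
    tif = ,
    tiff = tiff::writeTIFF(x, path, compression = "LZW"),
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}

#' Convert RGB to luminance grayscale
#'
#' Standard Rec. 601 luminance weights (0.299, 0.587, 0.114), returned as an
#' 8-bit H x W matrix.
#'
#' @param img H x W x 3 array in \[0, 255\].
#' @return H x W numeric matrix in \[0, 255\].
#' @export
to_grayscale <- function(img) {
  assert_rgb(img)
  g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  matrix(round(pmin(pmax(g, 0), 255)), dim(img)[1], dim(img)[2])
}

# Block-mean downscaling by an integer factor; trailing rows/cols that do not
# fill a full block are dropped.  Used both as the registration working-scale
# reduction and as the anti-aliased pyramid shrink.
downscale_mean <- function(img, factor) {
  factor <- as.integer(factor)
  if (factor == 1L) return(img)
  d <- dim(img)
  H <- (d[1] %/% factor) * factor
  W <- (d[2] %/% factor) * factor
  shrink1 <- function(m) {
    m <- m[seq_len(H), seq_len(W), drop = FALSE]
    # average factor x factor blocks
    m <- matrix(colMeans(matrix(m, nrow = factor)), nrow = H %/% factor)
    t(matrix(colMeans(matrix(t(m), nrow = factor)), nrow = W %/% factor))
  }
  if (length(d) == 2L) return(shrink1(img))
  out <- array(0, c(H %/% factor, W %/% factor, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- shrink1(img[, , ch])
  out
}

# Bilinear sampling of `img` at source coordinates (mapx, mapy), both
# matrices of the output shape, 0-based pixel centres. Out-of-field samples
# take `fill`.
warp_bilinear <- function(img, mapx, mapy, fill = 255) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  nc <- if (length(d) == 3L) d[3] else 1L
  inside <- mapx >= 0 & mapx <= (W - 1) & mapy >= 0 & mapy <= (H - 1)
  x0 <- pmin(pmax(floor(mapx), 0), W - 1)
  y0 <- pmin(pmax(floor(mapy), 0), H - 1)
  fx <- pmin(pmax(mapx - x0, 0), 1)
  fy <- pmin(pmax(mapy - y0, 0), 1)
  x1 <- pmin(x0 + 1, W - 1)
  y1 <- pmin(y0 + 1, H - 1)
  i00 <- y0 + x0 * H + 1; i10 <- y1 + x0 * H + 1
  i01 <- y0 + x1 * H + 1; i11 <- y1 + x1 * H + 1
  w00 <- (1 - fx) * (1 - fy); w10 <- (1 - fx) * fy
  w01 <- fx * (1 - fy);       w11 <- fx * fy
  sample_plane <- function(p) {
    v <- w00 * p[i00] + w10 * p[i10] + w01 * p[i01] + w11 * p[i11]
    v[!inside] <- fill
    matrix(v, nrow = nrow(mapx))
  }
  if (nc == 1L && length(d) == 2L) return(sample_plane(img))
  out <- array(fill, c(dim(mapx), nc))
  for (ch in seq_len(nc)) out[, , ch] <- sample_plane(img[, , ch])
  out
}
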