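# Tile, manifest and annotation-mask I/O shared by all pipeline stages.
# The manifest is a UTF-8 CSV with header and "." decimal separator; one row
# per grid tile, discarded tiles included (with an empty tile_path).

#' Write tile images and their manifest
#'
#' Writes one lossless PNG per non-discarded tile record and returns the
#' manifest with a `tile_path` column (empty for discarded records). Tiles
#' are cut from the full-resolution image at `he_tile_px`.
#'
#' @param image H x W x 3 RGB array the tiles are cut from.
#' @param records Manifest data.frame of tile records (see
#'   [build_dataset()]).
#' @param out_dir Output directory, created if needed.
#' @return The manifest with `tile_path` filled in.
#' @export
write_tiles <- function(image, records, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  records$tile_path <- rep("", nrow(records))
  if (nrow(records) == 0) return(records)
  tp <- records$he_tile_px[1]
  d <- dim(image)
  for (i in seq_len(nrow(records))) {
    r <- records$tile_row[i]; cc <- records$tile_col[i]
    if ((r + 1) * tp > d[1] || (cc + 1) * tp > d[2] || r < 0 || cc < 0)
      stop("coordinate error: tile (", r, ", ", cc, ") lies outside the image")
    if (identical(records$label[i], "discarded")) next
    tile <- image[(r * tp + 1):((r + 1) * tp), (cc * tp + 1):((cc + 1) * tp), , drop = FALSE]
    path <- file.path(out_dir, sprintf("%s_r%03d_c%03d.png", records$slide_id[i], r, cc))
    write_image(tile, path)
    records$tile_path[i] <- path
  }
  records
}

#' Read or write a label manifest CSV
#'
#' @param manifest Manifest data.frame.
#' @param path CSV path.
#' @return `read_manifest` returns the manifest data.frame.
#' @export
write_manifest <- function(manifest, path) {
  out <- manifest
  # 17 significant digits make the double -> text -> double trip lossless
  for (col in names(out))
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = which(vapply(out, is.character, logical(1))))
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("cannot read manifest: no such file: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  for (col in c("slide_id", "label", "reason", "tile_path"))
    if (!is.null(m[[col]])) m[[col]][is.na(m[[col]])] <- ""
  if (anyDuplicated(m[, c("slide_id", "tile_row", "tile_col")]))
    stop("manifest has duplicate (slide_id, tile_row, tile_col) keys")
  m
}

#' Read a pathologist annotation mask
#'
#' Accepts either a single-channel binary PNG raster of shape `shape`, or a
#' GeoJSON file of polygons in level-0 H&E pixel coordinates which is
#' rasterized to `shape`. Raster masks must contain exactly the two values
#' 0 and 255 (or 0 and 1).
#'
#' @param path PNG or GeoJSON path.
#' @param shape Target (H, W).
#' @return Logical H x W matrix, TRUE inside the annotated cancer region.
#' @export
read_annotation_mask <- function(path, shape) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("json", "geojson")) {
    gj <- jsonlite::read_json(path, simplifyVector = TRUE)
    mask <- matrix(FALSE, shape[1], shape[2])
    feats <- gj$features
    polys <- if (is.data.frame(feats)) seq_len(nrow(feats)) else seq_along(feats)
    for (i in polys) {
      coords <- if (is.data.frame(feats)) feats$geometry$coordinates[[i]] else
        feats[[i]]$geometry$coordinates
      ring <- matrix(unlist(coords), ncol = 2, byrow = !is.matrix(coords[[1]]))
      if (is.array(coords) && length(dim(coords)) == 3) ring <- coords[1, , ]
      mask <- mask | rasterize_polygon(ring, shape)
    }
    return(mask)
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  vals <- sort(unique(round(as.vector(img) * 255)))
  if (length(vals) > 2)
    stop("annotation mask must be binary; found ", length(vals), " gray levels")
  if (!identical(dim(img), as.integer(shape)))
    stop("shape error: mask is ", paste(dim(img), collapse = "x"),
         ", expected ", paste(shape, collapse = "x"))
  img > (max(vals) / 2 / 255)
}

# Even-odd rule polygon rasterization at pixel centres; vertices are
# 0-based (x, y) level-0 pixel coordinates.
rasterize_polygon <- function(ring, shape) {
  xs <- ring[, 1]; ys <- ring[, 2]
  n <- length(xs)
  xv <- matrix(rep(0:(shape[2] - 1), each = shape[1]), shape[1])
  yv <- matrix(rep(0:(shape[1] - 1), shape[2]), shape[1])
  inside <- matrix(FALSE, shape[1], shape[2])
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > yv) != (ys[j] > yv))
    xint <- (xs[j] - xs[i]) * (yv - ys[i]) / (ys[j] - ys[i] + 1e-300) + xs[i]
    inside <- xor(inside, crosses & (xv < xint))
    j <- i
  }
  inside
}
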