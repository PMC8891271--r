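# Tile-level label transfer. The H&E image is split into tile_px x tile_px
# tiles (default 224); labeling happens on the registered IHC image at the
# registration working scale, where each tile covers label_px x label_px
# pixels (224 / 5 -> 45). A tile is cancer when more than 2% of its pixels
# are DAB-positive, with an uncertainty band on mean DAB OD taking
# precedence, plus tissue-presence and slide-level quality filters.

#' Labeling configuration
#'
#' @param tile_px Full-resolution H&E tile size in pixels (default 224).
#' @param downscale Registration working-scale factor (default 5); the
#'   label tile size is `round(tile_px / downscale)`.
#' @param cancer_fraction_threshold Fraction of DAB-positive pixels above
#'   which a tile is cancer (default 0.02, the 2% rule).
#' @param dab_uncertain_low,dab_uncertain_high Mean-DAB-OD band (inclusive)
#'   inside which a tile is labeled uncertain regardless of the 2% rule
#'   (defaults 0.05 and 0.15 OD; user-selectable).
#' @param tissue_presence_min Minimum tissue fraction for a tile to count
#'   as containing tissue (default 0.05).
#' @param train_filter Apply the slide-level training filter in
#'   [build_dataset()] (default TRUE).
#' @param annotation_cover_min Fraction of a tile's area that must lie
#'   inside a pathologist annotation for the tile to be labeled cancer in
#'   annotation-based evaluation (default 0.5).
#' @return List of class `labeling_config`.
#' @export
labeling_config <- function(tile_px = 224L, downscale = 5L,
                            cancer_fraction_threshold = 0.02,
                            dab_uncertain_low = 0.05, dab_uncertain_high = 0.15,
                            tissue_presence_min = 0.05, train_filter = TRUE,
                            annotation_cover_min = 0.5) {
  stopifnot(tile_px >= 1, downscale >= 1,
            dab_uncertain_low >= 0, dab_uncertain_low <= dab_uncertain_high)
  structure(list(tile_px = as.integer(tile_px), downscale = as.integer(downscale),
                 label_px = as.integer(round(tile_px / downscale)),
                 cancer_fraction_threshold = cancer_fraction_threshold,
                 dab_uncertain_low = dab_uncertain_low,
                 dab_uncertain_high = dab_uncertain_high,
                 tissue_presence_min = tissue_presence_min,
                 train_filter = isTRUE(train_filter),
                 annotation_cover_min = annotation_cover_min),
            class = "labeling_config")
}

#' Tile grid of an image
#'
#' All non-overlapping, fully contained `tile_px` x `tile_px` tiles in
#' row-major order; partial tiles at the right/bottom edges are dropped.
#' Grid indices are 0-based: tile (r, c) covers pixel rows
#' `r * tile_px .. (r+1) * tile_px - 1`.
#'
#' @param image_shape (H, W).
#' @param tile_px Tile size in pixels.
#' @return data.frame with columns `tile_row`, `tile_col`.
#' @export
tile_grid <- function(image_shape, tile_px) {
  stopifnot(tile_px >= 1)
  nr <- image_shape[1] %/% tile_px
  nc <- image_shape[2] %/% tile_px
  if (nr == 0 || nc == 0)
    return(data.frame(tile_row = integer(), tile_col = integer()))
  expand.grid(tile_col = 0:(nc - 1), tile_row = 0:(nr - 1))[, c("tile_row", "tile_col")]
}

#' Label one tile from its DAB statistics
#'
#' Computes the DAB-positive pixel fraction over all pixels of the label
#' tile and the mean DAB OD over the tile's tissue pixels, then applies the
#' 2% rule: cancer iff the fraction exceeds
#' `cancer_fraction_threshold`, else normal. The uncertainty band takes
#' precedence: if the mean DAB OD falls inside
#' `[dab_uncertain_low, dab_uncertain_high]` the tile is uncertain no
#' matter what the fraction says.
#'
#' @param dab_positive Logical matrix, the positive mask restricted to the
#'   tile.
#' @param dab_od Numeric matrix, DAB OD of the tile.
#' @param tissue Logical matrix, tissue mask of the tile.
#' @param cfg A [labeling_config()].
#' @return List with `dab_positive_fraction`, `mean_dab_od`, `label`.
#' @export
label_tile <- function(dab_positive, dab_od, tissue, cfg = labeling_config()) {
  if (length(dab_positive) == 0) stop("empty tile")
  frac <- mean(dab_positive)
  mean_od <- if (any(tissue)) mean(dab_od[tissue]) else 0
  label <- if (frac > cfg$cancer_fraction_threshold) "cancer" else "normal"
  if (mean_od >= cfg$dab_uncertain_low && mean_od <= cfg$dab_uncertain_high)
    label <- "uncertain"
  list(dab_positive_fraction = frac, mean_dab_od = mean_od, label = label)
}

#' Tissue-presence check for a tile pair
#'
#' Guards against registration errors: a tile is discarded when exactly one
#' of the H&E / IHC tiles contains tissue (`"tissue_mismatch"`), and
#' dropped as background when neither does (`"no_tissue"`).
#'
#' @param tissue_fraction_he,tissue_fraction_ihc Tissue fractions of the
#'   aligned tile pair, in \[0, 1\].
#' @param cfg A [labeling_config()]; `tissue_presence_min` is the fraction
#'   at which a tile counts as containing tissue.
#' @return List with `keep` (logical) and `reason` (`""` when kept).
#' @export
tissue_presence_check <- function(tissue_fraction_he, tissue_fraction_ihc,
                                  cfg = labeling_config()) {
  he_has <- tissue_fraction_he >= cfg$tissue_presence_min
  ihc_has <- tissue_fraction_ihc >= cfg$tissue_presence_min
  if (he_has && ihc_has) list(keep = TRUE, reason = "")
  else if (!he_has && !ihc_has) list(keep = FALSE, reason = "no_tissue")
  else list(keep = FALSE, reason = "tissue_mismatch")
}

#' Slide-level training filter
#'
#' For a clean training set, only cancer tiles from cancer slides and only
#' normal tiles from non-cancer slides are kept; everything else is
#' re-labeled discarded with reason `"slide_filter"`. In `"eval"` mode the
#' records pass through untouched.
#'
#' @param records data.frame of tile records with a `label` column.
#' @param status Slide status, `"cancer"` or `"non_cancer"`.
#' @param mode `"train"` (default) or `"eval"`.
#' @return The records with updated `label` / `reason` columns.
#' @export
apply_slide_filter <- function(records, status = c("cancer", "non_cancer"),
                               mode = c("train", "eval")) {
  status <- match.arg(status)
  mode <- match.arg(mode)
  if (mode == "eval" || nrow(records) == 0) return(records)
  keep_label <- if (status == "cancer") "cancer" else "normal"
  drop <- records$label %in% c("cancer", "normal") & records$label != keep_label
  if (is.null(records$reason)) records$reason <- ""
  records$label[drop] <- "discarded"
  records$reason[drop] <- "slide_filter"
  records
}

# Label every tile of one registered slide pair. he_norm: normalized H&E at
# full resolution; ihc_reg: registered IHC at the working scale. Returns the
# per-tile record data.frame (all grid tiles, labeled or discarded).
label_slide <- function(slide_id, he_norm, ihc_reg, cfg = labeling_config(),
                        mode = c("train", "eval"),
                        status = c("cancer", "non_cancer")) {
  mode <- match.arg(mode); status <- match.arg(status)
  stack <- deconvolve_hed(ihc_reg)
  masks <- compute_masks(stack)
  he_small <- downscale_mean(he_norm, cfg$downscale)
  he_tissue <- segment_tissue(he_small)
  lp <- cfg$label_px
  nr <- min(dim(he_norm)[1] %/% cfg$tile_px, nrow(masks$tissue) %/% lp,
            nrow(he_tissue) %/% lp)
  nc <- min(dim(he_norm)[2] %/% cfg$tile_px, ncol(masks$tissue) %/% lp,
            ncol(he_tissue) %/% lp)
  out <- vector("list", nr * nc)
  k <- 0L
  for (r in seq_len(nr) - 1L) for (cc in seq_len(nc) - 1L) {
    rows <- (r * lp + 1):((r + 1) * lp)
    cols <- (cc * lp + 1):((cc + 1) * lp)
    tf_he <- mean(he_tissue[rows, cols])
    tf_ihc <- mean(masks$tissue[rows, cols])
    lab <- label_tile(masks$dab_positive[rows, cols], stack$dab[rows, cols],
                      masks$tissue[rows, cols], cfg)
    chk <- tissue_presence_check(tf_he, tf_ihc, cfg)
    label <- lab$label; reason <- ""
    if (!chk$keep) { label <- "discarded"; reason <- chk$reason }
    k <- k + 1L
    out[[k]] <- data.frame(
      slide_id = slide_id, tile_row = r, tile_col = cc,
      he_tile_px = cfg$tile_px, label_tile_px = lp,
      dab_positive_fraction = lab$dab_positive_fraction,
      mean_dab_od = lab$mean_dab_od,
      tissue_fraction_he = tf_he, tissue_fraction_ihc = tf_ihc,
      label = label, reason = reason, stringsAsFactors = FALSE
    )
  }
  records <- do.call(rbind, out)
  if (is.null(records)) records <- empty_manifest()
  if (mode == "train" && cfg$train_filter && nrow(records) > 0)
    records <- apply_slide_filter(records, status, mode = "train")
  if (status == "cancer" && mode == "train" &&
      nrow(records) > 0 && !any(records$label == "cancer"))
    warning("cancer slide ", slide_id, ": no cancer tiles survived labeling")
  records
}

empty_manifest <- function() {
  data.frame(slide_id = character(), tile_row = integer(), tile_col = integer(),
             he_tile_px = integer(), label_tile_px = integer(),
             dab_positive_fraction = numeric(), mean_dab_od = numeric(),
             tissue_fraction_he = numeric(), tissue_fraction_ihc = numeric(),
             label = character(), reason = character(), stringsAsFactors = FALSE)
}

#' Build a labeled tile dataset from registered slide pairs
#'
#' Runs mask computation, tiling, tile labeling, the tissue-presence check
#' and (in training mode) the slide-level filter for every pair, and
#' aggregates the per-tile records into one manifest.
#'
#' @param pairs List of slide pairs; each element is a list with
#'   `slide_id`, `he` (normalized full-resolution H&E), `ihc_reg`
#'   (registered IHC at the working scale) and `status`.
#' @param cfg A [labeling_config()].
#' @param mode `"train"` (slide filter applied) or `"eval"`.
#' @return Manifest data.frame of tile records across all slides.
#' @export
build_dataset <- function(pairs, cfg = labeling_config(),
                          mode = c("train", "eval")) {
  mode <- match.arg(mode)
  if (length(pairs) == 0) return(empty_manifest())
  do.call(rbind, lapply(pairs, function(p)
    label_slide(p$slide_id, p$he, p$ihc_reg, cfg, mode = mode, status = p$status)))
}

#' Label tiles from a pathologist annotation mask
#'
#' A tile is cancer when at least `annotation_cover_min` of its area lies
#' inside the annotation mask; remaining tiles are normal.
#'
#' @param mask Logical H&E-resolution annotation mask.
#' @param cfg A [labeling_config()].
#' @return data.frame with `tile_row`, `tile_col`, `label`.
#' @export
annotation_tile_labels <- function(mask, cfg = labeling_config()) {
  g <- tile_grid(dim(mask), cfg$tile_px)
  if (nrow(g) == 0) return(cbind(g, label = character()))
  g$label <- vapply(seq_len(nrow(g)), function(i) {
    rows <- (g$tile_row[i] * cfg$tile_px + 1):((g$tile_row[i] + 1) * cfg$tile_px)
    cols <- (g$tile_col[i] * cfg$tile_px + 1):((g$tile_col[i] + 1) * cfg$tile_px)
    if (mean(mask[rows, cols]) >= cfg$annotation_cover_min) "cancer" else "normal"
  }, character(1))
  g
}
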