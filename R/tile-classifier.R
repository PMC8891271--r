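# Transfer-learning tile classifier: a frozen feature backbone feeding a
# trainable head (one dense hidden layer + a single sigmoid output, binary
# cross-entropy, Adam). The bundled "tiny" backbone computes deterministic
# pooled color/stain/texture statistics so the package needs no pretrained
# weights; ImageNet-style backbones (vgg16 etc., 512-dim pooled features)
# plug in as user-supplied feature functions and are never updated during
# training.

#' Classifier specification
#'
#' @param backbone `"tiny"` (bundled, 32-dim deterministic features) or the
#'   name of an external backbone (`"vgg16"`, `"resnet50"`, `"vgg19"`,
#'   `"inceptionv3"`, `"xception"`); external backbones require
#'   `feature_fun`.
#' @param feature_fun Optional function `(tile) -> numeric vector`
#'   implementing an external frozen feature extractor (e.g. the 512-dim
#'   pooled VGG16 output).
#' @param hidden Width of the dense hidden layer (default 256).
#' @param epochs Training epochs (default 100).
#' @param lr Adam learning rate (default 1e-4).
#' @param batch_size Minibatch size (default 32).
#' @param augment Use rotation (0/90/180/270) and flip augmentation of
#'   training tiles (default TRUE).
#' @param seed RNG seed for weight initialization and shuffling.
#' @return List of class `classifier_spec`.
#' @export
classifier_spec <- function(backbone = c("tiny", "vgg16", "resnet50", "vgg19",
                                         "inceptionv3", "xception"),
                            feature_fun = NULL, hidden = 256L, epochs = 100L,
                            lr = 1e-4, batch_size = 32L, augment = TRUE,
                            seed = 1L) {
  backbone <- match.arg(backbone)
  if (backbone != "tiny" && !is.function(feature_fun))
    stop("backbone '", backbone, "' requires a feature_fun; pretrained weights are not bundled")
  structure(list(backbone = backbone, feature_fun = feature_fun,
                 hidden = as.integer(hidden), epochs = as.integer(epochs),
                 lr = lr, batch_size = as.integer(batch_size),
                 augment = isTRUE(augment), seed = as.integer(seed)),
            class = "classifier_spec")
}

# Pooled statistics of a matrix: mean, sd, 10th/90th percentiles.
pool_stats <- function(m) {
  q <- stats::quantile(m, c(0.1, 0.9), names = FALSE)
  c(mean(m), stats::sd(as.vector(m)), q)
}

#' Extract frozen backbone features from a tile
#'
#' The `"tiny"` backbone pools color (RGB), stain (H/E/DAB optical
#' density) and texture (gradient magnitude) statistics into a fixed 32-dim
#' vector; it has no weights, so it is trivially frozen and deterministic.
#' External backbones delegate to `spec$feature_fun` (512-dim for the VGG16
#' pooled output).
#'
#' @param tile H x W x 3 RGB array (any square size for `"tiny"`; must
#'   match the backbone's input size for external backbones).
#' @param spec A [classifier_spec()].
#' @return Numeric feature vector.
#' @export
extract_features <- function(tile, spec = classifier_spec()) {
  if (spec$backbone != "tiny") return(as.numeric(spec$feature_fun(tile)))
  assert_rgb(tile)
  stack <- deconvolve_hed(tile)
  g <- to_grayscale(tile)
  gx <- g[, -1, drop = FALSE] - g[, -ncol(g), drop = FALSE]
  gy <- g[-1, , drop = FALSE] - g[-nrow(g), , drop = FALSE]
  feats <- c(
    pool_stats(tile[, , 1]), pool_stats(tile[, , 2]), pool_stats(tile[, , 3]),
    pool_stats(stack$hematoxylin), pool_stats(stack$eosin), pool_stats(stack$dab),
    pool_stats(abs(gx)), pool_stats(abs(gy))
  )
  unname(feats)
}

# Geometric augmentations of a tile: 4 rotations x optional flip.
augment_tiles <- function(tile) {
  rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])
  rot_img <- function(img) {
    out <- array(0, c(dim(img)[2], dim(img)[1], 3))
    for (ch in 1:3) out[, , ch] <- rot90(img[, , ch])
    out
  }
  flip_img <- function(img) img[nrow(img):1, , , drop = FALSE]
  tiles <- list(tile)
  for (i in 1:3) tiles[[i + 1]] <- rot_img(tiles[[i]])
  c(tiles, lapply(tiles, flip_img))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train the tile classification head
#'
#' Fits the dense head (hidden ReLU layer + single sigmoid output) on a
#' feature matrix with binary cross-entropy loss and minibatch Adam. The
#' backbone contributes only the features and is never updated. Training is
#' exactly reproducible from `spec$seed`.
#'
#' @param x Numeric feature matrix, one row per tile.
#' @param y Labels: `"cancer"`/`"normal"` character vector or 0/1 numeric
#'   (1 = cancer).
#' @param spec A [classifier_spec()].
#' @return Object of class `hem_classifier`.
#' @export
hem_classifier <- function(x, y, spec = classifier_spec()) {
  x <- as.matrix(x)
  if (is.character(y) || is.factor(y)) y <- as.numeric(as.character(y) == "cancer")
  if (length(unique(y)) < 2)
    stop("training error: need both classes in the training labels")
  mu <- colMeans(x); sdv <- apply(x, 2, stats::sd); sdv[sdv < 1e-8] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  n <- nrow(xs); p <- ncol(xs); h <- spec$hidden
  withr::with_seed(spec$seed, {
    W1 <- matrix(stats::rnorm(p * h, sd = sqrt(2 / p)), p, h)
    b1 <- numeric(h)
    W2 <- matrix(stats::rnorm(h, sd = sqrt(1 / h)), h, 1)
    b2 <- 0
    adam <- list(t = 0)
    m_ <- list(W1 = W1 * 0, b1 = b1 * 0, W2 = W2 * 0, b2 = 0)
    v_ <- m_
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    history <- numeric(spec$epochs)
    for (ep in seq_len(spec$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = spec$batch_size)) {
        idx <- ord[start:min(start + spec$batch_size - 1, n)]
        xb <- xs[idx, , drop = FALSE]; yb <- y[idx]
        a1 <- xb %*% W1
        a1 <- sweep(a1, 2, b1, "+")
        z1 <- pmax(a1, 0)
        out <- as.vector(sigmoid(z1 %*% W2 + b2))
        derr <- (out - yb) / length(yb)
        gW2 <- t(z1) %*% derr
        gb2 <- sum(derr)
        dz1 <- (derr %*% t(W2)) * (a1 > 0)
        gW1 <- t(xb) %*% dz1
        gb1 <- colSums(dz1)
        adam$t <- adam$t + 1
        upd <- function(par, g, mm, vv) {
          mm <- beta1 * mm + (1 - beta1) * g
          vv <- beta2 * vv + (1 - beta2) * g^2
          mhat <- mm / (1 - beta1^adam$t)
          vhat <- vv / (1 - beta2^adam$t)
          list(par = par - spec$lr * mhat / (sqrt(vhat) + eps), m = mm, v = vv)
        }
        u <- upd(W1, gW1, m_$W1, v_$W1); W1 <- u$par; m_$W1 <- u$m; v_$W1 <- u$v
        u <- upd(b1, gb1, m_$b1, v_$b1); b1 <- u$par; m_$b1 <- u$m; v_$b1 <- u$v
        u <- upd(W2, gW2, m_$W2, v_$W2); W2 <- u$par; m_$W2 <- u$m; v_$W2 <- u$v
        u <- upd(b2, gb2, m_$b2, v_$b2); b2 <- u$par; m_$b2 <- u$m; v_$b2 <- u$v
      }
      z1 <- pmax(sweep(xs %*% W1, 2, b1, "+"), 0)
      out <- as.vector(sigmoid(z1 %*% W2 + b2))
      history[ep] <- -mean(y * log(pmax(out, 1e-12)) +
                           (1 - y) * log(pmax(1 - out, 1e-12)))
    }
  })
  structure(list(spec = spec, mu = mu, sd = sdv,
                 W1 = W1, b1 = b1, W2 = W2, b2 = b2, loss = history),
            class = "hem_classifier")
}

#' @export
print.hem_classifier <- function(x, ...) {
  cat("Tile classifier: frozen '", x$spec$backbone, "' backbone (",
      length(x$mu), " features) + dense(", x$spec$hidden,
      ") + sigmoid head\n", sep = "")
  cat(sprintf("  trained %d epochs, final BCE loss %.4f\n",
              x$spec$epochs, x$loss[length(x$loss)]))
  invisible(x)
}

#' Predict cancer probability for tiles
#'
#' @param object A fitted `hem_classifier`.
#' @param newdata Feature matrix (rows = tiles) or a list of RGB tiles.
#' @param ... Unused.
#' @return Numeric vector of cancer probabilities in (0, 1), one per tile;
#'   independent of tile order.
#' @export
predict.hem_classifier <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.data.frame(newdata) && !is.matrix(newdata))
    newdata <- do.call(rbind, lapply(newdata, extract_features, spec = object$spec))
  x <- as.matrix(newdata)
  xs <- sweep(sweep(x, 2, object$mu), 2, object$sd, "/")
  z1 <- pmax(sweep(xs %*% object$W1, 2, object$b1, "+"), 0)
  as.vector(sigmoid(z1 %*% object$W2 + object$b2))
}

# Cut the full-resolution tile for a manifest row.
cut_tile <- function(image, tile_row, tile_col, tile_px) {
  image[(tile_row * tile_px + 1):((tile_row + 1) * tile_px),
        (tile_col * tile_px + 1):((tile_col + 1) * tile_px), , drop = FALSE]
}

#' Train a tile classifier from a label manifest
#'
#' Extracts backbone features for every kept (cancer/normal) tile —
#' including rotated/flipped copies when augmentation is on, each copy
#' inheriting its source tile's label — and fits the head.
#'
#' @param manifest Tile manifest (see [build_dataset()]); only rows with
#'   label `"cancer"` or `"normal"` are used.
#' @param images Named list mapping slide_id to the normalized H&E array.
#' @param spec A [classifier_spec()].
#' @return A fitted `hem_classifier`.
#' @export
train_tile_classifier <- function(manifest, images, spec = classifier_spec()) {
  rows <- manifest[manifest$label %in% c("cancer", "normal"), , drop = FALSE]
  if (nrow(rows) == 0) stop("training error: manifest has no kept tiles")
  feats <- list(); labs <- character(0)
  for (i in seq_len(nrow(rows))) {
    img <- images[[rows$slide_id[i]]]
    if (is.null(img)) stop("no image supplied for slide ", rows$slide_id[i])
    tile <- cut_tile(img, rows$tile_row[i], rows$tile_col[i], rows$he_tile_px[i])
    tiles <- if (spec$augment) augment_tiles(tile) else list(tile)
    for (t in tiles) {
      feats[[length(feats) + 1]] <- extract_features(t, spec)
      labs <- c(labs, rows$label[i])
    }
  }
  hem_classifier(do.call(rbind, feats), labs, spec)
}

#' Predict over a tile manifest
#'
#' @param model A fitted `hem_classifier`.
#' @param manifest Tile manifest; all rows are scored.
#' @param images Named list mapping slide_id to the normalized H&E array.
#' @return data.frame `slide_id`, `tile_row`, `tile_col`, `p_cancer`.
#' @export
predict_tiles <- function(model, manifest, images) {
  feats <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
    img <- images[[manifest$slide_id[i]]]
    if (is.null(img)) stop("no image supplied for slide ", manifest$slide_id[i])
    extract_features(cut_tile(img, manifest$tile_row[i], manifest$tile_col[i],
                              manifest$he_tile_px[i]), model$spec)
  }))
  data.frame(slide_id = manifest$slide_id, tile_row = manifest$tile_row,
             tile_col = manifest$tile_col,
             p_cancer = predict(model, feats), stringsAsFactors = FALSE)
}

#' Serialize / load a fitted classifier as JSON
#'
#' @param model A `hem_classifier`.
#' @param path JSON path.
#' @return `classifier_from_json` returns the restored model.
#' @export
classifier_to_json <- function(model, path) {
  obj <- list(spec = model$spec[c("backbone", "hidden", "epochs", "lr",
                                  "batch_size", "augment", "seed")],
              mu = model$mu, sd = model$sd,
              W1 = list(dim = dim(model$W1), data = as.vector(model$W1)),
              b1 = model$b1,
              W2 = as.vector(model$W2), b2 = model$b2, loss = model$loss)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname classifier_to_json
#' @export
classifier_from_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(classifier_spec, as.list(o$spec))
  structure(list(spec = spec, mu = o$mu, sd = o$sd,
                 W1 = matrix(o$W1$data, o$W1$dim[1], o$W1$dim[2]),
                 b1 = o$b1, W2 = matrix(o$W2, ncol = 1), b2 = o$b2,
                 loss = o$loss),
            class = "hem_classifier")
}
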