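# Evaluation of tile predictions against molecular (p53-derived) or
# pathologist-derived labels, and slide-level tumor purity as the
# tissue-area-weighted cancer fraction.

#' Balance classes by subsampling the dominant class
#'
#' The minority class is untouched; the majority class is subsampled
#' without replacement down to the minority count. Reproducible from
#' `seed`.
#'
#' @param records data.frame with a binary `label` column
#'   (`"cancer"`/`"normal"`).
#' @param seed RNG seed.
#' @return Row-subset of `records` with equal class counts.
#' @export
balance_classes <- function(records, seed = 1L) {
  tab <- table(records$label)
  if (length(tab) < 2) stop("both classes must be present to balance")
  nmin <- min(tab)
  keep <- withr::with_seed(seed, unlist(lapply(names(tab), function(cl) {
    idx <- which(records$label == cl)
    if (length(idx) > nmin) sort(sample(idx, nmin)) else idx
  })))
  records[sort(keep), , drop = FALSE]
}

#' ROC AUC
#'
#' Area under the receiver-operating curve, computed by the rank
#' (Mann-Whitney) formula: the probability that a random positive outranks
#' a random negative, ties counted half.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary truth: logical, 0/1, or `"cancer"`/`"normal"`.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.character(labels) == "cancer"
  labels <- as.logical(labels)
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Evaluate tile predictions against truth labels
#'
#' Joins predictions to truth on (slide_id, tile_row, tile_col), balances
#' the classes by subsampling the dominant class, then computes accuracy,
#' the confusion matrix (rows = truth, columns = prediction, positive class
#' cancer) and ROC AUC.
#'
#' @param predictions data.frame with `slide_id`, `tile_row`, `tile_col`,
#'   `p_cancer`.
#' @param truth data.frame with the same keys and a `label` column
#'   restricted to `"cancer"`/`"normal"`.
#' @param seed Balancing seed.
#' @param threshold Probability cut for the hard prediction (default 0.5).
#' @param balance Balance classes before scoring (default TRUE).
#' @return Object of class `eval_report`: `accuracy`, `confusion`,
#'   `roc_auc`, `n_per_class`, `balancing_seed`.
#' @export
evaluate_predictions <- function(predictions, truth, seed = 1L,
                                 threshold = 0.5, balance = TRUE) {
  truth <- truth[truth$label %in% c("cancer", "normal"), , drop = FALSE]
  j <- merge(predictions, truth[, c("slide_id", "tile_row", "tile_col", "label")],
             by = c("slide_id", "tile_row", "tile_col"))
  if (nrow(j) == 0) stop("empty join between predictions and truth labels")
  if (balance && length(unique(j$label)) == 2) j <- balance_classes(j, seed)
  pred <- ifelse(j$p_cancer > threshold, "cancer", "normal")
  confusion <- table(truth = factor(j$label, c("cancer", "normal")),
                     prediction = factor(pred, c("cancer", "normal")))
  auc <- if (length(unique(j$label)) == 2) roc_auc(j$p_cancer, j$label) else NA_real_
  structure(list(accuracy = mean(pred == j$label),
                 confusion = confusion, roc_auc = auc,
                 n_per_class = table(j$label), balancing_seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Tile evaluation: accuracy %.3f, ROC AUC %.3f (n = %s)\n",
              x$accuracy, x$roc_auc,
              paste(x$n_per_class, collapse = " + ")))
  print(x$confusion)
  invisible(x)
}

#' Estimate slide-level tumor purity
#'
#' Tissue-area-weighted cancer fraction: tile predictions are binarized at
#' `threshold` and each tile contributes its tissue fraction worth of area
#' (a half-background tile contributes half a tile of area), so
#' `purity = sum(cancer_tile * tissue_fraction) / sum(tissue_fraction)`
#' over tiles with any tissue. With `probabilistic = TRUE` the raw
#' probabilities replace the binarized calls.
#'
#' @param predictions data.frame with `slide_id` and `p_cancer` per tile.
#' @param tissue_fractions Numeric vector in \[0, 1\], one per prediction
#'   row (e.g. `tissue_fraction_he` from the manifest).
#' @param threshold Binarization cut (default 0.5).
#' @param probabilistic Weight by probabilities instead of hard calls
#'   (default FALSE).
#' @return data.frame of class `purity_estimate`, one row per slide:
#'   `slide_id`, `cancer_tissue_area`, `total_tissue_area`, `purity`.
#' @export
estimate_purity <- function(predictions, tissue_fractions, threshold = 0.5,
                            probabilistic = FALSE) {
  stopifnot(length(tissue_fractions) == nrow(predictions),
            all(tissue_fractions >= 0 & tissue_fractions <= 1))
  score <- if (probabilistic) predictions$p_cancer
           else as.numeric(predictions$p_cancer > threshold)
  out <- do.call(rbind, lapply(split(seq_len(nrow(predictions)),
                                     predictions$slide_id), function(idx) {
    tf <- tissue_fractions[idx]
    total <- sum(tf)
    if (total <= 0) stop("zero total tissue area for slide ",
                         predictions$slide_id[idx[1]])
    data.frame(slide_id = predictions$slide_id[idx[1]],
               cancer_tissue_area = sum(score[idx] * tf),
               total_tissue_area = total,
               purity = sum(score[idx] * tf) / total,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("purity_estimate", class(out))
  out
}

#' @export
print.purity_estimate <- function(x, ...) {
  cat("Tissue-area-weighted tumor purity:\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}
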