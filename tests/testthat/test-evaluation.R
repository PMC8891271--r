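test_that("class balancing subsamples only the dominant class", {
  rec <- data.frame(id = 1:140,
                    label = c(rep("cancer", 100), rep("normal", 40)),
                    stringsAsFactors = FALSE)
  b <- balance_classes(rec, seed = 5)
  expect_equal(as.vector(table(b$label)), c(40, 40))
  # minority class untouched
  expect_setequal(b$id[b$label == "normal"], 101:140)
  # reproducible
  expect_identical(balance_classes(rec, seed = 5), b)
  # already balanced -> unchanged
  even <- rec[61:140, ]
  expect_identical(balance_classes(even, seed = 1), even)
  expect_error(balance_classes(rec[1:100, ], 1), "both classes")
})

test_that("ROC AUC equals the pairwise positive-over-negative probability", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  # label inversion flips the area
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(1, 1, 0, 0)), 0.25)
  expect_error(roc_auc(c(0.5, 0.6), c(1, 1)), "both classes")
  # brute-force pairwise oracle with half-credit ties, random instances
  brute_auc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  set.seed(6)
  for (i in 1:10) {
    n <- sample(10:200, 1)
    s <- round(runif(n), 2)                      # ties happen
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y), brute_auc(s, y))
  }
  # independent library cross-check
  set.seed(7)
  s <- runif(150); y <- rbinom(150, 1, 0.5)
  expect_equal(roc_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<", levels = c(0, 1)))))
})

test_that("evaluation reports accuracy, confusion and AUC after balancing", {
  keys <- expand.grid(tile_row = 0:4, tile_col = 0:1)
  truth <- data.frame(slide_id = "s", keys,
                      label = rep(c("cancer", "normal"), each = 5),
                      stringsAsFactors = FALSE)
  # perfect predictions
  pred <- data.frame(slide_id = "s", keys,
                     p_cancer = rep(c(0.9, 0.1), each = 5),
                     stringsAsFactors = FALSE)
  rep1 <- evaluate_predictions(pred, truth, seed = 1)
  expect_equal(rep1$accuracy, 1)
  expect_equal(as.vector(rep1$confusion), c(5, 0, 0, 5))
  expect_equal(rep1$roc_auc, 1)
  # known 3-error case on 10 tiles -> accuracy 0.7, matching confusion cells
  pred3 <- pred
  pred3$p_cancer[c(1, 2, 6)] <- 1 - pred3$p_cancer[c(1, 2, 6)]
  rep3 <- evaluate_predictions(pred3, truth, seed = 1)
  expect_equal(rep3$accuracy, 0.7)
  expect_equal(unname(rep3$confusion["cancer", "normal"]), 2)
  expect_equal(unname(rep3$confusion["normal", "cancer"]), 1)
  expect_error(evaluate_predictions(pred[0, ], truth, 1), "empty join")
})

test_that("random predictions on balanced truth score near chance", {
  set.seed(8)
  n <- 400
  keys <- data.frame(tile_row = seq_len(n), tile_col = 0)
  truth <- data.frame(slide_id = "s", keys,
                      label = rep(c("cancer", "normal"), n / 2),
                      stringsAsFactors = FALSE)
  pred <- data.frame(slide_id = "s", keys, p_cancer = runif(n),
                     stringsAsFactors = FALSE)
  rep_r <- evaluate_predictions(pred, truth, seed = 2)
  expect_lt(abs(rep_r$roc_auc - 0.5), 0.08)
})

test_that("purity is the tissue-area-weighted cancer fraction", {
  # the half-background worked example: (1*1.0) / (1.0 + 0.5) = 2/3
  pred <- data.frame(slide_id = "s", p_cancer = c(0.9, 0.1))
  est <- estimate_purity(pred, c(1.0, 0.5))
  expect_equal(est$purity, 1 / 1.5)
  expect_equal(est$cancer_tissue_area, 1.0)
  expect_equal(est$total_tissue_area, 1.5)
  # all-cancer and no-cancer corner cases
  allc <- data.frame(slide_id = "s", p_cancer = c(0.8, 0.9, 0.99))
  expect_equal(estimate_purity(allc, c(0.2, 0.7, 1))$purity, 1)
  none <- data.frame(slide_id = "s", p_cancer = c(0.1, 0.2))
  expect_equal(estimate_purity(none, c(0.5, 1))$purity, 0)
  # probabilistic weighting option
  expect_equal(estimate_purity(pred, c(1, 1), probabilistic = TRUE)$purity, 0.5)
  expect_error(estimate_purity(none, c(0, 0)), "zero total tissue")
  # multi-slide input returns one row per slide
  multi <- data.frame(slide_id = c("a", "a", "b"), p_cancer = c(0.9, 0.1, 0.9))
  est2 <- estimate_purity(multi, c(1, 1, 1))
  expect_equal(nrow(est2), 2)
  expect_equal(est2$purity, c(0.5, 1))
})
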