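test_that("tile grids count by floor division and drop partial tiles", {
  expect_equal(nrow(tile_grid(c(448, 448), 224)), 4)
  expect_equal(nrow(tile_grid(c(500, 448), 224)), 4)   # 52-px band dropped
  expect_equal(nrow(tile_grid(c(100, 100), 224)), 0)
  # row-major order
  g <- tile_grid(c(448, 672), 224)
  expect_equal(g$tile_row, c(0, 0, 0, 1, 1, 1))
  expect_equal(g$tile_col, c(0, 1, 2, 0, 1, 2))
})

test_that("the 2% rule separates 41 from 40 positive pixels on a 45-px tile", {
  cfg <- labeling_config()                       # 224 px at downscale 5
  expect_equal(cfg$label_px, 45)
  tissue <- matrix(TRUE, 45, 45)
  dab_od <- matrix(0.5, 45, 45)                  # above the uncertain band
  mk_pos <- function(n) matrix(seq_len(45 * 45) <= n, 45, 45)
  lab41 <- label_tile(mk_pos(41), dab_od, tissue, cfg)
  expect_equal(lab41$dab_positive_fraction, 41 / 2025)
  expect_equal(lab41$label, "cancer")            # 0.02025 > 0.02
  lab40 <- label_tile(mk_pos(40), dab_od, tissue, cfg)
  expect_equal(lab40$label, "normal")            # 0.01975 <= 0.02
  expect_error(label_tile(matrix(logical(0), 0, 0), dab_od, tissue, cfg), "empty")
})

test_that("the uncertainty band overrides the 2% rule", {
  cfg <- labeling_config(dab_uncertain_low = 0.05, dab_uncertain_high = 0.15)
  tissue <- matrix(TRUE, 45, 45)
  in_band <- matrix(0.10, 45, 45)
  # high positive fraction, but mean DAB OD inside the band -> uncertain
  lab <- label_tile(matrix(TRUE, 45, 45), in_band, tissue, cfg)
  expect_equal(lab$label, "uncertain")
  # zero fraction, in band -> still uncertain
  lab0 <- label_tile(matrix(FALSE, 45, 45), in_band, tissue, cfg)
  expect_equal(lab0$label, "uncertain")
})

test_that("tissue-presence check flags mismatched and background tile pairs", {
  cfg <- labeling_config(tissue_presence_min = 0.05)
  expect_identical(tissue_presence_check(0, 0, cfg),
                   list(keep = FALSE, reason = "no_tissue"))
  expect_identical(tissue_presence_check(0.6, 0, cfg),
                   list(keep = FALSE, reason = "tissue_mismatch"))
  expect_identical(tissue_presence_check(0.02, 0.9, cfg),
                   list(keep = FALSE, reason = "tissue_mismatch"))
  expect_identical(tissue_presence_check(0.6, 0.7, cfg),
                   list(keep = TRUE, reason = ""))
})

test_that("the slide-level filter keeps only status-consistent tiles", {
  records <- data.frame(
    slide_id = "s", tile_row = 0:44, tile_col = 0,
    label = c(rep("cancer", 30), rep("normal", 10), rep("uncertain", 5)),
    stringsAsFactors = FALSE
  )
  cancer_kept <- apply_slide_filter(records, "cancer", "train")
  expect_equal(sum(cancer_kept$label == "cancer"), 30)
  expect_equal(sum(cancer_kept$label == "normal"), 0)
  expect_equal(sum(cancer_kept$label == "discarded"), 10)
  normal_kept <- apply_slide_filter(records, "non_cancer", "train")
  expect_equal(sum(normal_kept$label == "normal"), 10)
  expect_equal(sum(normal_kept$label == "cancer"), 0)
  # evaluation mode leaves everything intact
  eval_out <- apply_slide_filter(records, "cancer", "eval")
  expect_identical(eval_out$label, records$label)
  expect_equal(nrow(eval_out), 45)
})

test_that("build_dataset labels a registered cohort consistently with truth", {
  cfg <- labeling_config(tile_px = 64, downscale = 4)
  mk_pair <- function(seed, status) {
    p <- tiny_pair(seed, size = 320, status = status,
                   rotation_deg = 0, translation_px = c(0, 0))
    list(slide_id = p$pair$slide_id, he = p$pair$he,
         ihc_reg = hemlabel:::downscale_mean(p$pair$ihc, 4),
         status = status, truth = p$truth)
  }
  pairs <- list(mk_pair(31, "cancer"), mk_pair(32, "cancer"),
                mk_pair(33, "non_cancer"))
  suppressWarnings(man <- build_dataset(pairs, cfg, mode = "eval"))
  # label partition: every grid tile appears exactly once
  expect_equal(nrow(man), 3 * 25)
  expect_false(anyDuplicated(man[, c("slide_id", "tile_row", "tile_col")]) > 0)
  expect_true(all(man$label %in% c("cancer", "normal", "uncertain", "discarded")))
  expect_true(all(man$reason[man$label == "discarded"] != ""))
  # tile labels agree with ground-truth region membership away from borders
  for (p in pairs[1:2]) {
    truth_g <- truth_tile_labels(p$truth, 64, rule = "fraction")
    m <- man[man$slide_id == p$slide_id, ]
    j <- merge(m, truth_g, by = c("tile_row", "tile_col"))
    core <- j$label.x %in% c("cancer", "normal") & !is.na(j$label.y) &
      (j$tissue_fraction > 0.3)
    agree <- mean(j$label.x[core] == j$label.y[core])
    expect_gte(agree, 0.9)
  }
  # training mode + slide filter: conservation and consistency
  suppressWarnings(man_tr <- build_dataset(pairs, cfg, mode = "train"))
  expect_equal(nrow(man_tr), nrow(man))
  cancer_rows <- man_tr[man_tr$slide_id == pairs[[3]]$slide_id, ]
  expect_equal(sum(cancer_rows$label == "cancer"), 0)
  # empty input
  expect_equal(nrow(build_dataset(list())), 0)
})

test_that("raising the cancer-fraction threshold never adds cancer tiles", {
  p <- tiny_pair(35, size = 256, rotation_deg = 0, translation_px = c(0, 0))
  pair <- list(slide_id = "s", he = p$pair$he,
               ihc_reg = hemlabel:::downscale_mean(p$pair$ihc, 4),
               status = "cancer")
  counts <- vapply(c(0.01, 0.02, 0.1, 0.3), function(thr) {
    cfg <- labeling_config(tile_px = 64, downscale = 4,
                           cancer_fraction_threshold = thr)
    man <- build_dataset(list(pair), cfg, mode = "eval")
    sum(man$label == "cancer")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("annotation-derived tile labels follow the area-coverage rule", {
  mask <- matrix(FALSE, 128, 128)
  mask[1:64, 1:96] <- TRUE       # covers tiles fully / partially
  cfg <- labeling_config(tile_px = 64, downscale = 4, annotation_cover_min = 0.5)
  g <- annotation_tile_labels(mask, cfg)
  expect_equal(nrow(g), 4)
  lab <- g$label[order(g$tile_row, g$tile_col)]
  # top-left fully covered, top-right half covered (0.5 >= 0.5 -> cancer)
  expect_equal(lab, c("cancer", "cancer", "normal", "normal"))
})
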