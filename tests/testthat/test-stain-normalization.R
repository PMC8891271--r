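test_that("luminosity standardization restores a white background idempotently", {
  white <- flat_rgb(8, 8, c(255, 255, 255))
  expect_equal(standardize_luminosity(white), white)
  # uniformly dimmed slide: the 95th-percentile lightness maps back to max
  img <- tiny_pair(4, size = 128)$pair$he
  dim_img <- round(img * 0.5)
  fixed <- standardize_luminosity(dim_img)
  lab <- grDevices::convertColor(matrix(fixed, ncol = 3) / 255, "sRGB", "Lab")
  expect_gte(stats::quantile(lab[, 1], 0.95), 99)
  # idempotence within one intensity unit
  expect_lte(max(abs(standardize_luminosity(fixed) - fixed)), 1)
  expect_error(standardize_luminosity(flat_rgb(4, 4, c(0, 0, 0))), "degenerate")
})

test_that("optical density transform matches its closed form and inverts", {
  expect_equal(rgb_to_od(flat_rgb(2, 2, c(255, 255, 255)))[1, 1, ], rep(0, 3))
  expect_equal(rgb_to_od(flat_rgb(1, 1, c(25.5, 25.5, 25.5)))[1, 1, 1], 1.0)
  img <- tiny_pair(5, size = 96)$pair$he
  expect_true(all(rgb_to_od(img) >= 0))
  expect_equal(od_to_rgb(rgb_to_od(img)), img)       # round trip, >= 1 intensities
  # monotone decreasing in intensity
  od <- rgb_to_od(flat_rgb(1, 1, c(10, 100, 200)))[1, 1, ]
  expect_true(all(diff(od) < 0))
})

test_that("stain matrices are recovered from known-matrix mixes", {
  truth <- rj_stain_matrix()[1:2, ]
  pair <- tiny_pair(7, size = 384)
  S_m <- estimate_stain_matrix(pair$pair$he, "macenko")
  S_v <- estimate_stain_matrix(pair$pair$he, "vahadane")
  for (S in list(S_m, S_v)) {
    expect_equal(dim(S), c(2, 3))
    expect_equal(sqrt(rowSums(S^2)), c(1, 1), tolerance = 1e-6)
  }
  # both estimators land within 0.05 rad of the rendering matrix
  for (S in list(S_m, S_v)) {
    expect_lt(vec_angle(S[1, ], truth[1, ]), 0.05)
    expect_lt(vec_angle(S[2, ], truth[2, ]), 0.05)
  }
  # cross-method consistency on the same mix
  expect_lt(vec_angle(S_m[1, ], S_v[1, ]), 0.1)
  expect_lt(vec_angle(S_m[2, ], S_v[2, ]), 0.1)
})

test_that("degenerate stain inputs are rejected", {
  # pure single-stain image: rank error
  n <- 40
  od <- array(outer(rep(0.8, n * n), rj_stain_matrix()[1, ]), c(n, n, 3))
  img <- array(od_to_rgb(od), c(n, n, 3))
  expect_error(estimate_stain_matrix(img, "macenko"), "rank|insufficient")
  # blank slide: insufficient tissue
  expect_error(estimate_stain_matrix(flat_rgb(50, 50, c(255, 255, 255)), "macenko"),
               "insufficient tissue")
})

test_that("concentrations solve the non-negative Beer-Lambert model", {
  S <- rj_stain_matrix()[1:2, ]
  # pure stain
  expect_equal(as.vector(estimate_concentrations(matrix(S[1, ], 1), S)$C), c(1, 0),
               tolerance = 1e-10)
  expect_equal(as.vector(estimate_concentrations(matrix(0, 1, 3), S)$C), c(0, 0))
  # random non-negative mix, noise-free: exact recovery
  set.seed(11)
  C <- cbind(runif(500, 0, 2), runif(500, 0, 1.5))
  fit <- estimate_concentrations(C %*% S, S)
  expect_lt(max(abs(fit$C - C)), 1e-6)
  expect_lt(fit$residual, 1e-8)
  expect_true(all(fit$C >= 0))
  expect_error(estimate_concentrations(matrix(0, 1, 3), rbind(S[1, ], S[1, ])),
               "rank")
})

test_that("template selection minimizes distance to the median mean-color", {
  mk <- function(v) flat_rgb(4, 4, v)
  expect_equal(select_template(list(mk(c(10, 10, 10)))), 1)
  slides <- list(mk(c(100, 100, 100)), mk(c(120, 120, 120)), mk(c(200, 200, 200)))
  expect_equal(select_template(slides), 2)
  # tie -> lowest index
  expect_equal(select_template(list(mk(c(100, 0, 0)), mk(c(100, 0, 0)),
                                    mk(c(90, 0, 0)))), 1)
  # restricted to cancer slides when statuses supplied
  expect_equal(select_template(slides, c("non_cancer", "non_cancer", "cancer")), 3)
  expect_error(select_template(list()), "no slides")
})

test_that("normalization maps a slide onto the template stain profile", {
  # noise-free render: reconstruction through a 2-stain model can only be
  # near-lossless when the image is an exact 2-stain mix
  pair <- tiny_pair(9, size = 256, noise_sd = 0)
  tmpl <- fit_stain_template(pair$pair$he, "macenko")
  # self-normalization: almost all tissue pixels move by <= 2 units
  self <- normalize_to_template(pair$pair$he, tmpl, "macenko")
  delta <- apply(abs(self - standardize_luminosity(pair$pair$he)), c(1, 2), max)
  expect_gte(mean(delta <= 2), 0.99)
  # idempotence: re-normalizing the normalized slide barely changes it
  again <- normalize_to_template(self, tmpl, "macenko")
  expect_gte(mean(apply(abs(again - self), c(1, 2), max) <= 2), 0.99)
  # white background is preserved, blank slides pass through
  white <- flat_rgb(32, 32, c(255, 255, 255))
  expect_equal(normalize_to_template(white, tmpl, "macenko"), white)
  for (method in c("vahadane", "reinhard")) {
    out <- normalize_to_template(pair$pair$he, tmpl, method)
    expect_equal(dim(out), dim(pair$pair$he))
  }
})

test_that("normalization shrinks cross-slide channel-mean variation", {
  coh <- generate_cohort(3, 2, seed = 21, image_shape = c(192L, 192L))
  slides <- lapply(coh$slides, function(s) s$pair$he)
  ti <- select_template(slides, coh$manifest$status)
  tmpl <- fit_stain_template(slides[[ti]], "macenko")
  normed <- lapply(slides, normalize_to_template, template = tmpl, method = "macenko")
  sd_of <- function(imgs) {
    means <- t(vapply(imgs, function(s) apply(s, 3, mean), numeric(3)))
    mean(apply(means, 2, stats::sd))
  }
  expect_lt(sd_of(normed), sd_of(slides))
})
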