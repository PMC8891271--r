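test_that("grayscale conversion uses the standard luminance weights", {
  expect_equal(to_grayscale(flat_rgb(2, 2, c(77, 77, 77))), matrix(77, 2, 2))
  # green outranks red under luminance weights
  expect_gt(to_grayscale(flat_rgb(1, 1, c(0, 255, 0)))[1, 1],
            to_grayscale(flat_rgb(1, 1, c(255, 0, 0)))[1, 1])
  img <- tiny_pair(6, size = 64)$pair$he
  manual <- round(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  expect_equal(to_grayscale(img), manual)
})

test_that("mutual information matches hand-evaluated cases and its invariants", {
  half <- matrix(c(0, 0, 255, 255), 2, 2)
  expect_equal(mutual_information(half, half, bins = 2), log(2))
  # constant image has zero entropy, hence zero MI with anything
  checker <- matrix(c(0, 255, 255, 0), 2, 2)
  expect_equal(mutual_information(checker, matrix(100, 2, 2)), 0)
  # joint = product of marginals -> MI 0
  a <- matrix(c(0, 1, 0, 1), 2, 2, byrow = TRUE)
  b <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
  expect_equal(mutual_information(a, b, bins = 2), 0)
  expect_error(mutual_information(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
  expect_error(mutual_information(half, half, bins = 1), "bins")
  # symmetry and non-negativity over random images
  set.seed(3)
  for (i in 1:5) {
    x <- matrix(sample(0:255, 400, TRUE), 20)
    y <- matrix(sample(0:255, 400, TRUE), 20)
    expect_equal(mutual_information(x, y), mutual_information(y, x))
    expect_gte(mutual_information(x, y), 0)
  }
})

test_that("self-registration recovers the identity transform", {
  pair <- tiny_pair(8, size = 224, rotation_deg = 0, translation_px = c(0, 0))
  fit <- register_pair(pair$pair$he, pair$pair$ihc, downscale = 4,
                       do_bspline = FALSE, maxit = 60, init_search_px = 8)
  err <- affine_map_error(cbind(diag(2), c(0, 0)), fit$chain$affine,
                          fit$chain$fixed_shape)
  expect_lt(err, 0.5)
})

test_that("known rigid misalignments are recovered at the fitting resolution", {
  pair <- tiny_pair(12, size = 320, rotation_deg = -6, translation_px = c(10, -5))
  fit <- register_pair(pair$pair$he, pair$pair$ihc, downscale = 4,
                       do_bspline = FALSE)
  A_true <- hemlabel:::affine_at_scale(pair$truth$true_affine, 4)
  expect_lt(affine_map_error(A_true, fit$chain$affine, fit$chain$fixed_shape), 1)
  expect_lt(abs(affine_rotation_deg(A_true) - affine_rotation_deg(fit$chain$affine)),
            0.5)
  expect_gt(fit$report$mi_after_affine, fit$report$mi_before)
  expect_gte(fit$report$mi_after_bspline, fit$report$mi_after_affine)
})

test_that("a smooth sinusoidal warp is reduced by the B-spline phase", {
  pair <- tiny_pair(5, size = 192, rotation_deg = 2, translation_px = c(4, -3),
                    warp_amplitude_px = 4)
  fit <- register_pair(pair$pair$he, pair$pair$ihc, downscale = 1,
                       do_bspline = TRUE, bspline_spacing = 48,
                       bspline_maxit = 25, bspline_reg = 1e-5)
  tm <- hemlabel:::truth_map(pair$truth, fit$chain$fixed_shape)
  em <- hemlabel:::chain_map(fit$chain, fit$chain$fixed_shape)
  err <- sqrt((tm$x - em$x)^2 + (tm$y - em$y)^2)
  # the displacement field is only identifiable where there is tissue;
  # outside it the metric carries no signal
  residual <- mean(err[pair$truth$tissue_mask])
  expect_lt(residual, 2)
  expect_gte(fit$report$mi_after_bspline, fit$report$mi_after_affine)
})

test_that("apply_transform resamples all channels and fills with white", {
  img <- tiny_pair(10, size = 50)$pair$he
  idc <- transform_chain(cbind(diag(2), c(0, 0)), downscale = 1,
                         fixed_shape = c(50, 50))
  expect_equal(apply_transform(img, idc), img)
  # translation by (10, 0): sampling coordinates shift right, so the last
  # 10 columns fall outside the moving image and become white
  tc <- transform_chain(cbind(diag(2), c(10, 0)), downscale = 1,
                        fixed_shape = c(50, 50))
  out <- apply_transform(img, tc)
  expect_true(all(out[, 41:50, ] == 255))
  expect_equal(out[, 1:40, ], img[, 11:50, ])
  # grayscale(apply(rgb)) == apply(grayscale(rgb)) within interpolation error
  rc <- transform_chain(hemlabel:::affine_from_params(c(3.5, -2.5, 4, 0, 0, 0),
                                                      c(24.5, 24.5)),
                        downscale = 1, fixed_shape = c(50, 50))
  g1 <- to_grayscale(apply_transform(img, rc))
  g2 <- apply_transform(to_grayscale(img), rc)
  expect_lt(max(abs(g1 - g2)), 2 + 1e-9)
  expect_error(transform_chain(cbind(matrix(0, 2, 2), c(0, 0))), "singular")
})

test_that("transform chains serialize to JSON and back", {
  grid <- array(seq(-1, 1, length.out = 5 * 4 * 2), c(5, 4, 2))
  ch <- transform_chain(cbind(matrix(c(1.01, 0.02, -0.01, 0.99), 2), c(3.5, -2)),
                        bspline = list(grid = grid, spacing = 32),
                        downscale = 5, fixed_shape = c(120, 100))
  path <- withr::local_tempfile(fileext = ".json")
  transform_to_json(ch, path)
  back <- transform_from_json(path)
  expect_equal(back$affine, ch$affine)
  expect_equal(back$bspline$grid, ch$bspline$grid)
  expect_equal(back$bspline$spacing, ch$bspline$spacing)
  expect_equal(back$downscale, ch$downscale)
})
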