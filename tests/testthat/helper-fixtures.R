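# Shared fixtures: all synthetic, generated in code at test time.

# Angular distance between unit vectors (radians).
vec_angle <- function(a, b) acos(pmin(pmax(sum(a * b), -1), 1))

# A small synthetic slide pair; desk-scale default 256 px for unit tests.
tiny_pair <- function(seed, size = 256L, status = "cancer", ...) {
  generate_pair(synthetic_spec(image_shape = c(size, size), seed = seed,
                               status = status, ...))
}

# Flat color image.
flat_rgb <- function(h, w, rgb) {
  array(rep(rgb, each = h * w), c(h, w, 3))
}

# Rotation angle (degrees) of an affine's linear part.
affine_rotation_deg <- function(A) atan2(A[2, 1], A[1, 1]) * 180 / pi

# Mean displacement discrepancy (px) between two affines over a pixel grid.
affine_map_error <- function(A1, A2, shape) {
  m1 <- hemlabel:::affine_map(A1, shape)
  m2 <- hemlabel:::affine_map(A2, shape)
  mean(sqrt((m1$x - m2$x)^2 + (m1$y - m2$y)^2))
}

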