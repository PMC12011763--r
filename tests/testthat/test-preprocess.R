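test_that("to_grayscale applies Rec.709 luminance weights", {
  gray <- array(0.37, dim = c(5, 4, 3))
  expect_equal(to_grayscale(gray), matrix(0.37, 5, 4))
  expect_equal(to_grayscale(array(0, dim = c(3, 3, 3))), matrix(0, 3, 3))
  red <- array(0, dim = c(4, 4, 3)); red[, , 1] <- 1
  expect_equal(to_grayscale(red), matrix(0.2126, 4, 4))
  expect_error(to_grayscale(array(1, dim = c(4, 4, 2))),
               class = "mtloca_shape_error")
})

test_that("gaussian_kernel_2d matches the closed form", {
  k1 <- gaussian_kernel_2d(derivative_config(sigma = 1))
  ctr <- (nrow(k1) + 1) / 2
  expect_equal(k1[ctr, ctr], 1 / (2 * pi), tolerance = 1e-12)
  # point symmetry and x<->y symmetry
  expect_equal(k1, k1[rev(seq_len(nrow(k1))), rev(seq_len(ncol(k1)))])
  expect_equal(k1, t(k1))
  # discrete mass ~ 1; the 4-sigma truncation leaves ~3e-5 outside, a
  # 6-sigma radius brings the sum within 1e-6 of unity
  k2 <- gaussian_kernel_2d(derivative_config(sigma = 2, kernel_radius = 4))
  expect_equal(sum(k2), 1, tolerance = 1e-4)
  k3 <- gaussian_kernel_2d(derivative_config(sigma = 2, kernel_radius = 6))
  expect_equal(sum(k3), 1, tolerance = 1e-6)
})

test_that("derivative kernels match the closed form and are antisymmetric", {
  cfg <- derivative_config(sigma = 1)
  ks <- gaussian_derivative_kernels(cfg)
  ctr <- (nrow(ks$dx) + 1) / 2
  expect_identical(ks$dx[ctr, ctr], 0)             # value at (0, 0)
  expect_equal(ks$dx[, ctr], rep(0, nrow(ks$dx)))  # whole x = 0 column
  # value at x = 1, y = 0: -1/(2 pi) exp(-1/2)
  expect_equal(ks$dx[ctr, ctr + 1], -exp(-0.5) / (2 * pi),
               tolerance = 1e-12)
  expect_equal(ks$dx[ctr, ctr + 1], -0.096532, tolerance = 1e-5)
  # antisymmetry: dx + horizontally flipped dx == 0; dy is dx transposed
  expect_equal(ks$dx + ks$dx[, rev(seq_len(ncol(ks$dx)))],
               matrix(0, nrow(ks$dx), ncol(ks$dx)))
  expect_identical(ks$dy, t(ks$dx))
  for (sg in c(0.8, 1.5, 2.5)) {
    k <- gaussian_derivative_kernels(derivative_config(sigma = sg))
    expect_lt(abs(sum(k$dx)), 1e-10)
    expect_lt(abs(sum(k$dy)), 1e-10)
  }
})

test_that("gradient_magnitude: constant, ramp, and step behave analytically", {
  cfg <- derivative_config(sigma = 1.5)
  expect_equal(gradient_magnitude(matrix(0.6, 32, 32), cfg),
               matrix(0, 32, 32), tolerance = 1e-12)
  # linear ramp f(x, y) = x / W: interior magnitude == slope 1/W
  W <- 48L
  ramp <- matrix(rep((0:(W - 1)) / W, each = W), W, W)
  m <- gradient_magnitude(ramp, cfg)
  interior <- m[15:34, 15:34]
  expect_lt(max(abs(interior - 1 / W)), 1e-5)  # kernel-truncation floor
  # step edge: response maximal on the edge, Gaussian decay off it
  step <- cbind(matrix(0, 40, 20), matrix(1, 40, 20))
  ms <- gradient_magnitude(step, cfg)
  peak_col <- which.max(ms[20, ])
  expect_true(peak_col %in% 20:21)
  off <- ms[20, peak_col + 6]
  expect_lt(off, ms[20, peak_col] / 2)
  expect_true(all(ms >= 0))
})

test_that("gradient_magnitude matches a brute-force convolution oracle", {
  set.seed(31)
  img <- matrix(runif(32 * 32), 32, 32)
  cfg <- derivative_config(sigma = 1.2, kernel_radius = 3)
  ks <- gaussian_derivative_kernels(cfg)
  gx <- oracle_conv2d_reflect(img, ks$dx)
  gy <- oracle_conv2d_reflect(img, ks$dy)
  expect_equal(gradient_magnitude(img, cfg), sqrt(gx^2 + gy^2),
               tolerance = 1e-6)
  # image smaller than the kernel is a shape error
  expect_error(gradient_magnitude(matrix(0, 4, 4), cfg),
               class = "mtloca_shape_error")
})

test_that("build_model_input resizes, stacks and preserves cases", {
  spec <- test_phantom_spec(seed = 21)
  s <- generate_sample(spec, "benign", seed = 3)
  mi <- build_model_input(s)
  expect_identical(dim(mi$channels), c(128L, 128L, 2L))
  expect_identical(mi$channels[, , 1], s$image)  # 128 input: no resampling
  expect_true(all(mi$channels[, , 2] >= 0 & mi$channels[, , 2] <= 1))
  # normal sample: empty mask stays empty through the resize
  n <- generate_sample(spec, "normal", seed = 3)
  n$image <- resize_bilinear(n$image, 256, 256)
  n$mask <- matrix(0, 256, 256)
  mi_n <- build_model_input(n)
  expect_identical(dim(mi_n$channels), c(128L, 128L, 2L))
  expect_true(all(mi_n$mask == 0))
})

test_that("augment applies shared geometry, leaves masks binary", {
  spec <- test_phantom_spec(seed = 22)
  mi <- build_model_input(generate_sample(spec, "malignant", seed = 5))
  # identity configuration
  id_cfg <- augment_config(rotation_range = c(0, 0), flip_h = FALSE,
                           flip_v = FALSE, crop_prob = 0,
                           gamma_range = c(1, 1))
  out <- augment(mi, id_cfg, seed = 1)
  expect_equal(out$channels, mi$channels, tolerance = 1e-12)
  expect_identical(out$mask, mi$mask)
  # random draws: mask binary, intensities clipped, finite
  full <- augment_config()
  for (sd in 1:6) {
    a <- augment(mi, full, seed = sd)
    expect_true(all(a$mask %in% c(0, 1)))
    expect_true(all(is.finite(a$channels)))
    expect_true(all(a$channels[, , 1] >= 0 & a$channels[, , 1] <= 1))
  }
})

test_that("flips are involutions and contrast never touches the mask", {
  spec <- test_phantom_spec(seed = 23)
  mi <- build_model_input(generate_sample(spec, "benign", seed = 9))
  flip_cfg <- augment_config(rotation_range = c(0, 0), flip_h = TRUE,
                             flip_v = FALSE, crop_prob = 0,
                             gamma_range = c(1, 1))
  # find a seed whose flip decision fires, then apply twice
  sd <- which(vapply(1:20, function(s) {
    !identical(augment(mi, flip_cfg, seed = s)$mask, mi$mask)
  }, TRUE))[1]
  expect_false(is.na(sd))
  once <- augment(mi, flip_cfg, seed = sd)
  twice <- augment(once, flip_cfg, seed = sd)
  expect_equal(twice$channels, mi$channels, tolerance = 1e-12)
  expect_identical(twice$mask, mi$mask)
  # gamma-only augmentation changes intensity but not the mask
  gm_cfg <- augment_config(rotation_range = c(0, 0), flip_h = FALSE,
                           flip_v = FALSE, crop_prob = 0,
                           gamma_range = c(0.7, 0.71))
  g <- augment(mi, gm_cfg, seed = 2)
  expect_identical(g$mask, mi$mask)
  expect_gt(max(abs(g$channels[, , 1] - mi$channels[, , 1])), 0)
  expect_equal(sum(g$mask), sum(mi$mask))
})

test_that("rotation by theta then -theta restores the interior", {
  set.seed(77)
  img <- matrix(runif(64 * 64), 64, 64)
  sm <- conv2d_same(img, gaussian_kernel_2d(derivative_config(sigma = 1)) /
                           sum(gaussian_kernel_2d(derivative_config(sigma = 1))))
  back <- rotate_image(rotate_image(sm, 23), -23)
  interior <- 17:48
  expect_lt(mean(abs(back[interior, interior] - sm[interior, interior])),
            0.02)
})
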