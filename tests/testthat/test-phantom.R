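test_that("normal samples have empty masks and benign/malignant do not", {
  spec <- test_phantom_spec(seed = 4)
  for (sd in 1:5) {
    s <- generate_sample(spec, "normal", seed = sd)
    expect_true(all(s$mask == 0))
    expect_true(all(s$image >= 0 & s$image <= 1))
  }
  b <- generate_sample(spec, "benign", seed = 2)
  m <- generate_sample(spec, "malignant", seed = 2)
  expect_gt(sum(b$mask), 0)
  expect_gt(sum(m$mask), 0)
  expect_true(all(b$mask %in% c(0, 1)))
})

test_that("generation is deterministic under a fixed seed", {
  spec <- test_phantom_spec(seed = 4)
  a <- generate_sample(spec, "benign", seed = 7)
  b <- generate_sample(spec, "benign", seed = 7)
  expect_identical(a, b)
  d1 <- generate_dataset(spec, 9)
  d2 <- generate_dataset(spec, 9)
  expect_identical(d1$samples, d2$samples)
  expect_identical(d1$manifest, d2$manifest)
})

test_that("datasets written twice are byte-identical on disk", {
  spec <- test_phantom_spec(seed = 11)
  d1 <- file.path(tempdir(), "ph_a"); d2 <- file.path(tempdir(), "ph_b")
  generate_dataset(spec, 6, out_dir = d1)
  generate_dataset(spec, 6, out_dir = d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("malignant mask area lies in the radius-implied bounds", {
  spec <- test_phantom_spec(seed = 1)
  r <- spec$malignant_shape$radius
  amp <- spec$malignant_shape$amplitude
  for (sd in 1:10) {
    s <- generate_sample(spec, "malignant", seed = sd)
    area <- sum(s$mask)  # brute-force pixel count
    expect_gte(area, pi * r[1]^2 * 0.95)   # rasterization slack
    expect_lte(area, pi * (r[2] + amp)^2 * 1.05)
  }
})

test_that("lesions are hypoechoic and spiculation raises the shape factor", {
  spec <- test_phantom_spec(seed = 2)
  sf_b <- sf_m <- numeric(8)
  for (sd in 1:8) {
    b <- generate_sample(spec, "benign", seed = sd)
    m <- generate_sample(spec, "malignant", seed = sd + 100)
    # hypoechoic: mean inside lesion clearly below background mean
    expect_lt(mean(b$image[b$mask == 1]), mean(b$image[b$mask == 0]))
    expect_lt(mean(m$image[m$mask == 1]), mean(m$image[m$mask == 0]))
    sf_b[sd] <- mask_shape_factor(b$mask)
    sf_m[sd] <- mask_shape_factor(m$mask)
  }
  expect_gt(min(sf_m), max(sf_b))
})

test_that("class counts follow the mix with largest-remainder rounding", {
  expect_identical(mtloca:::.class_counts(c(n = 1, b = 1, m = 1) / 3, 30),
                   c(10L, 10L, 10L))
  expect_identical(mtloca:::.class_counts(c(benign = 1), 1), 1L)
  # published three-class composition: 437 benign, 210 malignant, 133 normal
  counts <- mtloca:::.class_counts(
    c(normal = 133, benign = 437, malignant = 210) / 780, 780)
  expect_identical(counts, c(133L, 437L, 210L))
})

test_that("generate_dataset writes a loadable phantom layout", {
  spec <- phantom_spec(class_mix = c(benign = 1), seed = 3)
  out <- file.path(tempdir(), "ph_layout")
  ds <- generate_dataset(spec, 1, out_dir = out)
  expect_identical(nrow(ds$manifest), 1L)
  expect_identical(ds$manifest$label, "benign")
  expect_setequal(names(ds$manifest), c("id", "label", "image_path",
                                        "mask_path"))
  back <- load_dataset(out)
  expect_identical(back$manifest$id, ds$manifest$id)
  # 8-bit quantization on disk
  expect_lt(max(abs(back$samples[[1]]$image - ds$samples[[1]]$image)),
            1 / 255)
  expect_identical(back$samples[[1]]$mask, ds$samples[[1]]$mask)
  expect_true(check_dataset(back))
  unlink(out, recursive = TRUE)
})

test_that("class-mask consistency holds for every generated sample", {
  ds <- generate_dataset(test_phantom_spec(seed = 8), 15)
  expect_true(check_dataset(ds))
})

test_that("speckle variance matches the configured level within 20%", {
  spec <- test_phantom_spec(seed = 5)
  s <- generate_sample(spec, "normal", seed = 1)
  # homogeneous background: relative variance ~ speckle sd^2 (>= 1e4 px)
  expect_gte(length(s$image), 1e4)
  rel_sd <- stats::sd(s$image) / mean(s$image)
  expect_gt(rel_sd, 0)
  expect_lt(abs(rel_sd^2 - spec$speckle$sd^2) / spec$speckle$sd^2, 0.2)
})

test_that("impossible lesion sizes are rejected with a sizing error", {
  expect_error(
    phantom_spec(image_size = 32,
                 benign_shape = list(axes = c(20, 30), ratio_max = 1.5,
                                     contrast = 0.4)),
    class = "mtloca_sizing_error")
  expect_error(
    phantom_spec(image_size = 40,
                 malignant_shape = list(radius = c(18, 22), amplitude = 5,
                                        spikes = 7, contrast = 0.6)),
    class = "mtloca_sizing_error")
  expect_error(phantom_spec(class_mix = c(normal = 0.5, benign = 0.4)),
               "sum to 1")
})
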