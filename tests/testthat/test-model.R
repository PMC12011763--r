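test_that("the classifier pools globally and is permutation invariant", {
  cfg <- model_config(base_channels = 4L, groupnorm_groups = 2L,
                      hidden = 8L)
  params <- model_init(cfg, seed = 4)
  H <- W <- 8L
  # spatially constant features pool to the constant vector
  v <- stats::rnorm(cfg$backbone$feat_channels)
  x <- matrix(rep(v, each = H * W), H * W, length(v))
  cl <- classify(x, H, W, 1L, params)
  ref <- pmax(v %*% params[["cls.W1"]] + params[["cls.b1"]], 0) %*%
    params[["cls.W2"]] + params[["cls.b2"]]
  expect_equal(as.numeric(cl$logits), as.numeric(ref), tolerance = 1e-9)
  # permuting pixels leaves logits unchanged
  set.seed(5)
  xr <- matrix(stats::rnorm(H * W * length(v)), H * W, length(v))
  perm <- sample(H * W)
  expect_equal(classify(xr, H, W, 1L, params)$logits,
               classify(xr[perm, ], H, W, 1L, params)$logits,
               tolerance = 1e-10)
  # argmax labelling
  expect_identical(CLASS_LEVELS <- c("normal", "benign", "malignant"),
                   mtloca:::CLASS_LEVELS)
  expect_identical(which.max(c(0.1, 2.3, -1)), 2L)  # benign
})

test_that("combined loss satisfies the weighting arithmetic exactly", {
  set.seed(6)
  N <- 40L; B <- 4L
  soft <- matrix(rnorm(N * 2), N, 2)
  aug <- matrix(rnorm(N * 2), N, 2)
  cls <- matrix(rnorm(B * 3), B, 3)
  mask <- stats::rbinom(N, 1, 0.5)
  labels <- sample(1:3, B, replace = TRUE)
  lb <- combined_loss(soft, aug, mask, cls, labels)
  expect_equal(lb$alpha, 0.4)                       # default weighting
  expect_identical(lb$l_s, 0.4 * lb$l_soft + lb$l_aug)
  expect_identical(lb$total, lb$l_s + lb$l_c)
  expect_true(all(c(lb$l_soft, lb$l_aug, lb$l_c) >= 0))
  # no-OCA arm: l_soft contributes zero
  lb0 <- combined_loss(NULL, aug, mask, cls, labels)
  expect_identical(lb0$l_soft, 0)
  expect_identical(lb0$l_s, lb0$l_aug)
  # near-one-hot predictions drive the total toward zero
  hot_aug <- matrix(-20, N, 2); hot_aug[cbind(1:N, mask + 1)] <- 20
  hot_soft <- hot_aug
  hot_cls <- matrix(-20, B, 3); hot_cls[cbind(1:B, labels)] <- 20
  lb1 <- combined_loss(hot_soft, hot_aug, mask, hot_cls, labels)
  expect_lt(lb1$total, 1e-8)
  # validation errors
  expect_error(combined_loss(soft, aug, mask + 2, cls, labels),
               class = "mtloca_validation_error")
  expect_error(combined_loss(soft, aug, mask, cls, rep(7L, B)),
               class = "mtloca_validation_error")
})

test_that("label names are accepted and mapped in class order", {
  aug <- matrix(0, 10, 2)
  cls <- matrix(c(5, 0, 0), 1, 3, byrow = TRUE)
  lb_name <- combined_loss(NULL, aug, rep(0, 10), cls, "normal")
  lb_idx <- combined_loss(NULL, aug, rep(0, 10), cls, 1L)
  expect_identical(lb_name$l_c, lb_idx$l_c)
})

test_that("grad_cam produces normalized 128x128 heatmaps", {
  spec <- test_phantom_spec(seed = 33)
  input <- build_model_input(generate_sample(spec, "malignant", seed = 2))
  cfg <- model_config(base_channels = 4L, groupnorm_groups = 2L,
                      hidden = 8L)
  params <- model_init(cfg, seed = 7)
  # force a positive class pathway so the map is non-degenerate at
  # random initialization (features are post-ReLU, hence nonnegative)
  params[["cls.W1"]] <- abs(params[["cls.W1"]])
  params[["cls.W2"]] <- abs(params[["cls.W2"]])
  hm <- grad_cam(params, cfg, input, "malignant")
  expect_identical(dim(hm), c(128L, 128L))
  expect_true(all(hm >= 0 & hm <= 1))
  expect_equal(max(hm), 1)
  # zero gradient (dead class column) -> all-zero heatmap
  params0 <- params
  params0[["cls.W2"]][, 2] <- 0
  hm0 <- grad_cam(params0, cfg, input, "benign")
  expect_true(all(hm0 == 0))
  expect_error(grad_cam(params, cfg, input, 9),
               class = "mtloca_validation_error")
  # works for the classification-from-OCA wiring too
  cfg2 <- model_config("cls_from_oca", base_channels = 4L,
                       groupnorm_groups = 2L, hidden = 8L)
  hm2 <- grad_cam(model_init(cfg2, seed = 7), cfg2, input, 3L)
  expect_identical(dim(hm2), c(128L, 128L))
})

test_that("checkpoints round-trip parameters and config", {
  cfg <- model_config("no_oca", base_channels = 4L, groupnorm_groups = 2L,
                      hidden = 8L)
  params <- model_init(cfg, seed = 8)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(params, cfg, f)
  back <- load_checkpoint(f)
  expect_identical(back$params, params)
  expect_identical(back$cfg$variant, "no_oca")
  expect_error(load_checkpoint(tempfile()), class = "mtloca_io_error")
  unlink(f)
})

test_that("model_predict returns masks, labels and probabilities", {
  spec <- test_phantom_spec(seed = 34)
  inputs <- lapply(c("normal", "benign"), function(l)
    build_model_input(generate_sample(spec, l, seed = 3)))
  cfg <- model_config(base_channels = 4L, groupnorm_groups = 2L,
                      hidden = 8L)
  params <- model_init(cfg, seed = 9)
  preds <- model_predict(params, cfg, inputs)
  expect_length(preds, 2)
  for (p in preds) {
    expect_identical(dim(p$mask), c(128L, 128L))
    expect_true(all(p$mask %in% c(0, 1)))
    expect_true(p$label %in% mtloca:::CLASS_LEVELS)
    expect_equal(sum(p$probs), 1, tolerance = 1e-9)
  }
})
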