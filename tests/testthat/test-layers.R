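# Correctness of the network primitives: the fused C++ ops are checked
# against compositions of the simple double-precision ops, the convolution
# against a triple-loop oracle, and gradients against finite differences
# where precision permits.

test_that("3x3 convolution matches a zero-padded loop oracle", {
  set.seed(5)
  H <- 9L; W <- 7L; B <- 2L; Cin <- 3L; Cout <- 2L
  x <- matrix(rnorm(H * W * B * Cin), H * W * B, Cin)
  Wm <- matrix(rnorm(Cin * 9 * Cout), Cin * 9, Cout)
  b <- rnorm(Cout)
  out <- mtloca:::conv_fw(x, H, W, B, Wm, b)$out
  for (bb in seq_len(B)) {
    rows <- ((bb - 1) * H * W + 1):(bb * H * W)
    for (co in seq_len(Cout)) {
      ref <- matrix(b[co], H, W)
      for (ci in seq_len(Cin)) {
        img <- matrix(x[rows, ci], H, W)
        # weight rows q = (ci-1)*9 + (dx+1)*3 + (dy+1) + 1; build the
        # 3x3 tap kernel with rows = dy, cols = dx
        ker <- matrix(0, 3, 3)
        for (dx in -1:1)
          for (dy in -1:1)
            ker[dy + 2, dx + 2] <- Wm[(ci - 1) * 9 + (dx + 1) * 3 + dy + 2, co]
        ref <- ref + oracle_conv2d_zero(img, ker)
      }
      expect_equal(matrix(out[rows, co], H, W), ref, tolerance = 1e-10)
    }
  }
})

test_that("fused residual block agrees with the double-precision composition", {
  set.seed(9)
  H <- 16L; W <- 12L; B <- 3L; C1 <- 5L; C2 <- 4L; Cout <- 6L; g <- 2L
  N <- H * W * B
  x <- matrix(rnorm(N * C1), N, C1)
  x2 <- matrix(rnorm(N * C2), N, C2)
  Wm <- matrix(rnorm((C1 + C2) * 9 * Cout, sd = 0.3), (C1 + C2) * 9, Cout)
  bc <- rnorm(Cout)
  pW <- matrix(rnorm((C1 + C2) * Cout, sd = 0.3), C1 + C2, Cout)
  pb <- rnorm(Cout)
  ga <- runif(Cout, 0.5, 1.5); be <- rnorm(Cout)

  r <- mtloca:::cpp_block_fw(x, x2, H, W, B, Wm, bc, pW, pb, ga, be, g, 1e-5)
  xc <- cbind(x, x2)
  cv <- mtloca:::conv_fw(xc, H, W, B, Wm, bc)
  gn <- mtloca:::gn_fw(cv$out, H, W, B, g, ga, be)
  pj <- mtloca:::lin_fw(xc, pW, pb)
  ref_out <- pmax(gn$out + pj$out, 0)
  expect_equal(r$out, ref_out, tolerance = 1e-5)

  dy <- matrix(rnorm(N * Cout), N, Cout)
  bw <- mtloca:::cpp_block_bw(dy, r$out, r$xhat, r$sds, ga, x, x2,
                              H, W, B, Wm, pW, g, r$xf, r$x2f)
  dpre <- dy * (ref_out > 0)
  gnb <- mtloca:::gn_bw(dpre, gn$cache)
  cvb <- mtloca:::conv_bw(gnb$dx, cv$cache)
  pjb <- mtloca:::lin_bw(dpre, pj$cache)
  dxc <- cvb$dx + pjb$dx
  expect_equal(bw$dW, cvb$dW, tolerance = 1e-4)
  expect_equal(as.numeric(bw$db), cvb$db, tolerance = 1e-6)
  expect_equal(bw$dpW, pjb$dW, tolerance = 1e-10)
  expect_equal(as.numeric(bw$dgamma), gnb$dgamma, tolerance = 1e-6)
  expect_equal(bw$dx, dxc[, 1:C1], tolerance = 1e-5)
  expect_equal(bw$dx2, dxc[, C1 + (1:C2)], tolerance = 1e-5)
})

test_that("fused linear+GN+ReLU agrees with the composition", {
  set.seed(10)
  H <- 10L; W <- 8L; B <- 2L; C1 <- 4L; C2 <- 3L; Cout <- 6L; g <- 3L
  N <- H * W * B
  x <- matrix(rnorm(N * C1), N, C1)
  x2 <- matrix(rnorm(N * C2), N, C2)
  Wl <- matrix(rnorm((C1 + C2) * Cout, sd = 0.4), C1 + C2, Cout)
  b <- rnorm(Cout); ga <- runif(Cout, 0.5, 1.5); be <- rnorm(Cout)
  rl <- mtloca:::cpp_lingnrelu_fw(x, x2, H, W, B, Wl, b, ga, be, g, 1e-5)
  ll <- mtloca:::lin_fw(cbind(x, x2), Wl, b)
  gl <- mtloca:::gn_fw(ll$out, H, W, B, g, ga, be)
  ref <- pmax(gl$out, 0)
  expect_equal(rl$out, ref, tolerance = 1e-5)  # float32 linear stage
  dy <- matrix(rnorm(N * Cout), N, Cout)
  bw <- mtloca:::cpp_lingnrelu_bw(dy, rl$out, rl$xhat, rl$sds, ga, x, x2,
                                  H, W, B, Wl, g)
  dpre <- dy * (ref > 0)
  glb <- mtloca:::gn_bw(dpre, gl$cache)
  llb <- mtloca:::lin_bw(glb$dx, ll$cache)
  expect_equal(bw$dW, llb$dW, tolerance = 1e-5)
  expect_equal(cbind(bw$dx, bw$dx2), llb$dx, tolerance = 1e-5)
  expect_equal(as.numeric(bw$dgamma), glb$dgamma, tolerance = 1e-6)
})

test_that("group normalization standardizes per image and group", {
  set.seed(6)
  H <- 8L; W <- 8L; B <- 2L; C <- 6L; g <- 3L
  x <- matrix(rnorm(H * W * B * C, mean = 3, sd = 2), H * W * B, C)
  r <- mtloca:::gn_fw(x, H, W, B, g, rep(1, C), rep(0, C))
  cg <- C / g
  for (b in seq_len(B)) {
    rows <- ((b - 1) * H * W + 1):(b * H * W)
    for (gg in seq_len(g)) {
      blk <- r$out[rows, ((gg - 1) * cg + 1):(gg * cg)]
      expect_equal(mean(blk), 0, tolerance = 1e-8)
      expect_equal(mean(blk^2), 1, tolerance = 1e-4)  # eps-deflated
    }
  }
})

test_that("pooling and upsampling are exact adjoints / route to the argmax", {
  set.seed(7)
  H <- 8L; W <- 6L; B <- 2L; C <- 3L
  x <- matrix(rnorm(H * W * B * C), H * W * B, C)
  # bilinear upsample: <dy, U x> == <U' dy, x> (linear operator adjoint)
  dy <- matrix(rnorm(4 * H * W * B * C), 4 * H * W * B, C)
  up <- mtloca:::upsample_fw(x, H, W, B)
  down <- mtloca:::upsample_bw(dy, H, W, B)
  expect_equal(sum(dy * up), sum(down * x), tolerance = 1e-8)
  # maxpool backward puts each gradient on the argmax element only
  mp <- mtloca:::maxpool_fw(x, H, W, B)
  g <- matrix(1, nrow(mp$out), C)
  bk <- mtloca:::maxpool_bw(g, mp$cache)
  expect_equal(colSums(bk), colSums(g))
  expect_true(all(bk %in% c(0, 1)))
  expect_equal(sum(x[bk == 1]), sum(mp$out))
})

test_that("softmax cross-entropy matches direct evaluation and its gradient", {
  set.seed(8)
  z <- matrix(rnorm(12 * 3), 12, 3)
  t <- sample(1:3, 12, replace = TRUE)
  r <- mtloca:::ce_fw_bw(z, t)
  p <- exp(z) / rowSums(exp(z))
  expect_equal(r$loss, -mean(log(p[cbind(1:12, t)])), tolerance = 1e-12)
  for (trial in 1:6) {
    i <- sample(length(z), 1)
    eps <- 1e-6
    zp <- z; zp[i] <- zp[i] + eps
    zm <- z; zm[i] <- zm[i] - eps
    num <- (mtloca:::ce_fw_bw(zp, t)$loss -
              mtloca:::ce_fw_bw(zm, t)$loss) / (2 * eps)
    expect_equal(r$dlogits[i], num, tolerance = 1e-5)
  }
  expect_error(mtloca:::ce_fw_bw(z, rep(5L, 12)), "class range")
})

test_that("full-model gradients match directional finite differences", {
  # float32 convolutions cap pointwise FD precision, so check the
  # directional derivative with a moderate step instead
  set.seed(42)
  H <- W <- 16L; B <- 2L
  x <- matrix(runif(H * W * B * 2), H * W * B, 2)
  mask <- stats::rbinom(H * W * B, 1, 0.3)
  labels <- c(2L, 3L)
  for (variant in c("cls_from_backbone", "cls_from_oca", "no_oca")) {
    cfg <- model_config(variant, base_channels = 4L,
                        groupnorm_groups = 2L, hidden = 8L)
    params <- model_init(cfg, seed = 3)
    res <- mtloca:::model_loss_and_grads(params, cfg, x, H, W, B, mask,
                                         labels)
    dirs <- lapply(params, function(p) {
      d <- stats::rnorm(length(p)); dim(d) <- dim(p); d
    })
    analytic <- sum(vapply(names(params), function(nm)
      sum(res$grads[[nm]] * dirs[[nm]]), 0))
    eps <- 1e-4
    shift <- function(s) {
      p2 <- params
      for (nm in names(p2)) p2[[nm]] <- p2[[nm]] + s * dirs[[nm]]
      mtloca:::model_loss_and_grads(p2, cfg, x, H, W, B, mask,
                                    labels)$loss$total
    }
    numeric_d <- (shift(eps) - shift(-eps)) / (2 * eps)
    expect_equal(analytic, numeric_d, tolerance = 2e-2)
  }
})
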