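# Independent oracles used across tests. These are deliberately naive
# (plain R loops) and share no code with the package implementation paths
# they check.

# Direct (non-separable) 2D "same" convolution with symmetric reflection,
# triple loop. Oracle for gradient_magnitude / conv2d_same.
oracle_conv2d_reflect <- function(img, ker) {
  H <- nrow(img); W <- ncol(img)
  kh <- nrow(ker); kw <- ncol(ker)
  ph <- (kh - 1) / 2; pw <- (kw - 1) / 2
  reflect <- function(i, n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
    min(max(i, 1), n)
  }
  out <- matrix(0, H, W)
  for (y in 1:H) {
    for (x in 1:W) {
      acc <- 0
      for (i in 1:kh) {
        for (j in 1:kw) {
          ys <- reflect(y - (i - ph - 1), H)  # convolution: kernel flipped
          xs <- reflect(x - (j - pw - 1), W)
          acc <- acc + img[ys, xs] * ker[i, j]
        }
      }
      out[y, x] <- acc
    }
  }
  out
}

# Zero-padded "same" cross-correlation triple loop (oracle for the network
# convolution path, which uses standard Conv2D semantics).
oracle_conv2d_zero <- function(img, ker) {
  H <- nrow(img); W <- ncol(img)
  kh <- nrow(ker); kw <- ncol(ker)
  ph <- (kh - 1) / 2; pw <- (kw - 1) / 2
  out <- matrix(0, H, W)
  for (y in 1:H) {
    for (x in 1:W) {
      acc <- 0
      for (i in 1:kh) {
        for (j in 1:kw) {
          ys <- y + (i - ph - 1)
          xs <- x + (j - pw - 1)
          if (ys >= 1 && ys <= H && xs >= 1 && xs <= W)
            acc <- acc + img[ys, xs] * ker[i, j]
        }
      }
      out[y, x] <- acc
    }
  }
  out
}

# Brute-force object-contextual attention pipeline with identity transforms:
# given pixel features x (N x C) and raw soft-region scores s (N x K),
# computes d (softmax over pixels per region), f_k = sum_i d_ki x_i,
# w_ik = softmax_k(x_i . f_k / sqrt(C)), y_i = sum_k w_ik f_k — all with
# explicit loops.
oracle_oca <- function(x, s) {
  N <- nrow(x); C <- ncol(x); K <- ncol(s)
  d <- matrix(0, N, K)
  for (k in 1:K) {
    e <- exp(s[, k] - max(s[, k]))
    d[, k] <- e / sum(e)
  }
  f <- matrix(0, K, C)
  for (k in 1:K)
    for (i in 1:N)
      f[k, ] <- f[k, ] + d[i, k] * x[i, ]
  w <- matrix(0, N, K)
  for (i in 1:N) {
    l <- numeric(K)
    for (k in 1:K) l[k] <- sum(x[i, ] * f[k, ]) / sqrt(C)
    e <- exp(l - max(l))
    w[i, ] <- e / sum(e)
  }
  y <- matrix(0, N, C)
  for (i in 1:N)
    for (k in 1:K)
      y[i, ] <- y[i, ] + w[i, k] * f[k, ]
  list(d = d, f = f, w = w, y = y)
}

# Equal-thirds phantom world used widely in tests.
test_phantom_spec <- function(seed = 1L, ...) {
  phantom_spec(class_mix = c(normal = 1, benign = 1, malignant = 1) / 3,
               seed = seed, ...)
}
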