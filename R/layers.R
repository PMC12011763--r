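# Neural-network primitives with hand-written forward/backward passes.
#
# Activations are dense (H*W*B) x C matrices: row index runs over image
# height fastest, then width, then batch ("pixel-major"); one column per
# channel. Spatial dims travel alongside as plain integers. Every *_fw
# returns list(out, cache); every *_bw consumes the upstream gradient plus
# that cache and returns gradients for inputs and parameters.

PAD_ZERO <- 0L
PAD_REFLECT <- 1L

# 3x3 "same" convolution, zero padding (standard Conv2D semantics), via
# nine shifted dgemms in C++. Weight layout: (Cin*9) x Cout with row index
# q = c*9 + (dx+1)*3 + (dy+1).
conv_fw <- function(x, H, W, B, Wm, b) {
  out <- cpp_conv3x3_fw(x, H, W, B, Wm, b)
  list(out = out, cache = list(x = x, Wm = Wm, H = H, W = W, B = B,
                               Cin = ncol(x)))
}

conv_bw <- function(dy, cache) {
  list(dx = cpp_conv3x3_bw_dx(dy, cache$H, cache$W, cache$B, cache$Wm,
                              cache$Cin),
       dW = cpp_conv3x3_bw_dw(cache$x, dy, cache$H, cache$W, cache$B),
       db = colSums(dy))
}

lin_fw <- function(x, Wm, b) {
  list(out = cpp_lin_bias(x, Wm, b), cache = list(x = x, Wm = Wm))
}

lin_bw <- function(dy, cache) {
  list(dx = tcrossprod(dy, cache$Wm),
       dW = crossprod(cache$x, dy),
       db = colSums(dy))
}

relu_fw <- function(x) {
  out <- cpp_relu(x)
  list(out = out, cache = out)  # backward mask is (out > 0)
}

relu_bw <- function(dy, ref) cpp_relu_bw(dy, ref)

# Group normalization over (H*W, channels-in-group) per image.
gn_fw <- function(x, H, W, B, groups, gamma, beta, eps = 1e-5) {
  stopifnot(ncol(x) %% groups == 0)
  r <- cpp_groupnorm_affine(x, H, W, B, groups, gamma, beta, eps)
  list(out = r$out, cache = list(xhat = r$xhat, sds = r$sds, gamma = gamma,
                                 H = H, W = W, B = B, groups = groups))
}

gn_bw <- function(dy, cache) {
  r <- cpp_groupnorm_affine_bw(dy, cache$xhat, cache$sds, cache$gamma,
                               cache$H, cache$W, cache$B, cache$groups)
  list(dx = r$dx, dgamma = r$dgamma, dbeta = r$dbeta)
}

maxpool_fw <- function(x, H, W, B) {
  r <- cpp_maxpool2(x, H, W, B)
  list(out = r$y, cache = list(argmax = r$argmax, nrow_in = nrow(x)))
}

maxpool_bw <- function(dy, cache) {
  cpp_maxpool2_bw(dy, cache$argmax, cache$nrow_in)
}

upsample_fw <- function(x, H, W, B) cpp_upsample2(x, H, W, B)

upsample_bw <- function(dy, H, W, B) cpp_upsample2_bw(dy, H, W, B)

# Global average pooling: (H*W*B) x C -> B x C.
gap_fw <- function(x, H, W, B) {
  HW <- H * W
  out <- matrix(0, B, ncol(x))
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * HW + 1L):(b * HW)
    out[b, ] <- colMeans(x[rows, , drop = FALSE])
  }
  out
}

gap_bw <- function(dv, H, W, B) cpp_gap_bw(dv, H, W, B)

softmax_rows <- function(z) {
  e <- exp(z - cpp_row_max(z))
  e / rowSums(e)
}

# Mean cross-entropy over rows; `target` is a 1-based class index per row.
# Returns loss plus the gradient wrt logits.
ce_fw_bw <- function(logits, target) {
  assert_that(all(is.finite(logits)), "non-finite logits in cross-entropy")
  assert_that(all(target >= 1L & target <= ncol(logits)),
              "target labels outside the valid class range")
  r <- cpp_softmax_ce(logits, as.integer(target))
  list(loss = r$loss, dlogits = r$dlogits)
}

he_init <- function(nin, nout, fan_in = nin) {
  matrix(rnorm(nin * nout, sd = sqrt(2 / fan_in)), nin, nout)
}

# Adam ----------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mh <- state$m[[nm]] / bc1
    vh <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

acc_grad <- function(grads, nm, g) {
  grads[[nm]] <- if (is.null(grads[[nm]])) g else grads[[nm]] + g
  grads
}
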