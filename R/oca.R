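# Object-contextual attention: soft object regions, object-region
# representations (weighted feature pooling), pixel-region relation
# (attention softmax over regions) and contextual representations, followed
# by concatenation with the pixel representations to produce the final
# segmentation logits.
#
# Conventions. Pixel representations are N x C matrices (one row per pixel).
# The raw soft-region map (N x K) doubles as the coarse segmentation logits
# supervised by the auxiliary loss; for region pooling it is normalized by a
# softmax ACROSS PIXELS within each region channel, so each region
# representation is a convex combination of pixel features.

#' Softmax across pixels per region channel
#'
#' @param logits N x K matrix of raw soft-region scores.
#' @return N x K matrix; every column sums to 1.
#' @export
pixel_softmax <- function(logits) {
  n <- nrow(logits)
  cmax <- vapply(seq_len(ncol(logits)), function(j) max(logits[, j]), 0)
  e <- exp(logits - rep(cmax, each = n))
  e * rep(1 / colSums(e), each = n)
}

#' Soft object regions from pixel representations
#'
#' A learned 1x1 projection of the pixel features into K region scores.
#' Returns both the raw logits (the coarse segmentation mask that receives
#' the auxiliary supervision) and the pixel-softmax-normalized weights used
#' for region pooling.
#'
#' @param x N x C pixel representations.
#' @param W C x K projection weights.
#' @param b length-K bias.
#' @return list(`logits` N x K, `weights` N x K with unit column sums).
#' @export
soft_regions <- function(x, W, b = numeric(ncol(W))) {
  assert_that(ncol(x) == nrow(W), "feature/projection width mismatch",
              class = "mtloca_shape_error")
  logits <- sweep(x %*% W, 2L, b, "+")
  list(logits = logits, weights = pixel_softmax(logits))
}

#' Object-region representations
#'
#' `f_k = sum_i d_ki x_i`: each region's representation is the
#' d-weighted sum of pixel features.
#'
#' @param x N x C pixel representations.
#' @param d N x K soft-region weights.
#' @return K x C matrix of region representations.
#' @export
region_representations <- function(x, d) {
  assert_that(nrow(x) == nrow(d), "x and d disagree on pixel count",
              class = "mtloca_shape_error")
  crossprod(d, x)
}

#' Pixel-region relation (attention over regions)
#'
#' `w_ik = exp(l(x_i, f_k)) / sum_j exp(l(x_i, f_j))` where the
#' compatibility `l` is a scaled dot product between (optionally learned
#' 1x1-transformed) pixel and region vectors. With `Wq = Wk = NULL` the
#' transforms are the identity (test mode).
#'
#' @param x N x C pixel representations.
#' @param f K x C region representations.
#' @param Wq,Wk optional C x A transform matrices for pixels and regions.
#' @param scaled divide scores by `sqrt(A)` (default TRUE).
#' @return N x K row-stochastic relation matrix.
#' @export
pixel_region_relation <- function(x, f, Wq = NULL, Wk = NULL,
                                  scaled = TRUE) {
  assert_that(nrow(f) >= 2, "need at least K = 2 regions")
  q <- if (is.null(Wq)) x else x %*% Wq
  k <- if (is.null(Wk)) f else f %*% Wk
  assert_that(ncol(q) == ncol(k), "query/key width mismatch",
              class = "mtloca_shape_error")
  sc <- tcrossprod(q, k)
  if (scaled) sc <- sc / sqrt(ncol(q))
  assert_that(all(is.finite(sc)),
              "non-finite attention scores", class = "mtloca_numeric_error")
  softmax_rows(sc)
}

#' Contextual representations
#'
#' `y_i = delta(sum_k w_ik H(f_k))`: each pixel's context is its
#' relation-weighted mixture of transformed region representations, passed
#' through a final transform. Both transforms default to the identity.
#'
#' @param w N x K pixel-region relation.
#' @param f K x C region representations.
#' @param H_fun,delta_fun transforms applied to `f` (before) and to the
#'   weighted sum (after).
#' @return N x C' contextual feature matrix.
#' @export
contextual_representation <- function(w, f, H_fun = identity,
                                      delta_fun = identity) {
  hf <- H_fun(f)
  assert_that(ncol(w) == nrow(hf), "w and H(f) disagree on region count",
              class = "mtloca_shape_error")
  delta_fun(w %*% hf)
}

#' Augmented representation and segmentation logits
#'
#' Concatenates contextual and pixel representations, applies the learned
#' head (1x1 conv equivalents) and returns segmentation logits plus the
#' argmax mask with ties broken toward the lower (background) class.
#'
#' @param x N x C pixel representations.
#' @param y N x C2 contextual representations.
#' @param Wa,ba head weights `(C2+C) x Ca`; `Wo,bo` logit weights `Ca x K`.
#' @return list(`augmented` N x (C2+C), `head` N x Ca, `seg_logits` N x K,
#'   `mask` length-N integer in `0..K-1`).
#' @export
augmented_segmentation <- function(x, y, Wa, ba, Wo, bo) {
  assert_that(nrow(x) == nrow(y), "x and y disagree on pixel count",
              class = "mtloca_shape_error")
  z <- cbind(y, x)
  h <- pmax(sweep(z %*% Wa, 2L, ba, "+"), 0)
  logits <- sweep(h %*% Wo, 2L, bo, "+")
  mask <- max.col(logits, ties.method = "first") - 1L
  list(augmented = z, head = h, seg_logits = logits, mask = mask)
}

# Learned module: initialization, batched forward, backward -------------------

oca_init <- function(C_f, K = 2L, A = NULL, C2 = NULL, Ca = NULL) {
  A <- A %||% C_f
  C2 <- C2 %||% C_f
  Ca <- Ca %||% C_f
  p <- list()
  p[["oca.sW"]] <- he_init(C_f, K, fan_in = C_f)
  p[["oca.sb"]] <- numeric(K)
  p[["oca.qW"]] <- he_init(C_f, A, fan_in = C_f)
  p[["oca.qb"]] <- numeric(A)
  p[["oca.kW"]] <- he_init(C_f, A, fan_in = C_f)
  p[["oca.kb"]] <- numeric(A)
  p[["oca.hW"]] <- he_init(C_f, C2, fan_in = C_f)
  p[["oca.hb"]] <- numeric(C2)
  p[["oca.dW"]] <- he_init(C2, C2, fan_in = C2)
  p[["oca.db"]] <- numeric(C2)
  p[["oca.dgamma"]] <- rep(1, C2)
  p[["oca.dbeta"]] <- numeric(C2)
  p[["oca.aW"]] <- he_init(C2 + C_f, Ca, fan_in = C2 + C_f)
  p[["oca.ab"]] <- numeric(Ca)
  p[["oca.agamma"]] <- rep(1, Ca)
  p[["oca.abeta"]] <- numeric(Ca)
  p[["oca.oW"]] <- he_init(Ca, K, fan_in = Ca)
  p[["oca.ob"]] <- numeric(K)
  p
}

# x: (H*W*B) x C_f. Per-image softmaxes and small gemms run in a C++ core;
# the delta transform and the augmented head are fused 1x1-linear + GN +
# ReLU ops; the head consumes (y, x) as two parts so the concatenated
# augmented representation is never materialized.
oca_fw <- function(params, x, H, W, B, groups, K = 2L, check = FALSE) {
  S <- cpp_lin_bias(x, params[["oca.sW"]], params[["oca.sb"]])
  Q <- cpp_lin_bias(x, params[["oca.qW"]], params[["oca.qb"]])
  core <- cpp_oca_fw_core(x, S, Q, params[["oca.kW"]], params[["oca.kb"]],
                          params[["oca.hW"]], params[["oca.hb"]], H, W, B)
  assert_that(isTRUE(core$finite), "non-finite attention scores",
              class = "mtloca_numeric_error")
  if (check)
    assert_that(max(abs(rowSums(core$wrel) - 1)) < 1e-6,
                "pixel-region relation rows do not sum to 1")
  dl <- cpp_lingnrelu_fw(core$ctx, NULL, H, W, B, params[["oca.dW"]],
                         params[["oca.db"]], params[["oca.dgamma"]],
                         params[["oca.dbeta"]], groups, 1e-5)
  y <- dl$out
  al <- cpp_lingnrelu_fw(y, x, H, W, B, params[["oca.aW"]],
                         params[["oca.ab"]], params[["oca.agamma"]],
                         params[["oca.abeta"]], groups, 1e-5)
  ol <- lin_fw(al$out, params[["oca.oW"]], params[["oca.ob"]])
  list(soft_logits = S, seg_logits = ol$out, head = al$out, y = y,
       d = core$d, f = core$f, w = core$wrel,
       cache = list(S = S, Q = Q, core = core, x = x, y = y,
                    dl = dl, al = al, ol = ol$cache,
                    H = H, W = W, B = B, K = K))
}

# dseg: gradient on seg_logits; dsoft: gradient on soft-region logits (from
# the auxiliary loss); dhead_extra: optional gradient on the post-head
# features (classification-from-OCA wiring). Returns dx plus param grads.
oca_bw <- function(dseg, dsoft, cache, params, grads = list(), groups,
                   dhead_extra = NULL) {
  H <- cache$H; W <- cache$W; B <- cache$B
  ob <- lin_bw(dseg, cache$ol)
  grads <- acc_grad(grads, "oca.oW", ob$dW)
  grads <- acc_grad(grads, "oca.ob", ob$db)
  dhead <- ob$dx
  if (!is.null(dhead_extra)) dhead <- cpp_axpy(dhead, dhead_extra)
  ab <- cpp_lingnrelu_bw(dhead, cache$al$out, cache$al$xhat,
                         cache$al$sds, params[["oca.agamma"]], cache$y,
                         cache$x, H, W, B, params[["oca.aW"]], groups)
  grads <- acc_grad(grads, "oca.aW", ab$dW)
  grads <- acc_grad(grads, "oca.ab", ab$db)
  grads <- acc_grad(grads, "oca.agamma", ab$dgamma)
  grads <- acc_grad(grads, "oca.abeta", ab$dbeta)
  dy <- ab$dx
  dx <- ab$dx2

  db_ <- cpp_lingnrelu_bw(dy, cache$dl$out, cache$dl$xhat, cache$dl$sds,
                          params[["oca.dgamma"]], cache$core$ctx, NULL,
                          H, W, B, params[["oca.dW"]], groups)
  grads <- acc_grad(grads, "oca.dW", db_$dW)
  grads <- acc_grad(grads, "oca.db", db_$db)
  grads <- acc_grad(grads, "oca.dgamma", db_$dgamma)
  grads <- acc_grad(grads, "oca.dbeta", db_$dbeta)

  core <- cache$core
  cb <- cpp_oca_bw_core(db_$dx, cache$x, core$d, core$wrel, cache$Q,
                        core$f, core$kf, core$hfpre, core$hfout,
                        params[["oca.kW"]], params[["oca.hW"]], H, W, B)
  grads <- acc_grad(grads, "oca.kW", cb$dkW)
  grads <- acc_grad(grads, "oca.kb", cb$dkb)
  grads <- acc_grad(grads, "oca.hW", cb$dhW)
  grads <- acc_grad(grads, "oca.hb", cb$dhb)
  dx <- cpp_axpy(dx, cb$dx)
  qb <- lin_bw(cb$dQ, list(x = cache$x, Wm = params[["oca.qW"]]))
  grads <- acc_grad(grads, "oca.qW", qb$dW)
  grads <- acc_grad(grads, "oca.qb", qb$db)
  dx <- cpp_axpy(dx, qb$dx)
  dS <- cb$dS
  if (!is.null(dsoft)) dS <- cpp_axpy(dS, dsoft)
  sb <- lin_bw(dS, list(x = cache$x, Wm = params[["oca.sW"]]))
  grads <- acc_grad(grads, "oca.sW", sb$dW)
  grads <- acc_grad(grads, "oca.sb", sb$db)
  dx <- cpp_axpy(dx, sb$dx)
  list(dx = dx, grads = grads)
}
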