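# Three-level residual U-Net backbone. Encoder blocks: Conv2D -> GroupNorm
# (+ 1x1 residual projection) -> ReLU -> MaxPool. Decoder blocks: bilinear
# Upsample -> skip concatenation -> Conv2D -> GroupNorm (+ projection) ->
# ReLU. A final 1x1 fusing convolution yields the per-pixel representations
# consumed by both heads, at full input resolution (stride 1).

#' Backbone configuration
#'
#' @param base_channels channel width of the first encoder block; widths
#'   double per level (base, 2x, 4x; bottleneck 8x).
#' @param feat_channels width of the fused pixel representation (default
#'   `2 * base_channels`); the attention module and both heads consume
#'   features of this width, so it sets the pooled classifier capacity.
#' @param groupnorm_groups groups per GroupNorm layer; must divide
#'   `base_channels`.
#' @param in_channels input channels (2: intensity + edge magnitude).
#' @param depth encoder/decoder level count; fixed at 3.
#' @return a `backbone_config` list.
#' @export
backbone_config <- function(base_channels = 32L, groupnorm_groups = 8L,
                            in_channels = 2L, depth = 3L,
                            feat_channels = NULL) {
  assert_that(depth == 3L, "depth is fixed at 3")
  assert_that(base_channels %% groupnorm_groups == 0,
              "base_channels must be divisible by groupnorm_groups")
  feat_channels <- feat_channels %||% (2L * as.integer(base_channels))
  assert_that(feat_channels %% groupnorm_groups == 0,
              "feat_channels must be divisible by groupnorm_groups")
  structure(list(base_channels = as.integer(base_channels),
                 groupnorm_groups = as.integer(groupnorm_groups),
                 in_channels = as.integer(in_channels),
                 depth = 3L,
                 feat_channels = as.integer(feat_channels)),
            class = "backbone_config")
}

.block_channels <- function(cfg) {
  b <- cfg$base_channels
  list(e1 = c(cfg$in_channels, b),
       e2 = c(b, 2L * b),
       e3 = c(2L * b, 4L * b),
       bott = c(4L * b, 8L * b),
       d3 = c(8L * b + 4L * b, 4L * b),
       d2 = c(4L * b + 2L * b, 2L * b),
       d1 = c(2L * b + b, b),
       fuse = c(b, cfg$feat_channels))
}

backbone_init <- function(cfg) {
  ch <- .block_channels(cfg)
  p <- list()
  for (nm in c("e1", "e2", "e3", "bott", "d3", "d2", "d1")) {
    cin <- ch[[nm]][1]; cout <- ch[[nm]][2]
    p[[paste0(nm, ".W")]] <- he_init(cin * 9L, cout, fan_in = cin * 9L)
    p[[paste0(nm, ".b")]] <- numeric(cout)
    p[[paste0(nm, ".pW")]] <- he_init(cin, cout, fan_in = cin)
    p[[paste0(nm, ".pb")]] <- numeric(cout)
    p[[paste0(nm, ".gamma")]] <- rep(1, cout)
    p[[paste0(nm, ".beta")]] <- numeric(cout)
  }
  p[["fuse.W"]] <- he_init(ch$fuse[1], ch$fuse[2], fan_in = ch$fuse[1])
  p[["fuse.b"]] <- numeric(ch$fuse[2])
  p[["fuse.gamma"]] <- rep(1, ch$fuse[2])
  p[["fuse.beta"]] <- numeric(ch$fuse[2])
  p
}

# Residual conv block: ReLU(GroupNorm(conv3x3(x)) + proj1x1(x)), fused in
# C++; `x2` supplies the skip part of a decoder block's concatenated input
# without materializing the concatenation.
.block_fw <- function(x, H, W, B, p, nm, groups, x2 = NULL) {
  r <- cpp_block_fw(x, x2, H, W, B,
                    p[[paste0(nm, ".W")]], p[[paste0(nm, ".b")]],
                    p[[paste0(nm, ".pW")]], p[[paste0(nm, ".pb")]],
                    p[[paste0(nm, ".gamma")]], p[[paste0(nm, ".beta")]],
                    groups, 1e-5)
  list(out = r$out,
       cache = list(out = r$out, xhat = r$xhat, sds = r$sds, x = x,
                    x2 = x2, xf = r$xf, x2f = r$x2f, nm = nm,
                    H = H, W = W, B = B, groups = groups))
}

.block_bw <- function(dy, cache, p, grads) {
  nm <- cache$nm
  r <- cpp_block_bw(dy, cache$out, cache$xhat, cache$sds,
                    p[[paste0(nm, ".gamma")]], cache$x, cache$x2,
                    cache$H, cache$W, cache$B,
                    p[[paste0(nm, ".W")]], p[[paste0(nm, ".pW")]],
                    cache$groups, cache$xf, cache$x2f)
  grads <- acc_grad(grads, paste0(nm, ".W"), r$dW)
  grads <- acc_grad(grads, paste0(nm, ".b"), r$db)
  grads <- acc_grad(grads, paste0(nm, ".pW"), r$dpW)
  grads <- acc_grad(grads, paste0(nm, ".pb"), r$dpb)
  grads <- acc_grad(grads, paste0(nm, ".gamma"), r$dgamma)
  grads <- acc_grad(grads, paste0(nm, ".beta"), r$dbeta)
  list(dx = r$dx, dx2 = r$dx2, grads = grads)
}

#' Backbone forward pass
#'
#' @param params named parameter list from the model initializer.
#' @param x `(H*W*B) x in_channels` activation matrix (see package
#'   internals; [inputs_to_batch()] builds it from model inputs).
#' @param H,W,B spatial size and batch size.
#' @param cfg a [backbone_config()].
#' @return list with `features` (`(H*W*B) x feat_channels` pixel
#'   representations at stride 1) and `cache` for the backward pass.
#' @export
backbone_forward <- function(params, x, H, W, B, cfg) {
  g <- cfg$groupnorm_groups
  e1 <- .block_fw(x, H, W, B, params, "e1", g)
  p1 <- maxpool_fw(e1$out, H, W, B)
  e2 <- .block_fw(p1$out, H / 2, W / 2, B, params, "e2", g)
  p2 <- maxpool_fw(e2$out, H / 2, W / 2, B)
  e3 <- .block_fw(p2$out, H / 4, W / 4, B, params, "e3", g)
  p3 <- maxpool_fw(e3$out, H / 4, W / 4, B)
  bt <- .block_fw(p3$out, H / 8, W / 8, B, params, "bott", g)
  u3 <- upsample_fw(bt$out, H / 8, W / 8, B)
  d3 <- .block_fw(u3, H / 4, W / 4, B, params, "d3", g, x2 = e3$out)
  u2 <- upsample_fw(d3$out, H / 4, W / 4, B)
  d2 <- .block_fw(u2, H / 2, W / 2, B, params, "d2", g, x2 = e2$out)
  u1 <- upsample_fw(d2$out, H / 2, W / 2, B)
  d1 <- .block_fw(u1, H, W, B, params, "d1", g, x2 = e1$out)
  fz <- cpp_lingnrelu_fw(d1$out, NULL, H, W, B, params[["fuse.W"]],
                         params[["fuse.b"]], params[["fuse.gamma"]],
                         params[["fuse.beta"]], g, 1e-5)
  list(features = fz$out,
       cache = list(e1 = e1, p1 = p1, e2 = e2, p2 = p2, e3 = e3, p3 = p3,
                    bt = bt, d3 = d3, d2 = d2, d1 = d1,
                    fuse = list(out = fz$out, xhat = fz$xhat, sds = fz$sds,
                                x = d1$out),
                    dims = c(H = H, W = W, B = B), groups = g))
}

backbone_backward <- function(dfeat, cache, params, grads = list()) {
  H <- cache$dims[["H"]]; W <- cache$dims[["W"]]; B <- cache$dims[["B"]]
  fz <- cpp_lingnrelu_bw(dfeat, cache$fuse$out, cache$fuse$xhat,
                         cache$fuse$sds, params[["fuse.gamma"]],
                         cache$fuse$x, NULL, H, W, B, params[["fuse.W"]],
                         cache$groups)
  grads <- acc_grad(grads, "fuse.W", fz$dW)
  grads <- acc_grad(grads, "fuse.b", fz$db)
  grads <- acc_grad(grads, "fuse.gamma", fz$dgamma)
  grads <- acc_grad(grads, "fuse.beta", fz$dbeta)

  r <- .block_bw(fz$dx, cache$d1$cache, params, grads); grads <- r$grads
  de1 <- r$dx2
  dd2 <- upsample_bw(r$dx, H / 2, W / 2, B)
  r <- .block_bw(dd2, cache$d2$cache, params, grads); grads <- r$grads
  de2 <- r$dx2
  dd3 <- upsample_bw(r$dx, H / 4, W / 4, B)
  r <- .block_bw(dd3, cache$d3$cache, params, grads); grads <- r$grads
  de3 <- r$dx2
  dbt <- upsample_bw(r$dx, H / 8, W / 8, B)

  r <- .block_bw(dbt, cache$bt$cache, params, grads); grads <- r$grads
  dp3 <- cpp_axpy(maxpool_bw(r$dx, cache$p3$cache), de3)
  r <- .block_bw(dp3, cache$e3$cache, params, grads); grads <- r$grads
  dp2 <- cpp_axpy(maxpool_bw(r$dx, cache$p2$cache), de2)
  r <- .block_bw(dp2, cache$e2$cache, params, grads); grads <- r$grads
  dp1 <- cpp_axpy(maxpool_bw(r$dx, cache$p1$cache), de1)
  r <- .block_bw(dp1, cache$e1$cache, params, grads); grads <- r$grads
  list(dx = r$dx, grads = grads)
}

#' Print backbone/model layer shapes
#'
#' @param cfg a [backbone_config()].
#' @param input_size spatial side of the input (default 128).
#' @return invisibly, a data.frame of stages and shapes.
#' @export
model_summary <- function(cfg = backbone_config(), input_size = 128L) {
  ch <- .block_channels(cfg)
  s <- input_size
  rows <- list(
    c("input", s, cfg$in_channels),
    c("enc1", s, ch$e1[2]), c("pool1", s / 2, ch$e1[2]),
    c("enc2", s / 2, ch$e2[2]), c("pool2", s / 4, ch$e2[2]),
    c("enc3", s / 4, ch$e3[2]), c("pool3", s / 8, ch$e3[2]),
    c("bottleneck", s / 8, ch$bott[2]),
    c("dec3", s / 4, ch$d3[2]),
    c("dec2", s / 2, ch$d2[2]),
    c("dec1", s, ch$d1[2]),
    c("pixel-representations", s, ch$fuse[2]))
  df <- data.frame(stage = vapply(rows, `[`, "", 1),
                   spatial = as.integer(vapply(rows, `[`, "", 2)),
                   channels = as.integer(vapply(rows, `[`, "", 3)))
  for (i in seq_len(nrow(df)))
    cat(sprintf("%-22s %4dx%-4d x %d\n", df$stage[i], df$spatial[i],
                df$spatial[i], df$channels[i]))
  invisible(df)
}
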