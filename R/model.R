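# Full multi-task model: backbone + (optionally) the object-contextual
# attention head for segmentation + a two-layer MLP classifier over globally
# pooled features. Three wirings are supported, matching the ablation arms:
#   no_oca            - segmentation logits straight from a 1x1 conv on the
#                       backbone features; classifier pools those features
#   cls_from_oca      - OCA refines segmentation; classifier pools the
#                       OCA head (augmented-representation) features
#   cls_from_backbone - OCA refines segmentation; classifier pools backbone
#                       features (the proposed wiring)

MODEL_VARIANTS <- c("no_oca", "cls_from_oca", "cls_from_backbone")

#' Model configuration
#'
#' @param variant one of `"no_oca"`, `"cls_from_oca"`,
#'   `"cls_from_backbone"` (the proposed wiring, default).
#' @param base_channels backbone width (see [backbone_config()]).
#' @param groupnorm_groups GroupNorm groups.
#' @param in_channels input channels.
#' @param n_classes classification classes (3).
#' @param K segmentation classes / soft object regions (2).
#' @param alpha weight of the soft-region (coarse) segmentation loss.
#' @param hidden MLP hidden width.
#' @param feat_channels fused pixel-representation width (see
#'   [backbone_config()]).
#' @return a `model_config` list (embeds a [backbone_config()]).
#' @export
model_config <- function(variant = "cls_from_backbone", base_channels = 32L,
                         groupnorm_groups = 8L, in_channels = 2L,
                         n_classes = 3L, K = 2L, alpha = 0.4,
                         hidden = 128L, feat_channels = NULL) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  assert_that(alpha >= 0 && alpha <= 1, "alpha must be in [0,1]")
  bb <- backbone_config(base_channels, groupnorm_groups, in_channels,
                        feat_channels = feat_channels)
  structure(list(variant = variant, backbone = bb, n_classes = n_classes,
                 K = as.integer(K), alpha = alpha,
                 hidden = as.integer(hidden)),
            class = "model_config")
}

# all three wirings pool a feature map of width feat_channels (the OCA
# head width equals C_f by construction)
# the backbone wirings pool the fused features; the classification-from-
# attention wiring pools the attention head, whose width follows 2x base
.cls_in_channels <- function(cfg) {
  if (cfg$variant == "cls_from_oca") 2L * cfg$backbone$base_channels
  else cfg$backbone$feat_channels
}

#' Initialize model parameters
#'
#' @param cfg a [model_config()].
#' @param seed integer seed for the (He-normal) initialization.
#' @return named list of parameter matrices/vectors.
#' @export
model_init <- function(cfg, seed = 1L) {
  with_seed(seed, {
    p <- backbone_init(cfg$backbone)
    C_f <- cfg$backbone$feat_channels
    if (cfg$variant == "no_oca") {
      p[["seg.W"]] <- he_init(C_f, cfg$K, fan_in = C_f)
      p[["seg.b"]] <- numeric(cfg$K)
    } else {
      # attention/context widths follow 2x base (64 at full scale), kept
      # independent of the fused feature width
      w <- 2L * cfg$backbone$base_channels
      p <- c(p, oca_init(C_f, K = cfg$K, A = w, C2 = w, Ca = w))
    }
    cin <- .cls_in_channels(cfg)
    p[["cls.W1"]] <- he_init(cin, cfg$hidden, fan_in = cin)
    p[["cls.b1"]] <- numeric(cfg$hidden)
    p[["cls.W2"]] <- he_init(cfg$hidden, cfg$n_classes, fan_in = cfg$hidden)
    p[["cls.b2"]] <- numeric(cfg$n_classes)
    p
  })
}

#' Classify from pixel representations
#'
#' Global average pooling over pixels followed by a two-layer MLP ending in
#' three neurons ordered (normal, benign, malignant).
#'
#' @param x `(H*W*B) x C` feature matrix.
#' @param H,W,B spatial/batch dims.
#' @param params parameter list holding `cls.W1/b1/W2/b2`.
#' @return list(`logits` B x 3, `cache`).
#' @export
classify <- function(x, H, W, B, params) {
  v <- gap_fw(x, H, W, B)
  l1 <- lin_fw(v, params[["cls.W1"]], params[["cls.b1"]])
  r1 <- relu_fw(l1$out)
  l2 <- lin_fw(r1$out, params[["cls.W2"]], params[["cls.b2"]])
  list(logits = l2$out,
       cache = list(l1 = l1$cache, r1 = r1$cache, l2 = l2$cache,
                    H = H, W = W, B = B))
}

classify_bw <- function(dlogits, cache, grads = list()) {
  l2b <- lin_bw(dlogits, cache$l2)
  grads <- acc_grad(grads, "cls.W2", l2b$dW)
  grads <- acc_grad(grads, "cls.b2", l2b$db)
  dr1 <- relu_bw(l2b$dx, cache$r1)
  l1b <- lin_bw(dr1, cache$l1)
  grads <- acc_grad(grads, "cls.W1", l1b$dW)
  grads <- acc_grad(grads, "cls.b1", l1b$db)
  dx <- gap_bw(l1b$dx, cache$H, cache$W, cache$B)
  list(dx = dx, grads = grads)
}

#' Combined multi-task loss breakdown
#'
#' Cross-entropies on the soft object regions (`l_soft`), the augmented
#' segmentation logits (`l_aug`) and the class logits (`l_c`), combined as
#' `l_s = alpha * l_soft + l_aug` and `total = l_s + l_c`.
#'
#' @param soft_logits N x K coarse-mask logits, or `NULL` (no-OCA arm;
#'   `l_soft` is then 0).
#' @param aug_logits N x K final segmentation logits.
#' @param mask_target length-N vector in `{0, 1}` (1 = lesion).
#' @param class_logits B x 3 classification logits.
#' @param label_target length-B labels: integers in 1..3 or the class names.
#' @param alpha soft-loss weight, default 0.4.
#' @return a `loss_breakdown` list with `l_soft`, `l_aug`, `l_s`, `l_c`,
#'   `total`, `alpha` and (attribute-free) gradient entries `d_soft`,
#'   `d_aug`, `d_cls` for internal use.
#' @export
combined_loss <- function(soft_logits, aug_logits, mask_target,
                          class_logits, label_target, alpha = 0.4) {
  assert_that(alpha >= 0 && alpha <= 1, "alpha must be in [0,1]")
  assert_that(all(mask_target %in% c(0, 1)),
              "mask target must be binary {0,1}",
              class = "mtloca_validation_error")
  if (is.character(label_target))
    label_target <- match(label_target, CLASS_LEVELS)
  assert_that(!anyNA(label_target) &&
                all(label_target %in% seq_len(ncol(class_logits))),
              "class labels outside {0,1,2} / known names",
              class = "mtloca_validation_error")
  seg_t <- as.integer(mask_target) + 1L
  aug <- ce_fw_bw(aug_logits, seg_t)
  cls <- ce_fw_bw(class_logits, as.integer(label_target))
  if (is.null(soft_logits)) {
    l_soft <- 0
    d_soft <- NULL
  } else {
    soft <- ce_fw_bw(soft_logits, seg_t)
    l_soft <- soft$loss
    d_soft <- soft$dlogits * alpha
  }
  l_s <- alpha * l_soft + aug$loss
  structure(list(l_soft = l_soft, l_aug = aug$loss, l_s = l_s,
                 l_c = cls$loss, total = l_s + cls$loss, alpha = alpha,
                 d_soft = d_soft, d_aug = aug$dlogits, d_cls = cls$dlogits),
            class = "loss_breakdown")
}

#' Full model forward pass
#'
#' @param params parameters from [model_init()].
#' @param cfg a [model_config()].
#' @param x `(H*W*B) x in_channels` input batch matrix.
#' @param H,W,B dims.
#' @param keep_cache keep layer caches for a backward pass.
#' @return list with `feat`, `soft_logits` (NULL for no_oca), `seg_logits`,
#'   `class_logits`, `cls_feat_dims`, and caches when requested.
#' @export
model_forward <- function(params, cfg, x, H, W, B, keep_cache = FALSE) {
  bb <- backbone_forward(params, x, H, W, B, cfg$backbone)
  g <- cfg$backbone$groupnorm_groups
  if (cfg$variant == "no_oca") {
    sl <- lin_fw(bb$features, params[["seg.W"]], params[["seg.b"]])
    oc <- NULL
    soft_logits <- NULL
    seg_logits <- sl$out
    cls_src <- bb$features
    seg_cache <- sl$cache
  } else {
    oc <- oca_fw(params, bb$features, H, W, B, g, K = cfg$K)
    soft_logits <- oc$soft_logits
    seg_logits <- oc$seg_logits
    cls_src <- if (cfg$variant == "cls_from_oca") oc$head else bb$features
    seg_cache <- NULL
  }
  cl <- classify(cls_src, H, W, B, params)
  out <- list(feat = bb$features, soft_logits = soft_logits,
              seg_logits = seg_logits, class_logits = cl$logits,
              oca = if (!is.null(oc))
                list(d = oc$d, f = oc$f, w = oc$w, y = oc$y,
                     head = oc$head))
  if (keep_cache)
    out$cache <- list(bb = bb$cache, oca = if (!is.null(oc)) oc$cache,
                      seg = seg_cache, cls = cl$cache,
                      H = H, W = W, B = B)
  out
}

# One training step's losses and parameter gradients.
model_loss_and_grads <- function(params, cfg, x, H, W, B, mask_target,
                                 label_target) {
  fw <- model_forward(params, cfg, x, H, W, B, keep_cache = TRUE)
  lb <- combined_loss(fw$soft_logits, fw$seg_logits, mask_target,
                      fw$class_logits, label_target, alpha = cfg$alpha)
  grads <- list()
  cb <- classify_bw(lb$d_cls, fw$cache$cls, grads)
  grads <- cb$grads
  if (cfg$variant == "no_oca") {
    sb <- lin_bw(lb$d_aug, fw$cache$seg)
    grads <- acc_grad(grads, "seg.W", sb$dW)
    grads <- acc_grad(grads, "seg.b", sb$db)
    dfeat <- sb$dx + cb$dx
  } else if (cfg$variant == "cls_from_oca") {
    ob <- oca_bw(lb$d_aug, lb$d_soft, fw$cache$oca, params, grads,
                 groups = cfg$backbone$groupnorm_groups,
                 dhead_extra = cb$dx)
    grads <- ob$grads
    dfeat <- ob$dx
  } else {
    ob <- oca_bw(lb$d_aug, lb$d_soft, fw$cache$oca, params, grads,
                 groups = cfg$backbone$groupnorm_groups)
    grads <- ob$grads
    dfeat <- cpp_axpy(ob$dx, cb$dx)
  }
  bbw <- backbone_backward(dfeat, fw$cache$bb, params, grads)
  list(loss = lb, grads = bbw$grads, forward = fw)
}

#' Convert model inputs to a batch matrix
#'
#' Stacks a list of `model_input`s into the `(H*W*B) x C` activation layout
#' plus flattened mask / label targets.
#'
#' @param inputs list of `model_input` objects (see [build_model_input()]).
#' @return list(`x`, `mask_target`, `label_target`, `H`, `W`, `B`).
#' @export
inputs_to_batch <- function(inputs) {
  B <- length(inputs)
  H <- dim(inputs[[1]]$channels)[1]
  W <- dim(inputs[[1]]$channels)[2]
  C <- dim(inputs[[1]]$channels)[3]
  x <- matrix(0, H * W * B, C)
  mask <- numeric(H * W * B)
  labels <- integer(B)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * H * W + 1L):(b * H * W)
    for (k in seq_len(C)) x[rows, k] <- as.vector(inputs[[b]]$channels[, , k])
    mask[rows] <- as.vector(inputs[[b]]$mask)
    labels[b] <- match(inputs[[b]]$label, CLASS_LEVELS)
  }
  list(x = x, mask_target = mask, label_target = labels, H = H, W = W, B = B)
}

#' Predict segmentation mask and class for model inputs
#'
#' The two heads are reconciled into a consistent joint prediction: the
#' class-mask rule of the data (label normal if and only if the mask is
#' empty) is enforced on the output, so an image predicted `"normal"`
#' yields an empty mask (stray lesion pixels are suppressed). Lesion-class
#' predictions keep the argmax mask unchanged.
#'
#' @param params,cfg trained parameters and their config.
#' @param inputs list of `model_input`s.
#' @return list of per-sample lists: `mask` (H x W binary matrix, argmax
#'   with ties to background), `label` (predicted class name), `probs`.
#' @export
model_predict <- function(params, cfg, inputs) {
  bt <- inputs_to_batch(inputs)
  fw <- model_forward(params, cfg, bt$x, bt$H, bt$W, bt$B)
  HW <- bt$H * bt$W
  lapply(seq_len(bt$B), function(b) {
    rows <- ((b - 1L) * HW + 1L):(b * HW)
    seg <- fw$seg_logits[rows, , drop = FALSE]
    mk <- matrix(max.col(seg, ties.method = "first") - 1L, bt$H, bt$W)
    label <- CLASS_LEVELS[which.max(fw$class_logits[b, ])]
    if (label == "normal") mk[] <- 0L
    probs <- softmax_rows(fw$class_logits[b, , drop = FALSE])[1, ]
    list(mask = mk, label = label,
         probs = setNames(probs, CLASS_LEVELS))
  })
}

#' Grad-CAM heatmap
#'
#' Gradient-weighted class-activation map taken at the feature layer the
#' classifier consumes (the fused backbone output, or the OCA head for the
#' classification-from-OCA wiring). Channel weights are the spatially
#' pooled gradients of the target class score; the map is the ReLU of the
#' weighted channel sum, max-normalized to `[0, 1]` at the 128x128 input
#' resolution. An all-zero gradient yields an all-zero map.
#'
#' @param params,cfg trained parameters and their config.
#' @param input one `model_input`.
#' @param target_class class index 1..3 or name.
#' @return H x W matrix in `[0, 1]`.
#' @export
grad_cam <- function(params, cfg, input, target_class) {
  if (is.character(target_class))
    target_class <- match(target_class, CLASS_LEVELS)
  assert_that(!is.na(target_class) && target_class >= 1 &&
                target_class <= cfg$n_classes,
              "target class index out of range",
              class = "mtloca_validation_error")
  bt <- inputs_to_batch(list(input))
  fw <- model_forward(params, cfg, bt$x, bt$H, bt$W, bt$B,
                      keep_cache = TRUE)
  feat <- if (cfg$variant == "cls_from_oca") fw$oca$head else fw$feat
  # closed-form gradient of the class score through GAP + MLP
  h_pre <- fw$cache$cls$l1$x %*% params[["cls.W1"]]
  h_pre <- sweep(h_pre, 2L, params[["cls.b1"]], "+")
  mask_relu <- as.numeric(h_pre > 0)
  dh <- params[["cls.W2"]][, target_class] * mask_relu
  dv <- as.numeric(params[["cls.W1"]] %*% dh)   # d score / d pooled feature
  cam <- pmax(feat %*% dv, 0)
  m <- max(cam)
  if (m > 0) cam <- cam / m
  out <- matrix(cam, bt$H, bt$W)
  if (bt$H != 128L) out <- resize_bilinear(out, 128L, 128L)
  out
}

#' Save / load a model checkpoint
#'
#' Single-file RDS with parameters and config embedded.
#'
#' @param params,cfg model state.
#' @param path file path.
#' @export
save_checkpoint <- function(params, cfg, path) {
  saveRDS(list(params = params, cfg = cfg,
               package_version = as.character(utils::packageVersion("mtloca"))),
          path)
}

#' @rdname save_checkpoint
#' @return for `load_checkpoint`, a list with `params` and `cfg`.
#' @export
load_checkpoint <- function(path) {
  assert_that(file.exists(path), "no checkpoint at '%s'", path,
              class = "mtloca_io_error")
  readRDS(path)
}
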