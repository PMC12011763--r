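# Orchestration: stratified k-fold cross-validation, Adam training with the
# combined loss, held-out evaluation, and the three-arm ablation harness.

#' Training configuration
#'
#' Full-scale defaults follow the published protocol: 400 epochs, batch 16,
#' Adam at 1e-3, 5 folds. The desk profile shrinks the budget so the whole
#' pipeline runs on one CPU: width 8 (fused features 32), 30 epochs,
#' batch 4 (more optimizer steps per epoch at small scale). No learning-rate
#' schedule, weight decay or early stopping is applied by default.
#'
#' @param epochs training epochs per fold.
#' @param batch_size minibatch size.
#' @param learning_rate Adam initial learning rate.
#' @param folds cross-validation folds.
#' @param seed master seed (weight init, fold split, data order,
#'   augmentation all derive from it).
#' @param variant ablation arm; see [model_config()].
#' @param scale `"full"` or `"desk"`.
#' @param base_channels backbone width; `NULL` picks 32 (full) / 8 (desk).
#' @param groupnorm_groups GroupNorm groups.
#' @param feat_channels fused pixel-representation width; the desk default
#'   (4x base) keeps the pooled classifier features rich at small widths.
#' @param augment apply training-time augmentation.
#' @param alpha soft-loss weight.
#' @param sigma Gaussian-derivative sigma for input building.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = NULL, batch_size = NULL,
                         learning_rate = 1e-3, folds = 5L, seed = 1L,
                         variant = "cls_from_backbone",
                         scale = c("full", "desk"), base_channels = NULL,
                         groupnorm_groups = NULL, feat_channels = NULL,
                         augment = TRUE, alpha = 0.4, sigma = 1.5) {
  scale <- match.arg(scale)
  variant <- match.arg(variant, MODEL_VARIANTS)
  desk <- scale == "desk"
  epochs <- epochs %||% (if (desk) 30L else 400L)
  batch_size <- batch_size %||% (if (desk) 4L else 16L)
  base_channels <- base_channels %||% (if (desk) 8L else 32L)
  groupnorm_groups <- groupnorm_groups %||% min(8L, base_channels)
  feat_channels <- as.integer(feat_channels %||%
                                (if (desk) 4L * base_channels
                                 else 2L * base_channels))
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, folds = as.integer(folds),
                 seed = as.integer(seed), variant = variant, scale = scale,
                 base_channels = as.integer(base_channels),
                 groupnorm_groups = as.integer(groupnorm_groups),
                 feat_channels = feat_channels,
                 augment = isTRUE(augment), alpha = alpha, sigma = sigma),
            class = "train_config")
}

#' Desk-scale profile
#'
#' Convenience wrapper for CPU-scale runs (width 8, 30 epochs, batch 4).
#' @param ... overrides passed to [train_config()].
#' @export
desk_profile <- function(...) train_config(scale = "desk", ...)

.as_model_config <- function(config) {
  model_config(variant = config$variant,
               base_channels = config$base_channels,
               groupnorm_groups = config$groupnorm_groups,
               feat_channels = config$feat_channels,
               alpha = config$alpha)
}

#' Stratified k-fold plan
#'
#' Ids are shuffled within each class (seeded) and dealt round-robin to
#' folds, so per-fold class counts differ from exact proportionality by at
#' most one sample.
#'
#' @param manifest data.frame with `id` and `label` columns.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return a `fold_plan`: list with `folds` (each `list(train =, val =)`
#'   id vectors), `assignment` data.frame, `k`, `seed`.
#' @export
make_folds <- function(manifest, k = 5L, seed = 1L) {
  assert_that(k >= 2, "k must be >= 2")
  tab <- table(manifest$label)
  bad <- names(tab)[tab < k]
  if (length(bad) > 0)
    stop_mtloca("class '%s' has %d samples, fewer than k = %d folds",
                bad[1], tab[[bad[1]]], k,
                class = "mtloca_stratification_error")
  fold_of <- integer(nrow(manifest))
  with_seed(derive_seed(seed, 101L), {
    for (cl in names(tab)) {
      idx <- which(manifest$label == cl)
      idx <- idx[sample.int(length(idx))]
      fold_of[idx] <- rep(seq_len(k), length.out = length(idx))
    }
  })
  folds <- lapply(seq_len(k), function(f) {
    list(train = manifest$id[fold_of != f], val = manifest$id[fold_of == f])
  })
  structure(list(folds = folds,
                 assignment = data.frame(id = manifest$id,
                                         label = manifest$label,
                                         fold = fold_of,
                                         stringsAsFactors = FALSE),
                 k = k, seed = seed),
            class = "fold_plan")
}

# Build (and cache) model inputs for every sample of a dataset.
.prepare_inputs <- function(ds, sigma) {
  cfg <- derivative_config(sigma = sigma)
  inputs <- lapply(ds$samples, build_model_input, cfg = cfg)
  names(inputs) <- vapply(inputs, `[[`, "", "id")
  inputs
}

#' Train the multi-task model with cross-validation
#'
#' For each requested fold: seeded weight initialization, Adam updates on
#' shuffled minibatches of the fold's training ids (with optional
#' augmentation re-drawn every epoch), and a per-epoch log of the loss
#' breakdown. Aborts with a component diagnostic if the loss goes
#' non-finite.
#'
#' @param ds a `phantom_dataset` (from [generate_dataset()] or
#'   [load_dataset()]).
#' @param config a [train_config()].
#' @param plan optional [make_folds()] plan (built from the config seed
#'   otherwise).
#' @param folds_to_run integer vector of fold indices (default: all).
#' @param out_dir optional directory for per-fold checkpoints
#'   (`fold<i>.rds`) and a JSONL training log.
#' @param verbose print per-epoch losses.
#' @return a `trained_model`: list with per-fold `params`, `log`
#'   (data.frame of epoch losses), the `plan`, `config` and `model_cfg`.
#' @export
train_model <- function(ds, config = desk_profile(), plan = NULL,
                        folds_to_run = NULL, out_dir = NULL,
                        verbose = FALSE) {
  plan <- plan %||% make_folds(ds$manifest, k = config$folds,
                               seed = config$seed)
  folds_to_run <- folds_to_run %||% seq_len(plan$k)
  inputs <- .prepare_inputs(ds, config$sigma)
  mcfg <- .as_model_config(config)
  acfg <- augment_config()
  log_path <- if (!is.null(out_dir)) file.path(out_dir, "train_log.jsonl")
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  fold_results <- list()
  logs <- list()
  # raise the GC high-water mark once: every batch allocates hundreds of
  # MB of transient activation matrices, and with a cold heap the collector
  # runs inside nearly every step (measured ~2x slowdown)
  gc_ballast <- lapply(seq_len(6L), function(i) numeric(4e7))
  rm(gc_ballast)
  for (f in folds_to_run) {
    train_ids <- plan$folds[[f]]$train
    params <- model_init(mcfg, seed = derive_seed(config$seed, f, 7L))
    st <- adam_init(params)
    for (ep in seq_len(config$epochs)) {
      ord <- with_seed(derive_seed(config$seed, f, ep, 11L),
                       sample(train_ids))
      comps <- c(l_soft = 0, l_aug = 0, l_c = 0, total = 0)
      nb <- 0
      for (start in seq(1, length(ord), by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, length(ord))]
        batch_inputs <- inputs[idx]
        if (config$augment) {
          batch_inputs <- lapply(seq_along(idx), function(j)
            augment(batch_inputs[[j]], acfg,
                    seed = derive_seed(config$seed, f, ep,
                                       match(idx[j], train_ids), 13L)))
        }
        bt <- inputs_to_batch(batch_inputs)
        res <- model_loss_and_grads(params, mcfg, bt$x, bt$H, bt$W, bt$B,
                                    bt$mask_target, bt$label_target)
        lb <- res$loss
        if (!is.finite(lb$total))
          stop_mtloca(paste0("non-finite loss at fold %d epoch %d: ",
                             "l_soft=%g l_aug=%g l_c=%g"),
                      f, ep, lb$l_soft, lb$l_aug, lb$l_c,
                      class = "mtloca_numeric_error")
        up <- adam_step(params, res$grads, st, lr = config$learning_rate)
        params <- up$params
        st <- up$state
        comps <- comps + c(lb$l_soft, lb$l_aug, lb$l_c, lb$total)
        nb <- nb + 1
      }
      comps <- comps / nb
      logs[[length(logs) + 1]] <- data.frame(fold = f, epoch = ep,
                                             l_soft = comps[1],
                                             l_aug = comps[2],
                                             l_c = comps[3],
                                             total = comps[4],
                                             row.names = NULL)
      if (verbose)
        message(sprintf("fold %d epoch %3d  total %.4f (soft %.4f aug %.4f cls %.4f)",
                        f, ep, comps[4], comps[1], comps[2], comps[3]))
      if (!is.null(out_dir))
        cat(jsonlite::toJSON(c(list(fold = f, epoch = ep),
                               as.list(comps)), auto_unbox = TRUE),
            "\n", sep = "", file = log_path, append = TRUE)
    }
    fold_results[[as.character(f)]] <- params
    if (!is.null(out_dir))
      save_checkpoint(params, mcfg,
                      file.path(out_dir, sprintf("fold%d.rds", f)))
  }
  structure(list(params = fold_results,
                 log = do.call(rbind, logs),
                 plan = plan, config = config, model_cfg = mcfg,
                 inputs = inputs),
            class = "trained_model")
}

#' Evaluate a trained model on its held-out folds
#'
#' Validation-fold-only evaluation: per-image Dice/IoU on the predicted
#' masks, the 3x3 confusion matrix of predicted classes, per fold and
#' pooled (pooled confusion = sum of fold confusions; pooled Dice/IoU =
#' mean over all evaluated images).
#'
#' @param trained a `trained_model` from [train_model()].
#' @param ds the dataset it was trained on.
#' @return list with `per_fold` (named list of `metrics_report`) and
#'   `pooled` (one `metrics_report`).
#' @export
evaluate_model <- function(trained, ds) {
  inputs <- trained$inputs %||% .prepare_inputs(ds, trained$config$sigma)
  all_dice <- c(); all_iou <- c()
  pooled_cm <- matrix(0L, 3, 3, dimnames = list(CLASS_LEVELS, CLASS_LEVELS))
  per_fold <- list()
  for (f in names(trained$params)) {
    val_ids <- trained$plan$folds[[as.integer(f)]]$val
    params <- trained$params[[f]]
    dice <- c(); iou <- c()
    cm <- matrix(0L, 3, 3, dimnames = list(CLASS_LEVELS, CLASS_LEVELS))
    bs <- max(1L, trained$config$batch_size)
    for (start in seq(1, length(val_ids), by = bs)) {
      ids <- val_ids[start:min(start + bs - 1, length(val_ids))]
      preds <- model_predict(params, trained$model_cfg, inputs[ids])
      for (j in seq_along(ids)) {
        truth <- inputs[[ids[j]]]$mask
        di <- dice_iou(preds[[j]]$mask, truth)
        dice <- c(dice, di[["dice"]])
        iou <- c(iou, di[["iou"]])
        cm[inputs[[ids[j]]]$label, preds[[j]]$label] <-
          cm[inputs[[ids[j]]]$label, preds[[j]]$label] + 1L
      }
    }
    per_fold[[f]] <- metrics_report(dice, iou, cm)
    all_dice <- c(all_dice, dice)
    all_iou <- c(all_iou, iou)
    pooled_cm <- pooled_cm + cm
  }
  list(per_fold = per_fold,
       pooled = metrics_report(all_dice, all_iou, pooled_cm))
}

#' Run the three-arm ablation
#'
#' Trains and evaluates the three wirings (no OCA / classification from OCA
#' / classification from backbone) with identical data, seed and training
#' budget, and tabulates Dice and accuracy per arm.
#'
#' @param ds dataset.
#' @param base_config a [train_config()]; the `variant` field is overridden
#'   per arm.
#' @param folds_to_run fold indices (default fold 1 only, for speed).
#' @return list with `reports` (per variant) and `table` (data.frame with
#'   `variant`, `dice`, `acc`).
#' @export
run_ablation <- function(ds, base_config = desk_profile(),
                         folds_to_run = 1L) {
  plan <- make_folds(ds$manifest, k = base_config$folds,
                     seed = base_config$seed)
  reports <- list()
  for (v in MODEL_VARIANTS) {
    cfg <- base_config
    cfg$variant <- v
    tr <- train_model(ds, cfg, plan = plan, folds_to_run = folds_to_run)
    reports[[v]] <- evaluate_model(tr, ds)$pooled
  }
  tab <- data.frame(variant = MODEL_VARIANTS,
                    dice = vapply(reports, `[[`, 0, "dice"),
                    acc = vapply(reports, `[[`, 0, "acc"),
                    row.names = NULL)
  list(reports = reports, table = tab)
}
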