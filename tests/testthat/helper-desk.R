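# Desk-scale training runs shared between acceptance criteria. Results are
# memoised per (seed, variant) within a test session so the ablation and
# the training-surrogate criteria can share the proposed-variant runs
# instead of retraining them.

.desk_cache <- new.env(parent = emptyenv())

# The stated desk-scale world: 60 phantoms, 20 per class, defaults
# otherwise; one held-out fold of the 5-fold plan per run.
desk_dataset <- function(seed) {
  key <- paste0("ds", seed)
  if (is.null(.desk_cache[[key]])) {
    spec <- phantom_spec(class_mix = c(normal = 1, benign = 1,
                                       malignant = 1) / 3,
                         seed = derive_seed(seed, 17L))
    .desk_cache[[key]] <- generate_dataset(spec, 60L)
  }
  .desk_cache[[key]]
}

desk_run <- function(seed, variant = "cls_from_backbone") {
  key <- paste0(variant, seed)
  if (is.null(.desk_cache[[key]])) {
    ds <- desk_dataset(seed)
    cfg <- desk_profile(seed = seed, variant = variant)
    tr <- train_model(ds, cfg, folds_to_run = 1L)
    ev <- evaluate_model(tr, ds)
    .desk_cache[[key]] <- list(dice = ev$pooled$dice / 100,
                               acc = ev$pooled$acc / 100,
                               report = ev$pooled)
  }
  .desk_cache[[key]]
}
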