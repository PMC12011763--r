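# Metric suite: Dice / IoU for masks, per-class precision / sensitivity /
# specificity / F1 from a 3x3 confusion matrix, accuracy, and report
# serialization.

#' Dice coefficient and IoU of two binary masks
#'
#' `dice = 2|P & T| / (|P| + |T|)`, `iou = |P & T| / |P | T|`. When both
#' masks are empty (a normal image predicted normal) both scores are 1 by
#' convention; when exactly one is empty both are 0.
#'
#' @param pred,truth binary matrices of identical shape.
#' @return named numeric vector `c(dice = , iou = )`.
#' @export
dice_iou <- function(pred, truth) {
  assert_that(identical(dim(pred), dim(truth)),
              "mask shapes differ: [%s] vs [%s]",
              paste(dim(pred), collapse = ","),
              paste(dim(truth), collapse = ","),
              class = "mtloca_shape_error")
  assert_that(is_binary(pred) && is_binary(truth), "masks must be binary")
  p <- sum(pred); t <- sum(truth); i <- sum(pred * truth)
  if (p + t == 0) return(c(dice = 1, iou = 1))
  u <- p + t - i
  c(dice = 2 * i / (p + t), iou = i / u)
}

#' F1 score from precision and sensitivity
#'
#' Harmonic mean `2 P R / (P + R)`; 0 when both are 0.
#'
#' @param precision,sensitivity rates in `[0, 1]`.
#' @return the F1 score.
#' @export
f1_score <- function(precision, sensitivity) {
  ifelse(precision + sensitivity == 0, 0,
         2 * precision * sensitivity / (precision + sensitivity))
}

#' Per-class classification metrics from a confusion matrix
#'
#' One-vs-rest precision, sensitivity (recall), specificity and F1 per
#' class, plus overall accuracy. Rows of `confusion` are truth, columns are
#' predictions, in the order (normal, benign, malignant).
#'
#' @param confusion K x K nonnegative integer matrix.
#' @return list(`per_class` data.frame, `accuracy`).
#' @export
classification_metrics <- function(confusion) {
  assert_that(is.matrix(confusion) && nrow(confusion) == ncol(confusion),
              "confusion must be square", class = "mtloca_shape_error")
  assert_that(all(confusion >= 0) && all(confusion == round(confusion)),
              "confusion entries must be nonnegative integers")
  total <- sum(confusion)
  assert_that(total > 0, "all-zero confusion matrix: metrics undefined",
              class = "mtloca_undefined_error")
  k <- nrow(confusion)
  labs <- rownames(confusion) %||% CLASS_LEVELS[seq_len(k)]
  res <- data.frame(label = labs, precision = NA_real_,
                    sensitivity = NA_real_, specificity = NA_real_,
                    f1 = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    tp <- confusion[i, i]
    fp <- sum(confusion[-i, i])
    fn <- sum(confusion[i, -i])
    tn <- total - tp - fp - fn
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    res$precision[i] <- prec
    res$sensitivity[i] <- sens
    res$specificity[i] <- spec
    res$f1[i] <- if (!is.na(prec) && !is.na(sens)) f1_score(prec, sens)
                 else NA_real_
  }
  list(per_class = res, accuracy = sum(diag(confusion)) / total)
}

#' Build a metrics report
#'
#' @param dice,iou per-image Dice/IoU values (fractions in `[0, 1]`).
#' @param confusion 3x3 confusion matrix (rows truth, cols predicted).
#' @return a `metrics_report`: `dice` and `iou` as percent means, `acc` as
#'   percent, `per_class` rates, `confusion`, `n`.
#' @export
metrics_report <- function(dice, iou, confusion) {
  cm <- classification_metrics(confusion)
  structure(list(dice = 100 * mean(dice), iou = 100 * mean(iou),
                 acc = 100 * cm$accuracy, per_class = cm$per_class,
                 confusion = confusion, n = sum(confusion)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Dice %.2f%%  IoU %.2f%%  Acc %.2f%%  (n = %d)\n",
              x$dice, x$iou, x$acc, x$n))
  df <- x$per_class
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-9s P %.3f  Sens %.3f  Spec %.3f  F1 %.3f\n",
                df$label[i], df$precision[i], df$sensitivity[i],
                df$specificity[i], df$f1[i]))
  cat("confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' Serialize a metrics report
#'
#' @param report a `metrics_report`.
#' @param json_path,csv_path output paths (either may be NULL).
#' @export
write_metrics_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(dice = report$dice, iou = report$iou, acc = report$acc,
           per_class = report$per_class,
           confusion = unclass(report$confusion), n = report$n),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) write.csv(report$per_class, csv_path,
                                    row.names = FALSE)
  invisible(report)
}
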