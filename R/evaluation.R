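# Per-seed-image evaluation: ROC curves, AUC and confusion counts against a
# reference label table. AUC is the probability the classifier ranks a random
# germinated image above a random un-germinated one; the trapezoidal curve
# area equals that rank statistic exactly (ties get half credit).

#' ROC curve and AUC
#'
#' Thresholds are the distinct score values, predicting germinated when
#' `score >= threshold`, swept from high to low; the curve starts at (0, 0)
#' (threshold `Inf`) and ends at (1, 1). Tied scores produce diagonal
#' segments, so the trapezoidal area equals the Mann-Whitney estimator
#' `(concordant + 0.5 * tied) / (n_pos * n_neg)` exactly.
#'
#' @param scores numeric vector (higher = more germinated-like, e.g. the k-NN
#'   germinated-vote fraction).
#' @param labels binary reference labels aligned with `scores`.
#' @return A `roc_result` with `points` (`threshold`, `fpr`, `tpr` ordered by
#'   descending threshold), `auc`, `n_positive`, `n_negative`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  if (any(!is.finite(scores))) stop2("scores must be finite")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop2("AUC undefined: both classes must be present")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # collapse tied scores into single operating points
  last_of_run <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(l)[last_of_run]
  fp <- cumsum(1L - l)[last_of_run]
  pts <- data.frame(
    threshold = c(Inf, s[last_of_run]),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  structure(
    list(points = pts, auc = auc, n_positive = n_pos, n_negative = n_neg),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f  (%d germinated / %d un-germinated)\n",
              x$auc, x$n_positive, x$n_negative))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  graphics::legend("bottomright", sprintf("AUC = %.3f", x$auc), bty = "n")
  invisible(x)
}

#' Confusion counts against a reference
#'
#' Positive class is germinated: a false positive is predicted germinated
#' while the reference says un-germinated. `fp_frac` and `fn_frac` are
#' fractions of all images (the style `558/8394 (0.066)`); `fpr`/`fnr` are
#' the per-class rates.
#'
#' @param predicted,reference binary label vectors of equal length.
#' @return A `confusion_counts` with `tp`, `fp`, `tn`, `fn`, `n`, `fp_frac`,
#'   `fn_frac`, `fpr`, `fnr`, `accuracy`.
#' @export
confusion <- function(predicted, reference) {
  predicted <- as.integer(predicted)
  reference <- as.integer(reference)
  if (length(predicted) != length(reference)) stop2("length mismatch")
  stopifnot(all(predicted %in% c(0L, 1L)), all(reference %in% c(0L, 1L)))
  tp <- sum(predicted == 1L & reference == 1L)
  fp <- sum(predicted == 1L & reference == 0L)
  tn <- sum(predicted == 0L & reference == 0L)
  fn <- sum(predicted == 0L & reference == 1L)
  n <- length(predicted)
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn, n = n,
         fp_frac = fp / n, fn_frac = fn / n,
         fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
         fnr = if (fn + tp > 0) fn / (fn + tp) else NA_real_,
         accuracy = (tp + tn) / n),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> FP %d/%d (%.3f), FN %d/%d (%.3f), accuracy %.3f\n",
              x$fp, x$n, x$fp_frac, x$fn, x$n, x$fn_frac, x$accuracy))
  invisible(x)
}

#' Repeated split / classify / evaluate runs
#'
#' For each repeat, splits the *seeds* (all frames of a seed fall on the same
#' side) with a fresh seed derived from `base_seed`, fits the preprocessing
#' (min-max normalization, optionally PCA) on the training rows only, fits
#' the k-NN model and scores the test rows, then computes the ROC/AUC and the
#' confusion at the majority-vote decision (`score >= ceiling(k/2)/k`).
#'
#' @param matrix a `feature_matrix` at stage `"raw"` (preprocessing is fitted
#'   per split) or `"normalized"`/`"pca"` with `preprocess = "none"`.
#' @param table a [label_table()] of reference labels covering the keys.
#' @param train_fraction fraction of seeds used for training.
#' @param k neighbours.
#' @param n_repeats number of random splits.
#' @param base_seed integer; repeat `i` uses seed `base_seed + i - 1`.
#' @param preprocess `"normalize"`, `"pca"` or `"none"`.
#' @param n_components PCA width when `preprocess = "pca"`.
#' @return An `evaluation_summary`: per-repeat `data.frame` (`auc`,
#'   `fp_frac`, `fn_frac`, `n_test`), means and standard deviations, and the
#'   last repeat's `roc_result`.
#' @export
evaluate_run <- function(matrix, table, train_fraction = 0.5, k = 7L,
                         n_repeats = 1L, base_seed = 1234L,
                         preprocess = c("normalize", "pca", "none"),
                         n_components = 21L) {
  preprocess <- match.arg(preprocess)
  stopifnot(inherits(matrix, "feature_matrix"), n_repeats >= 1L)
  table <- label_table(table)
  pos <- match(image_key(matrix$keys$seed_id, matrix$keys$time_index),
               image_key(table$seed_id, table$time_index))
  if (anyNA(pos)) stop2("label table does not cover all matrix keys")
  labels <- table$label[pos]
  seeds <- unique(matrix$keys$seed_id)
  per <- vector("list", n_repeats)
  roc <- NULL
  for (i in seq_len(n_repeats)) {
    sp <- split_dataset(seeds, train_fraction, base_seed + i - 1L)
    in_train <- matrix$keys$seed_id %in% seeds[sp$train]
    tr_x <- matrix$values[in_train, , drop = FALSE]
    te_x <- matrix$values[!in_train, , drop = FALSE]
    if (preprocess != "none") {
      tr_fm <- feature_matrix(tr_x, matrix$keys[in_train, , drop = FALSE], "raw")
      te_fm <- feature_matrix(te_x, matrix$keys[!in_train, , drop = FALSE], "raw")
      norm <- normalize_features(tr_fm)
      tr_x <- norm$matrix$values
      te_x <- normalize_features(te_fm, norm$params)$matrix$values
      if (preprocess == "pca") {
        pca <- pca_fit(norm$matrix, n_components)
        tr_x <- pca_project(norm$matrix, pca)$values
        te_x <- pca_project(
          feature_matrix(te_x, matrix$keys[!in_train, , drop = FALSE],
                         "normalized"),
          pca
        )$values
      }
    }
    model <- knn_model(tr_x, labels[in_train], k, rng_seed = base_seed + i - 1L)
    pred <- predict(model, te_x, keys = matrix$keys[!in_train, , drop = FALSE])
    ref <- labels[!in_train]
    roc <- roc_curve(pred$score, ref)
    cm <- confusion(as.integer(pred$score >= ceiling(k / 2) / k), ref)
    per[[i]] <- data.frame(auc = roc$auc, fp_frac = cm$fp_frac,
                           fn_frac = cm$fn_frac, n_test = length(ref))
  }
  per <- do.call(rbind, per)
  structure(
    list(
      per_repeat = per,
      mean = colMeans(per[c("auc", "fp_frac", "fn_frac")]),
      sd = apply(per[c("auc", "fp_frac", "fn_frac")], 2, stats::sd),
      roc = roc, k = k, n_repeats = n_repeats, base_seed = base_seed,
      preprocess = preprocess
    ),
    class = "evaluation_summary"
  )
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(sprintf(
    "<evaluation_summary> %d repeat(s), k=%d, preprocess=%s\n  mean AUC %.4f  FP %.4f  FN %.4f\n",
    x$n_repeats, x$k, x$preprocess, x$mean["auc"], x$mean["fp_frac"],
    x$mean["fn_frac"]
  ))
  invisible(x)
}
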