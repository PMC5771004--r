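# Euclidean k-nearest-neighbour majority vote with a vote certainty.
#
# The classifier places every image in the n-dimensional feature space and
# classifies a query by majority vote among its k closest training images.
# With odd k the vote is never tied; with even k a tied vote is broken at
# random from a reproducible stream keyed by the query's image key. The
# certainty is max(m, k - m) / k, where m of the k neighbours are labelled
# germinated: 0.5 means an even split, 1 unanimity.

#' Fit (store) a k-NN germination classifier
#'
#' k-NN has no training phase beyond retaining the labelled feature matrix;
#' this constructor validates and freezes it together with `k` and the seed
#' of the tie-breaking stream.
#'
#' @param x numeric `n_train x d` matrix (normalized features or PC scores).
#' @param y binary labels (0 = un-germinated, 1 = germinated), length
#'   `n_train`.
#' @param k number of neighbours (default 7).
#' @param rng_seed integer seed for even-`k` vote ties.
#' @return An object of class `knn_model`.
#' @export
knn_model <- function(x, y, k = 7L, rng_seed = 1234L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (anyNA(x) || anyNA(y)) stop2("missing values in training data")
  if (nrow(x) != length(y)) stop2("labels must align with training rows")
  if (!all(y %in% c(0L, 1L))) stop2("labels must be 0 or 1")
  k <- as.integer(k)
  if (k < 1L || k > nrow(x)) stop2("k must satisfy 1 <= k <= n_train")
  structure(
    list(x = x, y = y, k = k, rng_seed = as.integer(rng_seed)),
    class = "knn_model"
  )
}

#' @export
print.knn_model <- function(x, ...) {
  cat(sprintf("<knn_model> k=%d, %d training images in %d dimensions (%d germinated)\n",
              x$k, nrow(x$x), ncol(x$x), sum(x$y)))
  invisible(x)
}

# squared Euclidean cross-distances, queries x training
cross_dist2 <- function(q, tr) {
  d2 <- outer(rowSums(q^2), rep(1, nrow(tr))) +
    outer(rep(1, nrow(q)), rowSums(tr^2)) - 2 * q %*% t(tr)
  pmax(d2, 0)
}

# core batch prediction; keys drive the tie-break substreams
knn_predict_core <- function(model, q, keys) {
  k <- model$k
  n <- nrow(q)
  label <- integer(n)
  score <- numeric(n)
  neighbours <- vector("list", n)
  chunk <- 512L
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- cross_dist2(q[idx, , drop = FALSE], model$x)
    for (j in seq_along(idx)) {
      # order() is stable: distance ties at the k-th rank resolve to the
      # lowest training-row index
      nb <- order(d2[j, ])[seq_len(k)]
      m <- sum(model$y[nb])
      i <- idx[j]
      neighbours[[i]] <- nb
      score[i] <- m / k
      label[i] <- if (2L * m > k) {
        1L
      } else if (2L * m < k) {
        0L
      } else {
        with_rng(stream_seed(model$rng_seed, keys[i]),
                 sample(c(0L, 1L), 1L))
      }
    }
  }
  out <- data.frame(label = label, score = score,
                    certainty = pmax(score, 1 - score))
  out$neighbours <- neighbours
  out
}

#' Predict germination for new images
#'
#' For each query row the `k` training images at smallest Euclidean distance
#' vote; `score` is the fraction of the `k` neighbours labelled germinated,
#' `certainty = max(score, 1 - score)`. Distance ties at the k-th rank are
#' resolved deterministically towards the lowest training-row index. For even
#' `k`, a tied vote is broken at random from a stream keyed by the query's
#' image key, so batch results do not depend on row order.
#'
#' @param object a [knn_model()].
#' @param newdata numeric matrix (or single vector) of queries, `d` columns.
#' @param keys optional `data.frame` with `seed_id`, `time_index` (or a
#'   character vector) identifying each query; defaults to row numbers.
#' @param ... unused.
#' @return A `data.frame` with columns `label`, `score`, `certainty` and a
#'   list column `neighbours` of training-row indices.
#' @export
predict.knn_model <- function(object, newdata, keys = NULL, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$x)) {
    stop2("query dimension ", ncol(newdata), " does not match training dimension ",
          ncol(object$x))
  }
  if (is.null(keys)) {
    keys <- as.character(seq_len(nrow(newdata)))
  } else if (is.data.frame(keys)) {
    keys <- image_key(keys$seed_id, keys$time_index)
  } else {
    keys <- as.character(keys)
  }
  if (length(keys) != nrow(newdata)) stop2("one key per query row required")
  knn_predict_core(object, newdata, keys)
}

#' Score a labelled set against itself
#'
#' Runs the classifier over the labelled images themselves, either
#' leave-one-out (`mode = "loo"`, each image scored against all others) or
#' against a held-out training part (`mode = "holdout"` with a
#' [split_dataset()] spec). This is the scoring step of the label-amendment
#' loop: low-certainty images are the candidates for human re-checking.
#'
#' @param x numeric `n x d` feature matrix.
#' @param labels binary labels aligned with rows.
#' @param k number of neighbours.
#' @param mode `"loo"` or `"holdout"`.
#' @param split a `split_spec` (required for `"holdout"`): the model is fitted
#'   on `split$train` rows and scores the `split$test` rows.
#' @param keys optional image keys as in [predict.knn_model()].
#' @param rng_seed seed for even-`k` vote ties.
#' @return A `data.frame` as from [predict.knn_model()], plus a `row` column
#'   mapping each prediction back to its row in `x` (for `"holdout"`, only
#'   test rows appear).
#' @export
self_score <- function(x, labels, k = 7L, mode = c("loo", "holdout"),
                       split = NULL, keys = NULL, rng_seed = 1234L) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(keys)) {
    keys <- as.character(seq_len(n))
  } else if (is.data.frame(keys)) {
    keys <- image_key(keys$seed_id, keys$time_index)
  }
  if (mode == "holdout") {
    stopifnot(inherits(split, "split_spec"), split$n == n)
    model <- knn_model(x[split$train, , drop = FALSE], labels[split$train],
                       k, rng_seed)
    out <- knn_predict_core(model, x[split$test, , drop = FALSE],
                            keys[split$test])
    out$row <- split$test
    return(out)
  }
  if (n < k + 1L) stop2("leave-one-out needs n >= k + 1")
  labels <- as.integer(labels)
  out_rows <- vector("list", n)
  chunk <- 512L
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- cross_dist2(x[idx, , drop = FALSE], x)
    for (j in seq_along(idx)) {
      i <- idx[j]
      d <- d2[j, ]
      d[i] <- Inf                       # exclude the image itself
      nb <- order(d)[seq_len(k)]
      m <- sum(labels[nb])
      lab <- if (2L * m > k) {
        1L
      } else if (2L * m < k) {
        0L
      } else {
        with_rng(stream_seed(rng_seed, keys[i]), sample(c(0L, 1L), 1L))
      }
      out_rows[[i]] <- list(label = lab, score = m / k, nb = nb)
    }
  }
  out <- data.frame(
    label = vapply(out_rows, `[[`, integer(1), "label"),
    score = vapply(out_rows, `[[`, numeric(1), "score")
  )
  out$certainty <- pmax(out$score, 1 - out$score)
  out$neighbours <- lapply(out_rows, `[[`, "nb")
  out$row <- seq_len(n)
  out
}
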