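# Uncertainty-driven label curation: the classifier's least-certain images
# are surfaced for human re-checking, iterating until no label changes. The
# resulting reference set is the "amended human assessment".

#' Queue the least-certain images for review
#'
#' @param predictions `data.frame` with columns `seed_id`, `time_index`,
#'   `label`, `certainty` (e.g. a [self_score()] result joined to its keys).
#' @param batch_size maximum number of images to queue.
#' @return A `review_queue`: the `batch_size` lowest-certainty rows, sorted
#'   ascending by certainty with ties ordered by image key.
#' @export
build_review_queue <- function(predictions, batch_size) {
  stopifnot(batch_size >= 1)
  need <- c("seed_id", "time_index", "label", "certainty")
  if (nrow(predictions) == 0L) stop2("no predictions to review")
  stopifnot(all(need %in% names(predictions)))
  key <- image_key(predictions$seed_id, predictions$time_index)
  ord <- order(predictions$certainty, key)
  out <- predictions[ord[seq_len(min(batch_size, nrow(predictions)))],
                     need, drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("review_queue", "data.frame")
  out
}

#' Amend labels until the classifier and reviewer agree
#'
#' Repeats: score every image against the rest ([self_score()]), queue the
#' `batch_size` least-certain images, ask the `reviewer` for each, apply any
#' changed labels (provenance `"amended"`), and stop when an iteration
#' changes no reviewed labels (or after `max_iter` iterations, in which case
#' the log carries a warning status).
#'
#' Germination is a monotone state, so an amendment is applied as a statement
#' about the whole sequence: confirming "germinated at t" marks every later
#' frame of that seed germinated (forward propagation), while "not yet
#' germinated at t" clears every earlier frame too. A plain running-maximum
#' re-propagation cannot lower labels, so without the backward rule a
#' downward correction would be immediately undone by an uncorrected earlier
#' error and the loop would oscillate. Against a monotone ground truth these
#' sequence-consistent updates can only move labels toward the truth.
#' Unreviewed seeds keep their stored labels: a sequence-scored table is
#' monotone by construction, so a running-maximum pass over it is a no-op,
#' while over a table carrying label errors it would only manufacture new
#' ones from erroneous early germination calls.
#'
#' @param matrix a `feature_matrix` (stage normalized or pca).
#' @param table a [label_table()] covering the matrix keys.
#' @param k neighbours for the scoring classifier.
#' @param batch_size images reviewed per iteration; default 1% of the images,
#'   minimum 10.
#' @param reviewer function `(key_df, current_label) -> label`; `key_df` is a
#'   one-row data.frame with `seed_id`, `time_index`. Must be deterministic
#'   within one run. Tests use a ground-truth oracle; interactive use can
#'   prompt a human with the tile path.
#' @param max_iter iteration cap.
#' @param mode scoring mode passed to [self_score()].
#' @param rng_seed seed for even-`k` ties in scoring.
#' @return List with the final `table` and an `amendment_log`: per-iteration
#'   counts, every reviewed change with old/new labels (plus the number of
#'   other frames each change dragged along, `n_induced`), and a `status` of
#'   `"converged"` or `"max_iter"`.
#' @export
amend_until_stable <- function(matrix, table, k = 7L,
                               batch_size = NULL, reviewer,
                               max_iter = 20L, mode = "loo",
                               rng_seed = 1234L) {
  stopifnot(inherits(matrix, "feature_matrix"), is.function(reviewer))
  table <- label_table(table)
  mkey <- image_key(matrix$keys$seed_id, matrix$keys$time_index)
  tkey <- image_key(table$seed_id, table$time_index)
  pos <- match(mkey, tkey)
  if (anyNA(pos)) stop2("label table does not cover all matrix keys")
  n <- nrow(matrix$values)
  if (is.null(batch_size)) batch_size <- max(10L, ceiling(0.01 * n))

  # sequence-consistent amendment: germinated at t => germinated at every
  # t' >= t; not germinated at t => not germinated at any t' <= t
  apply_amendment <- function(table, sid, t, new_lab) {
    rows <- if (new_lab == 1L) {
      which(table$seed_id == sid & table$time_index >= t)
    } else {
      which(table$seed_id == sid & table$time_index <= t)
    }
    touched <- rows[table$label[rows] != new_lab]
    table$label[touched] <- new_lab
    table$provenance[touched] <- "amended"
    list(table = table, n_induced = length(touched) - 1L)
  }

  iterations <- list()
  status <- "max_iter"
  for (it in seq_len(max_iter)) {
    labs <- table$label[pos]
    preds <- self_score(matrix$values, labs, k = k, mode = mode,
                        keys = matrix$keys, rng_seed = rng_seed)
    preds <- data.frame(matrix$keys[preds$row, , drop = FALSE],
                        label = labs[preds$row],
                        certainty = preds$certainty)
    queue <- build_review_queue(preds, batch_size)
    changes <- list()
    for (qi in seq_len(nrow(queue))) {
      row <- queue[qi, ]
      at <- which(tkey == image_key(row$seed_id, row$time_index))
      current <- table$label[at]     # may have been dragged by a prior review
      new_lab <- as.integer(reviewer(row[c("seed_id", "time_index")], current))
      if (!new_lab %in% c(0L, 1L)) stop2("reviewer must return 0 or 1")
      if (new_lab != current) {
        upd <- apply_amendment(table, row$seed_id, row$time_index, new_lab)
        table <- upd$table
        changes[[length(changes) + 1L]] <- data.frame(
          seed_id = row$seed_id, time_index = row$time_index,
          old = current, new = new_lab, n_induced = upd$n_induced
        )
      }
    }
    iterations[[it]] <- list(
      n_reviewed = nrow(queue),
      n_changed = length(changes),
      changes = if (length(changes)) do.call(rbind, changes) else NULL
    )
    if (length(changes) == 0L) {
      status <- "converged"
      break
    }
  }
  log <- structure(
    list(iterations = iterations, status = status,
         total_changed = sum(vapply(iterations, `[[`, integer(1), "n_changed"))),
    class = "amendment_log"
  )
  list(table = table, log = log)
}

#' @export
print.amendment_log <- function(x, ...) {
  cat(sprintf("<amendment_log> %d iteration(s), %d label(s) changed, status=%s\n",
              length(x$iterations), x$total_changed, x$status))
  invisible(x)
}
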