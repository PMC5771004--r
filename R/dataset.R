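# Labelled feature matrices: assembly, min-max normalization, PCA reduction,
# time-series label propagation, time-zero exclusion and random splits.

#' Feature matrix with image identity and processing stage
#'
#' @param values numeric `n_images x n_features` matrix, no missing values.
#' @param keys `data.frame` with columns `seed_id`, `time_index`, one row per
#'   image, `(seed_id, time_index)` unique.
#' @param stage `"raw"`, `"normalized"` or `"pca"`.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, keys, stage = c("raw", "normalized", "pca")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  if (anyNA(values)) stop2("feature matrix contains missing values")
  stopifnot(
    is.data.frame(keys),
    all(c("seed_id", "time_index") %in% names(keys)),
    nrow(keys) == nrow(values)
  )
  k <- image_key(keys$seed_id, keys$time_index)
  if (anyDuplicated(k)) stop2("duplicate (seed_id, time_index) keys")
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  }
  structure(
    list(values = values,
         keys = data.frame(seed_id = as.character(keys$seed_id),
                           time_index = as.integer(keys$time_index)),
         stage = stage),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d images x %d features, stage=%s\n",
              nrow(x$values), ncol(x$values), x$stage))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Assemble a feature matrix from an extractor table
#'
#' @param table `data.frame` as returned by [extract_features_dir()] or
#'   [dataset_features()]: identity columns `seed_id`, `time_index` (and
#'   optionally `dish_id`) followed by feature columns.
#' @return A `feature_matrix` at stage `"raw"`.
#' @export
as_feature_matrix <- function(table) {
  id_cols <- intersect(c("seed_id", "time_index", "dish_id"), names(table))
  feat <- setdiff(names(table), id_cols)
  feature_matrix(as.matrix(table[feat]), table[c("seed_id", "time_index")], "raw")
}

#' Min-max normalise features to [0, 1]
#'
#' With `params = "fit"` the per-feature minimum and maximum are learned from
#' `matrix` itself (the training data) and each feature is mapped by
#' `(x - min) / (max - min)`; constant features map to 0. With learned
#' `params` supplied (test data), transformed values are clipped to `[0, 1]`.
#'
#' @param matrix a `feature_matrix` at stage `"raw"`.
#' @param params `"fit"` or a `normalization_params` object.
#' @return List with elements `matrix` (stage `"normalized"`) and `params`.
#' @export
normalize_features <- function(matrix, params = "fit") {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (matrix$stage != "raw") stop2("normalize_features() expects stage \"raw\"")
  x <- matrix$values
  fitting <- identical(params, "fit")
  if (fitting) {
    params <- structure(
      list(min = apply(x, 2, min), max = apply(x, 2, max),
           feature_names = colnames(x)),
      class = "normalization_params"
    )
  } else {
    stopifnot(inherits(params, "normalization_params"))
    if (!identical(params$feature_names, colnames(x))) {
      stop2("feature names do not match the normalization params")
    }
  }
  rng <- params$max - params$min
  scale <- ifelse(rng > 0, rng, 1)
  out <- sweep(sweep(x, 2, params$min), 2, scale, "/")
  out[, rng == 0] <- 0
  if (!fitting) out <- pmin(pmax(out, 0), 1)
  list(matrix = feature_matrix(out, matrix$keys, "normalized"), params = params)
}

#' Invert a min-max normalization (non-constant features)
#'
#' @param matrix a `feature_matrix` at stage `"normalized"`.
#' @param params the `normalization_params` used to normalise it.
#' @return A `feature_matrix` at stage `"raw"`.
#' @export
denormalize_features <- function(matrix, params) {
  stopifnot(inherits(matrix, "feature_matrix"),
            inherits(params, "normalization_params"))
  rng <- params$max - params$min
  out <- sweep(sweep(matrix$values, 2, ifelse(rng > 0, rng, 0), "*"), 2,
               params$min, "+")
  feature_matrix(out, matrix$keys, "raw")
}

#' Fit a principal component analysis
#'
#' Components are eigenvectors of the covariance of the mean-centred data
#' (features are already equalised in scale by min-max normalization, so the
#' covariance rather than the correlation matrix is decomposed), ordered by
#' decreasing eigenvalue. The sign of each loading vector is fixed so its
#' largest-magnitude entry is positive.
#'
#' @param matrix a `feature_matrix` at stage `"normalized"`.
#' @param n_components number of components to retain (default 21).
#' @return A `pca_model` with `mean`, `loadings` (features x components),
#'   `var_fraction` (per retained component, of the total variance),
#'   `eigenvalues`, `n_components`, `feature_names`.
#' @export
pca_fit <- function(matrix, n_components = 21L) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (matrix$stage != "normalized") stop2("pca_fit() expects stage \"normalized\"")
  x <- matrix$values
  if (n_components > min(dim(x))) {
    stop2("n_components exceeds min(n_images, n_features)")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  keep <- seq_len(n_components)
  load <- pc$rotation[, keep, drop = FALSE]
  flip <- apply(load, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  load <- sweep(load, 2, flip, "*")
  structure(
    list(mean = pc$center, loadings = load,
         var_fraction = ev[keep] / sum(ev), eigenvalues = ev[keep],
         n_components = as.integer(n_components), feature_names = colnames(x)),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components over %d features; %.1f%% variance\n",
              x$n_components, length(x$mean), 100 * sum(x$var_fraction)))
  invisible(x)
}

#' Project a feature matrix onto a fitted PCA
#'
#' @param matrix a `feature_matrix` whose feature names match the model.
#' @param model a `pca_model` from [pca_fit()].
#' @return A `feature_matrix` at stage `"pca"` with `n_components` columns.
#' @export
pca_project <- function(matrix, model) {
  stopifnot(inherits(matrix, "feature_matrix"), inherits(model, "pca_model"))
  if (!identical(colnames(matrix$values), model$feature_names)) {
    stop2("feature names do not match the PCA model")
  }
  scores <- sweep(matrix$values, 2, model$mean) %*% model$loadings
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  feature_matrix(scores, matrix$keys, "pca")
}

#' Save / load a PCA model as JSON
#'
#' @param model a `pca_model`.
#' @param path JSON file path.
#' @return `write_pca_model()` returns `path` invisibly; `read_pca_model()`
#'   the reconstructed `pca_model`.
#' @export
write_pca_model <- function(model, path) {
  stopifnot(inherits(model, "pca_model"))
  obj <- list(
    mean = unname(model$mean), loadings = unname(model$loadings),
    var_fraction = model$var_fraction, eigenvalues = model$eigenvalues,
    n_components = model$n_components, feature_names = model$feature_names
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pca_model
#' @param path JSON file path.
#' @export
read_pca_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  load <- obj$loadings
  mean <- obj$mean
  names(mean) <- obj$feature_names
  rownames(load) <- obj$feature_names
  colnames(load) <- paste0("PC", seq_len(ncol(load)))
  structure(
    list(mean = mean, loadings = load, var_fraction = obj$var_fraction,
         eigenvalues = obj$eigenvalues,
         n_components = as.integer(obj$n_components),
         feature_names = obj$feature_names),
    class = "pca_model"
  )
}

#' Germination label table
#'
#' One row per (seed_id, time_index): `label` 0 (un-germinated) or 1
#' (germinated) and a `provenance` of `"human"`, `"amended"` or `"predicted"`.
#'
#' @param df `data.frame` with columns `seed_id`, `time_index`, `label` and
#'   optionally `provenance` (default `"human"`).
#' @return A `label_table` (a validated `data.frame`).
#' @export
label_table <- function(df) {
  stopifnot(all(c("seed_id", "time_index", "label") %in% names(df)))
  out <- data.frame(
    seed_id = as.character(df$seed_id),
    time_index = as.integer(df$time_index),
    label = as.integer(df$label),
    provenance = if ("provenance" %in% names(df)) {
      as.character(df$provenance)
    } else {
      "human"
    },
    stringsAsFactors = FALSE
  )
  if (!all(out$label %in% c(0L, 1L))) stop2("labels must be 0 or 1")
  if (!all(out$provenance %in% c("human", "amended", "predicted"))) {
    stop2("provenance must be human, amended or predicted")
  }
  if (anyDuplicated(image_key(out$seed_id, out$time_index))) {
    stop2("duplicate (seed_id, time_index) in label table")
  }
  class(out) <- c("label_table", "data.frame")
  out
}

#' Propagate germination forward in time
#'
#' Once a seed is marked germinated, all of its later time points are marked
#' germinated too (per-seed running maximum over `time_index`). Provenance is
#' preserved for unchanged rows; rows flipped by propagation keep their
#' original provenance, as the flip is a consequence of the earlier call.
#'
#' @param table a [label_table()].
#' @return The propagated `label_table` (same row order).
#' @export
propagate_labels <- function(table) {
  table <- label_table(table)
  ord <- order(table$seed_id, table$time_index)
  lab <- table$label[ord]
  runmax <- stats::ave(lab, table$seed_id[ord], FUN = cummax)
  out <- table
  out$label[ord] <- as.integer(runmax)
  out
}

#' Drop time-zero (pre-test) images
#'
#' Removes every row with `time_index == 0` consistently from a feature
#' matrix and its label table.
#'
#' @param matrix a `feature_matrix`.
#' @param table a [label_table()] covering the same keys.
#' @return List with the filtered `matrix` and `table`.
#' @export
drop_time_zero <- function(matrix, table) {
  stopifnot(inherits(matrix, "feature_matrix"))
  table <- label_table(table)
  keep_m <- matrix$keys$time_index != 0L
  m2 <- feature_matrix(matrix$values[keep_m, , drop = FALSE],
                       matrix$keys[keep_m, , drop = FALSE], matrix$stage)
  t2 <- table[table$time_index != 0L, , drop = FALSE]
  class(t2) <- class(table)
  list(matrix = m2, table = t2)
}

#' Random train/test split
#'
#' Assigns `round(n * train_fraction)` of the `n` units (round half up) to the
#' training set uniformly at random without replacement, reproducibly from
#' `rng_seed`. Units can be image rows or — as in per-seed splitting — seed
#' ids; pass whichever vector of unit keys applies.
#'
#' @param n number of units, or a vector of unit keys.
#' @param train_fraction fraction in (0, 1).
#' @param rng_seed integer seed.
#' @return A `split_spec` with integer index vectors `train` and `test`
#'   (disjoint, exhaustive), plus `n`, `train_fraction`, `rng_seed`.
#' @export
split_dataset <- function(n, train_fraction, rng_seed) {
  keys <- NULL
  if (length(n) > 1L || !is.numeric(n)) {
    keys <- n
    n <- length(keys)
  }
  n <- as.integer(n)
  if (n < 2L) stop2("need at least 2 units to split")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop2("train_fraction must be in (0, 1)")
  }
  n_train <- as.integer(floor(n * train_fraction + 0.5))
  n_train <- max(1L, min(n - 1L, n_train))
  train <- with_rng(rng_seed, sort(sample.int(n, n_train)))
  structure(
    list(train = train, test = setdiff(seq_len(n), train), keys = keys,
         n = n, train_fraction = train_fraction,
         rng_seed = as.integer(rng_seed)),
    class = "split_spec"
  )
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> %d train / %d test (fraction %.3g, seed %d)\n",
              length(x$train), length(x$test), x$train_fraction, x$rng_seed))
  invisible(x)
}

#' Read / write label tables as CSV
#'
#' CSV columns: `seed_id`, `time_index`, `label`, `provenance`.
#'
#' @param path CSV file path.
#' @return `read_label_csv()` returns a [label_table()].
#' @export
read_label_csv <- function(path) {
  label_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_label_csv
#' @param table a [label_table()].
#' @export
write_label_csv <- function(table, path) {
  utils::write.csv(label_table(table), path, row.names = FALSE)
  invisible(path)
}
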