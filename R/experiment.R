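# End-to-end experiment runner wiring the pipeline stages into the four
# canonical modes:
#   objects_only     - the 25 object-counter features, min-max normalized
#   all_values       - all 1561 features (objects + colour histograms)
#   pca              - all values reduced to 21 principal components
#   optimised_subset - the 21-component pipeline with a 1:2 train:test split,
#                      intended for a clean ("optimised") image set
# Every stage is reproducible from a single rng seed (default 1234).

experiment_modes <- c("objects_only", "all_values", "pca", "optimised_subset")

#' Run one germination-scoring experiment
#'
#' Assembles features and labels (from a directory of tiles + label CSV, a
#' pre-extracted feature table, or a synthetic [generator_config()]),
#' propagates labels forward in time, drops the pre-test (time-zero) frames,
#' then repeatedly splits by seed, normalizes (and PCA-reduces, mode
#' permitting) on the training side only, classifies with k-NN and evaluates
#' ROC/AUC and error fractions.
#'
#' @param mode one of `"objects_only"`, `"all_values"`, `"pca"`,
#'   `"optimised_subset"`.
#' @param features a feature `data.frame` (as from [dataset_features()] or
#'   [extract_features_dir()]), or `NULL` to use `images_dir` / `generator`.
#' @param labels a [label_table()] (or `NULL` when `generator` supplies
#'   ground truth).
#' @param images_dir directory of tiles for [extract_features_dir()].
#' @param generator a [generator_config()]; its ground truth supplies labels.
#' @param k neighbours (default 7).
#' @param train_fraction training fraction; defaults to 0.5, or 1/3 (the 1:2
#'   split) for `mode = "optimised_subset"`.
#' @param n_repeats random splits to average over.
#' @param n_components PCA width for the PCA-based modes.
#' @param rng_seed master seed (default 1234).
#' @param out_dir optional directory; writes `predictions` inputs, the ROC
#'   points, a JSON summary and a JSON-lines run log.
#' @return An `experiment_result`: the [evaluate_run()] summary plus the
#'   resolved configuration and the feature matrix dimensions.
#' @export
run_experiment <- function(mode = experiment_modes,
                           features = NULL, labels = NULL,
                           images_dir = NULL, generator = NULL,
                           k = 7L, train_fraction = NULL,
                           n_repeats = 1L, n_components = 21L,
                           rng_seed = 1234L, out_dir = NULL) {
  mode <- match.arg(mode)
  t0 <- Sys.time()
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1L]] <<- list(
      stage = stage, elapsed_s = as.numeric(Sys.time() - t0, units = "secs"), ...
    )
  }

  if (is.null(features)) {
    if (!is.null(generator)) {
      ds <- generate_dataset(generator)
      features <- dataset_features(ds)
      labels <- ds$labels
      note("simulate", n_images = nrow(features))
    } else if (!is.null(images_dir)) {
      features <- extract_features_dir(images_dir)
      note("extract", n_images = nrow(features))
    } else {
      stop2("supply `features`, `images_dir` or `generator`")
    }
  }
  if (is.null(labels)) stop2("labels are required")
  labels <- propagate_labels(labels)

  fm <- as_feature_matrix(features)
  if (mode == "objects_only") {
    fm <- feature_matrix(fm$values[, object_feature_names, drop = FALSE],
                         fm$keys, "raw")
  }
  dropped <- drop_time_zero(fm, labels)
  fm <- dropped$matrix; labels <- dropped$table
  note("assemble", n_images = nrow(fm$values), n_features = ncol(fm$values))

  train_fraction <- train_fraction %||%
    if (mode == "optimised_subset") 1 / 3 else 0.5
  preprocess <- if (mode %in% c("pca", "optimised_subset")) "pca" else "normalize"
  summary <- evaluate_run(
    fm, labels, train_fraction = train_fraction, k = k,
    n_repeats = n_repeats, base_seed = rng_seed,
    preprocess = preprocess, n_components = n_components
  )
  note("evaluate", mean_auc = unname(summary$mean["auc"]))

  res <- structure(
    list(mode = mode, summary = summary, k = k,
         train_fraction = train_fraction, n_repeats = n_repeats,
         n_components = if (preprocess == "pca") n_components else NA_integer_,
         rng_seed = rng_seed,
         n_images = nrow(fm$values), n_features = ncol(fm$values),
         log = log),
    class = "experiment_result"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary$roc$points, file.path(out_dir, "roc.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(mode = mode, k = k, train_fraction = train_fraction,
           n_repeats = n_repeats, rng_seed = rng_seed,
           n_images = res$n_images, n_features = res$n_features,
           auc_mean = unname(summary$mean["auc"]),
           fp_frac_mean = unname(summary$mean["fp_frac"]),
           fn_frac_mean = unname(summary$mean["fn_frac"])),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA
    )
    writeLines(vapply(log, function(e) jsonlite::toJSON(e, auto_unbox = TRUE),
                      character(1)),
               file.path(out_dir, "run_log.jsonl"))
  }
  res
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf(
    "<experiment_result> mode=%s  %d images x %d features, k=%d, %d repeat(s)\n",
    x$mode, x$n_images, x$n_features, x$k, x$n_repeats
  ))
  cat(sprintf("  mean AUC %.4f  FP frac %.4f  FN frac %.4f\n",
              x$summary$mean["auc"], x$summary$mean["fp_frac"],
              x$summary$mean["fn_frac"]))
  invisible(x)
}

#' Run an experiment from a YAML config file
#'
#' The file may hold any [run_experiment()] argument (`mode`, `k`,
#' `train_fraction`, `n_repeats`, `n_components`, `rng_seed`, `out_dir`,
#' `images_dir`, `labels_csv`, `features_csv`) plus `preset` /
#' `n_seeds` / `n_timepoints` for a synthetic run.
#'
#' @param path YAML config path.
#' @return The `experiment_result`.
#' @export
run_experiment_file <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- cfg[intersect(names(cfg),
                        c("mode", "k", "train_fraction", "n_repeats",
                          "n_components", "rng_seed", "out_dir", "images_dir"))]
  if (!is.null(cfg$features_csv)) {
    args$features <- utils::read.csv(cfg$features_csv, check.names = FALSE)
  }
  if (!is.null(cfg$labels_csv)) args$labels <- read_label_csv(cfg$labels_csv)
  if (!is.null(cfg$preset)) {
    ps <- presets(
      n_seeds = cfg$n_seeds %||% 400L,
      n_timepoints = cfg$n_timepoints %||% 4L,
      rng_seed = cfg$rng_seed %||% 1234L
    )
    args$generator <- ps[[match.arg(cfg$preset, names(ps))]]
  }
  do.call(run_experiment, args)
}
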