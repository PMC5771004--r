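fm_raw <- function(x) {
  feature_matrix(x, data.frame(seed_id = paste0("s", seq_len(nrow(x))),
                               time_index = 1L), "raw")
}

test_that("min-max normalization maps to [0,1] with stated degenerate rules", {
  x <- cbind(a = c(2, 4, 6), b = c(5, 5, 5))
  norm <- normalize_features(fm_raw(x))
  expect_equal(unname(norm$matrix$values[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(norm$matrix$values[, "b"]), c(0, 0, 0))
  expect_equal(norm$matrix$stage, "normalized")

  # test-time transform clips outside the training range
  test <- fm_raw(cbind(a = c(8, 1), b = c(7, 5)))
  out <- normalize_features(test, norm$params)$matrix
  expect_equal(unname(out$values[, "a"]), c(1, 0))

  wrong <- fm_raw(cbind(z = c(1, 2, 3), b = c(1, 2, 3)))
  expect_error(normalize_features(wrong, norm$params), "feature names")
})

test_that("normalization round-trips non-constant features to 1e-9", {
  set.seed(8)
  x <- matrix(rnorm(200, sd = 50), 20, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  norm <- normalize_features(fm_raw(x))
  back <- denormalize_features(norm$matrix, norm$params)
  expect_lt(max(abs(back$values - x)), 1e-9)
})

test_that("PCA recovers structure: line, isotropy, width and identities", {
  # points exactly on a line: one component carries all variance
  set.seed(13)
  t <- rnorm(50)
  line <- fm_raw(cbind(f1 = 0.2 + 3 * t, f2 = 1 - 2 * t))
  line$stage <- "normalized"
  m_line <- pca_fit(line, 2)
  expect_equal(m_line$var_fraction[1], 1)

  # isotropic Gaussian: equal fractions to within 0.02
  iso <- fm_raw(matrix(rnorm(30000), 10000, 3,
                       dimnames = list(NULL, c("f1", "f2", "f3"))))
  iso$stage <- "normalized"
  m_iso <- pca_fit(iso, 3)
  expect_true(all(abs(m_iso$var_fraction - 1 / 3) < 0.02))

  # default width is 21 components
  x <- matrix(rnorm(4000), 100, 40, dimnames = list(NULL, paste0("f", 1:40)))
  fm <- fm_raw(x); fm$stage <- "normalized"
  model <- pca_fit(fm)
  proj <- pca_project(fm, model)
  expect_equal(ncol(proj$values), 21)
  expect_equal(proj$stage, "pca")
  expect_error(pca_fit(fm, 101), "n_components")

  # loadings orthonormal; fractions non-increasing; scores variance = eigenvalues
  full <- pca_fit(fm, 40)
  gram <- t(full$loadings) %*% full$loadings
  expect_lt(max(abs(gram - diag(40))), 1e-8)
  expect_true(all(diff(full$var_fraction) <= 1e-12))
  expect_lte(sum(full$var_fraction), 1 + 1e-9)
  scores <- pca_project(fm, full)
  expect_equal(unname(apply(scores$values, 2, stats::var)),
               unname(full$eigenvalues), tolerance = 1e-10)

  # full reconstruction and zero projection of the mean
  recon <- scores$values %*% t(full$loadings) +
    matrix(full$mean, 100, 40, byrow = TRUE)
  expect_lt(max(abs(recon - x)), 1e-8)
  mean_scores <- sweep(matrix(full$mean, 1), 2, full$mean) %*% full$loadings
  expect_lt(max(abs(mean_scores)), 1e-12)

  # truncation consistency: k' < k projection equals truncated columns
  m5 <- pca_fit(fm, 5)
  expect_equal(pca_project(fm, m5)$values,
               scores$values[, 1:5, drop = FALSE])
})

test_that("PCA models survive a JSON round trip", {
  set.seed(2)
  x <- matrix(runif(300), 30, 10, dimnames = list(NULL, paste0("f", 1:10)))
  fm <- fm_raw(x); fm$stage <- "normalized"
  model <- pca_fit(fm, 4)
  path <- tempfile(fileext = ".json")
  write_pca_model(model, path)
  back <- read_pca_model(path)
  expect_equal(back$loadings, model$loadings, tolerance = 1e-12)
  expect_equal(pca_project(fm, back)$values, pca_project(fm, model)$values,
               tolerance = 1e-12)
  unlink(path)
})

test_that("label propagation is the per-seed running maximum", {
  tab <- label_table(data.frame(
    seed_id = rep(c("a", "b"), each = 4),
    time_index = rep(0:3, 2),
    label = c(0, 1, 0, 0, 0, 0, 0, 0)
  ))
  prop <- propagate_labels(tab)
  expect_equal(prop$label[prop$seed_id == "a"], c(0L, 1L, 1L, 1L))
  expect_equal(prop$label[prop$seed_id == "b"], c(0L, 0L, 0L, 0L))
  expect_identical(propagate_labels(prop)$label, prop$label)  # idempotent

  dup <- data.frame(seed_id = c("a", "a"), time_index = c(1, 1), label = c(0, 1))
  expect_error(propagate_labels(dup), "duplicate")
})

test_that("propagation never decreases labels on random tables", {
  set.seed(31)
  for (rep in 1:25) {
    tab <- label_table(data.frame(
      seed_id = rep(sprintf("s%d", 1:8), each = 5),
      time_index = rep(0:4, 8),
      label = sample(0:1, 40, replace = TRUE)
    ))
    shuffled <- tab[sample(nrow(tab)), ]
    prop <- propagate_labels(shuffled)
    expect_true(all(prop$label >= shuffled$label))
    expect_gte(sum(prop$label), sum(shuffled$label))
    by_seed <- split(prop[order(prop$time_index), ], f = prop$seed_id[order(prop$time_index)])
    expect_true(all(vapply(by_seed, function(d) all(diff(d$label) >= 0), logical(1))))
  }
})

test_that("time-zero frames are excluded consistently", {
  keys <- expand.grid(time_index = 0:3, seed_id = sprintf("s%d", 1:10),
                      stringsAsFactors = FALSE)
  x <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, paste0("f", 1:3)))
  fm <- feature_matrix(x, keys, "raw")
  tab <- label_table(data.frame(keys, label = 0L))
  out <- drop_time_zero(fm, tab)
  expect_equal(nrow(out$matrix$values), 30)
  expect_equal(nrow(out$table), 30)
  expect_true(all(out$matrix$keys$time_index != 0))

  again <- drop_time_zero(out$matrix, out$table)
  expect_equal(dim(again$matrix$values), dim(out$matrix$values))
})

test_that("splits have the stated sizes and are reproducible", {
  sp <- split_dataset(16896, 0.5, 1234)
  expect_equal(length(sp$train), 8448)
  expect_equal(length(sp$test), 8448)
  expect_identical(split_dataset(16896, 0.5, 1234)$train, sp$train)
  expect_false(identical(split_dataset(16896, 0.5, 99)$train, sp$train))

  sp3 <- split_dataset(711, 1 / 3, 1)
  expect_equal(length(sp3$train), 237)
  expect_equal(length(sp3$test), 474)
  expect_identical(sort(c(sp3$train, sp3$test)), 1:711)

  expect_error(split_dataset(1, 0.5, 1), "at least 2")
  expect_error(split_dataset(10, 1.2, 1), "train_fraction")
})

test_that("label tables round-trip through CSV", {
  tab <- label_table(data.frame(seed_id = c("a", "a", "b"),
                                time_index = c(0, 1, 0),
                                label = c(0, 1, 0),
                                provenance = c("human", "amended", "human")))
  path <- tempfile(fileext = ".csv")
  write_label_csv(tab, path)
  back <- read_label_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  unlink(path)
})
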