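test_that("generator configs validate probabilities and geometry", {
  expect_s3_class(tiny_config(), "generator_config")
  expect_error(tiny_config(germination_fraction = 1.4), "probabilities")
  expect_error(tiny_config(tile = c(40L, 40L)), "tile too small")
  expect_error(generator_config(axis_b = c(1, 2)), "semi-axes")
})

test_that("presets exist with the documented contrast", {
  ps <- presets(n_seeds = 10)
  expect_named(ps, c("easy", "hard"))
  expect_equal(ps$easy$mould_prob, 0)
  expect_equal(ps$easy$broken_prob, 0)
  expect_gt(ps$hard$mould_prob, 0)
  expect_gt(ps$hard$broken_prob, 0)
  expect_lt(ps$hard$radicle_initial[2], ps$easy$radicle_initial[1])
})

test_that("germinator counts are deterministic, not sampled", {
  ds <- generate_dataset(tiny_config(n_seeds = 100L, germination_fraction = 0.5))
  germ <- vapply(ds$params, `[[`, logical(1), "germinates")
  expect_equal(sum(germ), 50)

  none <- generate_dataset(tiny_config(n_seeds = 10L, germination_fraction = 0))
  expect_true(all(none$labels$label == 0))

  odd <- generate_dataset(tiny_config(n_seeds = 25L, germination_fraction = 0.3))
  expect_equal(sum(vapply(odd$params, `[[`, logical(1), "germinates")),
               round(25 * 0.3))
})

test_that("ground truth is monotone and already propagated", {
  ds <- generate_dataset(tiny_config(n_seeds = 30L))
  expect_identical(propagate_labels(ds$labels)$label, ds$labels$label)
  gt <- ds$ground_truth
  expect_true(all((gt$radicle_length > 0) == (gt$germinated == 1)))
  expect_true(all(gt$germinated[gt$time_index == 0] == 0))
})

test_that("rendering is byte-identical for a fixed stream and seed set", {
  ds <- generate_dataset(tiny_config(n_seeds = 5L))
  a <- render_seed_tile(ds, "s0002", 2)
  b <- render_seed_tile(ds, "s0002", 2)
  expect_identical(a$pixels, b$pixels)

  # adding seeds never perturbs existing images
  bigger <- generate_dataset(tiny_config(n_seeds = 9L))
  c <- render_seed_tile(bigger, "s0002", 2)
  expect_identical(a$pixels, c$pixels)
})

test_that("a noise-free ellipse segments to its analytic area within 2%", {
  cfg <- tiny_config(n_seeds = 4L, noise_sd = 0, germination_fraction = 0)
  ds <- generate_dataset(cfg)
  for (sid in names(ds$params)) {
    p <- ds$params[[sid]]
    img <- render_seed_tile(ds, sid, 0)
    area <- extract_features(img)[["area"]]
    expect_lt(abs(area - pi * p$a * p$b) / (pi * p$a * p$b), 0.02)
  }
})

test_that("a germinated frame has strictly more object pixels than before", {
  cfg <- tiny_config(n_seeds = 10L, noise_sd = 0, swell = 0,
                     germination_fraction = 1)
  ds <- generate_dataset(cfg)
  for (sid in names(ds$params)[1:5]) {
    p <- ds$params[[sid]]
    before <- extract_features(render_seed_tile(ds, sid, p$t_germ - 1L))[["area"]]
    after <- extract_features(render_seed_tile(ds, sid, p$t_germ))[["area"]]
    expect_gt(after, before)
  }
})

test_that("broken seeds split into halves and mould speckles darken tiles", {
  cfg <- tiny_config(n_seeds = 12L, germination_fraction = 0, broken_prob = 1,
                     noise_sd = 0)
  ds <- generate_dataset(cfg)
  p <- ds$params[[1]]
  expect_true(p$broken)
  img <- render_seed_tile(ds, p$seed_id, 1)
  objs <- label_objects(threshold_image(img))
  expect_gte(length(objs), 2)  # two displaced half-ellipses
  whole <- extract_features(render_seed_tile(
    generate_dataset(tiny_config(n_seeds = 12L, germination_fraction = 0,
                                 noise_sd = 0)),
    p$seed_id, 1
  ))[["area"]]
  half <- extract_features(img)[["area"]]
  expect_lt(half, 0.75 * whole)

  mcfg <- tiny_config(n_seeds = 6L, germination_fraction = 0, mould_prob = 1,
                      rng_seed = 17L)
  mds <- generate_dataset(mcfg)
  pm <- mds$params[[1]]
  t_on <- pm$t_mould
  with_m <- render_seed_tile(mds, pm$seed_id, t_on)
  gt <- mds$ground_truth
  expect_true(all(gt$mould[gt$time_index >= t_on & gt$seed_id == pm$seed_id]))
  # mould pixels pull mid-grey counts into the tile
  grey <- (with_m$pixels[, , 1] + with_m$pixels[, , 2] + with_m$pixels[, , 3]) / 3
  expect_gt(sum(grey > 100 & grey < 160), 20)
})

test_that("datasets written to disk round-trip through the extractor", {
  dir <- tempfile("tiles")
  cfg <- tiny_config(n_seeds = 3L, n_timepoints = 2L)
  ds <- generate_dataset(cfg, dir = dir)
  files <- list.files(dir)
  expect_true(all(sprintf("s000%d_t%d.png", rep(1:3, each = 2), 0:1) %in% files))
  expect_true("labels.csv" %in% files)
  expect_true("config.yaml" %in% files)

  tab <- extract_features_dir(dir)
  expect_equal(nrow(tab), 6)
  expect_equal(ncol(tab), 1563)  # 2 identity + 1561 features
  direct <- dataset_features(ds)
  expect_equal(as.matrix(tab[order(tab$seed_id, tab$time_index), -(1:2)]),
               as.matrix(direct[order(direct$seed_id, direct$time_index), -(1:2)]),
               tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
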