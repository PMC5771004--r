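# Programmatic fixtures.

# A flat grey tile with optional darker rectangular blocks.
make_tile <- function(h = 20, w = 20, bg = 200, blocks = list(),
                      seed_id = "s1", time_index = 1L) {
  g <- matrix(bg, h, w)
  for (b in blocks) {
    g[b$rows, b$cols] <- b$value
  }
  seed_image(array(rep(g, 3L), c(h, w, 3L)), seed_id, time_index)
}

# A small, fast generator configuration (96 x 96 tiles, easy-like lot).
tiny_config <- function(...) {
  defaults <- list(
    n_seeds = 20L, n_timepoints = 4L, rng_seed = 99L,
    axis_a = c(12, 14), axis_b = c(8, 10), seed_shade = c(70, 95),
    radicle_initial = c(9, 14), radicle_growth = 4, radicle_max = 18,
    radicle_halfwidth = 4, swell = 0.015, noise_sd = 3,
    tile = c(96L, 96L), center_jitter = 2
  )
  do.call(generator_config, utils::modifyList(defaults, list(...)))
}

# Separable numeric time-series features with monotone ground-truth labels:
# germinated frames cluster away from un-germinated ones.
make_labelled_features <- function(n_seeds = 30L, n_time = 3L, sep = 4,
                                   sd = 0.4, seed = 7L) {
  set.seed(seed)
  keys <- expand.grid(
    time_index = seq_len(n_time),
    seed_id = sprintf("s%03d", seq_len(n_seeds)),
    stringsAsFactors = FALSE
  )[, c("seed_id", "time_index")]
  t_germ <- stats::setNames(
    sample(c(seq_len(n_time), rep(Inf, n_time)), n_seeds, replace = TRUE),
    sprintf("s%03d", seq_len(n_seeds))
  )
  lab <- as.integer(keys$time_index >= t_germ[keys$seed_id])
  x <- cbind(rnorm(nrow(keys), sep * lab, sd), rnorm(nrow(keys), -sep * lab, sd))
  colnames(x) <- c("f1", "f2")
  list(
    matrix = feature_matrix(x, keys, "normalized"),
    table = label_table(data.frame(keys, label = lab))
  )
}
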