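# Synthetic seed-image generator. Emulates the phenotype diversity of a
# germination time course photographed as per-seed tiles: a dark ellipsoidal
# seed on a light background, slight swelling from water uptake over time, a
# tapered radicle protruding from one apex once the seed germinates, mould
# speckle clusters near (and over) the seed, and broken seeds rendered as two
# displaced half-ellipses. Every tile is deterministic given the dataset seed
# and its (seed_id, time_index), so adding seeds never perturbs existing
# images.

#' Configuration of the synthetic dataset generator
#'
#' Lengths are pixels, shades 8-bit grey levels. Exactly
#' `round(n_seeds * germination_fraction)` seeds germinate (deterministic
#' count); each germinator draws its germination time uniformly from
#' `germination_time_range`. Broken seeds are drawn only among
#' non-germinators (a broken seed cannot germinate).
#'
#' @param n_seeds number of seed positions.
#' @param n_timepoints frames per seed; `time_index` runs `0 ..
#'   n_timepoints - 1` and 0 is the pre-test photograph.
#' @param germination_fraction fraction of seeds that germinate.
#' @param germination_time_range inclusive integer range of germination
#'   `time_index` (default `c(1, n_timepoints - 1)`).
#' @param axis_a,axis_b ranges of the ellipse semi-axes at time 0.
#' @param seed_shade range of the seed's base grey shade.
#' @param background_shade,noise_sd background grey level and per-channel
#'   Gaussian pixel noise sd.
#' @param radicle_initial range of radicle length at the germination frame.
#' @param radicle_growth radicle elongation per subsequent timepoint.
#' @param radicle_max cap on radicle length (radicles curl rather than grow
#'   straight indefinitely).
#' @param radicle_halfwidth radicle half-width at its base (tapers to 20%).
#' @param radicle_shade grey shade of the radicle (paler than the seed coat).
#' @param swell fractional semi-axis growth per timepoint (water uptake).
#' @param mould_prob probability a seed carries mould.
#' @param mould_density multiplier on the number of mould speckles.
#' @param mould_shade grey shade of mould speckles (blended at 85% opacity).
#' @param broken_prob probability a non-germinating seed is broken.
#' @param broken_gap range of the gap between the two halves of a broken
#'   seed.
#' @param tile tile `(height, width)`; the nominal camera tile is 282 x 341.
#' @param center_jitter maximal offset of the seed centre from the tile
#'   centre, per axis.
#' @param rng_seed master seed; all per-seed and per-tile substreams derive
#'   from it.
#' @return A validated `generator_config`.
#' @export
generator_config <- function(n_seeds = 400L,
                             n_timepoints = 4L,
                             germination_fraction = 0.5,
                             germination_time_range = NULL,
                             axis_a = c(39, 41),
                             axis_b = c(27, 29),
                             seed_shade = c(70, 95),
                             background_shade = 200,
                             noise_sd = 3,
                             radicle_initial = c(35, 55),
                             radicle_growth = 18,
                             radicle_max = 90,
                             radicle_halfwidth = 8,
                             radicle_shade = 100,
                             swell = 0.015,
                             mould_prob = 0,
                             mould_density = 1,
                             mould_shade = 120,
                             broken_prob = 0,
                             broken_gap = c(6, 14),
                             tile = c(282L, 341L),
                             center_jitter = 4,
                             rng_seed = 1234L) {
  cfg <- list(
    n_seeds = as.integer(n_seeds), n_timepoints = as.integer(n_timepoints),
    germination_fraction = germination_fraction,
    germination_time_range = as.integer(
      germination_time_range %||% c(1L, max(1L, n_timepoints - 1L))
    ),
    axis_a = axis_a, axis_b = axis_b, seed_shade = seed_shade,
    background_shade = background_shade, noise_sd = noise_sd,
    radicle_initial = radicle_initial, radicle_growth = radicle_growth,
    radicle_max = radicle_max, radicle_halfwidth = radicle_halfwidth,
    radicle_shade = radicle_shade, swell = swell,
    mould_prob = mould_prob, mould_density = mould_density,
    mould_shade = mould_shade, broken_prob = broken_prob,
    broken_gap = broken_gap, tile = as.integer(tile),
    center_jitter = center_jitter, rng_seed = as.integer(rng_seed)
  )
  probs <- c(cfg$germination_fraction, cfg$mould_prob, cfg$broken_prob)
  if (any(probs < 0 | probs > 1)) stop2("probabilities must lie in [0, 1]")
  if (cfg$axis_b[1] < 2 || cfg$axis_a[1] < 2) stop2("semi-axes must be >= 2 px")
  if (cfg$n_timepoints < 2L) stop2("need at least 2 timepoints")
  if (cfg$germination_time_range[1] < 1L ||
      cfg$germination_time_range[2] > cfg$n_timepoints - 1L) {
    stop2("germination_time_range must lie within 1 .. n_timepoints - 1")
  }
  reach <- max(cfg$axis_a) * (1 + cfg$swell)^(cfg$n_timepoints - 1) +
    cfg$radicle_max + cfg$center_jitter + 3
  if (reach > min(cfg$tile) / 2) {
    stop2("tile too small: seed plus maximal radicle (", round(reach),
          " px reach) exceeds half the tile (", min(cfg$tile) / 2, " px)")
  }
  structure(cfg, class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    "<generator_config> %d seeds x %d timepoints, %.0f%% germinating, tile %d x %d, seed %d\n",
    x$n_seeds, x$n_timepoints, 100 * x$germination_fraction,
    x$tile[1], x$tile[2], x$rng_seed
  ))
  invisible(x)
}

#' Built-in generator presets
#'
#' `"easy"` emulates the optimised image subset: a graded (size-sorted) seed
#' lot with long distinct radicles, no mould, no broken seeds and low noise.
#' `"hard"` emulates the full non-ideal set: an ungraded lot with short pale
#' radicles, mould on 30% of seeds and 10% of non-germinators broken.
#'
#' @param n_seeds,n_timepoints,rng_seed shared study dimensions.
#' @return Named list of [generator_config()]s with elements `easy` and
#'   `hard`.
#' @export
presets <- function(n_seeds = 400L, n_timepoints = 4L, rng_seed = 1234L) {
  list(
    easy = generator_config(
      n_seeds = n_seeds, n_timepoints = n_timepoints, rng_seed = rng_seed
    ),
    hard = generator_config(
      n_seeds = n_seeds, n_timepoints = n_timepoints, rng_seed = rng_seed,
      axis_a = c(30, 46), axis_b = c(20, 32), seed_shade = c(60, 110),
      background_shade = 195, noise_sd = 8,
      radicle_initial = c(12, 25), radicle_growth = 12, radicle_max = 60,
      radicle_halfwidth = 4, radicle_shade = 135, swell = 0.02,
      mould_prob = 0.3, mould_density = 1, broken_prob = 0.1
    )
  )
}

# static per-seed parameters, drawn from a substream keyed by the seed id
seed_params <- function(cfg, i, germinates) {
  sid <- sprintf("s%04d", i)
  with_rng(stream_seed(cfg$rng_seed, "params", sid), {
    list(
      seed_id = sid,
      a = stats::runif(1, cfg$axis_a[1], cfg$axis_a[2]),
      b = stats::runif(1, cfg$axis_b[1], cfg$axis_b[2]),
      angle = stats::runif(1, 0, pi),
      shade = stats::runif(1, cfg$seed_shade[1], cfg$seed_shade[2]),
      cx = (cfg$tile[2] - 1) / 2 + stats::runif(1, -cfg$center_jitter, cfg$center_jitter),
      cy = (cfg$tile[1] - 1) / 2 + stats::runif(1, -cfg$center_jitter, cfg$center_jitter),
      germinates = germinates,
      t_germ = if (germinates) {
        sample(cfg$germination_time_range[1]:cfg$germination_time_range[2], 1L)
      } else {
        NA_integer_
      },
      radicle_init = stats::runif(1, cfg$radicle_initial[1], cfg$radicle_initial[2]),
      radicle_side = sample(c(-1, 1), 1L),
      mould = stats::runif(1) < cfg$mould_prob,
      t_mould = sample(1:max(1L, cfg$n_timepoints - 1L), 1L),
      broken = !germinates && stats::runif(1) < cfg$broken_prob,
      gap = stats::runif(1, cfg$broken_gap[1], cfg$broken_gap[2])
    )
  })
}

radicle_length_at <- function(cfg, p, t) {
  if (!p$germinates || t < p$t_germ) return(0)
  min(p$radicle_init + cfg$radicle_growth * (t - p$t_germ), cfg$radicle_max)
}

#' Render one synthetic seed tile
#'
#' Deterministic for a fixed dataset and `(seed_id, time_index)`: the pixel
#' noise stream is keyed by both.
#'
#' @param dataset a `seed_dataset` from [generate_dataset()].
#' @param seed_id one of the dataset's seed ids.
#' @param time_index frame to render, `0 .. n_timepoints - 1`.
#' @return A [seed_image()].
#' @export
render_seed_tile <- function(dataset, seed_id, time_index) {
  stopifnot(inherits(dataset, "seed_dataset"))
  p <- dataset$params[[seed_id]]
  if (is.null(p)) stop2("unknown seed_id: ", seed_id)
  render_tile_impl(dataset$config, p, as.integer(time_index))
}

render_tile_impl <- function(cfg, p, t) {
  H <- cfg$tile[1]; W <- cfg$tile[2]
  X <- matrix(0:(W - 1), H, W, byrow = TRUE)
  Y <- matrix(0:(H - 1), H, W)
  grow <- (1 + cfg$swell)^t
  a_t <- p$a * grow; b_t <- p$b * grow
  ux <- cos(p$angle); uy <- sin(p$angle)     # major-axis direction (x, y)

  ellipse_mask <- function(cx, cy, half_plane = 0) {
    dx <- X - cx; dy <- Y - cy
    s_ax <- dx * ux + dy * uy
    s_pp <- -dx * uy + dy * ux
    m <- (s_ax / a_t)^2 + (s_pp / b_t)^2 <= 1
    if (half_plane < 0) m & s_ax <= 0 else if (half_plane > 0) m & s_ax > 0 else m
  }

  shade <- matrix(cfg$background_shade, H, W)
  region <- matrix(0L, H, W)                 # 0 bg, 1 seed, 2 radicle, 3 mould

  if (p$broken) {
    g <- p$gap / 2
    seed_px <- ellipse_mask(p$cx - g * ux, p$cy - g * uy, half_plane = -1) |
      ellipse_mask(p$cx + g * ux, p$cy + g * uy, half_plane = 1)
  } else {
    seed_px <- ellipse_mask(p$cx, p$cy)
  }
  shade[seed_px] <- p$shade
  region[seed_px] <- 1L

  L <- radicle_length_at(cfg, p, t)
  if (L > 0) {
    apex_x <- p$cx + p$radicle_side * a_t * ux
    apex_y <- p$cy + p$radicle_side * a_t * uy
    dx <- X - apex_x; dy <- Y - apex_y
    s <- (dx * ux + dy * uy) * p$radicle_side
    perp <- abs(-dx * uy + dy * ux)
    rad_px <- s >= 0 & s <= L &
      perp <= cfg$radicle_halfwidth * (1 - 0.8 * s / L) & !seed_px
    shade[rad_px] <- cfg$radicle_shade
    region[rad_px] <- 2L
  }

  with_rng(stream_seed(cfg$rng_seed, "tile", p$seed_id, t), {
    if (p$mould && t >= p$t_mould) {
      n_clusters <- 1L + (t - p$t_mould)
      for (ci in seq_len(n_clusters)) {
        psi <- stats::runif(1, 0, 2 * pi)
        f <- stats::runif(1, 0.85, 1.25)
        mx <- p$cx + f * (a_t * cos(psi) * ux - b_t * sin(psi) * uy)
        my <- p$cy + f * (a_t * cos(psi) * uy + b_t * sin(psi) * ux)
        n_spk <- round(40 * cfg$mould_density * (1 + 0.5 * t))
        sx <- round(stats::rnorm(n_spk, mx, 5))
        sy <- round(stats::rnorm(n_spk, my, 5))
        keep <- sx >= 0 & sx < W & sy >= 0 & sy < H
        idx <- unique(sy[keep] + 1L + sx[keep] * H)
        shade[idx] <- 0.15 * shade[idx] + 0.85 * cfg$mould_shade
        region[idx] <- 3L
      }
    }
    tint <- rbind(bg = c(1, 1, 1), seed = c(1.12, 1, 0.72),
                  radicle = c(1.08, 1.04, 0.85), mould = c(0.9, 1, 0.85))
    px <- array(0L, c(H, W, 3L))
    for (ch in 1:3) {
      v <- shade * tint[region + 1L, ch] +
        stats::rnorm(H * W, 0, cfg$noise_sd)
      px[, , ch] <- as.integer(pmin(pmax(round(v), 0), 255))
    }
    seed_image(px, p$seed_id, t)
  })
}

#' Generate a labelled synthetic dataset
#'
#' Draws all per-seed parameters, schedules germination, and builds the
#' propagated ground-truth label table. Images are rendered lazily with
#' [render_seed_tile()] / [dataset_features()]; pass `dir` to also write
#' every tile as `{seed_id}_t{time}.png` along with `labels.csv` and the
#' config as YAML.
#'
#' @param config a [generator_config()].
#' @param dir optional output directory for PNG tiles and tables.
#' @return A `seed_dataset`: `config`, per-seed `params`, `ground_truth`
#'   data.frame (`seed_id`, `time_index`, `germinated`, `radicle_length`,
#'   `mould`, `broken`) and `labels`, a [label_table()] (already monotone in
#'   time).
#' @export
generate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  n_germ <- round(config$n_seeds * config$germination_fraction)
  params <- lapply(seq_len(config$n_seeds), function(i) {
    seed_params(config, i, germinates = i <= n_germ)
  })
  names(params) <- vapply(params, `[[`, character(1), "seed_id")
  gt <- do.call(rbind, lapply(params, function(p) {
    t <- 0:(config$n_timepoints - 1L)
    rl <- vapply(t, function(tt) radicle_length_at(config, p, tt), numeric(1))
    data.frame(
      seed_id = p$seed_id, time_index = t,
      germinated = as.integer(rl > 0), radicle_length = rl,
      mould = p$mould & t >= p$t_mould, broken = p$broken
    )
  }))
  rownames(gt) <- NULL
  labels <- label_table(data.frame(
    seed_id = gt$seed_id, time_index = gt$time_index,
    label = gt$germinated, provenance = "human"
  ))
  ds <- structure(
    list(config = config, params = params, ground_truth = gt, labels = labels),
    class = "seed_dataset"
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (p in params) {
      for (t in 0:(config$n_timepoints - 1L)) {
        write_seed_image(
          render_seed_tile(ds, p$seed_id, t),
          file.path(dir, sprintf("%s_t%d.png", p$seed_id, t))
        )
      }
    }
    write_label_csv(labels, file.path(dir, "labels.csv"))
    yaml::write_yaml(unclass(config), file.path(dir, "config.yaml"))
  }
  ds
}

#' @export
print.seed_dataset <- function(x, ...) {
  cat(sprintf(
    "<seed_dataset> %d seeds x %d timepoints (%d germinating), tile %d x %d\n",
    x$config$n_seeds, x$config$n_timepoints,
    sum(vapply(x$params, `[[`, logical(1), "germinates")),
    x$config$tile[1], x$config$tile[2]
  ))
  invisible(x)
}

#' Render a dataset and extract every tile's features
#'
#' Streams tile by tile (render, segment, extract, discard) so the full image
#' stack is never held in memory.
#'
#' @param dataset a `seed_dataset`.
#' @param ... passed to [extract_features()].
#' @param progress print a dot every 100 tiles.
#' @return A `data.frame`: `seed_id`, `time_index`, then the 1561 features.
#' @export
dataset_features <- function(dataset, ..., progress = FALSE) {
  stopifnot(inherits(dataset, "seed_dataset"))
  cfg <- dataset$config
  total <- cfg$n_seeds * cfg$n_timepoints
  rows <- vector("list", total)
  keys <- vector("list", total)
  i <- 0L
  for (sid in names(dataset$params)) {
    for (t in 0:(cfg$n_timepoints - 1L)) {
      i <- i + 1L
      img <- render_seed_tile(dataset, sid, t)
      rows[[i]] <- extract_features(img, ...)
      keys[[i]] <- data.frame(seed_id = sid, time_index = t)
      if (progress && i %% 100L == 0L) cat(".")
    }
  }
  if (progress) cat("\n")
  data.frame(do.call(rbind, keys), as.data.frame(do.call(rbind, rows)),
             check.names = FALSE)
}
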