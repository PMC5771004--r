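# Feature extraction for one segmented seed object: 25 object-level
# morphology/intensity descriptors plus 6 x 256 colour-histogram counts.

object_feature_names <- c(
  "area", "perimeter", "bbox_min_x", "bbox_min_y", "bbox_width", "bbox_height",
  "centroid_x", "centroid_y", "mass_center_x", "mass_center_y",
  "dist_centroid_to_tile_center", "dist_mass_center_to_tile_center",
  "dist_centroid_to_mass_center", "mean_grey", "median_grey", "sd_grey",
  "min_grey", "max_grey", "grey_range", "integrated_density", "extent",
  "aspect_ratio", "equivalent_diameter", "circularity", "elongation"
)

histogram_feature_names <- function() {
  paste0(rep(c("R", "G", "B", "H", "S", "Br"), each = 256L), rep(0:255, 6L))
}

#' Feature column names of the full extractor
#'
#' @return Character vector of length 1561: the 25 object-feature names
#'   followed by the 1536 histogram bin names `R0..R255, G..., B..., H...,
#'   S..., Br0..Br255`.
#' @export
feature_names_full <- function() {
  c(object_feature_names, histogram_feature_names())
}

#' Extract the 25 object-level features
#'
#' Descriptors of the segmented object's geometry and of the grey levels
#' (rounded mean of R, G, B) under its mask, in the style of an ImageJ-type
#' object counter. Coordinates are 0-based; `x` is the column axis, `y` the
#' row axis. `perimeter` counts object pixels with at least one 4-neighbour
#' outside the object, `circularity = 4 * pi * area / perimeter^2`, and
#' `elongation` is the major/minor axis ratio from the second central moments
#' of the pixel coordinates (axis lengths `4 * sqrt(eigenvalue)`, floored at
#' 1 px so single-pixel and collinear objects stay finite).
#'
#' @param object an `object_mask` from [label_objects()].
#' @param image the [seed_image()] the mask was derived from.
#' @return Named numeric vector with the 25 features.
#' @export
extract_object_features <- function(object, image) {
  stopifnot(inherits(object, "object_mask"), inherits(image, "seed_image"))
  if (!all(object$dim == c(image$height, image$width))) {
    stop2("object mask and image dimensions differ")
  }
  nr <- object$dim[1]
  px <- object$pixels
  rows <- (px - 1L) %% nr            # 0-based y
  cols <- (px - 1L) %/% nr           # 0-based x
  g <- grey_matrix(image)[px]
  n <- length(px)

  # geometry
  bbox_min_x <- min(cols); bbox_min_y <- min(rows)
  bbox_w <- max(cols) - bbox_min_x + 1
  bbox_h <- max(rows) - bbox_min_y + 1
  cy <- mean(rows); cx <- mean(cols)
  tot_g <- sum(g)
  if (tot_g > 0) {
    my <- sum(rows * g) / tot_g
    mx <- sum(cols * g) / tot_g
  } else {
    my <- cy; mx <- cx
  }
  tile_ctr <- (c(image$height, image$width) - 1) / 2

  # perimeter: object pixels with a 4-neighbour outside the object
  m <- matrix(FALSE, nr + 2L, object$dim[2] + 2L)
  m[cbind(rows + 2L, cols + 2L)] <- TRUE
  inner <- cbind(rows + 2L, cols + 2L)
  interior <- m[inner + cbind(rep(1L, n), 0L)] & m[inner - cbind(rep(1L, n), 0L)] &
    m[inner + cbind(0L, rep(1L, n))] & m[inner - cbind(0L, rep(1L, n))]
  perim <- sum(!interior)

  # second central moments -> axis lengths
  dy <- rows - cy; dx <- cols - cx
  mu20 <- mean(dx^2); mu02 <- mean(dy^2); mu11 <- mean(dx * dy)
  half <- (mu20 + mu02) / 2
  delta <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  major <- max(1, 4 * sqrt(max(half + delta, 0)))
  minor <- max(1, 4 * sqrt(max(half - delta, 0)))

  c(
    area = n,
    perimeter = perim,
    bbox_min_x = bbox_min_x,
    bbox_min_y = bbox_min_y,
    bbox_width = bbox_w,
    bbox_height = bbox_h,
    centroid_x = cx,
    centroid_y = cy,
    mass_center_x = mx,
    mass_center_y = my,
    dist_centroid_to_tile_center = sqrt((cy - tile_ctr[1])^2 + (cx - tile_ctr[2])^2),
    dist_mass_center_to_tile_center = sqrt((my - tile_ctr[1])^2 + (mx - tile_ctr[2])^2),
    dist_centroid_to_mass_center = sqrt((cy - my)^2 + (cx - mx)^2),
    mean_grey = mean(g),
    median_grey = stats::median(g),
    sd_grey = if (n > 1L) stats::sd(g) else 0,
    min_grey = min(g),
    max_grey = max(g),
    grey_range = max(g) - min(g),
    integrated_density = sum(g),
    extent = n / (bbox_w * bbox_h),
    aspect_ratio = bbox_w / bbox_h,
    equivalent_diameter = sqrt(4 * n / pi),
    circularity = 4 * pi * n / perim^2,
    elongation = major / minor
  )
}

# RGB (0..255 integers) -> HSB with each component quantised to 0..255
# (ImageJ-style shared 256-bin scale). Hue wraps so pure red maps to H = 0.
rgb_to_hsb256 <- function(r, g, b) {
  hsv <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 255)
  q <- function(v) as.integer(round(v * 255)) %% 256L
  list(h = q(hsv[1, ]), s = q(hsv[2, ]), b = q(hsv[3, ]))
}

#' Extract the 1536 colour-histogram features
#'
#' Counts the pixels at each of the 256 levels of the R, G and B channels and
#' of the hue, saturation and brightness components (each quantised to 0--255)
#' over the masked object pixels, or over the whole tile with
#' `whole_tile = TRUE`. The returned order is fixed:
#' `R0..R255, G0..G255, B0..B255, H0..H255, S0..S255, Br0..Br255`.
#'
#' @inheritParams extract_object_features
#' @param whole_tile count every tile pixel instead of only masked ones.
#' @return Named integer vector of length 1536; each channel sums to the
#'   number of counted pixels.
#' @export
extract_histograms <- function(object, image, whole_tile = FALSE) {
  stopifnot(inherits(image, "seed_image"))
  px <- image$pixels
  if (whole_tile) {
    idx <- seq_len(image$height * image$width)
  } else {
    stopifnot(inherits(object, "object_mask"))
    idx <- object$pixels
  }
  np <- image$height * image$width
  r <- px[idx]; g <- px[idx + np]; b <- px[idx + 2L * np]
  hsb <- rgb_to_hsb256(r, g, b)
  out <- c(
    tabulate(r + 1L, 256L), tabulate(g + 1L, 256L), tabulate(b + 1L, 256L),
    tabulate(hsb$h + 1L, 256L), tabulate(hsb$s + 1L, 256L), tabulate(hsb$b + 1L, 256L)
  )
  names(out) <- histogram_feature_names()
  out
}

#' Segment a tile and extract its full 1561-feature vector
#'
#' Runs threshold -> 8-connected labeling -> central-object selection, then
#' concatenates the 25 object features and the 1536 histogram counts.
#'
#' @inheritParams threshold_image
#' @param whole_tile_histograms compute histograms over the whole tile rather
#'   than the masked object.
#' @return Named numeric vector of length 1561.
#' @export
extract_features <- function(image,
                             method = c("otsu", "fixed"),
                             polarity = c("dark_object", "light_object"),
                             threshold = NULL,
                             whole_tile_histograms = FALSE) {
  mask <- threshold_image(image, method, polarity, threshold)
  obj <- select_central_object(label_objects(mask))
  c(
    extract_object_features(obj, image),
    extract_histograms(obj, image, whole_tile = whole_tile_histograms)
  )
}

#' Build a feature table from a directory of seed tiles
#'
#' Expects files named `{seed_id}_t{time_index}.png` (or `.tif`/`.tiff`), the
#' layout written by [generate_dataset()]. Each image contributes one row of
#' identity columns (`seed_id`, `time_index`) followed by the 1561 features.
#'
#' @param dir directory containing the image tiles.
#' @param ... passed to [extract_features()].
#' @return A `data.frame` with one row per image.
#' @export
extract_features_dir <- function(dir, ...) {
  files <- sort(list.files(dir, pattern = "\\.(png|tif|tiff)$", full.names = TRUE))
  if (length(files) == 0L) stop2("no PNG/TIFF images found in ", dir)
  base <- sub("\\.(png|tif|tiff)$", "", basename(files))
  mm <- regmatches(base, regexec("^(.*)_t(\\d+)$", base))
  bad <- vapply(mm, length, integer(1)) != 3L
  if (any(bad)) stop2("file names must look like {seed_id}_t{time}: ", base[bad][1])
  rows <- lapply(seq_along(files), function(i) {
    img <- read_seed_image(files[i], seed_id = mm[[i]][2],
                           time_index = as.integer(mm[[i]][3]))
    extract_features(img, ...)
  })
  out <- as.data.frame(do.call(rbind, rows))
  data.frame(
    seed_id = vapply(mm, `[`, character(1), 2L),
    time_index = as.integer(vapply(mm, `[`, character(1), 3L)),
    out,
    check.names = FALSE
  )
}
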