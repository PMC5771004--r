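#' Otsu threshold of an 8-bit grey image
#'
#' Scans all 256 candidate cut points `t` and returns the one maximising the
#' between-class variance of the split `{grey <= t}` vs `{grey > t}`. When the
#' maximum is attained on a plateau (empty histogram bins between the modes)
#' the lowest maximising threshold is returned, so the result is deterministic.
#'
#' @param grey integer matrix with values 0--255.
#' @return Integer threshold in 0--254.
#' @export
otsu_threshold <- function(grey) {
  h <- tabulate(as.integer(grey) + 1L, nbins = 256L)
  n <- sum(h)
  if (sum(h > 0L) < 2L) {
    stop2("no-foreground: image has a single grey level, Otsu threshold undefined")
  }
  lev <- 0:255
  w0 <- cumsum(h)[1:255]                 # pixels at level <= t, t = 0..254
  s0 <- cumsum(h * lev)[1:255]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  m0 <- s0 / w0
  m1 <- (sum(h * lev) - s0) / w1
  bcv <- ifelse(valid, (w0 / n) * (w1 / n) * (m0 - m1)^2, -Inf)
  which.max(bcv) - 1L
}

#' Threshold a seed tile to a foreground mask
#'
#' The tile is collapsed to grey (rounded mean of R, G, B) and cut at an Otsu
#' or user-fixed threshold. With polarity `"dark_object"` the foreground is
#' `grey <= threshold` (seeds darker than the background); `"light_object"`
#' selects the complementary side.
#'
#' @param image a [seed_image()].
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param polarity `"dark_object"` (default) or `"light_object"`.
#' @param threshold integer in 0--255, required for `method = "fixed"`.
#' @return Logical `H x W` matrix, `TRUE` on foreground.
#' @export
threshold_image <- function(image,
                            method = c("otsu", "fixed"),
                            polarity = c("dark_object", "light_object"),
                            threshold = NULL) {
  stopifnot(inherits(image, "seed_image"))
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  g <- grey_matrix(image)
  t <- if (method == "otsu") {
    otsu_threshold(g)
  } else {
    if (is.null(threshold) || threshold < 0 || threshold > 255) {
      stop2("fixed method needs a `threshold` in [0, 255]")
    }
    as.integer(threshold)
  }
  if (polarity == "dark_object") g <= t else g > t
}

#' Label 8-connected foreground objects
#'
#' @param mask logical `H x W` matrix.
#' @return A list of `object_mask` records, one per 8-connected component,
#'   each with `label_id`, `pixel_count`, `centroid` (0-based `(row, col)`),
#'   `pixels` (1-based linear indices into the matrix) and `dim`. The list is
#'   empty for an all-`FALSE` mask.
#' @export
label_objects <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  lab <- label_components(mask)
  n_obj <- max(lab)
  if (n_obj == 0L) return(list())
  idx <- which(lab > 0L)
  by_obj <- split(idx, lab[idx])
  nr <- nrow(mask)
  lapply(seq_len(n_obj), function(id) {
    px <- by_obj[[as.character(id)]]
    rows <- (px - 1L) %% nr          # 0-based
    cols <- (px - 1L) %/% nr
    structure(
      list(
        label_id = id,
        pixel_count = length(px),
        centroid = c(row = mean(rows), col = mean(cols)),
        pixels = px,
        dim = dim(mask)
      ),
      class = "object_mask"
    )
  })
}

#' @export
print.object_mask <- function(x, ...) {
  cat(sprintf(
    "<object_mask> id=%d  %d px  centroid (%.1f, %.1f)\n",
    x$label_id, x$pixel_count, x$centroid[1], x$centroid[2]
  ))
  invisible(x)
}

#' Pick the central-most object in a tile
#'
#' Selects the object whose centroid is closest (Euclidean) to the tile centre
#' `((H - 1) / 2, (W - 1) / 2)`; distance ties are broken by larger
#' `pixel_count`, then by lower `label_id`.
#'
#' @param objects list of `object_mask` records from [label_objects()].
#' @param tile_shape integer `(H, W)`; defaults to the objects' own `dim`.
#' @return The selected `object_mask`.
#' @export
select_central_object <- function(objects, tile_shape = NULL) {
  if (length(objects) == 0L) {
    stop2("no-object: segmentation produced no foreground object in this tile")
  }
  shp <- tile_shape %||% objects[[1]]$dim
  ctr <- (shp - 1) / 2
  d <- vapply(objects, function(o) {
    sqrt(sum((o$centroid - ctr)^2))
  }, numeric(1))
  size <- vapply(objects, function(o) o$pixel_count, numeric(1))
  id <- vapply(objects, function(o) o$label_id, numeric(1))
  objects[[order(d, -size, id)[1]]]
}
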