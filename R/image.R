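#' Single-seed image tile
#'
#' Container for one RGB tile of a single seed position at one time point.
#' Pixels are stored as an integer `H x W x 3` array with 8-bit channel values
#' (0--255), row 1 = top of the image. Coordinates reported by downstream
#' functions are 0-based `(row, col)` with the origin at the top-left pixel.
#'
#' @param pixels numeric or integer `H x W x 3` array with values in 0--255.
#' @param seed_id character scalar identifying the seed position.
#' @param time_index non-negative integer; 0 is the pre-test photograph.
#' @param dish_id optional character scalar identifying the dish/plate.
#'
#' @return An object of class `seed_image` with elements `pixels`, `seed_id`,
#'   `dish_id`, `time_index`, `height`, `width`.
#' @export
seed_image <- function(pixels, seed_id, time_index, dish_id = "") {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop2("`pixels` must be an H x W x 3 array")
  }
  if (dim(pixels)[1] < 8L || dim(pixels)[2] < 8L) {
    stop2("tile too small: need H >= 8 and W >= 8")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop2("channel values must lie in [0, 255] with no missing values")
  }
  storage.mode(pixels) <- "integer"
  structure(
    list(
      pixels = pixels,
      seed_id = as.character(seed_id),
      dish_id = as.character(dish_id),
      time_index = as.integer(time_index),
      height = dim(pixels)[1],
      width = dim(pixels)[2]
    ),
    class = "seed_image"
  )
}

#' @export
print.seed_image <- function(x, ...) {
  cat(sprintf(
    "<seed_image> %s t=%d  %d x %d px%s\n",
    x$seed_id, x$time_index, x$height, x$width,
    if (nzchar(x$dish_id)) paste0("  dish=", x$dish_id) else ""
  ))
  invisible(x)
}

# Grey-level image: rounded mean of the three channels, integer 0..255.
grey_matrix <- function(image) {
  px <- image$pixels
  g <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
  matrix(as.integer(round(g)), nrow(g), ncol(g))
}

#' Read a seed tile from a PNG or TIFF file
#'
#' 8-bit RGB (or greyscale, which is replicated across channels) images are
#' supported; an alpha channel, if present, is dropped.
#'
#' @inheritParams seed_image
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return A [seed_image()].
#' @export
read_seed_image <- function(path, seed_id, time_index, dish_id = "") {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop2("unsupported image format: .", ext, " (expected PNG or TIFF)")
  )
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3L), c(dim(arr), 3L))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]
  seed_image(round(arr * 255), seed_id, time_index, dish_id)
}

#' Write a seed tile to a PNG file
#'
#' @param image a [seed_image()].
#' @param path output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_seed_image <- function(image, path) {
  stopifnot(inherits(image, "seed_image"))
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}

#' Cut a whole-plate image into single-seed tiles
#'
#' The plate is divided into `grid_rows x grid_cols` equal tiles in row-major
#' order; any remainder pixels at the right and bottom edges are dropped. Tiles
#' receive deterministic seed ids `"r{row}c{col}"` (1-based grid positions).
#'
#' @param plate_pixels `H x W x 3` array with values 0--255 (e.g. a 4288 x 2848
#'   plate photograph).
#' @param grid_rows,grid_cols number of tile rows and columns.
#' @param time_index,dish_id identity passed on to every tile.
#' @return A list of [seed_image()] tiles, row-major.
#' @export
tile_plate_image <- function(plate_pixels, grid_rows, grid_cols,
                             time_index = 0L, dish_id = "") {
  d <- dim(plate_pixels)
  if (length(d) != 3L || d[3] != 3L) stop2("`plate_pixels` must be H x W x 3")
  th <- d[1] %/% grid_rows
  tw <- d[2] %/% grid_cols
  if (th < 1L || tw < 1L) stop2("grid larger than image")
  tiles <- vector("list", grid_rows * grid_cols)
  i <- 0L
  for (r in seq_len(grid_rows)) {
    for (cc in seq_len(grid_cols)) {
      i <- i + 1L
      rows <- ((r - 1L) * th + 1L):(r * th)
      cols <- ((cc - 1L) * tw + 1L):(cc * tw)
      tiles[[i]] <- seed_image(
        plate_pixels[rows, cols, , drop = FALSE],
        seed_id = sprintf("r%dc%d", r, cc),
        time_index = time_index, dish_id = dish_id
      )
    }
  }
  tiles
}
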