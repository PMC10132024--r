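#' Raster images and binary masks
#'
#' `raster_image()` wraps a numeric pixel array as the unit object the
#' detector operates on. Pixels are stored as an `height x width x channels`
#' array of intensities in `[0, 255]`, origin at the top-left corner with y
#' increasing downward. `load_image()` decodes a PNG or JPEG file into one.
#'
#' @param pixels Numeric array `h x w` (grayscale) or `h x w x c` with values
#'   in `[0, 255]`. A 4-channel (RGBA) array has its alpha channel dropped.
#' @return A `raster_image`: a list with elements `pixels`, `width`, `height`,
#'   `channels`. `image_area()` returns `width * height` in px^2.
#' @examples
#' img <- raster_image(array(255, dim = c(10, 10, 3)))
#' image_area(img)  # 100
#' @export
raster_image <- function(pixels) {
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L)
  if (!is.array(pixels) || length(dim(pixels)) != 3L) {
    abort("`pixels` must be a h x w or h x w x c numeric array.")
  }
  d <- dim(pixels)
  if (d[3] == 4L) pixels <- pixels[, , 1:3, drop = FALSE]  # drop alpha
  if (d[3] == 2L) pixels <- pixels[, , 1L, drop = FALSE]   # gray + alpha
  d <- dim(pixels)
  if (d[1] < 1L || d[2] < 1L) abort("image has zero dimension")
  if (!d[3] %in% c(1L, 3L)) abort("image must have 1 or 3 channels")
  rng <- range(pixels)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255) {
    abort("pixel intensities must lie in [0, 255]")
  }
  structure(
    list(pixels = pixels, width = d[2], height = d[1], channels = d[3]),
    class = "raster_image"
  )
}

#' @rdname raster_image
#' @param img A `raster_image`.
#' @export
image_area <- function(img) {
  stopifnot(inherits(img, "raster_image"))
  img$width * img$height
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image %d x %d px, %d channel%s>\n",
              x$width, x$height, x$channels, if (x$channels > 1) "s" else ""))
  invisible(x)
}

#' @rdname raster_image
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L) abort("`path` must be a single file path.")
  if (!file.exists(path)) abort(sprintf("image file does not exist: '%s'", path))
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      png  = png::readPNG(path),
      jpg  = ,
      jpeg = jpeg::readJPEG(path),
      abort(sprintf("unsupported image format '.%s' for '%s' (PNG/JPEG only)", ext, path))
    ),
    error = function(e) {
      abort(sprintf("failed to decode image '%s': %s", path, conditionMessage(e)))
    }
  )
  raster_image(arr * 255)
}

#' Convert a raster image to a grayscale intensity matrix
#'
#' Standard luminance weighting (0.299 R + 0.587 G + 0.114 B) for 3-channel
#' images; 1-channel images pass through. Returns an `h x w` matrix in
#' `[0, 255]`.
#'
#' @param img A `raster_image`.
#' @export
as_gray <- function(img) {
  stopifnot(inherits(img, "raster_image"))
  p <- img$pixels
  if (img$channels == 1L) {
    matrix(p[, , 1L], img$height, img$width)
  } else {
    0.299 * p[, , 1L] + 0.587 * p[, , 2L] + 0.114 * p[, , 3L]
  }
}

#' Binary pixel masks
#'
#' A `binary_mask` is an `h x w` integer matrix of 0/1 values, 1 marking a
#' selected dark-pixel candidate. Same top-left origin as [raster_image()].
#'
#' @param values Matrix of 0/1 values.
#' @export
binary_mask <- function(values) {
  if (!is.matrix(values)) abort("`values` must be a matrix.")
  if (!all(values %in% c(0, 1))) abort("mask values must be strictly 0/1")
  structure(list(values = matrix(as.integer(values), nrow(values), ncol(values)),
                 width = ncol(values), height = nrow(values)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %d x %d px, %d selected>\n",
              x$width, x$height, sum(x$values)))
  invisible(x)
}
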