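#' Preprocessing variants for the dark-pixel layer
#'
#' The first layer of the detection cascade selects dark pixels (warning
#' labels are required to carry black borders) and removes small noise by
#' blurring and morphology. Because real posts vary widely in contrast, the
#' cascade runs a small family of preprocessing variants in a fixed order;
#' a `preprocess_variant` records one member of that family.
#'
#' @param variant_id Short label naming the variant.
#' @param threshold_mode `"fixed"` (grayscale intensity cutoff) or
#'   `"adaptive"` (Otsu's method on the image histogram).
#' @param threshold_value Intensity cutoff in `[0, 255]`; used in fixed mode.
#' @param blur_kernel Odd box-blur width in pixels; 1 disables blurring.
#' @param morph_kernel Width in pixels of the square structuring element.
#' @param erode_iters,dilate_iters Number of erosion / dilation passes.
#' @return A `preprocess_variant` list.
#' @export
preprocess_variant <- function(variant_id,
                               threshold_mode = c("fixed", "adaptive"),
                               threshold_value = 100,
                               blur_kernel = 1L,
                               morph_kernel = 3L,
                               erode_iters = 0L,
                               dilate_iters = 0L) {
  threshold_mode <- match.arg(threshold_mode)
  threshold_value <- as.numeric(threshold_value)
  blur_kernel <- as.integer(blur_kernel)
  if (blur_kernel < 1L || blur_kernel %% 2L == 0L) abort("`blur_kernel` must be odd and >= 1")
  if (threshold_value < 0 || threshold_value > 255) abort("`threshold_value` must be in [0, 255]")
  if (morph_kernel < 1L) abort("`morph_kernel` must be >= 1")
  if (erode_iters < 0L || dilate_iters < 0L) abort("iteration counts must be >= 0")
  structure(
    list(variant_id = as.character(variant_id), threshold_mode = threshold_mode,
         threshold_value = threshold_value, blur_kernel = blur_kernel,
         morph_kernel = as.integer(morph_kernel),
         erode_iters = as.integer(erode_iters), dilate_iters = as.integer(dilate_iters)),
    class = "preprocess_variant"
  )
}

#' Default preprocessing variant family
#'
#' A deterministic, ordered list of four variants, applied first-to-last by
#' [detect_warning()]; the first variant that yields a confirmed label wins.
#' The set covers a plain dark threshold, the same threshold with blur and a
#' morphological opening (erode then dilate, removing speckle), a stricter
#' near-black threshold, and an adaptive (Otsu) threshold for images whose
#' label border is dark relative to the scene but not near-black.
#'
#' @return List of [preprocess_variant()] objects (length 4).
#' @export
default_variants <- function() {
  list(
    preprocess_variant("fixed100",       "fixed",    threshold_value = 100),
    preprocess_variant("fixed100-open",  "fixed",    threshold_value = 100,
                       blur_kernel = 3L, erode_iters = 1L, dilate_iters = 1L),
    preprocess_variant("fixed60",        "fixed",    threshold_value = 60),
    preprocess_variant("adaptive-otsu",  "adaptive")
  )
}

#' Serialize / deserialize a variant list
#'
#' Variants round-trip through a JSON file: an array of objects with keys
#' `variant_id`, `threshold_mode`, `threshold_value`, `blur_kernel`,
#' `morph_kernel`, `erode_iters`, `dilate_iters`.
#'
#' @param variants List of [preprocess_variant()] objects.
#' @param path File path to write to / read from.
#' @export
write_variants <- function(variants, path) {
  jsonlite::write_json(lapply(variants, unclass), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_variants
#' @export
read_variants <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(v) {
    preprocess_variant(v$variant_id, v$threshold_mode,
                       threshold_value = v$threshold_value,
                       blur_kernel = v$blur_kernel, morph_kernel = v$morph_kernel,
                       erode_iters = v$erode_iters, dilate_iters = v$dilate_iters)
  })
}

#' Select dark pixels
#'
#' Converts the image to grayscale and selects pixels darker than the
#' variant's cutoff: intensity strictly below `threshold_value` in fixed
#' mode, or below the Otsu threshold of the grayscale histogram in adaptive
#' mode. The result has the same dimensions as the input.
#'
#' @param img A [raster_image()].
#' @param variant A [preprocess_variant()].
#' @return A [binary_mask()].
#' @export
binarize_dark <- function(img, variant) {
  stopifnot(inherits(img, "raster_image"), inherits(variant, "preprocess_variant"))
  g <- as_gray(img)
  thr <- if (variant$threshold_mode == "fixed") {
    variant$threshold_value
  } else {
    # Otsu on the [0,1]-scaled histogram; EBImage expects x-by-y orientation
    255 * EBImage::otsu(t(g) / 255, range = c(0, 1))
  }
  binary_mask(g < thr)
}

#' Remove small noise components from a mask
#'
#' Applies the variant's blur (box blur re-binarized at 0.5) followed by
#' `erode_iters` erosions and `dilate_iters` dilations with a square
#' `morph_kernel` brush. An erode-then-dilate pass (opening) removes
#' connected specks smaller than the kernel while approximately preserving
#' larger components. With blur disabled and zero iterations the mask is
#' returned unchanged.
#'
#' @param mask A [binary_mask()].
#' @param variant A [preprocess_variant()].
#' @return A [binary_mask()] of the same dimensions.
#' @export
denoise <- function(mask, variant) {
  stopifnot(inherits(mask, "binary_mask"), inherits(variant, "preprocess_variant"))
  m <- t(mask$values)  # EBImage works x-by-y
  if (variant$blur_kernel > 1L) {
    k <- matrix(1, variant$blur_kernel, variant$blur_kernel)
    k <- k / sum(k)
    m <- (EBImage::filter2(m, k) >= 0.5) * 1L
  }
  if (variant$erode_iters > 0L || variant$dilate_iters > 0L) {
    brush <- EBImage::makeBrush(odd_size(variant$morph_kernel), shape = "box")
    for (i in seq_len(variant$erode_iters)) m <- EBImage::erode(m, brush)
    for (i in seq_len(variant$dilate_iters)) m <- EBImage::dilate(m, brush)
  }
  binary_mask(t(m))
}

# makeBrush requires odd sizes; round even kernels up
odd_size <- function(k) if (k %% 2L == 0L) k + 1L else k
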