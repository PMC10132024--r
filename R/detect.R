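#' Detector configuration
#'
#' Tunable parameters of the warning-label decision cascade.
#'
#' @param min_area Minimum contour interior area in px^2 a candidate must
#'   reach (default 600, the smallest box whose text the OCR layer can read).
#' @param max_area_fraction Maximum candidate area as a fraction of the image
#'   pixel area (default 0.5 — half the image size).
#' @param polygon_epsilon_frac Ramer-Douglas-Peucker tolerance as a fraction
#'   of the contour perimeter (default 0.03).
#' @param keyword Keyword whose presence confirms a warning (default
#'   `"warning"`; matched case-insensitively).
#' @param ocr_engine Text-recognition backend, see [ocr_backend()].
#' @param ocr_margin Pixels of context added around a candidate box before
#'   OCR (default 3).
#' @param fuzzy_keyword Accept an edit-distance-1 keyword match (default
#'   `FALSE`; fuzziness changes specificity and is off unless asked for).
#' @export
detector_config <- function(min_area = 600,
                            max_area_fraction = 0.5,
                            polygon_epsilon_frac = 0.03,
                            keyword = "warning",
                            ocr_engine = "template",
                            ocr_margin = 3L,
                            fuzzy_keyword = FALSE) {
  if (min_area <= 0) abort("`min_area` must be > 0")
  if (max_area_fraction <= 0 || max_area_fraction > 1) abort("`max_area_fraction` must be in (0, 1]")
  if (polygon_epsilon_frac <= 0 || polygon_epsilon_frac >= 0.2) abort("`polygon_epsilon_frac` must be in (0, 0.2)")
  structure(
    list(min_area = min_area, max_area_fraction = max_area_fraction,
         polygon_epsilon_frac = polygon_epsilon_frac, keyword = keyword,
         ocr_engine = ocr_engine, ocr_margin = as.integer(ocr_margin),
         fuzzy_keyword = isTRUE(fuzzy_keyword)),
    class = "detector_config"
  )
}

#' Detect a health-warning label in one image
#'
#' Runs the multi-layer cascade: for each preprocessing variant in order,
#' dark pixels are selected ([binarize_dark()]) and cleaned ([denoise()]),
#' connected contours are extracted ([extract_contours()]), kept when their
#' interior area lies in the configured band ([filter_by_area()]) and their
#' simplified outline is a convex quadrilateral ([classify_shape()]), and
#' finally confirmed by recognising the warning keyword inside the candidate
#' box ([ocr_contains_keyword()]). The first variant producing a confirmed
#' hit wins; among several confirmed candidates of one variant the
#' largest-area box (the regulatory object a viewer sees) is reported.
#' Overlapping boxes — the inner and outer edges of one thick border — are
#' deduplicated before OCR, keeping the outer box.
#'
#' The reported `area_fraction` is the bounding-box area of the detected
#' label over the image pixel area, the quantity the advertising area rule
#' is written about. Deterministic given `(img, cfg, variants)`.
#'
#' @param img A [raster_image()] (or a file path, which is loaded first).
#' @param cfg A [detector_config()].
#' @param variants Ordered list of [preprocess_variant()] objects.
#' @return A `warning_detection`: list with `found`, and when found: `bbox`,
#'   `label_area` (px^2), `area_fraction`, `placement` (`"upper"`/`"lower"`),
#'   `variant_id`, `ocr_text`.
#' @export
detect_warning <- function(img, cfg = detector_config(), variants = default_variants()) {
  if (is.character(img)) img <- load_image(img)
  stopifnot(inherits(img, "raster_image"))
  if (length(variants) < 1L) abort("need at least one preprocessing variant")
  total_area <- image_area(img)
  for (variant in variants) {
    mask <- denoise(binarize_dark(img, variant), variant)
    regions <- extract_contours(mask, min_trace_area = cfg$min_area)
    regions <- filter_by_area(regions, total_area, cfg)
    regions <- map(regions, classify_shape, cfg = cfg)
    quads <- keep(regions, function(r) isTRUE(r$is_quadrilateral))
    if (length(quads) == 0L) next
    quads <- dedupe_regions(quads)
    # OCR the largest candidates first; first confirmation is the winner
    quads <- quads[order(-map_dbl(quads, "area"))]
    for (r in quads) {
      hit <- ocr_contains_keyword(img, r$bbox, cfg)
      if (hit$found) {
        bb <- r$bbox
        box_area <- (bb[3] - bb[1]) * (bb[4] - bb[2])
        return(warning_detection(
          found = TRUE, bbox = bb, label_area = box_area,
          area_fraction = box_area / total_area,
          placement = placement_class(bb, img$height),
          variant_id = variant$variant_id, ocr_text = hit$text
        ))
      }
    }
  }
  warning_detection(found = FALSE)
}

# Drop candidates whose bbox overlaps a larger candidate's bbox by more
# than 80% of the smaller box: one label yields nested inner/outer
# quadrilaterals; the outer one is kept.
dedupe_regions <- function(regions, overlap = 0.8) {
  regions <- regions[order(-map_dbl(regions, "area"))]
  kept <- list()
  for (r in regions) {
    dup <- any(map_lgl(kept, function(k) bbox_overlap_frac(k$bbox, r$bbox) > overlap))
    if (!dup) kept <- c(kept, list(r))
  }
  kept
}

#' @rdname detect_warning
#' @param found Logical presence verdict.
#' @param bbox,label_area,area_fraction,placement,variant_id,ocr_text
#'   Geometry and provenance fields; present only when `found` is `TRUE`.
#' @export
warning_detection <- function(found, bbox = NULL, label_area = NULL,
                              area_fraction = NULL, placement = NULL,
                              variant_id = NULL, ocr_text = NULL) {
  if (!found) {
    bbox <- label_area <- area_fraction <- placement <- variant_id <- ocr_text <- NULL
  } else {
    stopifnot(!is.null(bbox), area_fraction >= 0, area_fraction <= 1)
  }
  structure(list(found = found, bbox = bbox, label_area = label_area,
                 area_fraction = area_fraction, placement = placement,
                 variant_id = variant_id, ocr_text = ocr_text),
            class = "warning_detection")
}

#' @export
print.warning_detection <- function(x, ...) {
  if (!x$found) {
    cat("<warning_detection: no label found>\n")
  } else {
    cat(sprintf("<warning_detection: %.1f%% of image, %s portion, variant '%s'>\n",
                100 * x$area_fraction, x$placement, x$variant_id))
  }
  invisible(x)
}

#' Detect warning labels across a set of images
#'
#' Maps [detect_warning()] over image files and returns one row per image,
#' sorted by path for reproducible reports.
#'
#' @param paths Character vector of image paths, or a directory (all
#'   `.png`/`.jpg`/`.jpeg` files inside are used).
#' @inheritParams detect_warning
#' @return Tibble with columns `path`, `found`, `x0`, `y0`, `x1`, `y1`,
#'   `label_area`, `area_fraction`, `placement`, `variant_id`.
#' @export
detect_warnings <- function(paths, cfg = detector_config(), variants = default_variants()) {
  paths <- expand_image_paths(paths)
  rows <- map(paths, function(p) {
    det <- detect_warning(p, cfg, variants)
    detection_row(p, det)
  })
  bind_rows(rows)
}

detection_row <- function(path, det) {
  tibble(
    path = path,
    found = det$found,
    x0 = if (det$found) det$bbox[1] else NA_real_,
    y0 = if (det$found) det$bbox[2] else NA_real_,
    x1 = if (det$found) det$bbox[3] else NA_real_,
    y1 = if (det$found) det$bbox[4] else NA_real_,
    label_area = det$label_area %||% NA_real_,
    area_fraction = det$area_fraction %||% NA_real_,
    placement = det$placement %||% NA_character_,
    variant_id = det$variant_id %||% NA_character_
  )
}

expand_image_paths <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                        full.names = TRUE)
  }
  sort(paths)
}
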