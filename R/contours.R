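#' Candidate regions from a binary mask
#'
#' Groups the selected pixels of a mask into connected components and traces
#' each component's external boundary. Hole boundaries are returned as
#' additional regions: a thick black label border forms a hollow rectangle
#' whose inner (white) rectangle must also be considered a candidate.
#'
#' Each region carries its contour (ordered boundary points, 0-based pixel
#' coordinates, top-left origin), its interior pixel area in px^2 (the filled
#' component for external boundaries, the hole itself for hole boundaries),
#' and its half-open bounding box `(x0, y0, x1, y1)`.
#'
#' @param mask A [binary_mask()].
#' @param min_trace_area Components with interior area below this are
#'   dropped before boundary tracing. The default 0 keeps everything; the
#'   detector passes its own area floor so speckle never gets traced.
#' @return A list of `candidate_region` objects (empty for an all-zero mask).
#' @export
extract_contours <- function(mask, min_trace_area = 0) {
  stopifnot(inherits(mask, "binary_mask"))
  m <- t(mask$values)  # x-by-y for EBImage
  out <- list()
  if (sum(m) > 0L) {
    lab <- EBImage::bwlabel(m)
    filled <- EBImage::fillHull(lab)
    out <- c(out, regions_from_labels(lab, area_labels = filled, hole = FALSE,
                                      min_area = min_trace_area))
  }
  # Holes: components of the complement that do not touch the image border.
  inv <- 1L - m
  if (sum(inv) > 0L) {
    labi <- EBImage::bwlabel(inv)
    border_ids <- unique(c(labi[1L, ], labi[nrow(labi), ], labi[, 1L], labi[, ncol(labi)]))
    keep_ids <- setdiff(seq_len(max(labi)), border_ids)
    if (length(keep_ids) > 0L) {
      labi[!(labi %in% keep_ids)] <- 0L
      labi <- EBImage::bwlabel(labi > 0L)
      out <- c(out, regions_from_labels(labi, area_labels = labi, hole = TRUE,
                                        min_area = min_trace_area))
    }
  }
  out
}

# Build candidate_region objects from an EBImage label matrix (x-by-y).
# `area_labels` supplies a per-label lower bound on the interior area (the
# per-object hole fill for external contours); components below `min_area`
# on that bound are discarded before the (expensive) boundary trace. Kept
# external regions then get their exact interior area from a bbox-local
# single-object fill, which also counts enclosed pixels belonging to other
# objects (text inside a label border).
regions_from_labels <- function(lab, area_labels, hole, min_area = 0) {
  n <- max(lab)
  if (n == 0L) return(list())
  areas <- tabulate(area_labels[area_labels > 0L], nbins = n)
  keep_ids <- which(areas >= min_area)
  if (length(keep_ids) == 0L) return(list())
  if (length(keep_ids) < n) {
    relab <- integer(n)
    relab[keep_ids] <- seq_along(keep_ids)
    lab[lab > 0L] <- relab[lab[lab > 0L]]
    areas <- areas[keep_ids]
  }
  contours <- EBImage::ocontour(lab)
  idx <- which(lab > 0L, arr.ind = TRUE)
  ids <- lab[lab > 0L]
  lapply(seq_along(keep_ids), function(k) {
    pts <- contours[[k]]  # 0-based (x, y)
    sub <- idx[ids == k, , drop = FALSE]
    bbox <- c(x0 = min(sub[, 1L]) - 1L, y0 = min(sub[, 2L]) - 1L,
              x1 = max(sub[, 1L]), y1 = max(sub[, 2L]))
    area <- if (hole) {
      areas[k]
    } else {
      loc <- lab[(bbox[1L] + 1L):bbox[3L], (bbox[2L] + 1L):bbox[4L], drop = FALSE]
      sum(EBImage::fillHull((loc == k) * 1L))
    }
    candidate_region(contour = pts, area = area, bbox = bbox, hole = hole)
  })
}

#' @rdname extract_contours
#' @param contour n x 2 matrix of ordered boundary points.
#' @param area Interior pixel area in px^2.
#' @param bbox Numeric `(x0, y0, x1, y1)`, half-open.
#' @param hole Whether this region is a hole (inner) boundary.
#' @export
candidate_region <- function(contour, area, bbox, hole = FALSE) {
  contour <- as.matrix(contour)
  if (area < 0) abort("region area must be >= 0")
  structure(
    list(contour = contour, area = as.numeric(area),
         bbox = as.numeric(bbox), hole = isTRUE(hole),
         vertex_count = NA_integer_, is_quadrilateral = NA),
    class = "candidate_region"
  )
}

#' @export
print.candidate_region <- function(x, ...) {
  cat(sprintf("<candidate_region area=%.0f px^2 bbox=[%g,%g)x[%g,%g)%s>\n",
              x$area, x$bbox[1], x$bbox[3], x$bbox[2], x$bbox[4],
              if (isTRUE(x$is_quadrilateral)) " quad" else ""))
  invisible(x)
}

#' Area-band filter on candidate regions
#'
#' Retains regions whose interior area lies between the detector's minimum
#' (600 px^2 by default, the smallest box whose text an OCR engine can read)
#' and half the image's pixel area; both bounds inclusive. Order preserved.
#'
#' @param regions List of `candidate_region` objects.
#' @param img_area Total image area in px^2.
#' @param cfg A [detector_config()].
#' @export
filter_by_area <- function(regions, img_area, cfg = detector_config()) {
  if (img_area <= 0) abort("`img_area` must be positive")
  max_area <- cfg$max_area_fraction * img_area
  keep(regions, function(r) r$area >= cfg$min_area && r$area <= max_area)
}

#' Quadrilateral shape test
#'
#' Simplifies the region's boundary with the Ramer-Douglas-Peucker tolerance
#' `polygon_epsilon_frac * perimeter` and marks the region a quadrilateral
#' when the simplified polygon has exactly 4 vertices and is convex.
#' Degenerate (collinear) contours are marked non-quadrilateral, not errors.
#'
#' @param region A `candidate_region`.
#' @param cfg A [detector_config()].
#' @return The region with `vertex_count` and `is_quadrilateral` populated.
#' @export
classify_shape <- function(region, cfg = detector_config()) {
  stopifnot(inherits(region, "candidate_region"))
  pts <- region$contour
  if (nrow(pts) < 3L) {
    region$vertex_count <- nrow(pts)
    region$is_quadrilateral <- FALSE
    return(region)
  }
  eps <- cfg$polygon_epsilon_frac * polygon_perimeter(pts)
  poly <- simplify_contour(pts, eps)
  region$vertex_count <- nrow(poly)
  region$is_quadrilateral <- nrow(poly) == 4L && is_convex_polygon(poly)
  region
}
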