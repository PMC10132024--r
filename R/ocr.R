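#' Text recognition backends
#'
#' The OCR confirmation layer is pluggable. Two backends ship with the
#' package:
#'
#' * `"template"` (default): a deterministic glyph matcher for the package's
#'   bundled dot-matrix font — the font the fixture generator renders with.
#'   It segments dark connected components in the crop, rescales each to the
#'   font grid, and accepts the best-matching glyph above a similarity
#'   cutoff. Valid only for that font; its virtue is bit-stable behaviour
#'   across machines, which the test-suite and audit reproducibility rely
#'   on.
#' * `"tesseract"`: shells out to a `tesseract` executable if one is on the
#'   PATH. If none is available an explicit configuration error is raised —
#'   never a silent "no text".
#'
#' @param name Backend name.
#' @return A function `(gray_matrix) -> character` recognising text in an
#'   `h x w` grayscale matrix (intensities 0-255).
#' @export
ocr_backend <- function(name = c("template", "tesseract")) {
  name <- match.arg(name)
  switch(name, template = ocr_template, tesseract = ocr_tesseract)
}

# ---- template backend -------------------------------------------------

# 8-connected component labeling of a 0/1 matrix: 4-connected labels, then
# labels touching only diagonally are merged with union-find. Needed because
# dot-matrix glyphs link their diagonal strokes corner-to-corner.
label8 <- function(m) {
  lab <- EBImage::bwlabel(m)
  n <- max(lab)
  if (n <= 1L) return(lab)
  a <- lab[-nrow(lab), -ncol(lab)]; b <- lab[-1L, -1L]
  cc <- lab[-nrow(lab), -1L]; dd <- lab[-1L, -ncol(lab)]
  pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                 cbind(as.vector(cc), as.vector(dd)))
  pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L & pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  parent <- seq_len(n)
  find_root <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(pairs))) {
    ri <- find_root(pairs[r, 1L]); rj <- find_root(pairs[r, 2L])
    if (ri != rj) parent[ri] <- rj
  }
  root <- vapply(seq_len(n), find_root, integer(1))
  new_id <- match(root, unique(root))
  out <- lab
  out[lab > 0L] <- new_id[lab[lab > 0L]]
  out
}

# Nearest-neighbour resize of a 0/1 matrix to nr x nc.
resize_binary <- function(m, nr, nc) {
  ri <- pmax(1L, ceiling(seq_len(nr) / nr * nrow(m)))
  ci <- pmax(1L, ceiling(seq_len(nc) / nc * ncol(m)))
  m[ri, ci, drop = FALSE]
}

# Tight-trimmed glyph templates, built once per session.
wl_templates <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- lapply(setNames(nm = wl_font_chars()), function(ch) {
        g <- wl_glyph_matrix(ch)
        rs <- which(rowSums(g) > 0); cs <- which(colSums(g) > 0)
        g[min(rs):max(rs), min(cs):max(cs), drop = FALSE]
      })
    }
    cache
  }
})

ocr_template <- function(gray) {
  ink <- (gray < 128) * 1L
  if (sum(ink) == 0L) return("")
  lab <- label8(t(ink))  # x-by-y
  n <- max(lab)
  if (n == 0L) return("")
  idx <- which(lab > 0L, arr.ind = TRUE)
  ids <- lab[lab > 0L]
  comps <- lapply(seq_len(n), function(k) {
    sub <- idx[ids == k, , drop = FALSE]
    x0 <- min(sub[, 1L]); x1 <- max(sub[, 1L])
    y0 <- min(sub[, 2L]); y1 <- max(sub[, 2L])
    bm <- matrix(0L, y1 - y0 + 1L, x1 - x0 + 1L)
    bm[cbind(sub[, 2L] - y0 + 1L, sub[, 1L] - x0 + 1L)] <- 1L
    list(x0 = x0, y0 = y0, w = x1 - x0 + 1L, h = y1 - y0 + 1L, bitmap = bm)
  })
  hs <- vapply(comps, `[[`, numeric(1), "h")
  med_h <- median(hs)
  # discard the label border frame (much taller than glyphs) and dust
  comps <- keep(comps, function(cc) cc$h >= 4 && cc$h <= 3 * med_h && cc$w <= 3 * med_h)
  if (length(comps) == 0L) return("")
  templates <- wl_templates()
  matched <- lapply(comps, function(cc) {
    best <- ""; best_sim <- 0
    asp_c <- cc$w / cc$h
    for (ch in names(templates)) {
      tp <- templates[[ch]]
      asp_t <- ncol(tp) / nrow(tp)
      if (asp_t / asp_c > 1.8 || asp_c / asp_t > 1.8) next
      # symmetric comparison: a glyph must match the template in both the
      # template's space and its own, or tiny templates match everything
      s1 <- mean(resize_binary(cc$bitmap, nrow(tp), ncol(tp)) == tp)
      s2 <- mean(resize_binary(tp, nrow(cc$bitmap), ncol(cc$bitmap)) == cc$bitmap)
      sim <- min(s1, s2)
      if (sim > best_sim) { best_sim <- sim; best <- ch }
    }
    c(cc, list(char = best, sim = best_sim))
  })
  matched <- keep(matched, function(m) m$sim >= 0.85)
  if (length(matched) == 0L) return("")
  # assemble lines: cluster on vertical centers, then sort by x
  yc <- vapply(matched, function(m) m$y0 + m$h / 2, numeric(1))
  ord <- order(yc)
  matched <- matched[ord]; yc <- yc[ord]
  line_id <- cumsum(c(1, diff(yc) > med_h * 0.7))
  glyph_w <- median(vapply(matched, `[[`, numeric(1), "w"))
  lines <- vapply(split(matched, line_id), function(row) {
    xs <- vapply(row, `[[`, numeric(1), "x0")
    row <- row[order(xs)]
    out <- ""
    prev_end <- NULL
    for (m in row) {
      if (!is.null(prev_end) && (m$x0 - prev_end) > 0.55 * glyph_w) {
        out <- paste0(out, " ")
      }
      out <- paste0(out, m$char)
      prev_end <- m$x0 + m$w
    }
    out
  }, character(1))
  paste(lines, collapse = "\n")
}

# ---- tesseract backend ------------------------------------------------

ocr_tesseract <- function(gray) {
  exe <- Sys.which("tesseract")
  if (!nzchar(exe)) {
    abort(paste0(
      "No 'tesseract' executable found on the PATH. Install the Tesseract ",
      "OCR engine and ensure it is on the PATH, or use the 'template' ",
      "backend (valid for the bundled fixture font only)."
    ), class = "warnscan_ocr_unavailable")
  }
  tmp_png <- tempfile(fileext = ".png")
  tmp_out <- tempfile()
  on.exit(unlink(c(tmp_png, paste0(tmp_out, ".txt"))), add = TRUE)
  png::writePNG(gray / 255, tmp_png)
  status <- system2(exe, c(tmp_png, tmp_out), stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(paste0(tmp_out, ".txt"))) {
    abort("tesseract invocation failed", class = "warnscan_ocr_unavailable")
  }
  paste(readLines(paste0(tmp_out, ".txt"), warn = FALSE), collapse = "\n")
}

# ---- keyword confirmation --------------------------------------------

#' Confirm the warning keyword inside a region
#'
#' Crops the bounding box (expanded by a small margin, clipped to the image),
#' runs the configured text-recognition backend on the grayscale crop, and
#' tests whether the recognised text contains the keyword as a
#' case-insensitive substring after whitespace normalisation. With
#' `cfg$fuzzy_keyword = TRUE` a single-character mismatch (edit distance 1)
#' is also accepted.
#'
#' @param img A [raster_image()].
#' @param bbox Half-open `(x0, y0, x1, y1)` in pixels, within image bounds.
#' @param cfg A [detector_config()].
#' @return List with `found` (logical) and `text` (raw recognised text).
#' @export
ocr_contains_keyword <- function(img, bbox, cfg = detector_config()) {
  stopifnot(inherits(img, "raster_image"))
  if (bbox[1] < 0 || bbox[2] < 0 || bbox[3] > img$width || bbox[4] > img$height ||
      bbox[3] <= bbox[1] || bbox[4] <= bbox[2]) {
    abort("`bbox` must be a non-empty box within the image bounds")
  }
  margin <- cfg$ocr_margin
  x0 <- max(0, floor(bbox[1]) - margin); x1 <- min(img$width, ceiling(bbox[3]) + margin)
  y0 <- max(0, floor(bbox[2]) - margin); y1 <- min(img$height, ceiling(bbox[4]) + margin)
  g <- as_gray(img)[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
  text <- ocr_backend(cfg$ocr_engine)(g)
  norm <- tolower(gsub("\\s+", " ", text))
  kw <- tolower(cfg$keyword)
  found <- grepl(kw, norm, fixed = TRUE)
  if (!found && isTRUE(cfg$fuzzy_keyword)) {
    found <- agrepl(kw, norm, max.distance = 1, fixed = TRUE)
  }
  list(found = found, text = text)
}
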