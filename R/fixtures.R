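#' Render a boxed health-warning label
#'
#' Draws the canonical advertising warning: a white rectangle with a black
#' border of the requested thickness and black text beginning with the
#' warning keyword, typeset in the package's bundled dot-matrix font. The
#' text is word-wrapped and scaled to the largest integer glyph scale that
#' fits; glyphs render at 14 px height or more so the OCR layer can read
#' them. Deterministic given its inputs.
#'
#' @param text Warning statement (rendered in upper case).
#' @param width_px,height_px Outer label dimensions in pixels.
#' @param border_px Border thickness in pixels (>= 2).
#' @return A 1-channel [raster_image()].
#' @export
render_label <- function(text = wl_default_warning_text(),
                         width_px, height_px, border_px = 6L) {
  border_px <- as.integer(border_px)
  if (border_px < 2L) abort("`border_px` must be >= 2")
  pad <- max(4L, border_px)
  inner_w <- width_px - 2L * (border_px + pad)
  inner_h <- height_px - 2L * (border_px + pad)
  if (inner_w < 10L || inner_h < 10L) abort("label box too small for any text")
  fit <- NULL
  for (s in rev(seq(2L, 10L))) {
    lines <- wl_wrap_text(text, max_cells = floor(inner_w / s))
    widest <- max(vapply(toupper(lines), wl_line_cells, integer(1)))
    text_h <- (length(lines) * WL_GLYPH_H + (length(lines) - 1L) * 3L) * s
    if (widest * s <= inner_w && text_h <= inner_h) { fit <- list(scale = s, lines = lines); break }
  }
  if (is.null(fit)) {
    abort("label box too small to typeset the text legibly (glyphs need >= 14 px height)")
  }
  canvas <- matrix(255, height_px, width_px)
  canvas[c(seq_len(border_px), height_px - border_px + seq_len(border_px)), ] <- 0
  canvas[, c(seq_len(border_px), width_px - border_px + seq_len(border_px))] <- 0
  ink <- wl_render_text(fit$lines, scale = fit$scale)
  oy <- border_px + pad + (inner_h - nrow(ink)) %/% 2L
  ox <- border_px + pad + (inner_w - ncol(ink)) %/% 2L
  region <- canvas[oy + seq_len(nrow(ink)), ox + seq_len(ncol(ink))]
  region[ink == 1L] <- 0
  canvas[oy + seq_len(nrow(ink)), ox + seq_len(ncol(ink))] <- region
  raster_image(canvas)
}

#' @rdname render_label
#' @export
wl_default_warning_text <- function() {
  "WARNING: Cigar smoking can cause cancers of the mouth and throat, even if you do not inhale."
}

#' Generate a seeded synthetic post corpus with ground truth
#'
#' Writes `n` PNG images emulating social-media promotional posts — varied
#' light-to-mid-dark backgrounds (flat, vertical gradient, speckle noise,
#' blotchy texture), an exact `round(n * prevalence)` of them carrying a
#' black-bordered warning label at a randomised size and position — plus a
#' truth manifest. Degraded variants reproduce the known detector failure
#' modes: `blur` (Gaussian-blurred label, unreadable text) and `shrink`
#' (label rendered then down-scaled, so its text — and for small base sizes
#' its contour area — drops below what the cascade can confirm). A fraction
#' of the unlabelled images carry a black-bordered decoy box with non-warning
#' text, exercising the OCR rejection path rather than only blank negatives.
#' Fully reproducible from the argument set.
#'
#' @param n Number of images.
#' @param prevalence Fraction of images carrying a true label.
#' @param degrade_mix Named fractions over `c("none", "blur", "shrink")`
#'   applied to the labelled images; defaults to all clean.
#' @param seed Integer seed.
#' @param dir Output directory (created if missing).
#' @param image_size `(width, height)` in pixels.
#' @param label_frac_range Range the label's target area fraction is drawn
#'   from (before any shrink).
#' @param aspect_range Range of label width:height ratios.
#' @param border_px Label border thickness.
#' @param blur_sigma Gaussian sigma for the `blur` degrade.
#' @param shrink_scale Linear scale of the `shrink` degrade.
#' @param decoy_frac Fraction of unlabelled images given a non-warning boxed
#'   caption.
#' @param text Warning statement to render.
#' @return The truth manifest as a tibble (also written to
#'   `dir/manifest.csv`): `path`, `has_label`, `x0`, `y0`, `x1`, `y1`,
#'   `area_fraction`, `placement`, `degrade`, `seed`.
#' @export
generate_corpus <- function(n, prevalence, degrade_mix = c(none = 1),
                            seed = 1L, dir = tempfile("corpus"),
                            image_size = c(800L, 800L),
                            label_frac_range = c(0.05, 0.35),
                            aspect_range = c(2.5, 4),
                            border_px = 6L,
                            blur_sigma = 3,
                            shrink_scale = 0.2,
                            decoy_frac = 0.25,
                            text = wl_default_warning_text()) {
  if (prevalence < 0 || prevalence > 1) abort("`prevalence` must be in [0, 1]")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) abort(sprintf("cannot create output directory '%s'", dir))
  degrade_mix <- degrade_mix / sum(degrade_mix)
  W <- as.integer(image_size[1]); H <- as.integer(image_size[2])
  n_label <- round(n * prevalence)
  with_preserved_rng({
    set.seed(seed)
    labelled <- sort(sample.int(n, n_label))
    tags <- sample(rep(names(degrade_mix),
                       times = diff(round(cumsum(c(0, degrade_mix)) * n_label))))
    decoys <- runif(n) < decoy_frac
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      arr <- wl_background(W, H)
      path <- file.path(dir, sprintf("post_%04d.png", i))
      li <- match(i, labelled)
      if (!is.na(li)) {
        g <- wl_place_label(arr, tags[li], text, label_frac_range, aspect_range,
                            border_px, blur_sigma, shrink_scale)
        arr <- g$arr
        rows[[i]] <- tibble(path = path, has_label = TRUE,
                            x0 = g$bbox[1], y0 = g$bbox[2], x1 = g$bbox[3], y1 = g$bbox[4],
                            area_fraction = g$area_fraction,
                            placement = placement_class(g$bbox, H),
                            degrade = tags[li], seed = seed)
      } else {
        if (decoys[i]) {
          g <- wl_place_label(arr, "none", wl_decoy_text(), c(0.04, 0.12),
                              aspect_range, border_px, blur_sigma, shrink_scale)
          arr <- g$arr
        }
        rows[[i]] <- tibble(path = path, has_label = FALSE,
                            x0 = NA_real_, y0 = NA_real_, x1 = NA_real_, y1 = NA_real_,
                            area_fraction = NA_real_, placement = NA_character_,
                            degrade = "none", seed = seed)
      }
      png::writePNG(arr / 255, path)
    }
  })
  manifest <- bind_rows(rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}

wl_decoy_text <- function() "LIMITED EDITION DROP - LINK IN BIO"

# Small boxes carry abbreviated statements, as real labels do: fall back to
# progressively shorter text until it typesets, erroring only if even the
# bare keyword cannot fit.
render_label_fitting <- function(text, w, h, border_px) {
  candidates <- unique(c(text, "WARNING: TOBACCO SMOKE HARMS YOU",
                         "WARNING: SMOKE HARMS", "WARNING"))
  for (cand in candidates) {
    out <- tryCatch(render_label(cand, w, h, border_px), error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  abort(sprintf("label box %dx%d too small even for the bare keyword", w, h))
}

# Random post-like background, h x w x 3 in [0, 255].
wl_background <- function(W, H) {
  kind <- sample(c("flat", "gradient", "noise", "texture"), 1L)
  base <- switch(kind,
    flat = matrix(runif(1, 150, 240), H, W),
    gradient = matrix(rep(seq(runif(1, 120, 200), runif(1, 180, 245), length.out = H), W), H, W),
    noise = {
      m <- matrix(runif(1, 140, 215), H, W) + matrix(runif(W * H, -35, 35), H, W)
      pmin(245, pmax(90, m))
    },
    texture = {
      coarse <- matrix(runif(64, 115, 230), 8, 8)
      fine <- EBImage::resize(t(coarse) / 255, w = W, h = H) * 255
      pmin(245, pmax(95, t(fine)))
    }
  )
  tint <- runif(3, 0.8, 1)
  arr <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) arr[, , ch] <- base * tint[ch]
  arr
}

# Render, optionally degrade, and composite one label onto `arr`.
wl_place_label <- function(arr, tag, text, frac_range, aspect_range,
                           border_px, blur_sigma, shrink_scale) {
  H <- dim(arr)[1]; W <- dim(arr)[2]
  f <- runif(1, frac_range[1], frac_range[2])
  a <- runif(1, aspect_range[1], aspect_range[2])
  w <- round(sqrt(f * W * H * a)); h <- round(sqrt(f * W * H / a))
  # floor at the smallest box that typesets the bare keyword legibly
  w <- max(w, 112L); h <- max(h, 42L)
  w <- min(w, W - 24L); h <- min(h, round(H / 2) - 24L)
  lab <- as_gray(render_label_fitting(text, w, h, border_px))
  if (tag == "blur") {
    lab <- t(EBImage::gblur(t(lab) / 255, sigma = blur_sigma)) * 255
  } else if (tag == "shrink") {
    lab <- t(EBImage::resize(t(lab) / 255, w = max(8L, round(w * shrink_scale)),
                             h = max(4L, round(h * shrink_scale)))) * 255
    h <- nrow(lab); w <- ncol(lab)
  }
  upper <- runif(1) < 0.5
  x0 <- round(runif(1, 8, max(9, W - w - 8)))
  y_up_max <- floor((H - h) / 2) - 2L
  y0 <- if (upper && y_up_max > 8L) {
    round(runif(1, 8, y_up_max))
  } else {
    round(runif(1, min(ceiling((H - h) / 2) + 2L, H - h - 8L), H - h - 8L))
  }
  for (ch in 1:3) arr[y0 + seq_len(h), x0 + seq_len(w), ch] <- lab
  list(arr = arr,
       bbox = c(x0, y0, x0 + w, y0 + h),
       area_fraction = (w * h) / (W * H))
}

# Evaluate `code` without disturbing the caller's RNG stream.
with_preserved_rng <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}
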