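# Shared fixture builders: everything is generated in code at test time.

# Grayscale raster with a filled dark rectangle on white; bbox is 0-based
# half-open (x0, y0, x1, y1).
rect_image <- function(W = 100, H = 100, bbox = c(10, 10, 40, 30),
                       fg = 0, bg = 255) {
  m <- matrix(bg, H, W)
  m[(bbox[2] + 1):bbox[4], (bbox[1] + 1):bbox[3]] <- fg
  raster_image(m)
}

rect_mask <- function(W = 100, H = 100, bbox = c(10, 10, 40, 30)) {
  m <- matrix(0L, H, W)
  m[(bbox[2] + 1):bbox[4], (bbox[1] + 1):bbox[3]] <- 1L
  binary_mask(m)
}

# A candidate region with the given area and a minimal square contour;
# enough for area-filter logic, which only reads `area`.
fake_region <- function(area) {
  s <- sqrt(area)
  candidate_region(contour = rbind(c(0, 0), c(s, 0), c(s, s), c(0, s)),
                   area = area, bbox = c(0, 0, s, s))
}

# Densely sampled boundary of a rectangle rotated by `angle_deg` around its
# center, ordered around the perimeter.
rotated_rect_contour <- function(cx = 50, cy = 50, w = 60, h = 30,
                                 angle_deg = 0, pts_per_edge = 40) {
  corners <- rbind(c(-w / 2, -h / 2), c(w / 2, -h / 2),
                   c(w / 2, h / 2), c(-w / 2, h / 2))
  edges <- lapply(1:4, function(i) {
    a <- corners[i, ]; b <- corners[if (i == 4) 1 else i + 1, ]
    t <- seq(0, 1, length.out = pts_per_edge + 1)[-(pts_per_edge + 1)]
    cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  })
  pts <- do.call(rbind, edges)
  th <- angle_deg * pi / 180
  rot <- cbind(pts[, 1] * cos(th) - pts[, 2] * sin(th),
               pts[, 1] * sin(th) + pts[, 2] * cos(th))
  cbind(rot[, 1] + cx, rot[, 2] + cy)
}

circle_contour <- function(cx = 50, cy = 50, r = 50, n = 200) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# A post-like image with one rendered warning label at a known bbox.
# Returns list(img, bbox, area_fraction).
labelled_post <- function(W = 400, H = 400, label_w = 220, label_h = 90,
                          x0 = 40, y0 = 40, bg = 210,
                          text = "WARNING: TOBACCO SMOKE HARMS") {
  m <- matrix(bg, H, W)
  lab <- as_gray(render_label(text, label_w, label_h, border_px = 4))
  m[y0 + seq_len(label_h), x0 + seq_len(label_w)] <- lab
  list(img = raster_image(m),
       bbox = c(x0, y0, x0 + label_w, y0 + label_h),
       area_fraction = (label_w * label_h) / (W * H))
}

# Compliance results built directly, bypassing detection: a quick way to
# assemble a corpus with known counts.
make_result <- function(has_warning, area_fraction = NA, placement = NA) {
  det <- if (has_warning) {
    list(found = TRUE, area_fraction = area_fraction, placement = placement)
  } else {
    list(found = FALSE)
  }
  evaluate_compliance(det)
}

# Corpus of compliance results with exact counts in each cell.
composed_audit_results <- function(n_total, n_warning, n_area, n_upper, n_full) {
  res <- list()
  # fully compliant: area >= .2 and upper
  for (i in seq_len(n_full)) res <- c(res, list(make_result(TRUE, 0.25, "upper")))
  # meets area only
  for (i in seq_len(n_area - n_full)) res <- c(res, list(make_result(TRUE, 0.25, "lower")))
  # upper only
  for (i in seq_len(n_upper - n_full)) res <- c(res, list(make_result(TRUE, 0.10, "upper")))
  # warning but neither rule
  n_rest <- n_warning - length(res)
  for (i in seq_len(n_rest)) res <- c(res, list(make_result(TRUE, 0.05, "lower")))
  # no warning
  for (i in seq_len(n_total - n_warning)) res <- c(res, list(make_result(FALSE)))
  res
}
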