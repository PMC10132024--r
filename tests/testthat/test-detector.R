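test_that("extract_contours finds components with exact area and bbox", {
  mask <- rect_mask(100, 80, bbox = c(10, 20, 40, 40))  # 30 x 20
  regions <- extract_contours(mask)
  expect_length(regions, 1)
  expect_equal(regions[[1]]$area, 600)
  expect_equal(regions[[1]]$bbox, c(10, 20, 40, 40))

  two <- matrix(0L, 60, 60)
  two[5:14, 5:14] <- 1L; two[40:55, 30:50] <- 1L
  expect_length(extract_contours(binary_mask(two)), 2)

  expect_identical(extract_contours(binary_mask(matrix(0L, 10, 10))), list())
})

test_that("hollow borders yield both the filled outer region and the hole", {
  m <- matrix(0L, 100, 100)
  m[21:60, 11:70] <- 1L       # 60 wide x 40 tall block
  m[26:55, 16:65] <- 0L       # hollowed: border 5 px thick
  regions <- extract_contours(binary_mask(m))
  expect_length(regions, 2)
  holes <- vapply(regions, function(r) r$hole, logical(1))
  outer <- regions[[which(!holes)]]
  inner <- regions[[which(holes)]]
  expect_equal(outer$area, 60 * 40)   # hole-filled interior area
  expect_equal(inner$area, 50 * 30)
  expect_equal(inner$bbox, c(15, 25, 65, 55))
})

test_that("filter_by_area applies the inclusive 600 / half-image band", {
  cfg <- detector_config()
  img_area <- 1000 * 1000
  keep_areas <- function(areas) {
    kept <- filter_by_area(lapply(areas, fake_region), img_area, cfg)
    vapply(kept, function(r) r$area, numeric(1))
  }
  expect_equal(keep_areas(c(599, 600, 601)), c(600, 601))
  expect_equal(keep_areas(c(500000, 500001)), 500000)
  expect_equal(keep_areas(c(100, 550000)), numeric(0))
})

test_that("filter_by_area output is an order-preserving subset and idempotent", {
  cfg <- detector_config()
  set.seed(1)
  for (trial in 1:20) {
    areas <- round(runif(30, 0, 1500))
    regions <- lapply(areas, fake_region)
    out <- filter_by_area(regions, 2000, cfg)
    out_areas <- vapply(out, function(r) r$area, numeric(1))
    # subset, in order
    expect_true(all(out_areas %in% areas))
    expect_equal(out_areas, areas[areas >= 600 & areas <= 1000])
    # idempotent
    expect_identical(filter_by_area(out, 2000, cfg), out)
  }
})

test_that("classify_shape recognises rectangles, including rotated ones", {
  cfg <- detector_config()
  r0 <- candidate_region(rotated_rect_contour(angle_deg = 0), area = 1800,
                         bbox = c(20, 35, 80, 65))
  expect_true(classify_shape(r0, cfg)$is_quadrilateral)
  expect_equal(classify_shape(r0, cfg)$vertex_count, 4)

  r10 <- candidate_region(rotated_rect_contour(angle_deg = 10), area = 1800,
                          bbox = c(0, 0, 100, 100))
  expect_true(classify_shape(r10, cfg)$is_quadrilateral)
})

test_that("classify_shape rejects circles and degenerate contours", {
  cfg <- detector_config()
  circ <- candidate_region(circle_contour(r = 50), area = pi * 50^2,
                           bbox = c(0, 0, 100, 100))
  out <- classify_shape(circ, cfg)
  expect_false(out$is_quadrilateral)
  expect_gt(out$vertex_count, 4)

  line <- candidate_region(cbind(seq(0, 10), seq(0, 10)), area = 0,
                           bbox = c(0, 0, 10, 10))
  expect_false(classify_shape(line, cfg)$is_quadrilateral)
})

test_that("ocr_contains_keyword confirms rendered warnings and rejects others", {
  cfg <- detector_config()
  post <- labelled_post()
  hit <- ocr_contains_keyword(post$img, post$bbox, cfg)
  expect_true(hit$found)
  expect_match(hit$text, "WARNING", fixed = TRUE)

  blank <- raster_image(matrix(255, 100, 100))
  miss <- ocr_contains_keyword(blank, c(10, 10, 90, 90), cfg)
  expect_false(miss$found)
  expect_equal(gsub("\\s", "", miss$text), "")

  winning <- labelled_post(text = "WINNING NUMBERS INSIDE")
  expect_false(ocr_contains_keyword(winning$img, winning$bbox, cfg)$found)
})

test_that("ocr_contains_keyword validates the bbox", {
  img <- raster_image(matrix(255, 50, 50))
  expect_error(ocr_contains_keyword(img, c(-1, 0, 10, 10)), "bounds")
  expect_error(ocr_contains_keyword(img, c(0, 0, 60, 10)), "bounds")
  expect_error(ocr_contains_keyword(img, c(10, 10, 10, 20)), "bounds")
})

test_that("tesseract backend raises a configuration error when absent", {
  if (Sys.which("tesseract") == "") {
    expect_error(
      ocr_backend("tesseract")(matrix(255, 20, 20)),
      class = "warnscan_ocr_unavailable"
    )
  } else {
    expect_type(ocr_backend("tesseract")(matrix(255, 20, 20)), "character")
  }
})

test_that("detect_warning finds a clean label with accurate geometry", {
  post <- labelled_post(W = 400, H = 400, label_w = 280, label_h = 140,
                        x0 = 50, y0 = 20)  # 28% of area, upper half
  det <- detect_warning(post$img)
  expect_true(det$found)
  expect_equal(det$placement, "upper")
  expect_lt(abs(det$area_fraction - post$area_fraction) / post$area_fraction, 0.10)
  expect_match(det$ocr_text, "WARNING", fixed = TRUE)
})

test_that("detect_warning returns found=false on negatives with empty geometry", {
  neg <- raster_image(matrix(200, 300, 300))
  det <- detect_warning(neg)
  expect_false(det$found)
  expect_null(det$bbox)
  expect_null(det$area_fraction)
  expect_null(det$placement)
})

test_that("labels below the minimum area are designed misses", {
  # label well under 600 px^2 total: the area band rejects it
  m <- matrix(210, 300, 300)
  m[141:160, 141:168] <- 0  # 20 x 28 dark box, 560 px^2
  det <- detect_warning(raster_image(m))
  expect_false(det$found)
})

test_that("removing variants never converts a miss into a detection", {
  full <- default_variants()
  post <- labelled_post()
  neg <- raster_image(matrix(180, 200, 200))
  for (img in list(post$img, neg)) {
    with_full <- detect_warning(img, variants = full)$found
    for (drop in seq_along(full)) {
      with_less <- detect_warning(img, variants = full[-drop])$found
      if (!with_full) expect_false(with_less)
    }
  }
})

test_that("detection is deterministic", {
  post <- labelled_post(bg = 190)
  d1 <- detect_warning(post$img)
  d2 <- detect_warning(post$img)
  expect_identical(d1, d2)
})

test_that("nested border contours are deduplicated to one detection", {
  post <- labelled_post(W = 400, H = 400, label_w = 260, label_h = 120,
                        x0 = 60, y0 = 240)
  det <- detect_warning(post$img)
  expect_true(det$found)
  # the reported box is the outer border box, not the inner hole
  expect_equal(det$bbox[1], post$bbox[1], tolerance = 3)
  expect_equal(det$bbox[3], post$bbox[3], tolerance = 3)
  expect_equal(det$placement, "lower")
})
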