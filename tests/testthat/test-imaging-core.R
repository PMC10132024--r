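test_that("load_image decodes PNG and JPEG with correct dimensions", {
  p <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(1, 10, 10), p)
  img <- load_image(p)
  expect_s3_class(img, "raster_image")
  expect_equal(c(img$width, img$height), c(10, 10))
  expect_equal(image_area(img), 100)
  expect_equal(img$channels, 1)

  # 3-channel stays 3-channel; alpha is dropped
  p3 <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(runif(8 * 6 * 4), dim = c(6, 8, 4)), p3)
  img3 <- load_image(p3)
  expect_equal(img3$channels, 3)
  expect_equal(c(img3$width, img3$height), c(8, 6))

  pj <- withr::local_tempfile(fileext = ".jpg")
  jpeg::writeJPEG(array(0.5, dim = c(5, 7, 3)), pj)
  expect_equal(load_image(pj)$width, 7)
})

test_that("load_image errors name the path on unreadable input", {
  p <- withr::local_tempfile(fileext = ".png")
  writeLines("not a png", p)
  expect_error(load_image(p), "decode.*\\.png")
  expect_error(load_image("does-not-exist.png"), "does-not-exist")
  pt <- withr::local_tempfile(fileext = ".txt")
  writeLines("x", pt)
  expect_error(load_image(pt), "unsupported")
})

test_that("loaded fixture dimensions match the generator manifest", {
  d <- withr::local_tempdir()
  manifest <- generate_corpus(2, prevalence = 0.5, seed = 11, dir = d,
                              image_size = c(300, 240))
  for (p in manifest$path) {
    img <- load_image(p)
    expect_equal(c(img$width, img$height), c(300, 240))
  }
})

test_that("binarize_dark selects exactly the sub-threshold pixels", {
  v <- preprocess_variant("t", "fixed", threshold_value = 128)
  black <- raster_image(matrix(0, 8, 8))
  white <- raster_image(matrix(255, 8, 8))
  expect_equal(sum(binarize_dark(black, v)$values), 64)
  expect_equal(sum(binarize_dark(white, v)$values), 0)

  half <- matrix(255, 10, 10); half[, 1:5] <- 0
  mask <- binarize_dark(raster_image(half), v)
  expect_equal(sum(mask$values), 50)
  expect_equal(unname(mask$values[, 1:5]), matrix(1L, 10, 5))
})

test_that("adaptive thresholding separates a bimodal image", {
  v <- preprocess_variant("otsu", "adaptive")
  m <- matrix(200, 20, 20); m[1:10, ] <- 30
  mask <- binarize_dark(raster_image(m), v)
  expect_equal(sum(mask$values), 200)
  expect_true(all(mask$values[1:10, ] == 1L))
})

test_that("binarize_dark is idempotent in effect", {
  v <- preprocess_variant("t", "fixed", threshold_value = 128)
  m <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  mask1 <- binarize_dark(raster_image(m), v)
  rendered <- raster_image((1L - mask1$values) * 255)  # selected pixels as black
  mask2 <- binarize_dark(rendered, v)
  expect_identical(mask1$values, mask2$values)
})

test_that("denoise removes sub-kernel specks and is identity when disabled", {
  sp <- matrix(0L, 20, 20); sp[5, 5] <- 1L
  v_open <- preprocess_variant("o", "fixed", erode_iters = 1, dilate_iters = 1)
  expect_equal(sum(denoise(binary_mask(sp), v_open)$values), 0)

  v_id <- preprocess_variant("id", "fixed")  # no blur, no morphology
  m <- matrix(rbinom(400, 1, 0.3), 20, 20)
  expect_identical(denoise(binary_mask(m), v_id)$values, binary_mask(m)$values)
})

test_that("morphological opening approximately preserves a large block", {
  big <- matrix(0L, 80, 80); big[11:60, 11:60] <- 1L  # 50x50 block
  v <- preprocess_variant("o", "fixed", erode_iters = 1, dilate_iters = 1)
  out <- denoise(binary_mask(big), v)
  expect_true(all(out$values %in% c(0L, 1L)))
  expect_lt(abs(sum(out$values) - 2500) / 2500, 0.04)
})

test_that("pure erosion never grows the selected set", {
  v <- preprocess_variant("e", "fixed", erode_iters = 1, dilate_iters = 0)
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(rbinom(900, 1, 0.4), 30, 30)
    out <- denoise(binary_mask(m), v)
    expect_lte(sum(out$values), sum(m))
    expect_true(all(out$values %in% c(0L, 1L)))
  }
})

test_that("default_variants is deterministic, valid, and covers the documented set", {
  a <- default_variants(); b <- default_variants()
  expect_identical(a, b)
  expect_gte(length(a), 3)
  for (v in a) {
    expect_s3_class(v, "preprocess_variant")
    expect_true(v$blur_kernel %% 2 == 1)
  }
  modes <- vapply(a, function(v) v$threshold_mode, character(1))
  blurs <- vapply(a, function(v) v$blur_kernel, integer(1))
  opens <- vapply(a, function(v) v$erode_iters > 0 && v$dilate_iters > 0, logical(1))
  expect_true(any(modes == "fixed" & blurs == 1))       # plain fixed threshold
  expect_true(any(modes == "fixed" & blurs > 1 & opens)) # fixed + blur + open
  expect_true(any(modes == "adaptive"))                  # adaptive
})

test_that("variant lists round-trip through JSON", {
  p <- withr::local_tempfile(fileext = ".json")
  write_variants(default_variants(), p)
  expect_identical(read_variants(p), default_variants())
})

test_that("invalid variants and images are rejected", {
  expect_error(preprocess_variant("x", "fixed", blur_kernel = 2), "odd")
  expect_error(preprocess_variant("x", "fixed", erode_iters = -1), ">= 0")
  expect_error(preprocess_variant("x", "fixed", threshold_value = 300), "0, 255")
  expect_error(raster_image(matrix(300, 2, 2)), "0, 255")
  expect_error(raster_image(array(1, c(2, 2, 5))), "channels")
  expect_error(binary_mask(matrix(2, 2, 2)), "0/1")
})
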