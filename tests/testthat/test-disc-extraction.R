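test_that("right-half crop keeps the half-open column range", {
  # coordinate-coded raster: value encodes the source column
  px <- array(0L, c(8, 512, 3))
  for (k in 1:3) px[, , k] <- matrix(rep(0:511 %% 256, each = 8), 8, 512)
  storage.mode(px) <- "integer"
  half <- crop_right_half(fundus_image(px))
  expect_identical(dim(pixels(half)), c(8L, 256L, 3L))
  expect_identical(half$meta$col_offset, 256)
  # pixel (r, 256) of the input (0-based) is pixel (r, 0) of the output
  expect_identical(pixels(half)[3, 1, 1], px[3, 257, 1])
  expect_identical(pixels(half)[5, 256, 2], px[5, 512, 2])

  two <- fundus_image(array(c(1L, 2L), c(1, 2, 3)))
  one <- crop_right_half(two)
  expect_identical(dim(pixels(one))[2], 1L)
  expect_identical(pixels(one)[1, 1, 1], pixels(two)[1, 2, 1])
})

test_that("brightness mask selects exactly the top share on distinct values", {
  # 1000 pixels with strictly increasing CIELab L: G coarse, B fine
  idx <- 0:999
  px <- array(0L, c(40, 25, 3))
  px[, , 2] <- matrix(idx %/% 5, 40, 25)
  px[, , 3] <- matrix(idx %% 5, 40, 25)
  m <- brightness_top_mask(fundus_image(px), disc_params(top_percent = 3.5))
  expect_identical(sum(pixels(m)), 35L)  # sort-and-count oracle: 3.5% of 1000
  # the selected pixels are precisely the 35 largest indices
  expect_true(all(which(pixels(m) == 1L) %in% which(matrix(idx, 40, 25) >= 965)))
})

test_that("brightness mask count law holds within quantisation", {
  for (seed in 1:5) {
    img <- fundus_image(random_rgb_raster(64, 64, seed))
    L <- fundustruct:::rgb_to_lab(pixels(img))[, , 1]
    p <- c(1, 3.5, 10)[1 + seed %% 3]
    m <- brightness_top_mask(img, disc_params(top_percent = p))
    k <- ceiling(p / 100 * length(L))
    thr <- sort(as.numeric(L), decreasing = TRUE)[k]
    expect_identical(sum(pixels(m)), sum(L >= thr))  # independent sort oracle
    expect_gte(sum(pixels(m)), k)  # ties only ever add pixels
  }
})

test_that("a constant image ties everywhere and selects every pixel", {
  m <- brightness_top_mask(flat_rgb(16, 16, c(90, 90, 90)))
  expect_true(all(pixels(m) == 1L))
})

test_that("the Hough detector recovers a clean filled circle", {
  mk <- matrix(0L, 256, 200)
  rr <- row(mk); cc <- col(mk)
  mk[(rr - 120)^2 + (cc - 100)^2 <= 30^2] <- 1L
  ci <- detect_disc_circle(binary_mask(mk, "brightness-mask"))
  expect_identical(ci$source, "hough")
  expect_lte(abs(ci$center_row - 120), 5)
  expect_lte(abs(ci$center_col - 100), 5)
  expect_lte(abs(ci$radius_detected - 30), 5)
  expect_equal(ci$radius, ci$radius_detected + 40)  # extension contract
})

test_that("an empty mask raises a detection error", {
  expect_error(detect_disc_circle(binary_mask(matrix(0L, 64, 64),
                                              "brightness-mask")),
               "no bright pixels", class = "fundustruct_detection_error")
})

test_that("a sparse blob defeats the Hough stage and falls back to centroid", {
  set.seed(8)
  mk <- matrix(0L, 200, 200)
  mk[cbind(sample(200, 20), sample(200, 20))] <- 1L
  ci <- detect_disc_circle(binary_mask(mk, "brightness-mask"))
  expect_identical(ci$source, "centroid-fallback")
  expect_equal(ci$radius, sqrt(20 / pi) + 40, tolerance = 1e-6)
})

test_that("blackout outside the circle is exhaustive and invertible cases hold", {
  img <- crop_right_half(cached_phantom("glaucoma", 502)$image)
  circle <- structure(list(center_row = 120, center_col = 90, radius = 55),
                      class = "disc_circle")
  out <- pixels(blackout_outside_circle(img, circle))
  d2 <- outer((seq_len(dim(out)[1]) - 120)^2,
              (seq_len(dim(out)[2]) - 90)^2, "+")
  outside <- d2 > 55^2
  for (k in 1:3) {
    expect_true(all(out[, , k][outside] == 0L))
    expect_identical(out[, , k][!outside], pixels(img)[, , k][!outside])
  }
  # a circle covering the whole raster leaves the image untouched
  big <- structure(list(center_row = 128, center_col = 128, radius = 1e4),
                   class = "disc_circle")
  expect_identical(pixels(blackout_outside_circle(img, big)), pixels(img))
})

test_that("disc extraction returns a 64 x 64 grey crop with geometry attached", {
  ph <- cached_phantom("normal", 503)
  out <- extract_disc_region(ph$image)
  expect_s3_class(out, "gray_image")
  expect_identical(dim(pixels(out)), c(64L, 64L))
  ci <- attr(out, "circle")
  expect_s3_class(ci, "disc_circle")
  expect_identical(attr(out, "col_offset"), 256)
  # detected centre sits near the constructed disc, in right-half coordinates
  expect_lte(abs(ci$center_row - ph$disc_center["row"]), 8)
  expect_lte(abs(ci$center_col - (ph$disc_center["col"] - 256)), 8)
})
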