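test_that("background mask binds strictly above the grey threshold", {
  px <- array(0L, c(1, 3, 3))
  px[1, 1, ] <- 39L; px[1, 2, ] <- 40L; px[1, 3, ] <- 41L
  m <- compute_background_mask(fundus_image(px))
  expect_identical(as.vector(pixels(m)), c(0L, 0L, 1L))
  expect_identical(m$semantics, "background-mask")
  # all-black image -> all background
  all0 <- compute_background_mask(flat_rgb(8, 8, c(0, 0, 0)))
  expect_true(all(pixels(all0) == 0L))
})

test_that("foreground count of a bright disc matches an exhaustive scan", {
  px <- array(0L, c(512, 512, 3))
  rr <- row(matrix(0, 512, 512)); cc <- col(matrix(0, 512, 512))
  inside <- (rr - 256)^2 + (cc - 256)^2 <= 100^2
  for (k in 1:3) { ch <- px[, , k]; ch[inside] <- 255L; px[, , k] <- ch }
  m <- compute_background_mask(fundus_image(px))
  expect_identical(sum(pixels(m)), sum(inside))  # brute-force pixel count
})

test_that("mask foreground shrinks monotonically with the threshold", {
  img <- cached_phantom("normal", 501)$image
  prev <- NULL
  for (thr in c(10, 40, 100, 180)) {
    m <- pixels(compute_background_mask(img, preprocess_params(thr)))
    if (!is.null(prev)) expect_true(all(m <= prev))
    prev <- m
  }
})

test_that("mean fill sets background to the foreground channel means", {
  px <- array(0L, c(2, 2, 3))
  px[1, 1, ] <- c(10L, 20L, 30L)
  px[1, 2, ] <- c(30L, 40L, 50L)
  img <- fundus_image(px)
  mask <- binary_mask(matrix(c(1L, 0L, 1L, 0L), 2, 2), "background-mask")
  out <- pixels(fill_background_mean(img, mask))
  expect_identical(out[2, 1, ], c(20L, 30L, 40L))  # hand mean
  expect_identical(out[2, 2, ], c(20L, 30L, 40L))
  # foreground untouched, bit-exactly
  expect_identical(out[1, 1, ], px[1, 1, ])
  expect_identical(out[1, 2, ], px[1, 2, ])
})

test_that("mean fill handles the all-foreground and no-foreground cases", {
  img <- flat_rgb(4, 4, c(200, 100, 50))
  ones <- binary_mask(matrix(1L, 4, 4), "background-mask")
  expect_identical(pixels(fill_background_mean(img, ones)), pixels(img))
  zeros <- binary_mask(matrix(0L, 4, 4), "background-mask")
  expect_error(fill_background_mean(img, zeros),
               class = "fundustruct_degenerate_error")
})

test_that("the CIELab conversion matches the grDevices reference", {
  px <- random_rgb_raster(32, 32, seed = 14)
  lab <- fundustruct:::rgb_to_lab(px)
  ref <- grDevices::convertColor(matrix(as.numeric(px) / 255, ncol = 3),
                                 from = "sRGB", to = "Lab")
  expect_lt(max(abs(lab[, , 1] - matrix(ref[, 1], 32, 32))), 0.5)
  expect_lt(max(abs(lab[, , 2] - matrix(ref[, 2], 32, 32))), 0.5)
  expect_lt(max(abs(lab[, , 3] - matrix(ref[, 3], 32, 32))), 0.5)
  # own roundtrip is lossless at 8 bits
  expect_identical(fundustruct:::lab_to_rgb(lab), px * 1)
})

test_that("CLAHE keeps a flat field flat and never changes shape or range", {
  img <- flat_rgb(64, 64, c(120, 120, 120))
  out <- clahe_on_luminance(img)
  px <- pixels(out)
  expect_identical(dim(px), dim(pixels(img)))
  expect_true(min(px) >= 0 && max(px) <= 255)
  for (k in 1:3) expect_lte(diff(range(px[, , k])), 1)  # spatially constant
})

test_that("CLAHE expands the contrast of a low-contrast ramp", {
  set.seed(3)
  g <- matrix(rep(seq(90, 140, length.out = 64), each = 64), 64, 64) +
    matrix(rnorm(64 * 64, 0, 2), 64, 64)
  px <- array(round(pmin(pmax(g, 0), 255)), c(64, 64, 1))[, , rep(1, 3)]
  img <- fundus_image(px)
  l_in <- fundustruct:::rgb_to_lab(pixels(img))[, , 1]
  l_out <- fundustruct:::rgb_to_lab(pixels(clahe_on_luminance(img)))[, , 1]
  expect_gte(stats::sd(l_out), stats::sd(l_in))
})

test_that("black background reapplication composes with the mean fill", {
  ph <- cached_phantom("glaucoma", 502)
  img <- ph$image
  m <- compute_background_mask(img)
  expect_identical(pixels(reapply_black_background(img,
    binary_mask(matrix(1L, 512, 512), "background-mask"))), pixels(img))
  allbg <- reapply_black_background(img,
    binary_mask(matrix(0L, 512, 512), "background-mask"))
  expect_true(all(pixels(allbg) == 0L))
  filled <- fill_background_mean(img, m)
  re <- reapply_black_background(filled, m)
  bg <- pixels(m) == 0L
  for (k in 1:3) {
    expect_true(all(pixels(re)[, , k][bg] == 0L))
    expect_identical(pixels(re)[, , k][!bg], pixels(filled)[, , k][!bg])
  }
})

test_that("the preprocessing chain equals its manual composition", {
  img <- cached_phantom("normal", 503)$image
  res <- preprocess_fundus(img)
  m <- compute_background_mask(img)
  manual <- reapply_black_background(
    clahe_on_luminance(fill_background_mean(img, m)), m)
  expect_identical(pixels(res$image), pixels(manual))
  expect_identical(pixels(res$mask), pixels(m))
  # background exactly zero in all channels
  bg <- pixels(m) == 0L
  for (k in 1:3) expect_true(all(pixels(res$image)[, , k][bg] == 0L))
})

test_that("preprocessing a mid-grey image with threshold 255 is degenerate", {
  img <- flat_rgb(64, 64, c(128, 128, 128))
  expect_error(preprocess_fundus(img, preprocess_params(254.5)),
               class = "fundustruct_degenerate_error")
})

test_that("re-masking a preprocessed image never gains foreground", {
  img <- cached_phantom("glaucoma", 504)$image
  res <- preprocess_fundus(img)
  m2 <- compute_background_mask(res$image)
  expect_true(all(pixels(m2) <= pixels(res$mask)))
})

test_that("classifier input conversion greys and resizes", {
  img <- cached_phantom("normal", 501)$image
  out <- to_classifier_input(img)
  expect_s3_class(out, "gray_image")
  expect_identical(dim(pixels(out)), c(64L, 64L))
  # identity resize leaves values unchanged
  g <- gray_image(random_gray_raster(64, 64, seed = 9))
  expect_identical(pixels(to_classifier_input(g)), pixels(g))
  # flat field resizes to the same flat value
  cst <- flat_rgb(128, 128, c(77, 77, 77))
  expect_true(all(pixels(to_classifier_input(cst)) == 77L))
})

test_that("rotation augmentation obeys the count law and ordering", {
  imgs <- lapply(1:2, function(i) gray_image(random_gray_raster(32, 32, i)))
  for (step in c(10, 30, 90, 360)) {
    out <- rotation_augment(imgs, step)
    expect_length(out, 2 * 360 / step)
  }
  out <- rotation_augment(imgs, 90)
  expect_identical(pixels(out[[1]]), pixels(imgs[[1]]))  # 0-degree original
  expect_identical(pixels(out[[5]]), pixels(imgs[[2]]))  # image-major order
  expect_error(rotation_augment(imgs, 7), class = "fundustruct_param_error")
})

test_that("quarter-turn rotations are lossless on square rasters", {
  g <- gray_image(random_gray_raster(33, 33, seed = 4))
  r <- g
  for (i in 1:4) r <- rotate_raster(r, 90)
  expect_identical(pixels(r), pixels(g))
  expect_identical(pixels(rotate_raster(rotate_raster(g, 180), 180)),
                   pixels(g))
  # 90 + 270 compose to the identity as well
  expect_identical(pixels(rotate_raster(rotate_raster(g, 90), 270)),
                   pixels(g))
})

test_that("rotation fills out-of-frame corners with black", {
  g <- gray_image(matrix(255L, 32, 32))
  r <- pixels(rotate_raster(g, 45))
  expect_identical(r[1, 1], 0L)
  expect_identical(r[1, 32], 0L)
  expect_identical(r[32, 1], 0L)
  expect_identical(r[32, 32], 0L)
})

test_that("the train/validation split is a seeded disjoint partition", {
  imgs <- as.list(letters[1:32])
  s1 <- split_train_val(imgs, n_val = 2, seed = 11)
  s2 <- split_train_val(imgs, n_val = 2, seed = 11)
  expect_identical(s1$val_idx, s2$val_idx)
  expect_length(s1$train, 30L)
  expect_length(s1$val, 2L)
  expect_setequal(c(unlist(s1$train), unlist(s1$val)), letters[1:32])
  s3 <- split_train_val(imgs, n_val = 2, seed = 12)
  expect_length(s3$val, 2L)
  expect_error(split_train_val(imgs, n_val = 32, seed = 1),
               class = "fundustruct_param_error")
})
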