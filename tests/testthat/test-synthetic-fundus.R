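test_that("phantom generation is bit-deterministic under its seed", {
  a <- generate_phantom("glaucoma", phantom_params(), seed = 77)
  b <- generate_phantom("glaucoma", phantom_params(), seed = 77)
  expect_identical(pixels(a$image), pixels(b$image))
  expect_identical(pixels(a$vessel_mask), pixels(b$vessel_mask))
  expect_identical(a$disc_center, b$disc_center)
  c <- generate_phantom("glaucoma", phantom_params(), seed = 78)
  expect_false(identical(pixels(a$image), pixels(c$image)))
})

test_that("the class signal is the cup-to-disc ratio by construction", {
  g <- cached_phantom("glaucoma", 502)
  n <- cached_phantom("normal", 503)
  expect_gte(g$cup_radius / g$disc_radius, 0.7)
  expect_lte(n$cup_radius / n$disc_radius, 0.4)
  expect_lt(g$cup_radius, g$disc_radius)
  expect_lt(n$cup_radius, n$disc_radius)
})

test_that("phantom geometry honours its own invariants", {
  ph <- cached_phantom("normal", 501)
  px <- pixels(ph$image)
  s <- nrow(px[, , 1])
  # disc blob brighter than the eye field on average
  rr <- row(px[, , 1]); cc <- col(px[, , 1])
  d_disc <- sqrt((rr - ph$disc_center["row"])^2 + (cc - ph$disc_center["col"])^2)
  gray <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  in_disc <- d_disc <= ph$disc_radius
  in_field <- !in_disc & gray > 0
  expect_gt(mean(gray[in_disc]), mean(gray[in_field]))
  # vessel mask confined to the eye region (gray > 0 there by construction)
  expect_true(all(gray[pixels(ph$vessel_mask) == 1L] > 0))
  # disc in the temporal (right) half
  expect_gt(ph$disc_center["col"], s / 2)
})

test_that("threshold-40 foreground matches the constructed eye area", {
  for (seed in c(501, 502)) {
    ph <- cached_phantom(c("normal", "glaucoma")[1 + seed %% 2], seed)
    m <- compute_background_mask(ph$image)
    eye_area <- pi * (0.47 * 512)^2
    expect_lt(abs(sum(pixels(m)) - eye_area) / eye_area, 0.02)
  }
})

test_that("datasets are balanced, reproducible, and land on disk", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(3, phantom_params(), seed = 9, dir = dir)
  expect_length(ds$samples, 6L)
  expect_identical(sum(ds$labels$label == "glaucoma"), 3L)
  expect_identical(sum(ds$labels$label == "normal"), 3L)
  # every label-table id resolves to files on disk
  expect_true(all(file.exists(
    file.path(dir, "images", paste0(ds$labels$image_id, ".png")))))
  expect_true(all(file.exists(
    file.path(dir, "vessel_masks", paste0(ds$labels$image_id, ".png")))))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_identical(read_label_table(file.path(dir, "labels.csv"))$image_id,
                   ds$labels$image_id)
  ds2 <- generate_dataset(3, phantom_params(), seed = 9)
  expect_identical(pixels(ds$samples[[4]]$image), pixels(ds2$samples[[4]]$image))
})

test_that("patch pairs are aligned, vessel-rich, and bookkeeping-exact", {
  samples <- list(cached_phantom("glaucoma", 502), cached_phantom("normal", 503))
  pairs <- vessel_patch_pairs(samples, 64, seed = 15)
  expect_length(pairs, 64L)
  rich <- vapply(pairs, function(p) mean(pixels(p$mask)) >= 0.01, TRUE)
  expect_gte(sum(rich), 32L)
  for (p in pairs[c(1, 20, 64)]) {
    expect_identical(dim(pixels(p$image)), c(64L, 64L))
    o <- p$origin
    sm <- samples[[o["sample"]]]
    rows <- o["row"]:(o["row"] + 63L)
    cols <- o["col"]:(o["col"] + 63L)
    # the mask crop is exactly the ground-truth region at the crop origin
    expect_identical(pixels(p$mask), pixels(sm$vessel_mask)[rows, cols])
    expect_identical(pixels(p$image),
                     pixels(rgb_to_gray(sm$image))[rows, cols])
  }
})

test_that("a hand-written cup feature separates the classes", {
  # bright-pixel ratio inside the detected disc circle: the share of
  # near-cup-bright pixels among disc-bright pixels tracks (cup/disc)^2,
  # independent of the disc radius; threshold 0.3 is the midpoint of the
  # class ranges (0.4^2 = 0.16 vs 0.7^2 = 0.49).
  n_per <- 8
  correct <- 0
  for (i in seq_len(2 * n_per)) {
    lab <- if (i <= n_per) "glaucoma" else "normal"
    ph <- generate_phantom(lab, phantom_params(), seed = 700 + i)
    crop <- pixels(extract_disc_region(ph$image))
    ratio <- sum(crop >= 228) / max(1, sum(crop >= 195))
    pred <- if (ratio > 0.3) "glaucoma" else "normal"
    correct <- correct + (pred == lab)
  }
  expect_gte(correct / (2 * n_per), 0.9)
})

test_that("parameter validation rejects inconsistent ranges", {
  expect_error(phantom_params(cup_to_disc_normal = c(0.2, 0.8)),
               class = "fundustruct_validation_error")
  expect_error(phantom_params(disc_radius = c(60, 20)),
               class = "fundustruct_validation_error")
  expect_error(phantom_params(noise_sd = -1),
               class = "fundustruct_validation_error")
})
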