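# Fundus preprocessing: background masking at a grey threshold, mean-colour
# background fill, CLAHE on the CIELab luminance channel, black-background
# reapplication, plus rotation augmentation and the train/validation split.

#' Preprocessing parameters
#'
#' @param background_threshold grey level separating the eye region from the
#'   black camera background; a pixel is foreground when its luma-weighted
#'   grey value is strictly above this (default 40).
#' @param clahe_clip_limit CLAHE contrast clip limit (default 2).
#' @param clahe_tile_grid CLAHE tile grid edge count (default 8, i.e. 8 x 8).
#' @param classifier_size edge length of classifier inputs (default 64).
#' @return a `preprocess_params` list.
#' @export
preprocess_params <- function(background_threshold = 40,
                              clahe_clip_limit = 2,
                              clahe_tile_grid = 8L,
                              classifier_size = 64L) {
  abort_if(background_threshold <= 0 || background_threshold >= 255,
           "preprocess_params: background_threshold must be in (0, 255)")
  abort_if(clahe_clip_limit <= 0, "preprocess_params: clahe_clip_limit must be > 0")
  abort_if(!is_count(clahe_tile_grid) || clahe_tile_grid < 1,
           "preprocess_params: clahe_tile_grid must be a positive count")
  abort_if(!is_count(classifier_size) || classifier_size < 8,
           "preprocess_params: classifier_size must be >= 8")
  structure(list(background_threshold = background_threshold,
                 clahe_clip_limit = clahe_clip_limit,
                 clahe_tile_grid = as.integer(clahe_tile_grid),
                 classifier_size = as.integer(classifier_size)),
            class = "preprocess_params")
}

#' Background/eye-region mask
#'
#' Converts the image to grey (luma weights) and marks pixels with grey value
#' strictly above the threshold as foreground (1); the black camera background
#' stays 0.
#'
#' @param img a [fundus_image].
#' @param params a [preprocess_params].
#' @return a [binary_mask] with semantics `"background-mask"`.
#' @export
compute_background_mask <- function(img, params = preprocess_params()) {
  g <- rgb_to_gray(img, round_values = FALSE)
  binary_mask(g > params$background_threshold, semantics = "background-mask")
}

#' Fill the background with the mean foreground colour
#'
#' Sets every background pixel (mask == 0) to the per-channel mean of the
#' foreground pixels, rounded to the nearest integer, so the subsequent
#' histogram equalisation is not dominated by the black border. Foreground
#' pixels are untouched.
#'
#' @param img a [fundus_image].
#' @param mask the [binary_mask] from [compute_background_mask()].
#' @return a [fundus_image].
#' @export
fill_background_mean <- function(img, mask) {
  px <- pixels(img)
  m <- pixels(mask)
  abort_if(!all(dim(m) == dim(px)[1:2]),
           "fill_background_mean: mask dimensions do not match the image")
  abort_if(sum(m) == 0L,
           "fill_background_mean: degenerate input, mask has no foreground",
           class = "fundustruct_degenerate_error")
  fg <- m == 1L
  out <- px
  for (k in 1:3) {
    ch <- px[, , k]
    ch[!fg] <- round(mean(ch[fg]))
    out[, , k] <- ch
  }
  fundus_image(out, meta = img$meta)
}

#' CLAHE on the CIELab luminance channel
#'
#' Converts sRGB to CIELab (D65, 8-bit scaling), applies contrast-limited
#' adaptive histogram equalisation to the L channel only, leaves a/b
#' untouched, and converts back to RGB.
#'
#' @param img a [fundus_image].
#' @param params a [preprocess_params] supplying the clip limit and tile grid.
#' @return a [fundus_image] with the same dimensions.
#' @export
clahe_on_luminance <- function(img, params = preprocess_params()) {
  px <- pixels(img)
  lab <- rgb_to_lab(px)
  l01 <- clamp(lab[, , 1] / 100, 0, 1)
  l01 <- EBImage::clahe(l01,
                        nx = params$clahe_tile_grid,
                        ny = params$clahe_tile_grid,
                        limit = params$clahe_clip_limit)
  lab[, , 1] <- clamp(l01, 0, 1) * 100
  fundus_image(lab_to_rgb(lab), meta = img$meta)
}

#' Reapply the black background
#'
#' Sets pixels with mask == 0 to (0, 0, 0); foreground pixels are untouched.
#'
#' @param img a [fundus_image].
#' @param mask a [binary_mask] of matching dimensions.
#' @return a [fundus_image].
#' @export
reapply_black_background <- function(img, mask) {
  px <- pixels(img)
  m <- pixels(mask)
  abort_if(!all(dim(m) == dim(px)[1:2]),
           "reapply_black_background: mask dimensions do not match the image")
  bg <- m == 0L
  out <- px
  for (k in 1:3) {
    ch <- out[, , k]
    ch[bg] <- 0L
    out[, , k] <- ch
  }
  fundus_image(out, meta = img$meta)
}

#' Full preprocessing chain
#'
#' mask -> mean fill -> CLAHE on L -> back to RGB -> reapply black background.
#'
#' @param img a [fundus_image].
#' @param params a [preprocess_params].
#' @return a list with `image` (the preprocessed [fundus_image]) and `mask`
#'   (the background [binary_mask], reusable downstream).
#' @export
preprocess_fundus <- function(img, params = preprocess_params()) {
  mask <- compute_background_mask(img, params)
  filled <- fill_background_mean(img, mask)
  enhanced <- clahe_on_luminance(filled, params)
  list(image = reapply_black_background(enhanced, mask), mask = mask)
}

#' Convert a raster to a classifier input
#'
#' Grey conversion (if colour) followed by bilinear resize to
#' `classifier_size` x `classifier_size`.
#'
#' @param img a [fundus_image] or [gray_image].
#' @param params a [preprocess_params].
#' @return a [gray_image] of edge `classifier_size`.
#' @export
to_classifier_input <- function(img, params = preprocess_params()) {
  g <- if (inherits(img, "fundus_image") || length(dim(pixels(img))) == 3L)
    pixels(rgb_to_gray(img)) else pixels(img)
  s <- params$classifier_size
  if (!all(dim(g) == c(s, s))) {
    g <- round(clamp(resize_matrix(g, s, s), 0, 255))
  }
  gray_image(g)
}

#' Rotate a raster about its centre
#'
#' Inverse-map bilinear rotation; out-of-frame corners are filled with 0.
#' Rotations by multiples of 90 degrees on square integer rasters are
#' bit-exact.
#'
#' @param x a [gray_image], [binary_mask], [fundus_image], or bare matrix /
#'   H x W x C array.
#' @param angle_deg rotation angle in degrees (counter-clockwise).
#' @return the rotated raster, same type and dimensions as the input.
#' @export
rotate_raster <- function(x, angle_deg) {
  px <- pixels(x)
  nd <- length(dim(px))
  rot1 <- function(m) {
    h <- nrow(m); w <- ncol(m)
    th <- angle_deg * pi / 180
    cs <- cos(th); sn <- sin(th)
    cr <- (h + 1) / 2; cc <- (w + 1) / 2
    r <- rep(seq_len(h), times = w) - cr
    c <- rep(seq_len(w), each = h) - cc
    # inverse map: source coords of each output pixel
    sr <- cs * r + sn * c + cr
    sc <- -sn * r + cs * c + cc
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    val <- function(ri, ci) {
      ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
      v <- numeric(length(ri))
      v[ok] <- m[cbind(ri[ok], ci[ok])]
      v
    }
    out <- (1 - fr) * (1 - fc) * val(r0, c0) +
      (1 - fr) * fc * val(r0, c0 + 1) +
      fr * (1 - fc) * val(r0 + 1, c0) +
      fr * fc * val(r0 + 1, c0 + 1)
    matrix(out, h, w)
  }
  out <- if (nd == 2L) rot1(px) else {
    a <- array(0, dim(px))
    for (k in seq_len(dim(px)[3])) a[, , k] <- rot1(px[, , k])
    a
  }
  if (is.integer(px)) out <- round(clamp(out, 0, 255))
  if (inherits(x, "gray_image")) gray_image(out)
  else if (inherits(x, "binary_mask")) binary_mask(out > 0.5, x$semantics)
  else if (inherits(x, "fundus_image")) fundus_image(out, meta = x$meta)
  else out
}

#' Rotation augmentation
#'
#' Expands each raster into 360 / `step_deg` rotated copies (including the
#' zero-degree original), in image-major then increasing-angle order.
#'
#' @param images list of rasters accepted by [rotate_raster()].
#' @param step_deg rotation step in degrees; must divide 360 (default 10).
#' @return a list of length `length(images) * 360 / step_deg`.
#' @export
rotation_augment <- function(images, step_deg = 10) {
  abort_if(!is.list(images), "rotation_augment: images must be a list")
  abort_if(step_deg <= 0 || 360 %% step_deg != 0,
           "rotation_augment: step_deg must divide 360",
           class = "fundustruct_param_error")
  angles <- seq(0, 360 - step_deg, by = step_deg)
  out <- vector("list", length(images) * length(angles))
  i <- 1L
  for (img in images) {
    for (a in angles) {
      out[[i]] <- if (a == 0) img else rotate_raster(img, a)
      i <- i + 1L
    }
  }
  out
}

#' Seeded train/validation split
#'
#' Draws `n_val` validation indices uniformly at random under the given seed;
#' the split is disjoint and exhaustive. Augmentation should be applied
#' after splitting so validation rotations never leak into training.
#'
#' @param images a list (or vector) of items to split.
#' @param n_val number of validation items (default 2).
#' @param seed integer seed making the split reproducible.
#' @return a list with `train`, `val`, and the drawn `val_idx`.
#' @export
split_train_val <- function(images, n_val = 2L, seed) {
  n <- length(images)
  abort_if(n_val >= n, "split_train_val: n_val must be smaller than the set",
           class = "fundustruct_param_error")
  abort_if(n_val < 1, "split_train_val: n_val must be >= 1",
           class = "fundustruct_param_error")
  idx <- local_seed(seed, sample.int(n, n_val))
  list(train = images[-idx], val = images[idx], val_idx = sort(idx))
}
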