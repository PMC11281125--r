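# Internal helpers shared across modules.

abort <- function(..., class = "fundustruct_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

abort_if <- function(cond, ..., class = "fundustruct_error") {
  if (isTRUE(cond)) abort(..., class = class)
  invisible(NULL)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded stages never perturb the caller's stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Standard 8-bit luma weights for RGB -> grey conversion.
LUMA_WEIGHTS <- c(0.299, 0.587, 0.114)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Bilinear resize of a single-channel matrix to h x w.
# EBImage treats the first array dimension as image width, so our row
# dimension maps to its `w` argument; the filter is axis-symmetric.
resize_matrix <- function(x, h, w) {
  EBImage::resize(x, w = h, h = w, filter = "bilinear")
}

# Bilinear resize of an H x W x C array (per channel).
resize_array <- function(x, h, w) {
  out <- array(0, c(h, w, dim(x)[3]))
  for (k in seq_len(dim(x)[3])) out[, , k] <- resize_matrix(x[, , k], h, w)
  out
}

#' Convert an RGB raster to grey levels
#'
#' Uses the standard luma weighting (0.299, 0.587, 0.114) on 0..255 channels.
#'
#' @param img a [fundus_image] or an H x W x 3 array in 0..255.
#' @param round_values round to integer grey levels (default `TRUE`).
#' @return a [gray_image] (rounded) or a numeric matrix.
#' @export
rgb_to_gray <- function(img, round_values = TRUE) {
  px <- pixels(img)
  abort_if(length(dim(px)) != 3L, "rgb_to_gray() expects a 3-channel raster")
  g <- LUMA_WEIGHTS[1] * px[, , 1] + LUMA_WEIGHTS[2] * px[, , 2] +
    LUMA_WEIGHTS[3] * px[, , 3]
  if (!is.matrix(g)) g <- matrix(g, dim(px)[1], dim(px)[2])
  if (round_values) gray_image(round(g)) else g
}

# sRGB <-> CIELab (D65 white point, 8-bit scaling), vectorised closed forms.
# grDevices::convertColor implements the same standard and serves as the
# independent oracle in the tests; these direct implementations are an order
# of magnitude faster on full rasters.
D65 <- c(X = 0.95047, Y = 1, Z = 1.08883)

srgb_linearise <- function(s) {
  ifelse(s > 0.04045, ((s + 0.055) / 1.055)^2.4, s / 12.92)
}
srgb_delinearise <- function(c) {
  ifelse(c > 0.0031308, 1.055 * c^(1 / 2.4) - 0.055, 12.92 * c)
}

# sRGB (0..255) -> CIELab, returning an H x W x 3 array with L in 0..100.
rgb_to_lab <- function(px) {
  d <- dim(px)
  r <- srgb_linearise(as.numeric(px[, , 1]) / 255)
  g <- srgb_linearise(as.numeric(px[, , 2]) / 255)
  b <- srgb_linearise(as.numeric(px[, , 3]) / 255)
  x <- (0.4124564 * r + 0.3575761 * g + 0.1804375 * b) / D65["X"]
  y <- 0.2126729 * r + 0.7151522 * g + 0.0721750 * b
  z <- (0.0193339 * r + 0.1191920 * g + 0.9503041 * b) / D65["Z"]
  f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3),
                          t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(x); fy <- f(y); fz <- f(z)
  out <- array(0, d)
  out[, , 1] <- 116 * fy - 16
  out[, , 2] <- 500 * (fx - fy)
  out[, , 3] <- 200 * (fy - fz)
  out
}

# CIELab -> sRGB in 0..255 (rounded, gamut-clipped).
lab_to_rgb <- function(lab) {
  d <- dim(lab)
  fy <- (as.numeric(lab[, , 1]) + 16) / 116
  fx <- fy + as.numeric(lab[, , 2]) / 500
  fz <- fy - as.numeric(lab[, , 3]) / 200
  finv <- function(t) ifelse(t > 6 / 29, t^3, 3 * (6 / 29)^2 * (t - 4 / 29))
  x <- finv(fx) * D65["X"]
  y <- finv(fy)
  z <- finv(fz) * D65["Z"]
  r <- 3.2404542 * x - 1.5371385 * y - 0.4985314 * z
  g <- -0.9692660 * x + 1.8760108 * y + 0.0415560 * z
  b <- 0.0556434 * x - 0.2040259 * y + 1.0572252 * z
  out <- array(0, d)
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  round(clamp(srgb_delinearise(clamp(out, 0, 1)), 0, 1) * 255)
}
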