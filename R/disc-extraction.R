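# Optic-disc extraction: right-half crop, top-percentile brightness mask on
# the CIELab L channel, circular Hough transform with a fixed radius
# extension, and blackout of everything outside the detected circle.

#' Disc-extraction parameters
#'
#' @param top_percent share of brightest L-channel pixels kept (default 3.5).
#' @param radius_extension pixels added to the detected radius so the disc is
#'   never clipped (default 40).
#' @param hough list of Hough-transform settings: `dp` (accumulator
#'   resolution divisor, kept at 1), `min_dist` (minimum distance between
#'   reported circles; `NULL` means half the smaller raster edge — a single
#'   disc is expected), `accumulator_threshold` (minimum votes at the
#'   accumulator peak before the centroid fallback triggers),
#'   `min_radius`/`max_radius` (candidate radii in pixels at 512-scale; they
#'   scale with the input), `n_theta` (angular samples per candidate radius),
#'   `min_support` (minimum angular support of the winning circle before the
#'   centroid fallback triggers).
#' @return a `disc_params` list.
#' @export
disc_params <- function(top_percent = 3.5,
                        radius_extension = 40,
                        hough = list()) {
  abort_if(top_percent <= 0 || top_percent >= 100,
           "disc_params: top_percent must be in (0, 100)")
  abort_if(radius_extension < 0, "disc_params: radius_extension must be >= 0")
  h <- utils::modifyList(
    list(dp = 1, min_dist = NULL, accumulator_threshold = 15,
         min_radius = 15, max_radius = 120, n_theta = 72L,
         min_support = 0.5),
    hough)
  abort_if(h$min_radius >= h$max_radius,
           "disc_params: min_radius must be smaller than max_radius")
  structure(list(top_percent = top_percent,
                 radius_extension = radius_extension, hough = h),
            class = "disc_params")
}

#' Crop the right half of an image
#'
#' Returns columns `[floor(W/2), W)` (half-open, 0-based), all rows. The
#' column offset is recorded in the result's `meta$col_offset` for mapping
#' detected coordinates back to the full frame.
#'
#' @param img a [fundus_image].
#' @return a [fundus_image] of width `ceiling(W/2)`.
#' @export
crop_right_half <- function(img) {
  px <- pixels(img)
  w <- dim(px)[2]
  abort_if(w < 2L, "crop_right_half: image must have at least 2 columns")
  off <- floor(w / 2)
  meta <- img$meta
  meta$col_offset <- off
  fundus_image(px[, (off + 1L):w, , drop = FALSE], meta = meta)
}

#' Top-percentile brightness mask on the CIELab L channel
#'
#' Selects the brightest `top_percent` of pixels: the threshold is the k-th
#' largest L value with `k = ceiling(top_percent/100 * N)`, and all ties at
#' the threshold are kept (so the mask may slightly exceed the nominal
#' share; a constant image selects every pixel).
#'
#' @param img a [fundus_image].
#' @param params a [disc_params].
#' @return a [binary_mask] with semantics `"brightness-mask"`.
#' @export
brightness_top_mask <- function(img, params = disc_params()) {
  px <- pixels(img)
  L <- rgb_to_lab(px)[, , 1]
  n <- length(L)
  k <- min(n, max(1L, ceiling(params$top_percent / 100 * n)))
  thr <- sort(as.numeric(L), decreasing = TRUE)[k]
  binary_mask(L >= thr, semantics = "brightness-mask")
}

# Boundary pixels of a binary mask (pixels whose 4-neighbourhood leaves the
# mask). The padding replicates the raster edge, so a region clipped by the
# crop border exposes only its true contour — the border itself is a crop
# artifact, not an object boundary. Returned as a 2-column (row, col) matrix.
mask_boundary <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0L, h + 2L, w + 2L)
  pad[2:(h + 1), 2:(w + 1)] <- m
  pad[1, 2:(w + 1)] <- m[1, ]
  pad[h + 2L, 2:(w + 1)] <- m[h, ]
  pad[2:(h + 1), 1] <- m[, 1]
  pad[2:(h + 1), w + 2L] <- m[, w]
  core <- pad[2:(h + 1), 2:(w + 1)]
  er <- core & pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  which(core == 1L & !er, arr.ind = TRUE)
}

# 3 x 3 box blur of an accumulator matrix (edge-replicated by zero padding).
box3 <- function(a) {
  h <- nrow(a); w <- ncol(a)
  p <- matrix(0, h + 2L, w + 2L)
  p[2:(h + 1), 2:(w + 1)] <- a
  p[1:h, 1:w] + p[1:h, 2:(w + 1)] + p[1:h, 3:(w + 2)] +
    p[2:(h + 1), 1:w] + p[2:(h + 1), 2:(w + 1)] + p[2:(h + 1), 3:(w + 2)] +
    p[3:(h + 2), 1:w] + p[3:(h + 2), 2:(w + 1)] + p[3:(h + 2), 3:(w + 2)]
}

#' Detect the optic-disc circle in a brightness mask
#'
#' Circular Hough transform on the binary mask. The mask is first
#' morphologically closed and then opened (5-px disc kernel): closing turns
#' speckled bright regions — the percentile mask keeps only a scattered
#' subset of a large disc — into solid ones, and opening removes speckle too
#' sparse to solidify, so only true outer contours vote. The resulting
#' boundary pixels then vote for candidate centres at each candidate radius,
#' and the top two vote peaks of every radius become candidate circles. Candidates are then scored by angular
#' support — the fraction of sampled directions in which the circle lands on
#' a (dilated) mask-boundary pixel, with out-of-frame points counting as
#' unsupported — so a fully supported small disc rim beats any partial
#' large-radius arc. Per centre, the detected radius is the largest one whose
#' support stays within 90\% of that centre's peak support (speckled bright
#' regions then resolve to their outer circular envelope); the best-supported
#' centre wins (tie-break: larger radius) and the radius is extended by
#' `radius_extension`. If the accumulator peak stays below
#' `accumulator_threshold`, or the winner's angular support below
#' `min_support`, the detector falls back to the mask centroid with radius
#' `sqrt(area / pi)`.
#'
#' @param mask a [binary_mask] (e.g. from [brightness_top_mask()]).
#' @param params a [disc_params].
#' @return a `disc_circle` list: `center_row`, `center_col`, `radius`
#'   (extended), `radius_detected` (pre-extension), `votes`, and `source`
#'   (`"hough"` or `"centroid-fallback"`).
#' @export
detect_disc_circle <- function(mask, params = disc_params()) {
  m <- pixels(mask)
  abort_if(sum(m) == 0L, "detect_disc_circle: no bright pixels",
           class = "fundustruct_detection_error")
  h <- nrow(m); w <- ncol(m)
  scale <- max(h, w) / 512
  rmin <- max(3L, round(params$hough$min_radius * scale))
  rmax <- max(rmin + 1L, round(params$hough$max_radius * scale))
  bnd <- mask_boundary(m)
  fallback <- function() {
    fg <- which(m == 1L, arr.ind = TRUE)
    structure(list(center_row = mean(fg[, 1]), center_col = mean(fg[, 2]),
                   radius = sqrt(sum(m) / pi) + params$radius_extension,
                   radius_detected = sqrt(sum(m) / pi),
                   votes = 0, source = "centroid-fallback"),
              class = "disc_circle")
  }
  # solidify speckled regions (closing), then drop sparse speckle that stays
  # porous (opening): only solid structures keep a contour worth voting on
  cleaned <- EBImage::opening(EBImage::closing(m, EBImage::makeBrush(5L, "disc")),
                              EBImage::makeBrush(5L, "disc"))
  bnd2 <- mask_boundary(cleaned)
  if (nrow(bnd2) >= 3L) bnd <- bnd2
  if (nrow(bnd) < 3L) return(fallback())
  # cap the number of voting pixels deterministically
  if (nrow(bnd) > 2000L) {
    bnd <- bnd[seq(1L, nrow(bnd), length.out = 2000L), , drop = FALSE]
  }
  nt <- params$hough$n_theta
  theta <- seq(0, 2 * pi, length.out = nt + 1L)[seq_len(nt)]
  ct <- cos(theta); st <- sin(theta)

  # dilated boundary lookup for the angular-support score
  bmask <- matrix(FALSE, h, w)
  bmask[bnd] <- TRUE
  dil <- bmask
  for (it in 1:2) {
    p <- matrix(FALSE, h + 2L, w + 2L)
    p[2:(h + 1), 2:(w + 1)] <- dil
    dil <- p[1:h, 2:(w + 1)] | p[3:(h + 2), 2:(w + 1)] |
      p[2:(h + 1), 1:w] | p[2:(h + 1), 3:(w + 2)] |
      p[2:(h + 1), 2:(w + 1)] | p[1:h, 1:w] | p[1:h, 3:(w + 2)] |
      p[3:(h + 2), 1:w] | p[3:(h + 2), 3:(w + 2)]
  }
  support <- function(row, col, r) {
    pr <- round(row + r * ct); pc <- round(col + r * st)
    ok <- pr >= 1L & pr <= h & pc >= 1L & pc <= w
    s <- logical(nt)
    s[ok] <- dil[cbind(pr[ok], pc[ok])]
    mean(s)
  }

  # vote stage: per-radius accumulators; the top two peaks of every radius
  # (non-max suppressed) become candidate centres
  cand <- list()
  for (r in seq(rmin, rmax, by = 2L)) {
    cr <- round(rep(bnd[, 1], each = nt) - r * rep(ct, times = nrow(bnd)))
    cc <- round(rep(bnd[, 2], each = nt) - r * rep(st, times = nrow(bnd)))
    ok <- cr >= 1L & cr <= h & cc >= 1L & cc <= w
    if (!any(ok)) next
    sm <- box3(matrix(tabulate((cc[ok] - 1L) * h + cr[ok], nbins = h * w),
                      h, w))
    for (i in 1:2) {
      peak <- which.max(sm)
      if (sm[peak] <= 0) break
      pr <- (peak - 1L) %% h + 1L; pc <- (peak - 1L) %/% h + 1L
      cand[[length(cand) + 1L]] <- list(row = pr, col = pc, votes = sm[peak])
      sm[max(1L, pr - 20L):min(h, pr + 20L),
         max(1L, pc - 20L):min(w, pc + 20L)] <- 0
    }
  }
  if (length(cand) == 0L ||
      max(vapply(cand, `[[`, 0, "votes")) < params$hough$accumulator_threshold) {
    return(fallback())
  }
  # dedupe nearby candidate centres, keeping the strongest
  cand <- cand[order(-vapply(cand, `[[`, 0, "votes"))]
  kept <- list()
  for (cd in cand) {
    dup <- any(vapply(kept, function(k)
      (k$row - cd$row)^2 + (k$col - cd$col)^2 <= 25, TRUE))
    if (!dup) kept[[length(kept) + 1L]] <- cd
  }
  cand <- kept

  # support stage: per-centre radius profile; the detected radius is the
  # largest one whose angular support stays within 90% of the centre's peak.
  # Centres are ranked by support weighted by the mask's fill density inside
  # the circle: the disc region is densely selected by the percentile mask,
  # while bright-field speckle is sparse.
  radii <- seq(rmin, rmax)
  rowg <- matrix(seq_len(h), h, w)
  colg <- matrix(seq_len(w), h, w, byrow = TRUE)
  best <- NULL
  for (cd in cand) {
    sup <- vapply(radii, function(r) support(cd$row, cd$col, r), 0)
    peak <- max(sup)
    rbest <- max(radii[sup >= 0.9 * peak])
    inside <- (rowg - cd$row)^2 + (colg - cd$col)^2 <= rbest^2
    density <- if (any(inside)) mean(m[inside]) else 0
    score <- peak * (0.5 + 0.5 * density)
    if (is.null(best) || score > best$score ||
        (abs(score - best$score) < 1e-12 && rbest > best$r)) {
      best <- list(row = cd$row, col = cd$col, r = rbest, score = score,
                   support = peak, votes = cd$votes)
    }
  }
  if (best$support < params$hough$min_support) return(fallback())
  structure(list(center_row = best$row, center_col = best$col,
                 radius = best$r + params$radius_extension,
                 radius_detected = best$r,
                 votes = best$votes, support = best$support,
                 source = "hough"),
            class = "disc_circle")
}

#' @export
print.disc_circle <- function(x, ...) {
  cat(sprintf("<disc_circle (%s) centre (%.1f, %.1f), radius %.1f (detected %.1f)>\n",
              x$source, x$center_row, x$center_col, x$radius,
              x$radius_detected))
  invisible(x)
}

#' Black out everything outside a circle
#'
#' @param img a [fundus_image] in the same coordinate frame as `circle`.
#' @param circle a `disc_circle`.
#' @return a [fundus_image] where pixels with Euclidean distance greater than
#'   `circle$radius` from the centre are (0, 0, 0).
#' @export
blackout_outside_circle <- function(img, circle) {
  px <- pixels(img)
  h <- dim(px)[1]; w <- dim(px)[2]
  d2 <- outer((seq_len(h) - circle$center_row)^2,
              (seq_len(w) - circle$center_col)^2, "+")
  keep <- d2 <= circle$radius^2
  out <- px
  for (k in 1:3) {
    ch <- out[, , k]
    ch[!keep] <- 0L
    out[, , k] <- ch
  }
  fundus_image(out, meta = img$meta)
}

#' Extract the optic-disc region
#'
#' Full chain: right-half crop, top-percentile brightness mask, Hough circle
#' detection (radius extended), blackout outside the circle, grey conversion,
#' bilinear resize to `size` x `size`.
#'
#' @param img a [fundus_image] (right-eye fundus photograph).
#' @param params a [disc_params].
#' @param size output edge length (default 64).
#' @return a [gray_image] of edge `size`; attributes `circle` (the detected
#'   `disc_circle`, right-half coordinates) and `col_offset` record the
#'   geometry.
#' @export
extract_disc_region <- function(img, params = disc_params(), size = 64L) {
  half <- crop_right_half(img)
  mask <- brightness_top_mask(half, params)
  circle <- detect_disc_circle(mask, params)
  blacked <- blackout_outside_circle(half, circle)
  g <- pixels(rgb_to_gray(blacked))
  out <- gray_image(round(clamp(resize_matrix(g, size, size), 0, 255)))
  attr(out, "circle") <- circle
  attr(out, "col_offset") <- half$meta$col_offset
  out
}
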