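# Seeded phantom-fundus generator. Phantoms emulate the geometry every
# pipeline stage relies on: a black background outside a roughly circular eye
# field, a bright optic disc in the temporal (right) half with a brighter
# concentric cup whose radius ratio encodes the class (glaucoma: enlarged
# cup), and a darker branching vessel tree rendered into both the image and
# a ground-truth binary mask.

#' Phantom generation parameters
#'
#' @param size image edge length in pixels (default 512).
#' @param eye_radius_frac eye-field radius as a fraction of `size`
#'   (default 0.47).
#' @param disc_radius range of disc radii in pixels (default `c(20, 60)`).
#' @param cup_to_disc_normal cup-to-disc ratio range for normal eyes
#'   (default `c(0.2, 0.4)`).
#' @param cup_to_disc_glaucoma ratio range for glaucomatous eyes
#'   (default `c(0.7, 0.9)`); must not overlap the normal range.
#' @param n_vessel_branches range of primary vessel branches
#'   (default `c(6, 12)`).
#' @param vessel_width range of vessel widths in pixels (default `c(2, 6)`).
#' @param noise_sd additive Gaussian noise level on 0..255 channels
#'   (default 4).
#' @return a `phantom_params` list.
#' @export
phantom_params <- function(size = 512L, eye_radius_frac = 0.47,
                           disc_radius = c(20, 60),
                           cup_to_disc_normal = c(0.2, 0.4),
                           cup_to_disc_glaucoma = c(0.7, 0.9),
                           n_vessel_branches = c(6L, 12L),
                           vessel_width = c(2, 6),
                           noise_sd = 4) {
  rng_ok <- function(r) length(r) == 2L && r[1] <= r[2]
  abort_if(!rng_ok(disc_radius) || !rng_ok(cup_to_disc_normal) ||
             !rng_ok(cup_to_disc_glaucoma) || !rng_ok(n_vessel_branches) ||
             !rng_ok(vessel_width),
           "phantom_params: ranges must be nonempty (lo <= hi)",
           class = "fundustruct_validation_error")
  abort_if(min(cup_to_disc_normal) <= 0 || max(cup_to_disc_glaucoma) >= 1,
           "phantom_params: cup-to-disc ranges must lie in (0, 1)",
           class = "fundustruct_validation_error")
  abort_if(max(cup_to_disc_normal) >= min(cup_to_disc_glaucoma),
           "phantom_params: class cup-to-disc ranges must be disjoint",
           class = "fundustruct_validation_error")
  abort_if(noise_sd < 0, "phantom_params: noise_sd must be >= 0",
           class = "fundustruct_validation_error")
  structure(list(size = as.integer(size), eye_radius_frac = eye_radius_frac,
                 disc_radius = disc_radius,
                 cup_to_disc_normal = cup_to_disc_normal,
                 cup_to_disc_glaucoma = cup_to_disc_glaucoma,
                 n_vessel_branches = as.integer(n_vessel_branches),
                 vessel_width = vessel_width, noise_sd = noise_sd),
            class = "phantom_params")
}

# Rasterise a polyline point set into a logical mask with a disk stamp of
# the given radius at every point.
stamp_points <- function(mask, rows, cols, radius) {
  h <- nrow(mask); w <- ncol(mask)
  r <- max(0L, round(radius))
  off <- expand.grid(dr = -r:r, dc = -r:r)
  off <- off[off$dr^2 + off$dc^2 <= radius^2 + 0.25, ]
  pr <- round(rep(rows, each = nrow(off))) + rep(off$dr, times = length(rows))
  pc <- round(rep(cols, each = nrow(off))) + rep(off$dc, times = length(cols))
  ok <- pr >= 1L & pr <= h & pc >= 1L & pc <= w
  mask[cbind(pr[ok], pc[ok])] <- TRUE
  mask
}

# One random-walk vessel path from (r0, c0) heading `theta0`, stopping at the
# eye rim. Returns the visited (row, col) points.
vessel_walk <- function(r0, c0, theta0, eye_c, eye_r, max_steps = 400L) {
  rows <- numeric(max_steps); cols <- numeric(max_steps)
  r <- r0; c <- c0; th <- theta0
  n <- 0L
  for (i in seq_len(max_steps)) {
    r <- r + 2 * sin(th)
    c <- c + 2 * cos(th)
    if ((r - eye_c[1])^2 + (c - eye_c[2])^2 > (0.96 * eye_r)^2) break
    n <- n + 1L
    rows[n] <- r; cols[n] <- c
    th <- th + stats::rnorm(1L, 0, 0.15)
  }
  list(rows = rows[seq_len(n)], cols = cols[seq_len(n)])
}

#' Generate one phantom fundus image
#'
#' Deterministic given `(label, params, seed)`: renders the black background,
#' an orange-toned circular eye field with radial shading, a bright disc blob
#' in the temporal half with a brighter concentric cup (radius ratio drawn
#' from the label's cup-to-disc range), and a branching vessel tree walked
#' out from the disc centre, rasterised into both the image and the
#' ground-truth vessel mask; Gaussian noise is added inside the eye field
#' only.
#'
#' @param label `"glaucoma"` or `"normal"`.
#' @param params a [phantom_params].
#' @param seed integer seed.
#' @return a `phantom_sample` list: `image` ([fundus_image]), `vessel_mask`
#'   ([binary_mask]), `disc_center` (row, col), `disc_radius`, `cup_radius`,
#'   `label`, `seed`.
#' @export
generate_phantom <- function(label = c("glaucoma", "normal"),
                             params = phantom_params(), seed) {
  label <- match.arg(label)
  abort_if(!inherits(params, "phantom_params"),
           "generate_phantom: invalid params",
           class = "fundustruct_validation_error")
  local_seed(seed, {
    s <- params$size
    rr <- matrix(rep(seq_len(s), times = s), s, s)
    cc <- matrix(rep(seq_len(s), each = s), s, s)
    eye_c <- c(s / 2 + stats::runif(1, -0.01, 0.01) * s,
               s / 2 + stats::runif(1, -0.01, 0.01) * s)
    eye_r <- params$eye_radius_frac * s
    d_eye <- sqrt((rr - eye_c[1])^2 + (cc - eye_c[2])^2)
    eye <- d_eye <= eye_r

    # radial shading: brightest at centre, ~35% darker at the rim
    shade <- 1 - 0.35 * pmin(d_eye / eye_r, 1)^2
    base <- c(205, 115, 58)  # orange fundus tone
    img <- array(0, c(s, s, 3L))
    for (k in 1:3) img[, , k] <- base[k] * shade

    # optic disc in the temporal (right) half, fully inside the eye field
    disc_r <- stats::runif(1, params$disc_radius[1], params$disc_radius[2])
    disc_row <- eye_c[1] + stats::runif(1, -0.10, 0.10) * s
    disc_col <- eye_c[2] + stats::runif(1, 0.18, 0.30) * s
    cdr_rng <- if (label == "glaucoma") params$cup_to_disc_glaucoma
               else params$cup_to_disc_normal
    cdr <- stats::runif(1, cdr_rng[1], cdr_rng[2])
    cup_r <- cdr * disc_r
    d_disc <- sqrt((rr - disc_row)^2 + (cc - disc_col)^2)
    w_disc <- 1 / (1 + exp((d_disc - disc_r) / 1.5))
    w_cup <- 1 / (1 + exp((d_disc - cup_r) / 1.2))
    disc_col3 <- c(238, 208, 148)
    cup_col3 <- c(255, 238, 196)
    for (k in 1:3) {
      ch <- img[, , k]
      ch <- ch * (1 - w_disc) + disc_col3[k] * w_disc
      ch <- ch * (1 - w_cup) + cup_col3[k] * w_cup
      img[, , k] <- ch
    }

    # vessel tree: primary branches from the disc centre, one optional child
    vmask <- matrix(FALSE, s, s)
    n_br <- sample(params$n_vessel_branches[1]:params$n_vessel_branches[2], 1L)
    for (b in seq_len(n_br)) {
      th0 <- pi + stats::rnorm(1, 0, 1.1)  # biased away from the temporal rim
      wd <- stats::runif(1, params$vessel_width[1], params$vessel_width[2])
      path <- vessel_walk(disc_row, disc_col, th0, eye_c, eye_r)
      if (length(path$rows) == 0L) next
      vmask <- stamp_points(vmask, path$rows, path$cols, wd / 2)
      if (stats::runif(1) < 0.5 && length(path$rows) > 20L) {
        mid <- length(path$rows) %/% 2L
        child <- vessel_walk(path$rows[mid], path$cols[mid],
                             th0 + stats::runif(1, -1, 1), eye_c, eye_r,
                             max_steps = 200L)
        if (length(child$rows) > 0L) {
          vmask <- stamp_points(vmask, child$rows, child$cols,
                                max(1, wd / 2 - 0.5))
        }
      }
    }
    vmask <- vmask & eye
    vessel_col3 <- c(95, 36, 30)
    for (k in 1:3) {
      ch <- img[, , k]
      ch[vmask] <- 0.15 * ch[vmask] + 0.85 * vessel_col3[k]
      img[, , k] <- ch
    }

    # noise inside the eye field, hard black outside
    if (params$noise_sd > 0) {
      img <- img + array(stats::rnorm(length(img), 0, params$noise_sd),
                         dim(img))
    }
    img <- round(clamp(img, 0, 255))
    for (k in 1:3) {
      ch <- img[, , k]
      ch[!eye] <- 0
      img[, , k] <- ch
    }

    structure(list(
      image = fundus_image(img, meta = list(synthetic_seed = seed,
                                            label = label)),
      vessel_mask = binary_mask(vmask, "vessel-mask"),
      disc_center = c(row = disc_row, col = disc_col),
      disc_radius = disc_r, cup_radius = cup_r,
      label = label, seed = seed),
      class = "phantom_sample")
  })
}

#' Generate a balanced phantom dataset
#'
#' Per-sample seeds are derived from the master seed, so the dataset is fully
#' reproducible. When `dir` is given, writes `images/*.png`,
#' `vessel_masks/*.png`, `labels.csv`, and `manifest.json` in the layout the
#' pipeline consumes.
#'
#' @param n_per_class samples per class (>= 1).
#' @param params a [phantom_params].
#' @param seed master seed.
#' @param dir optional output directory.
#' @return a list: `samples` (list of `phantom_sample`), `labels`
#'   (a [label_table]).
#' @export
generate_dataset <- function(n_per_class, params = phantom_params(), seed,
                             dir = NULL) {
  abort_if(!is_count(n_per_class) || n_per_class < 1L,
           "generate_dataset: n_per_class must be >= 1")
  n <- 2L * n_per_class
  seeds <- local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  labels <- rep(c("glaucoma", "normal"), each = n_per_class)
  ids <- sprintf("%s_%03d", labels, c(seq_len(n_per_class),
                                      seq_len(n_per_class)))
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    samples[[i]] <- generate_phantom(labels[i], params, seeds[i])
    samples[[i]]$image_id <- ids[i]
  }
  tbl <- label_table(ids, labels)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "images"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(dir, "vessel_masks"), recursive = TRUE,
               showWarnings = FALSE)
    for (i in seq_len(n)) {
      write_image(samples[[i]]$image,
                  file.path(dir, "images", paste0(ids[i], ".png")))
      write_image(samples[[i]]$vessel_mask,
                  file.path(dir, "vessel_masks", paste0(ids[i], ".png")))
    }
    write_label_table(tbl, file.path(dir, "labels.csv"))
    jsonlite::write_json(
      list(n_per_class = n_per_class, seed = seed,
           params = unclass(params)),
      file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  list(samples = samples, labels = tbl)
}

#' Aligned grey/mask training patches for vessel segmentation
#'
#' Random 64 x 64 crops from the phantoms' grey images at native resolution,
#' with the bit-exact matching vessel-mask crops. At least half of the
#' returned patches are rejection-sampled to contain at least 1\% vessel
#' pixels, so training batches are never vessel-free.
#'
#' @param samples nonempty list of `phantom_sample` objects.
#' @param n_patches number of pairs to return (default 64).
#' @param seed integer seed.
#' @param patch_size crop edge (default 64).
#' @return a list of `list(image = gray 64 x 64, mask = binary 64 x 64,
#'   origin = c(sample, row, col))`; `origin` records the 1-based crop
#'   position so the mask's provenance is auditable.
#' @export
vessel_patch_pairs <- function(samples, n_patches = 64L, seed,
                               patch_size = 64L) {
  abort_if(length(samples) == 0L, "vessel_patch_pairs: samples is empty")
  local_seed(seed, {
    scaled <- lapply(samples, function(sm) {
      list(g = pixels(rgb_to_gray(sm$image)), m = pixels(sm$vessel_mask))
    })
    out <- vector("list", n_patches)
    n_rich <- ceiling(n_patches / 2)
    for (i in seq_len(n_patches)) {
      want_rich <- i <= n_rich
      for (try in 1:50) {
        si <- sample.int(length(scaled), 1L)
        sc <- scaled[[si]]
        r0 <- sample.int(nrow(sc$g) - patch_size + 1L, 1L)
        c0 <- sample.int(ncol(sc$g) - patch_size + 1L, 1L)
        gi <- sc$g[r0:(r0 + patch_size - 1L), c0:(c0 + patch_size - 1L)]
        mi <- sc$m[r0:(r0 + patch_size - 1L), c0:(c0 + patch_size - 1L)]
        if (!want_rich || mean(mi) >= 0.01) break
      }
      out[[i]] <- list(image = gray_image(gi),
                       mask = binary_mask(mi, "vessel-mask"),
                       origin = c(sample = si, row = r0, col = c0))
    }
    out
  })
}
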