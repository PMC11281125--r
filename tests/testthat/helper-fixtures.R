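# Shared fixtures, built in code. Phantoms are cached per test session since
# several files exercise the same seeded samples.

.fixture_env <- new.env(parent = emptyenv())

cached_phantom <- function(label, seed) {
  key <- paste0(label, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_phantom(label, phantom_params(),
                                            seed = seed)
  }
  .fixture_env[[key]]
}

random_rgb_raster <- function(h, w, seed) {
  withr::with_seed(seed, {
    array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3))
  })
}

random_gray_raster <- function(h, w, seed) {
  withr::with_seed(seed, {
    matrix(sample(0:255, h * w, replace = TRUE), h, w)
  })
}

# Solid grey image of one value
flat_rgb <- function(h, w, rgb) {
  px <- array(0, c(h, w, 3))
  for (k in 1:3) px[, , k] <- rgb[k]
  fundus_image(px)
}

# Small specs keeping network tests fast
small_branch <- function() branch_spec(c(2L, 3L, 4L, 5L))
small_head <- function() head_spec(c(6L, 7L, 8L), dense_units = c(8L, 2L))
small_resunet <- function(input_size = 64L) {
  resunet_spec(c(4L, 6L, 8L), 12L, input_size = input_size)
}
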