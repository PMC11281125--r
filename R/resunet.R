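# Patch-based retinal-vessel segmentation: a residual U-Net (six residual
# blocks — three encoder, three decoder — joined by a bridge, with one skip
# connection per level), sixteen-patch tiling of a 256 x 256 grey input, and
# the stitching that inverts it bit-exactly.

#' ResU-Net architecture specification
#'
#' @param encoder_filters filter counts of the three encoder residual blocks
#'   (default `c(16, 32, 64)`); the decoder mirrors them.
#' @param bridge_filters filter count of the bridge block (default 128).
#' @param input_size input patch edge length (default 64); must be divisible
#'   by 8 (three 2x pooling stages).
#' @return a `resunet_spec` list; `n_residual_blocks` is always 6.
#' @export
resunet_spec <- function(encoder_filters = c(16L, 32L, 64L),
                         bridge_filters = 128L,
                         input_size = 64L) {
  abort_if(length(encoder_filters) != 3L,
           "resunet_spec: exactly three encoder levels are supported")
  abort_if(input_size %% 8L != 0L || input_size < 8L,
           "resunet_spec: input_size must be a positive multiple of 8")
  structure(list(encoder_filters = as.integer(encoder_filters),
                 bridge_filters = as.integer(bridge_filters),
                 input_size = as.integer(input_size),
                 n_residual_blocks = 6L),
            class = "resunet_spec")
}

# Residual block: conv-BN-ReLU, conv-BN, identity shortcut (1x1 projection
# when channel counts differ), ReLU. The `add` node carries the
# "residual_block" role tag used by introspection.
add_res_block <- function(net, prefix, input, filters) {
  cin <- net$shapes[[input]][3]
  net <- nn_add(net, paste0(prefix, "_c1"), nn_conv(filters, 3L), input)
  net <- nn_add(net, paste0(prefix, "_bn1"), nn_bn(), paste0(prefix, "_c1"))
  net <- nn_add(net, paste0(prefix, "_r1"), nn_relu(), paste0(prefix, "_bn1"))
  net <- nn_add(net, paste0(prefix, "_c2"), nn_conv(filters, 3L),
                paste0(prefix, "_r1"))
  net <- nn_add(net, paste0(prefix, "_bn2"), nn_bn(), paste0(prefix, "_c2"))
  shortcut <- input
  if (cin != filters) {
    net <- nn_add(net, paste0(prefix, "_proj"), nn_conv(filters, 1L), input)
    shortcut <- paste0(prefix, "_proj")
  }
  net <- nn_add(net, paste0(prefix, "_add"), nn_add_op(),
                c(paste0(prefix, "_bn2"), shortcut), role = "residual_block")
  nn_add(net, paste0(prefix, "_out"), nn_relu(), paste0(prefix, "_add"))
}

#' Build a ResU-Net segmentation model
#'
#' Encoder of three residual blocks with 2x2 max-pool downsampling, a
#' two-convolution bridge, and a decoder of three residual blocks with
#' nearest-neighbour upsampling and per-level skip concatenation; final 1x1
#' convolution with sigmoid, so the output is a single-channel map in
#' \[0, 1\] of the input size.
#'
#' @param spec a [resunet_spec].
#' @param seed optional integer; seeds weight initialisation.
#' @return a `resunet_model` (fields `net`, `spec`).
#' @export
build_resunet <- function(spec = resunet_spec(), seed = NULL) {
  abort_if(!inherits(spec, "resunet_spec"), "build_resunet: invalid spec")
  build <- function() {
    f <- spec$encoder_filters
    net <- nn_network(list(x = c(spec$input_size, spec$input_size, 1L)))
    net <- add_res_block(net, "enc1", "x", f[1])
    net <- nn_add(net, "pool1", nn_pool(), "enc1_out")
    net <- add_res_block(net, "enc2", "pool1", f[2])
    net <- nn_add(net, "pool2", nn_pool(), "enc2_out")
    net <- add_res_block(net, "enc3", "pool2", f[3])
    net <- nn_add(net, "pool3", nn_pool(), "enc3_out")
    net <- nn_add(net, "bridge_c1", nn_conv(spec$bridge_filters, 3L, "relu"),
                  "pool3", role = "bridge")
    net <- nn_add(net, "bridge_c2", nn_conv(spec$bridge_filters, 3L, "relu"),
                  "bridge_c1", role = "bridge")
    net <- nn_add(net, "up1", nn_upsample(), "bridge_c2")
    net <- nn_add(net, "skip1", nn_concat(), c("up1", "enc3_out"),
                  role = "skip")
    net <- add_res_block(net, "dec1", "skip1", f[3])
    net <- nn_add(net, "up2", nn_upsample(), "dec1_out")
    net <- nn_add(net, "skip2", nn_concat(), c("up2", "enc2_out"),
                  role = "skip")
    net <- add_res_block(net, "dec2", "skip2", f[2])
    net <- nn_add(net, "up3", nn_upsample(), "dec2_out")
    net <- nn_add(net, "skip3", nn_concat(), c("up3", "enc1_out"),
                  role = "skip")
    net <- add_res_block(net, "dec3", "skip3", f[1])
    nn_add(net, "head", nn_conv(1L, 1L, "sigmoid"), "dec3_out", role = "head")
  }
  net <- if (is.null(seed)) build() else local_seed(seed, build())
  structure(list(net = net, spec = spec), class = "resunet_model")
}

#' Count residual blocks of a model
#' @param model a model wrapping an `nn_network`.
#' @return integer count of residual-block nodes.
#' @export
n_residual_blocks <- function(model) {
  sum(nn_layer_table(model)$role == "residual_block", na.rm = TRUE)
}

#' Count skip connections of a model
#' @param model a model wrapping an `nn_network`.
#' @return integer count of encoder-to-decoder skip concatenations.
#' @export
n_skip_connections <- function(model) {
  sum(nn_layer_table(model)$role == "skip", na.rm = TRUE)
}

#' @export
print.resunet_model <- function(x, ...) {
  cat(sprintf("<resunet_model %d residual blocks, %d skips, filters [%s]+%d, input %d>\n",
              n_residual_blocks(x), n_skip_connections(x),
              paste(x$spec$encoder_filters, collapse = ","),
              x$spec$bridge_filters, x$spec$input_size))
  invisible(x)
}

# ---- tiling ----------------------------------------------------------------

#' Tile a 256 x 256 grey image into sixteen 64 x 64 patches
#'
#' Non-overlapping 4 x 4 tiling in row-major order: patch (i, j) covers rows
#' `[64i, 64i + 64)` and columns `[64j, 64j + 64)` (0-based, half-open).
#'
#' @param img a [gray_image] or numeric matrix, exactly 256 x 256.
#' @return a `patch_grid`: `patches` (list of 16 matrices, row-major),
#'   `grid` (the 4 x 4 index map), `source_size` (256).
#' @export
tile_image <- function(img) {
  m <- pixels(img)
  abort_if(!all(dim(m) == c(256L, 256L)),
           "tile_image: input must be exactly 256 x 256",
           class = "fundustruct_param_error")
  patches <- vector("list", 16L)
  k <- 1L
  for (i in 0:3) for (j in 0:3) {
    patches[[k]] <- m[(64L * i + 1L):(64L * i + 64L),
                      (64L * j + 1L):(64L * j + 64L)]
    k <- k + 1L
  }
  structure(list(patches = patches,
                 grid = matrix(1:16, 4L, 4L, byrow = TRUE),
                 source_size = 256L),
            class = "patch_grid")
}

#' Stitch a patch grid back into the source image
#'
#' Exact inverse of [tile_image()]: `stitch_patches(tile_image(x))` equals
#' `x` bit-exactly.
#'
#' @param grid a `patch_grid`.
#' @return a 256 x 256 matrix.
#' @export
stitch_patches <- function(grid) {
  abort_if(!inherits(grid, "patch_grid") || length(grid$patches) != 16L,
           "stitch_patches: malformed patch grid")
  abort_if(!all(vapply(grid$patches, function(p)
    is.matrix(p) && all(dim(p) == c(64L, 64L)), TRUE)),
    "stitch_patches: every patch must be a 64 x 64 matrix")
  m <- matrix(0, 256L, 256L)
  for (i in 0:3) for (j in 0:3) {
    m[(64L * i + 1L):(64L * i + 64L), (64L * j + 1L):(64L * j + 64L)] <-
      grid$patches[[grid$grid[i + 1L, j + 1L]]]
  }
  if (all(vapply(grid$patches, is.integer, TRUE))) storage.mode(m) <- "integer"
  m
}

# ---- training and inference ------------------------------------------------

#' Vessel-segmentation training configuration
#'
#' @param epochs training epochs (>= 1).
#' @param batch_size minibatch size (default 8).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param loss `"bce"` (binary cross-entropy; the only loss currently wired).
#' @param pos_weight weight of vessel pixels in the loss, compensating the
#'   strong background/vessel imbalance (default 8).
#' @param seed integer fixing initialisation and shuffling.
#' @return a `vessel_train_config` list.
#' @export
vessel_train_config <- function(epochs = 10L, batch_size = 8L,
                                learning_rate = 1e-3, loss = "bce",
                                pos_weight = 8, seed = 1L) {
  abort_if(!is_count(epochs) || epochs < 1L,
           "vessel_train_config: epochs must be >= 1")
  abort_if(loss != "bce", "vessel_train_config: unsupported loss ", loss)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, loss = loss,
                 pos_weight = pos_weight, seed = as.integer(seed)),
            class = "vessel_train_config")
}

patches_to_tensor <- function(patches, size) {
  n <- length(patches)
  x <- array(0, c(n, size, size, 1L))
  for (i in seq_len(n)) {
    p <- pixels(patches[[i]])
    x[i, , , 1L] <- if (max(p) > 1) p / 255 else p
  }
  x
}

#' Train the vessel-segmentation model
#'
#' Trains a ResU-Net on aligned (grey patch, binary vessel mask) pairs with
#' binary cross-entropy and Adam; fully deterministic under the config seed.
#'
#' @param pairs list of `list(image = , mask = )` pairs, both 64 x 64
#'   (e.g. from [vessel_patch_pairs()]).
#' @param cfg a [vessel_train_config].
#' @param spec a [resunet_spec] for the model architecture.
#' @return a list: `model` (a `resunet_model`) and `history` (per-epoch mean
#'   loss data.frame).
#' @export
train_vessel_model <- function(pairs, cfg = vessel_train_config(),
                               spec = resunet_spec()) {
  abort_if(length(pairs) == 0L, "train_vessel_model: empty training set",
           class = "fundustruct_param_error")
  s <- spec$input_size
  x <- patches_to_tensor(lapply(pairs, `[[`, "image"), s)
  y <- array(0, c(length(pairs), s, s, 1L))
  for (i in seq_along(pairs)) {
    mp <- pixels(pairs[[i]]$mask)
    abort_if(!all(mp %in% c(0L, 1L)), "train_vessel_model: masks must be binary")
    y[i, , , 1L] <- mp
  }
  local_seed(cfg$seed, {
    model <- build_resunet(spec)
    history <- fit_network(model$net, list(x = x), y, loss = "bce",
                           epochs = cfg$epochs, batch_size = cfg$batch_size,
                           lr = cfg$learning_rate,
                           pos_weight = cfg$pos_weight)
    list(model = model, history = history)
  })
}

#' Dice coefficient between two binary masks
#'
#' @param pred predicted mask (matrix/array in \{0, 1\}, or probabilities to
#'   be thresholded at 0.5).
#' @param truth ground-truth mask.
#' @return Dice score in \[0, 1\]; 1 when both masks are empty.
#' @export
dice_coefficient <- function(pred, truth) {
  p <- as.numeric(pixels(pred)) >= 0.5
  t <- as.numeric(pixels(truth)) >= 0.5
  denom <- sum(p) + sum(t)
  if (denom == 0) return(1)
  2 * sum(p & t) / denom
}

#' Segment retinal vessels in a fundus image
#'
#' Grey conversion, bilinear resize to 256 x 256, sixteen-patch tiling,
#' per-patch ResU-Net inference, stitching back to 256 x 256, and resize to
#' `classifier_size`; output values lie in \[0, 1\].
#'
#' @param img a [fundus_image] or [gray_image] (any size).
#' @param model a trained (or freshly built) `resunet_model` with
#'   `input_size` 64.
#' @param classifier_size output edge length (default 64).
#' @return a numeric `classifier_size` x `classifier_size` vessel probability
#'   map in \[0, 1\].
#' @export
segment_vessels <- function(img, model, classifier_size = 64L) {
  abort_if(!inherits(model, "resunet_model"), "segment_vessels: invalid model")
  abort_if(model$spec$input_size != 64L,
           "segment_vessels: the tiling pipeline requires 64 x 64 patches")
  g <- if (length(dim(pixels(img))) == 3L) pixels(rgb_to_gray(img))
       else pixels(img)
  if (!all(dim(g) == c(256L, 256L))) {
    g <- clamp(resize_matrix(g, 256L, 256L), 0, 255)
  }
  grid <- tile_image(round(g))
  x <- patches_to_tensor(grid$patches, 64L)
  pred <- net_forward(model$net, list(x = x), train = FALSE)
  out_grid <- grid
  for (i in 1:16) out_grid$patches[[i]] <- matrix(pred[i, , , 1L], 64L, 64L)
  full <- stitch_patches(out_grid)
  clamp(resize_matrix(full, classifier_size, classifier_size), 0, 1)
}
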