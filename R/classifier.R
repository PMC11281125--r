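# The three-branch glaucoma classifier: one CNN branch per input
# (preprocessed image, vessel map, optic-disc crop), scaled dot-product
# attention fusing each structure branch with the image branch as query, a
# convolutional head, and a two-class softmax; plus the attention-free
# concatenation ablation that shares the same head.

#' CNN branch specification
#'
#' Four 3 x 3 convolution layers with ReLU; BatchNorm + 2 x 2 MaxPool applied
#' exactly twice (after layers 2 and 4), so the output spatial size is a
#' quarter of the input.
#'
#' @param conv_filters filter counts of the four convolutions (default
#'   `c(64, 128, 256, 512)`).
#' @param kernel convolution kernel edge (default 3).
#' @param input_size input edge length (default 64).
#' @return a `branch_spec` list.
#' @export
branch_spec <- function(conv_filters = c(64L, 128L, 256L, 512L),
                        kernel = 3L, input_size = 64L) {
  abort_if(length(conv_filters) != 4L,
           "branch_spec: exactly four convolution layers are required")
  abort_if(input_size %% 4L != 0L,
           "branch_spec: input_size must be divisible by 4")
  structure(list(conv_filters = as.integer(conv_filters),
                 kernel = as.integer(kernel),
                 input_size = as.integer(input_size)),
            class = "branch_spec")
}

#' Classifier head specification
#'
#' Three convolutions after the fusion (the last with a 1 x 1 kernel),
#' BatchNorm, flatten, then dense layers ending in a two-class softmax.
#'
#' @param conv_filters head convolution filters (default
#'   `c(2048, 4096, 4096)`).
#' @param kernel kernel of the first two head convolutions (default 3; with
#'   1 the head acts as a per-position MLP, which preserves the
#'   count-of-activated-positions structure that global pooling consumes).
#' @param final_kernel kernel of the last head convolution (default 1).
#' @param dense_units dense layer widths; the last must be 2 (default
#'   `c(256, 2)`).
#' @param global_pool if `TRUE`, collapse the final feature map by global
#'   average pooling instead of flattening before the dense layers. The
#'   default keeps the flatten; pooling yields per-channel activation counts,
#'   a scale-robust summary that generalises from far fewer images (the
#'   pipeline's desk-scale configuration uses it).
#' @return a `head_spec` list.
#' @export
head_spec <- function(conv_filters = c(2048L, 4096L, 4096L),
                      kernel = 3L,
                      final_kernel = 1L, dense_units = c(256L, 2L),
                      global_pool = FALSE) {
  abort_if(length(conv_filters) != 3L,
           "head_spec: exactly three head convolutions are required")
  abort_if(final_kernel != 1L, "head_spec: the final convolution must be 1 x 1")
  abort_if(utils::tail(dense_units, 1L) != 2L,
           "head_spec: the final dense layer must have width 2")
  structure(list(conv_filters = as.integer(conv_filters),
                 kernel = as.integer(kernel),
                 final_kernel = as.integer(final_kernel),
                 dense_units = as.integer(dense_units),
                 global_pool = isTRUE(global_pool)),
            class = "head_spec")
}

CLASS_LEVELS <- c("glaucoma", "normal")

# Branch: conv-conv-BN-pool-conv-conv-BN-pool; returns the updated net, the
# output node id carries the "branch_output" role.
add_branch <- function(net, prefix, input, spec) {
  f <- spec$conv_filters; k <- spec$kernel
  net <- nn_add(net, paste0(prefix, "_c1"), nn_conv(f[1], k, "relu"), input)
  net <- nn_add(net, paste0(prefix, "_c2"), nn_conv(f[2], k, "relu"),
                paste0(prefix, "_c1"))
  net <- nn_add(net, paste0(prefix, "_bn1"), nn_bn(), paste0(prefix, "_c2"))
  net <- nn_add(net, paste0(prefix, "_p1"), nn_pool(), paste0(prefix, "_bn1"))
  net <- nn_add(net, paste0(prefix, "_c3"), nn_conv(f[3], k, "relu"),
                paste0(prefix, "_p1"))
  net <- nn_add(net, paste0(prefix, "_c4"), nn_conv(f[4], k, "relu"),
                paste0(prefix, "_c3"))
  net <- nn_add(net, paste0(prefix, "_bn2"), nn_bn(), paste0(prefix, "_c4"))
  nn_add(net, paste0(prefix, "_out"), nn_pool(), paste0(prefix, "_bn2"),
         role = "branch_output")
}

#' Build a single CNN feature-extraction branch
#'
#' @param spec a [branch_spec].
#' @param seed optional integer; seeds weight initialisation.
#' @return a `branch_model` (fields `net`, `spec`); its forward pass maps
#'   `input_size^2 x 1` to `(input_size/4)^2 x conv_filters[4]`.
#' @export
build_branch <- function(spec = branch_spec(), seed = NULL) {
  abort_if(!inherits(spec, "branch_spec"), "build_branch: invalid spec")
  s <- spec$input_size
  build <- function() {
    net <- nn_network(list(x = c(s, s, 1L)))
    add_branch(net, "branch", "x", spec)
  }
  net <- if (is.null(seed)) build() else local_seed(seed, build())
  structure(list(net = net, spec = spec), class = "branch_model")
}

#' Filter sequence of the convolution layers of a model
#'
#' @param model a model wrapping an `nn_network`.
#' @param prefix optional node-id prefix restricting the scan (e.g. a branch).
#' @return integer vector of filter counts in layer order (1 x 1 residual
#'   projections excluded).
#' @export
conv_filter_sequence <- function(model, prefix = NULL) {
  tab <- nn_layer_table(model)
  tab <- tab[tab$type == "conv" & !grepl("_proj$", tab$id), ]
  if (!is.null(prefix)) tab <- tab[startsWith(tab$id, prefix), ]
  tab$filters
}

#' Scaled dot-product attention between two feature maps
#'
#' Flattens the spatial positions of both maps; queries come from
#' `query_feats`, keys and values from `key_value_feats`. Per-query weights
#' are `softmax(q . k / sqrt(C))`: nonnegative and summing to one. The output
#' has the key/value map's shape.
#'
#' @param query_feats feature map `H x W x C` (or a batch `N x H x W x C`).
#' @param key_value_feats feature map of the same shape.
#' @param return_weights also return the attention weight matrix (one
#'   `P x P` matrix per sample, `P = H * W`).
#' @return the attended map; if `return_weights`, a list
#'   `list(output, weights)`.
#' @export
attention_fuse <- function(query_feats, key_value_feats,
                           return_weights = FALSE) {
  q <- query_feats; kv <- key_value_feats
  single <- length(dim(q)) == 3L
  if (single) {
    dim(q) <- c(1L, dim(q))
    dim(kv) <- c(1L, dim(kv))
  }
  abort_if(!all(dim(q) == dim(kv)),
           "attention_fuse: query and key/value shapes differ")
  layer <- nn_attention()
  out <- layer_forward(layer, list(q, kv))
  w <- layer$cache$A
  if (single) {
    d <- dim(out)
    out <- array(out[1, , , ], d[-1])
    w <- w[[1]]
  }
  if (return_weights) list(output = out, weights = w) else out
}

#' Build the multi-input glaucoma classifier
#'
#' Three inputs (`image`, `vessel`, `disc`, each `input_size^2 x 1`), one CNN
#' branch per input. In `"attention"` mode the vessel and disc branch outputs
#' are each attention-fused with the image branch as query and the two
#' attended maps concatenated (2 x branch channels); in `"concat"` mode the
#' three branch outputs are concatenated directly (3 x branch channels).
#' Either way the fusion is followed by BatchNorm, 2 x 2 MaxPool, the three
#' head convolutions (last one 1 x 1), BatchNorm, flatten, and dense layers
#' with ReLU then a two-class softmax.
#'
#' @param branch a [branch_spec] (shared hyper-parameters; each branch has
#'   its own weights).
#' @param head a [head_spec].
#' @param fusion `"attention"` or `"concat"` (the ablation variant).
#' @param seed optional integer; seeds weight initialisation.
#' @return a `glaucoma_model` (fields `net`, `branch`, `head`, `fusion`,
#'   `classes`).
#' @export
build_glaucoma_model <- function(branch = branch_spec(), head = head_spec(),
                                 fusion = c("attention", "concat"),
                                 seed = NULL) {
  fusion <- match.arg(fusion)
  abort_if(!inherits(branch, "branch_spec") || !inherits(head, "head_spec"),
           "build_glaucoma_model: invalid specs")
  s <- branch$input_size
  build <- function() {
    net <- nn_network(list(image = c(s, s, 1L), vessel = c(s, s, 1L),
                           disc = c(s, s, 1L)))
    net <- add_branch(net, "img", "image", branch)
    net <- add_branch(net, "ves", "vessel", branch)
    net <- add_branch(net, "dsc", "disc", branch)
    if (fusion == "attention") {
      net <- nn_add(net, "att_vessel", nn_attention(),
                    c("img_out", "ves_out"), role = "attention")
      net <- nn_add(net, "att_disc", nn_attention(),
                    c("img_out", "dsc_out"), role = "attention")
      net <- nn_add(net, "fused", nn_concat(), c("att_vessel", "att_disc"),
                    role = "fusion")
    } else {
      net <- nn_add(net, "fused", nn_concat(),
                    c("img_out", "ves_out", "dsc_out"), role = "fusion")
    }
    net <- nn_add(net, "fuse_bn", nn_bn(), "fused")
    net <- nn_add(net, "fuse_pool", nn_pool(), "fuse_bn")
    net <- nn_add(net, "head_c1",
                  nn_conv(head$conv_filters[1], head$kernel, "relu"),
                  "fuse_pool", role = "head")
    net <- nn_add(net, "head_c2",
                  nn_conv(head$conv_filters[2], head$kernel, "relu"),
                  "head_c1", role = "head")
    net <- nn_add(net, "head_c3",
                  nn_conv(head$conv_filters[3], head$final_kernel, "relu"),
                  "head_c2", role = "head")
    net <- nn_add(net, "head_bn", nn_bn(), "head_c3")
    net <- nn_add(net, "flat",
                  if (head$global_pool) nn_gap() else nn_flatten(),
                  "head_bn")
    du <- head$dense_units
    prev <- "flat"
    for (i in seq_along(du)) {
      id <- paste0("fc", i)
      act <- if (i == length(du)) "softmax" else "relu"
      net <- nn_add(net, id, nn_dense(du[i], act), prev,
                    role = if (i == length(du)) "output" else NA_character_)
      prev <- id
    }
    net
  }
  net <- if (is.null(seed)) build() else local_seed(seed, build())
  structure(list(net = net, branch = branch, head = head, fusion = fusion,
                 classes = CLASS_LEVELS),
            class = "glaucoma_model")
}

#' Channel count entering the classifier head
#'
#' 2 x branch channels in attention mode, 3 x in concat-ablation mode.
#'
#' @param model a `glaucoma_model`.
#' @return integer channel count of the fusion node.
#' @export
pre_head_channels <- function(model) {
  model$net$shapes[["fused"]][3]
}

#' @export
print.glaucoma_model <- function(x, ...) {
  cat(sprintf("<glaucoma_model fusion=%s, branch [%s], head [%s], pre-head %d ch>\n",
              x$fusion, paste(x$branch$conv_filters, collapse = ","),
              paste(x$head$conv_filters, collapse = ","),
              pre_head_channels(x)))
  invisible(x)
}

# Centre zoom of a matrix by factor f (inverse-map bilinear, black fill).
zoom_matrix <- function(m, f) {
  h <- nrow(m); w <- ncol(m)
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  sr <- (rep(seq_len(h), times = w) - cr) / f + cr
  sc <- (rep(seq_len(w), each = h) - cc) / f + cc
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  val <- function(ri, ci) {
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    v <- numeric(length(ri))
    v[ok] <- m[cbind(ri[ok], ci[ok])]
    v
  }
  matrix((1 - fr) * (1 - fc) * val(r0, c0) +
           (1 - fr) * fc * val(r0, c0 + 1) +
           fr * (1 - fc) * val(r0 + 1, c0) +
           fr * fc * val(r0 + 1, c0 + 1), h, w)
}

# Batch augmenter: an optional per-sample zoom shared across the three
# inputs, plus modality dropout — zeroing the image and vessel inputs of
# random samples so every branch must be independently predictive (the disc
# branch carries the diagnostic signal; without dropout the richer image
# texture lets the network memorise instead). `modality_dropout` may be a
# per-epoch vector: a warm-up schedule that starts at 1 trains the disc
# pathway alone first, then phases the other modalities in.
make_input_augmenter <- function(zoom_range = NULL, modality_dropout = 0) {
  function(xb, epoch = 1L) {
    n <- dim(xb[[1]])[1]
    if (!is.null(zoom_range) && diff(range(zoom_range)) > 0) {
      fs <- stats::runif(n, zoom_range[1], zoom_range[2])
      for (j in seq_along(xb)) {
        for (i in seq_len(n)) {
          xb[[j]][i, , , 1] <- zoom_matrix(xb[[j]][i, , , 1], fs[i])
        }
      }
    }
    p <- modality_dropout[min(epoch, length(modality_dropout))]
    if (p > 0) {
      for (nm in c("image", "vessel")) {
        drop <- if (p >= 1) rep(TRUE, n) else stats::runif(n) < p
        if (any(drop)) xb[[nm]][drop, , , ] <- 0
      }
    }
    xb
  }
}

# Normalise a raster/matrix to a [0,1] numeric matrix of edge `s`.
as_unit_input <- function(x, s) {
  m <- pixels(x)
  abort_if(!all(dim(m)[1:2] == c(s, s)),
           "classifier input must be ", s, " x ", s)
  m <- as.numeric(m)
  if (max(m) > 1) m <- m / 255
  matrix(m, s, s)
}

# Stack lists of image/vessel/disc rasters into the network's input tensors.
triples_to_tensors <- function(images, vessels, discs, s) {
  n <- length(images)
  mk <- function(lst) {
    x <- array(0, c(n, s, s, 1L))
    for (i in seq_len(n)) x[i, , , 1L] <- as_unit_input(lst[[i]], s)
    x
  }
  list(image = mk(images), vessel = mk(vessels), disc = mk(discs))
}

#' Assemble a labelled classifier dataset
#'
#' @param images,vessels,discs aligned lists of 64 x 64 rasters (grey images,
#'   \[0, 1\] maps, or matrices).
#' @param labels character vector of `"glaucoma"`/`"normal"`, aligned with
#'   the rasters.
#' @return a `classifier_dataset` list of input tensors and labels.
#' @export
classifier_dataset <- function(images, vessels, discs, labels) {
  n <- length(images)
  abort_if(length(vessels) != n || length(discs) != n || length(labels) != n,
           "classifier_dataset: inputs must be aligned per image")
  labels <- tolower(as.character(labels))
  abort_if(!all(labels %in% CLASS_LEVELS),
           "classifier_dataset: labels must be glaucoma/normal")
  s <- dim(pixels(images[[1]]))[1]
  structure(c(triples_to_tensors(images, vessels, discs, s),
              list(labels = labels, size = s)),
            class = "classifier_dataset")
}

labels_to_onehot <- function(labels) {
  y <- matrix(0, length(labels), 2L,
              dimnames = list(NULL, CLASS_LEVELS))
  y[cbind(seq_along(labels), match(labels, CLASS_LEVELS))] <- 1
  y
}

#' Classifier training configuration
#'
#' @param epochs training epochs (>= 1).
#' @param batch_size minibatch size (default 16).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param optimizer `"adam"` (the only optimiser wired).
#' @param weight_decay decoupled L2 weight decay on convolution/dense weights
#'   (default 1e-4; the small phantom datasets overfit quickly without it).
#' @param input_noise_sd standard deviation of Gaussian jitter added to the
#'   \[0, 1\] input maps of every training batch (default 0.05). With a few
#'   dozen base images the jitter is what stops the network from memorising
#'   per-image pixel signatures instead of the class geometry; validation
#'   inputs are never jittered.
#' @param zoom_range optional range of a random per-sample zoom factor
#'   applied jointly to the three input maps of every training batch
#'   (default `NULL`, disabled). Zoom jitter removes absolute-size shortcuts
#'   but slows convergence enough that it rarely pays within a small epoch
#'   budget; modality dropout and input jitter are the default regularisers.
#' @param modality_dropout probability of zeroing the image and (independently)
#'   the vessel input of a training sample, so no branch can free-ride on
#'   another's memorisation; validation inputs are untouched. A per-epoch
#'   vector defines a schedule — the default warms up with the structure-only
#'   phase (probability 1 for the first 40\% of epochs, i.e. the disc branch
#'   is learned first) before relaxing to 0.2.
#' @param seed integer fixing initialisation, split, and shuffling.
#' @param val_every evaluate the validation split every this many epochs
#'   (the last epoch is always evaluated; evaluation never perturbs
#'   training, so this is purely a runtime knob).
#' @param val_fraction share of samples held out for validation when no
#'   explicit validation set is given (stratified; default 0.25).
#' @return a `classifier_train_config` list.
#' @export
classifier_train_config <- function(epochs = 15L, batch_size = 16L,
                                    learning_rate = 1e-3, optimizer = "adam",
                                    weight_decay = 1e-4,
                                    input_noise_sd = 0.05,
                                    zoom_range = NULL,
                                    modality_dropout = NULL,
                                    seed = 1L, val_every = 1L,
                                    val_fraction = 0.25) {
  abort_if(!is_count(epochs) || epochs < 1L,
           "classifier_train_config: epochs must be >= 1")
  abort_if(optimizer != "adam",
           "classifier_train_config: unsupported optimizer ", optimizer)
  if (is.null(modality_dropout)) {
    warm <- max(1L, round(0.4 * epochs))
    modality_dropout <- c(rep(1, warm), rep(0.2, epochs - warm))
  }
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 weight_decay = weight_decay,
                 input_noise_sd = input_noise_sd,
                 zoom_range = zoom_range,
                 modality_dropout = modality_dropout,
                 val_every = as.integer(val_every),
                 loss = "categorical_crossentropy",
                 seed = as.integer(seed), val_fraction = val_fraction),
            class = "classifier_train_config")
}

subset_dataset <- function(ds, idx) {
  structure(list(image = batch_slice(ds$image, idx),
                 vessel = batch_slice(ds$vessel, idx),
                 disc = batch_slice(ds$disc, idx),
                 labels = ds$labels[idx], size = ds$size),
            class = "classifier_dataset")
}

#' Train the glaucoma classifier
#'
#' Trains a three-branch model (attention or concat-ablation fusion) with
#' Adam on categorical cross-entropy; deterministic under the config seed.
#' If no validation set is supplied, a seeded stratified split holds out
#' `val_fraction` of the samples.
#'
#' @param dataset a [classifier_dataset]; both classes must be present.
#' @param cfg a [classifier_train_config].
#' @param fusion `"attention"` or `"concat"`.
#' @param branch a [branch_spec].
#' @param head a [head_spec].
#' @param val optional explicit validation [classifier_dataset].
#' @return a list: `model` (a `glaucoma_model`), `history` (per-epoch
#'   train/validation loss and accuracy), `val` (the validation dataset).
#' @export
train_classifier <- function(dataset, cfg = classifier_train_config(),
                             fusion = c("attention", "concat"),
                             branch = branch_spec(), head = head_spec(),
                             val = NULL) {
  fusion <- match.arg(fusion)
  abort_if(!inherits(dataset, "classifier_dataset"),
           "train_classifier: dataset must be a classifier_dataset")
  abort_if(length(unique(dataset$labels)) < 2L,
           "train_classifier: both classes must be present",
           class = "fundustruct_param_error")
  local_seed(cfg$seed, {
    if (is.null(val)) {
      val_idx <- unlist(lapply(CLASS_LEVELS, function(cl) {
        ids <- which(dataset$labels == cl)
        sample(ids, max(1L, round(cfg$val_fraction * length(ids))))
      }))
      val <- subset_dataset(dataset, val_idx)
      dataset <- subset_dataset(dataset, setdiff(seq_along(dataset$labels),
                                                 val_idx))
    }
    model <- build_glaucoma_model(branch, head, fusion)
    history <- fit_network(
      model$net,
      list(image = dataset$image, vessel = dataset$vessel,
           disc = dataset$disc),
      labels_to_onehot(dataset$labels),
      loss = "softmax_ce",
      epochs = cfg$epochs, batch_size = cfg$batch_size,
      # smooth 1 -> 1/3 learning-rate decay stabilises the late epochs
      lr = cfg$learning_rate /
        (1 + 2 * (seq_len(cfg$epochs) - 1) / cfg$epochs),
      weight_decay = cfg$weight_decay,
      input_noise_sd = cfg$input_noise_sd,
      augment_fn = if ((!is.null(cfg$zoom_range) &&
                          diff(range(cfg$zoom_range)) > 0) ||
                         any(cfg$modality_dropout > 0))
        make_input_augmenter(cfg$zoom_range, cfg$modality_dropout),
      val_x = list(image = val$image, vessel = val$vessel, disc = val$disc),
      val_y = labels_to_onehot(val$labels), val_every = cfg$val_every)
    list(model = model, history = history, val = val)
  })
}

#' Class probabilities for a batch of input triples
#'
#' @param model a trained `glaucoma_model`.
#' @param dataset a [classifier_dataset] (labels may be arbitrary).
#' @return an N x 2 matrix of probabilities, columns `glaucoma`, `normal`.
#' @export
predict_proba <- function(model, dataset) {
  abort_if(!inherits(model, "glaucoma_model"), "predict_proba: invalid model")
  p <- net_forward(model$net,
                   list(image = dataset$image, vessel = dataset$vessel,
                        disc = dataset$disc),
                   train = FALSE)
  colnames(p) <- model$classes
  p
}

#' Predict the class of one input triple
#'
#' @param object a trained `glaucoma_model`.
#' @param triple a list with elements `image`, `vessel`, `disc`, each a
#'   64 x 64 raster or matrix.
#' @param ... unused.
#' @return a list: `label` (argmax class) and `probs` (named 2-vector
#'   summing to 1).
#' @export
predict.glaucoma_model <- function(object, triple, ...) {
  s <- object$branch$input_size
  ds <- structure(triples_to_tensors(list(triple$image), list(triple$vessel),
                                     list(triple$disc), s),
                  class = "classifier_dataset")
  p <- predict_proba(object, ds)[1L, ]
  list(label = object$classes[which.max(p)], probs = p)
}

#' Attention weights of the model's last forward pass
#'
#' @param model a `glaucoma_model` built with attention fusion.
#' @return a named list (`vessel`, `disc`) of per-sample attention weight
#'   matrices from the most recent forward pass.
#' @export
attention_weights <- function(model) {
  abort_if(model$fusion != "attention",
           "attention_weights: model has no attention layers")
  list(vessel = model$net$nodes[["att_vessel"]]$layer$cache$A,
       disc = model$net$nodes[["att_disc"]]$layer$cache$A)
}
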