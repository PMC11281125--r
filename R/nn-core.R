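# A small CPU neural-network engine used by the segmentation and
# classification models. Tensors are numeric arrays [N, H, W, C] (dense
# activations are [N, F]); convolutions are im2col + BLAS matmul; networks
# are DAGs of layers with explicit node ids so architectures can be
# introspected (block counts, skip connections, filter sequences).
#
# Output-layer convention: layers whose activation is "sigmoid" or "softmax"
# are loss-fused — their backward pass expects the incoming gradient to be
# taken with respect to the PRE-activation (the loss functions below supply
# exactly that), which is both numerically stable and cheap.

# ---- layer constructors ----------------------------------------------------

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- list()
  e$grads <- list()
  e$cache <- list()
  fields <- list(...)
  for (n in names(fields)) assign(n, fields[[n]], envir = e)
  class(e) <- c(paste0("nn_", type), "nn_layer")
  e
}

nn_conv <- function(filters, kernel = 3L, activation = "linear") {
  stopifnot(kernel %% 2L == 1L)
  new_layer("conv", filters = as.integer(filters), kernel = as.integer(kernel),
            activation = activation)
}
nn_bn <- function() new_layer("bn", momentum = 0.9, eps = 1e-5)
nn_relu <- function() new_layer("relu")
nn_pool <- function() new_layer("pool")
nn_upsample <- function() new_layer("upsample")
nn_concat <- function() new_layer("concat")
nn_add_op <- function() new_layer("add")
nn_flatten <- function() new_layer("flatten")
nn_gap <- function() new_layer("gap")
nn_dense <- function(units, activation = "linear") {
  new_layer("dense", units = as.integer(units), activation = activation)
}
nn_attention <- function() new_layer("attention")

# ---- shape inference -------------------------------------------------------

layer_out_shape <- function(layer, in_shapes) {
  s <- in_shapes[[1]]
  switch(layer$type,
    conv = c(s[1], s[2], layer$filters),
    bn = s,
    relu = s,
    pool = c(s[1] %/% 2L, s[2] %/% 2L, s[3]),
    upsample = c(s[1] * 2L, s[2] * 2L, s[3]),
    concat = c(s[1], s[2], sum(vapply(in_shapes, function(z) z[3], 0))),
    add = s,
    flatten = prod(s),
    gap = s[3],
    dense = layer$units,
    attention = in_shapes[[2]],
    abort("unknown layer type ", layer$type))
}

# Allocate parameters (He initialisation for conv/dense) given input shapes.
layer_build <- function(layer, in_shapes) {
  s <- in_shapes[[1]]
  if (layer$type == "conv") {
    cin <- s[3]
    fan_in <- layer$kernel^2 * cin
    layer$params$W <- matrix(stats::rnorm(fan_in * layer$filters,
                                          sd = sqrt(2 / fan_in)),
                             fan_in, layer$filters)
    layer$params$b <- numeric(layer$filters)
    layer$cin <- cin
  } else if (layer$type == "dense") {
    fin <- s[1]
    layer$params$W <- matrix(stats::rnorm(fin * layer$units,
                                          sd = sqrt(2 / fin)),
                             fin, layer$units)
    layer$params$b <- numeric(layer$units)
  } else if (layer$type == "bn") {
    nc <- s[length(s)]
    layer$params$gamma <- rep(1, nc)
    layer$params$beta <- rep(0, nc)
    layer$running_mean <- rep(0, nc)
    layer$running_var <- rep(1, nc)
  }
  invisible(layer)
}

# ---- shared low-level ops --------------------------------------------------

pad_array <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1], d[2] + 2L * p, d[3] + 2L * p, d[4]))
  xp[, (p + 1L):(p + d[2]), (p + 1L):(p + d[3]), ] <- x
  xp
}

# im2col for stride-1 'same' convolution: (N*H*W) x (k*k*C); compiled kernel
conv_im2col <- function(xp, k, H, W) {
  im2col_cpp(xp, as.integer(k), as.integer(H), as.integer(W))
}

act_apply <- function(z, activation) {
  switch(activation,
    linear = z,
    relu = z * (z > 0),
    sigmoid = 1 / (1 + exp(-z)),
    softmax = {
      e <- exp(z - apply(z, 1L, max))
      e / rowSums(e)
    },
    abort("unknown activation ", activation))
}

# Gradient through the activation; sigmoid/softmax are loss-fused (see top).
act_grad <- function(dout, y, activation) {
  switch(activation,
    linear = dout,
    relu = dout * (y > 0),
    sigmoid = dout,
    softmax = dout)
}

bn_flat <- function(x) {
  d <- dim(x)
  if (length(d) == 4L) {
    m <- prod(d[1:3]); nc <- d[4]
  } else {
    m <- d[1]; nc <- d[2]
  }
  dim(x) <- c(m, nc)
  x
}

# ---- forward ---------------------------------------------------------------

layer_forward <- function(layer, inputs, train = FALSE, cache = train) {
  x <- inputs[[1]]
  out <- switch(layer$type,
    conv = {
      d <- dim(x); N <- d[1]; H <- d[2]; W <- d[3]
      k <- layer$kernel
      P <- conv_im2col(pad_array(x, (k - 1L) %/% 2L), k, H, W)
      Z <- P %*% layer$params$W
      Z <- Z + rep(layer$params$b, each = nrow(Z))
      Y <- act_apply(Z, layer$activation)
      dim(Y) <- c(N, H, W, layer$filters)
      if (cache) layer$cache <- list(dims = d, P = P, y = Y)
      Y
    },
    dense = {
      Z <- sweep(x %*% layer$params$W, 2L, layer$params$b, "+")
      Y <- act_apply(Z, layer$activation)
      if (cache) layer$cache <- list(x = x, y = Y)
      Y
    },
    bn = {
      d <- dim(x)
      xm <- bn_flat(x)
      m <- nrow(xm)
      if (train) {
        mu <- colMeans(xm)
        xc <- xm - rep(mu, each = m)
        v <- colMeans(xc * xc)
        ivar <- 1 / sqrt(v + layer$eps)
        xhat <- xc * rep(ivar, each = m)
        layer$running_mean <- layer$momentum * layer$running_mean +
          (1 - layer$momentum) * mu
        layer$running_var <- layer$momentum * layer$running_var +
          (1 - layer$momentum) * v
        if (cache) layer$cache <- list(xhat = xhat, ivar = ivar, dims = d)
      } else {
        ivar <- 1 / sqrt(layer$running_var + layer$eps)
        xhat <- (xm - rep(layer$running_mean, each = m)) * rep(ivar, each = m)
      }
      y <- xhat * rep(layer$params$gamma, each = m) +
        rep(layer$params$beta, each = m)
      dim(y) <- d
      y
    },
    relu = {
      y <- x * (x > 0)
      if (cache) layer$cache <- list(y = y)
      y
    },
    pool = {
      d <- dim(x)
      ri <- seq(1L, d[2], by = 2L); ci <- seq(1L, d[3], by = 2L)
      a <- x[, ri, ci, , drop = FALSE]
      b <- x[, ri, ci + 1L, , drop = FALSE]
      cc <- x[, ri + 1L, ci, , drop = FALSE]
      dd <- x[, ri + 1L, ci + 1L, , drop = FALSE]
      M <- pmax(a, b, cc, dd)
      ma <- a == M; mb <- (b == M) & !ma
      mc <- (cc == M) & !ma & !mb; md <- !(ma | mb | mc)
      if (cache) layer$cache <- list(ma = ma, mb = mb, mc = mc, md = md,
                                     dims = d)
      M
    },
    upsample = {
      d <- dim(x)
      if (cache) layer$cache <- list(dims = d)
      x[, rep(seq_len(d[2]), each = 2L), rep(seq_len(d[3]), each = 2L), ,
        drop = FALSE]
    },
    concat = {
      chans <- vapply(inputs, function(z) dim(z)[4], 0L)
      if (cache) layer$cache <- list(chans = chans)
      d <- dim(x)
      out <- array(0, c(d[1], d[2], d[3], sum(chans)))
      at <- 0L
      for (z in inputs) {
        nc <- dim(z)[4]
        out[, , , (at + 1L):(at + nc)] <- z
        at <- at + nc
      }
      out
    },
    add = inputs[[1]] + inputs[[2]],
    flatten = {
      d <- dim(x)
      if (cache) layer$cache <- list(dims = d)
      dim(x) <- c(d[1], prod(d[-1]))
      x
    },
    gap = {
      d <- dim(x)
      if (cache) layer$cache <- list(dims = d)
      dim(x) <- c(d[1], d[2] * d[3], d[4])
      apply(x, c(1L, 3L), mean)
    },
    attention = {
      q <- inputs[[1]]; kv <- inputs[[2]]
      stopifnot(all(dim(q) == dim(kv)))
      d <- dim(q); N <- d[1]; P <- d[2] * d[3]; C <- d[4]
      out <- array(0, d)
      Qs <- Ks <- As <- vector("list", N)
      for (n in seq_len(N)) {
        Q <- q[n, , , ]; dim(Q) <- c(P, C)
        K <- kv[n, , , ]; dim(K) <- c(P, C)
        S <- tcrossprod(Q, K) / sqrt(C)
        # per-row max shift guards overflow; max.col is the fast row scan
        S <- S - S[cbind(seq_len(nrow(S)),
                         max.col(S, ties.method = "first"))]
        E <- exp(S)
        A <- E / rowSums(E)
        O <- A %*% K
        dim(O) <- c(d[2], d[3], C)
        out[n, , , ] <- O
        Qs[[n]] <- Q; Ks[[n]] <- K; As[[n]] <- A
      }
      # A is kept in evaluation mode too: attention_weights() reads it
      layer$cache <- if (cache) list(Q = Qs, K = Ks, A = As, dims = d)
                     else list(A = As, dims = d)
      out
    },
    abort("unknown layer type ", layer$type))
  out
}

# ---- backward --------------------------------------------------------------

# Returns a list of gradients, one per input of the node.
layer_backward <- function(layer, dout) {
  switch(layer$type,
    conv = {
      d <- layer$cache$dims
      N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
      k <- layer$kernel; p <- (k - 1L) %/% 2L
      F <- layer$filters
      yf <- layer$cache$y; dim(yf) <- c(N * H * W, F)
      dZ <- dout; dim(dZ) <- c(N * H * W, F)
      dZ <- act_grad(dZ, yf, layer$activation)
      P <- layer$cache$P
      layer$grads$W <- crossprod(P, dZ)
      layer$grads$b <- colSums(dZ)
      dP <- tcrossprod(dZ, layer$params$W)
      dxp <- col2im_add_cpp(dP, N, H + 2L * p, W + 2L * p, C, k, H, W)
      dx <- if (p > 0L) dxp[, (p + 1L):(p + H), (p + 1L):(p + W), ,
                            drop = FALSE] else dxp
      list(dx)
    },
    dense = {
      dZ <- act_grad(dout, layer$cache$y, layer$activation)
      layer$grads$W <- crossprod(layer$cache$x, dZ)
      layer$grads$b <- colSums(dZ)
      list(tcrossprod(dZ, layer$params$W))
    },
    bn = {
      d <- layer$cache$dims
      dy <- bn_flat(dout)
      m <- nrow(dy)
      xhat <- layer$cache$xhat
      ivar <- layer$cache$ivar
      layer$grads$gamma <- colSums(dy * xhat)
      layer$grads$beta <- colSums(dy)
      dxhat <- dy * rep(layer$params$gamma, each = m)
      s1 <- colSums(dxhat) / m
      s2 <- colSums(dxhat * xhat) / m
      dx <- (dxhat - rep(s1, each = m) - xhat * rep(s2, each = m)) *
        rep(ivar, each = m)
      dim(dx) <- d
      list(dx)
    },
    relu = list(dout * (layer$cache$y > 0)),
    pool = {
      cc <- layer$cache
      d <- cc$dims
      dx <- array(0, d)
      ri <- seq(1L, d[2], by = 2L); ci <- seq(1L, d[3], by = 2L)
      dx[, ri, ci, ] <- dout * cc$ma
      dx[, ri, ci + 1L, ] <- dout * cc$mb
      dx[, ri + 1L, ci, ] <- dout * cc$mc
      dx[, ri + 1L, ci + 1L, ] <- dout * cc$md
      list(dx)
    },
    upsample = {
      d <- layer$cache$dims
      ro <- seq(1L, 2L * d[2], by = 2L); co <- seq(1L, 2L * d[3], by = 2L)
      list(dout[, ro, co, , drop = FALSE] +
             dout[, ro, co + 1L, , drop = FALSE] +
             dout[, ro + 1L, co, , drop = FALSE] +
             dout[, ro + 1L, co + 1L, , drop = FALSE])
    },
    concat = {
      chans <- layer$cache$chans
      at <- 0L
      out <- vector("list", length(chans))
      for (i in seq_along(chans)) {
        out[[i]] <- dout[, , , (at + 1L):(at + chans[i]), drop = FALSE]
        at <- at + chans[i]
      }
      out
    },
    add = list(dout, dout),
    flatten = {
      dim(dout) <- layer$cache$dims
      list(dout)
    },
    gap = {
      # broadcast dout/(H*W) over the spatial positions
      d <- layer$cache$dims
      P <- d[2] * d[3]
      dx <- aperm(array(rep(t(dout) / P, each = P),
                        c(P, d[4], d[1])), c(3L, 1L, 2L))
      dim(dx) <- d
      list(dx)
    },
    attention = {
      cc <- layer$cache
      d <- cc$dims; N <- d[1]; P <- d[2] * d[3]; C <- d[4]
      dq <- array(0, d); dkv <- array(0, d)
      for (n in seq_len(N)) {
        dO <- dout[n, , , ]; dim(dO) <- c(P, C)
        A <- cc$A[[n]]; Q <- cc$Q[[n]]; K <- cc$K[[n]]
        dA <- tcrossprod(dO, K)
        dV <- crossprod(A, dO)
        dS <- A * (dA - rowSums(dA * A))
        dQ <- dS %*% K / sqrt(C)
        dK <- crossprod(dS, Q) / sqrt(C)
        g <- dK + dV; dim(g) <- c(d[2], d[3], C)
        dkv[n, , , ] <- g
        dim(dQ) <- c(d[2], d[3], C)
        dq[n, , , ] <- dQ
      }
      list(dq, dkv)
    },
    abort("unknown layer type ", layer$type))
}

# ---- network graph ---------------------------------------------------------

#' Create an empty network graph
#'
#' @param input_shapes named list of per-sample input shapes, e.g.
#'   `list(x = c(64, 64, 1))`.
#' @return an `nn_network` object.
#' @keywords internal
nn_network <- function(input_shapes) {
  input_shapes <- lapply(input_shapes, as.integer)
  structure(list(nodes = list(), order = character(),
                 input_shapes = input_shapes, shapes = input_shapes,
                 output = NULL),
            class = "nn_network")
}

# Add a node; nodes must be added in topological order. Builds the layer's
# parameters immediately (so the caller's RNG state governs initialisation).
nn_add <- function(net, id, layer, inputs, role = NA_character_) {
  abort_if(id %in% c(net$order, names(net$input_shapes)),
           "duplicate node id ", id)
  missing <- setdiff(inputs, c(net$order, names(net$input_shapes)))
  abort_if(length(missing) > 0L,
           "unknown inputs for node ", id, ": ", paste(missing, collapse = ", "))
  in_shapes <- lapply(inputs, function(i) net$shapes[[i]])
  layer_build(layer, in_shapes)
  layer$role <- role
  net$nodes[[id]] <- list(layer = layer, inputs = inputs)
  net$order <- c(net$order, id)
  net$shapes[[id]] <- as.integer(layer_out_shape(layer, in_shapes))
  net$output <- id
  net
}

#' Forward pass through a network
#'
#' @param net an `nn_network`.
#' @param inputs named list of input arrays `[N, ...]` matching the network's
#'   declared inputs.
#' @param train logical; `TRUE` uses batch statistics in batch-norm layers and
#'   caches activations for the backward pass.
#' @return the output array of the final node.
#' @keywords internal
net_forward <- function(net, inputs, train = FALSE, cache = train) {
  abort_if(!all(names(net$input_shapes) %in% names(inputs)),
           "net_forward: missing inputs: ",
           paste(setdiff(names(net$input_shapes), names(inputs)),
                 collapse = ", "))
  outs <- inputs
  for (id in net$order) {
    node <- net$nodes[[id]]
    outs[[id]] <- layer_forward(node$layer, outs[node$inputs], train = train,
                                cache = cache)
  }
  outs[[net$output]]
}

# Backward pass; dout is the gradient at the output node (pre-activation for
# loss-fused output layers). Fills each layer's $grads.
net_backward <- function(net, dout) {
  gacc <- list()
  gacc[[net$output]] <- dout
  for (id in rev(net$order)) {
    g <- gacc[[id]]
    if (is.null(g)) next
    node <- net$nodes[[id]]
    gins <- layer_backward(node$layer, g)
    for (j in seq_along(node$inputs)) {
      src <- node$inputs[j]
      if (src %in% names(net$input_shapes)) next
      gacc[[src]] <- if (is.null(gacc[[src]])) gins[[j]] else
        gacc[[src]] + gins[[j]]
    }
    gacc[[id]] <- NULL
  }
  invisible(NULL)
}

#' Tabulate the layers of a network
#'
#' One row per node: id, layer type, kernel size, filter/unit count, role
#' tag, and output shape. This is the introspection surface used to verify
#' architecture contracts (residual-block counts, filter sequences, final
#' kernel sizes).
#'
#' @param net an `nn_network` (or a model object wrapping one in `$net`).
#' @return a data.frame.
#' @export
nn_layer_table <- function(net) {
  if (!inherits(net, "nn_network") && !is.null(net$net)) net <- net$net
  rows <- lapply(net$order, function(id) {
    l <- net$nodes[[id]]$layer
    data.frame(id = id, type = l$type,
               kernel = if (!is.null(l$kernel)) l$kernel else NA_integer_,
               filters = if (!is.null(l$filters)) l$filters
                         else if (!is.null(l$units)) l$units else NA_integer_,
               role = if (is.null(l$role)) NA_character_ else l$role,
               out_shape = paste(net$shapes[[id]], collapse = "x"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Drop all per-layer activation caches (used after training so idle models
# hold only their parameters).
net_clear_cache <- function(net) {
  for (id in net$order) net$nodes[[id]]$layer$cache <- list()
  invisible(NULL)
}

# Precise batch-norm recalibration: re-estimates every batch-norm layer's
# population statistics under the final weights by averaging batch statistics
# over the data (momentum set to 1 - 1/k at the k-th chunk gives an equal-
# weight running average). Without this, channels whose variance collapses
# during training keep stale statistics and evaluation-mode normalisation
# amplifies tiny train/eval activation differences enormously.
calibrate_bn <- function(net, x, batch_size = 64L, max_samples = 96L) {
  bn_ids <- Filter(function(id) net$nodes[[id]]$layer$type == "bn", net$order)
  if (length(bn_ids) == 0L) return(invisible(NULL))
  saved <- lapply(bn_ids, function(id) net$nodes[[id]]$layer$momentum)
  n <- dim(x[[1]])[1]
  if (n > max_samples) {
    keep <- round(seq(1L, n, length.out = max_samples))
    x <- lapply(x, batch_slice, idx = keep)
    n <- max_samples
  }
  starts <- seq(1L, n, by = batch_size)
  for (k in seq_along(starts)) {
    idx <- starts[k]:min(starts[k] + batch_size - 1L, n)
    for (id in bn_ids) net$nodes[[id]]$layer$momentum <- 1 - 1 / k
    net_forward(net, lapply(x, batch_slice, idx = idx),
                train = TRUE, cache = FALSE)
  }
  for (i in seq_along(bn_ids)) {
    net$nodes[[bn_ids[i]]]$layer$momentum <- saved[[i]]
  }
  invisible(NULL)
}

# ---- optimiser and losses --------------------------------------------------

adam_init <- function(net) {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- list(); st$v <- list()
  for (id in net$order) {
    layer <- net$nodes[[id]]$layer
    for (pn in names(layer$params)) {
      key <- paste0(id, "/", pn)
      st$m[[key]] <- layer$params[[pn]] * 0
      st$v[[key]] <- layer$params[[pn]] * 0
    }
  }
  st
}

# Adam with decoupled weight decay (applied to conv/dense weights only, not
# biases or batch-norm parameters).
adam_step <- function(net, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (id in net$order) {
    layer <- net$nodes[[id]]$layer
    for (pn in names(layer$params)) {
      g <- layer$grads[[pn]]
      if (is.null(g)) next
      key <- paste0(id, "/", pn)
      st$m[[key]] <- beta1 * st$m[[key]] + (1 - beta1) * g
      st$v[[key]] <- beta2 * st$v[[key]] + (1 - beta2) * g * g
      step <- lr * (st$m[[key]] / bc1) / (sqrt(st$v[[key]] / bc2) + eps)
      if (weight_decay > 0 && pn == "W") {
        step <- step + lr * weight_decay * layer$params[[pn]]
      }
      layer$params[[pn]] <- layer$params[[pn]] - step
    }
  }
  invisible(NULL)
}

softmax_ce_loss <- function(probs, onehot) {
  -mean(rowSums(onehot * log(pmax(probs, 1e-12))))
}
softmax_ce_grad <- function(probs, onehot) (probs - onehot) / nrow(probs)

# Binary cross-entropy with an optional positive-class weight (vessels are a
# small share of the pixels); gradients are taken w.r.t. the pre-sigmoid
# logits.
bce_loss <- function(s, t, pos_weight = 1) {
  s <- clamp(s, 1e-7, 1 - 1e-7)
  -mean(pos_weight * t * log(s) + (1 - t) * log(1 - s))
}
bce_grad_logits <- function(s, t, pos_weight = 1) {
  (s * (1 + (pos_weight - 1) * t) - pos_weight * t) / length(t)
}

# Subset the first (batch) dimension of an array or matrix.
batch_slice <- function(x, idx) {
  if (length(dim(x)) == 4L) x[idx, , , , drop = FALSE]
  else x[idx, , drop = FALSE]
}

# ---- shared training loop --------------------------------------------------

# Trains `net` in place. x is a named list of input arrays; y the target
# (one-hot matrix for "softmax_ce", mask array for "bce"); lr may be a
# scalar or a per-epoch vector (recycled). Returns a per-epoch history
# data.frame. Caller is responsible for seeding.
fit_network <- function(net, x, y, loss = c("softmax_ce", "bce"),
                        epochs, batch_size, lr, weight_decay = 0,
                        input_noise_sd = 0, augment_fn = NULL,
                        val_x = NULL, val_y = NULL, val_every = 1L,
                        pos_weight = 1, verbose = FALSE) {
  loss <- match.arg(loss)
  n <- dim(x[[1]])[1]
  st <- adam_init(net)
  lr_ep <- rep_len(lr, epochs)
  hist <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    lr <- lr_ep[ep]
    ord <- sample.int(n)
    losses <- c(); accs <- c()
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      xb <- lapply(x, batch_slice, idx = idx)
      if (!is.null(augment_fn)) xb <- augment_fn(xb, ep)
      if (input_noise_sd > 0) {
        xb <- lapply(xb, function(z)
          z + array(stats::rnorm(length(z), 0, input_noise_sd), dim(z)))
      }
      yb <- batch_slice(y, idx)
      out <- net_forward(net, xb, train = TRUE)
      if (loss == "softmax_ce") {
        losses <- c(losses, softmax_ce_loss(out, yb))
        accs <- c(accs, mean(max.col(out) == max.col(yb)))
        net_backward(net, softmax_ce_grad(out, yb))
      } else {
        losses <- c(losses, bce_loss(out, yb, pos_weight))
        net_backward(net, bce_grad_logits(out, yb, pos_weight))
      }
      adam_step(net, st, lr = lr, weight_decay = weight_decay)
    }
    row <- data.frame(epoch = ep, train_loss = mean(losses))
    if (loss == "softmax_ce") row$train_acc <- mean(accs)
    if (!is.null(val_x)) {
      if (ep %% val_every == 0L || ep == epochs) {
        # recalibration + evaluation draw no random numbers, so the
        # validation cadence never changes the training trajectory
        calibrate_bn(net, x)
        vout <- net_forward(net, val_x, train = FALSE)
        if (loss == "softmax_ce") {
          row$val_loss <- softmax_ce_loss(vout, val_y)
          row$val_acc <- mean(max.col(vout) == max.col(val_y))
        } else {
          row$val_loss <- bce_loss(vout, val_y, pos_weight)
        }
      } else {
        row$val_loss <- NA_real_
        if (loss == "softmax_ce") row$val_acc <- NA_real_
      }
    }
    hist[[ep]] <- row
    if (verbose) {
      message(sprintf("epoch %d: %s", ep,
                      paste(sprintf("%s=%.4f", names(row)[-1],
                                    unlist(row[-1])), collapse = " ")))
    }
  }
  if (is.null(val_x)) calibrate_bn(net, x)
  net_clear_cache(net)
  do.call(rbind, hist)
}
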