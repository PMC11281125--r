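# Brute-force scaled dot-product attention, the independent oracle: explicit
# loops, no shared code with the implementation.
brute_attention <- function(q, kv) {
  d <- dim(q)
  P <- d[1] * d[2]; C <- d[3]
  Q <- matrix(q, P, C); K <- matrix(kv, P, C)
  W <- matrix(0, P, P)
  for (i in seq_len(P)) {
    logits <- vapply(seq_len(P), function(j) sum(Q[i, ] * K[j, ]) / sqrt(C), 0)
    W[i, ] <- exp(logits) / sum(exp(logits))
  }
  out <- matrix(0, P, C)
  for (i in seq_len(P)) {
    for (j in seq_len(P)) out[i, ] <- out[i, ] + W[i, j] * K[j, ]
  }
  list(output = array(out, d), weights = W)
}

test_that("attention matches the brute-force softmax oracle on small maps", {
  for (seed in 1:3) {
    set.seed(seed)
    dims <- list(c(1, 2, 2), c(1, 3, 4), c(3, 1, 2))[[seed]]
    q <- array(rnorm(prod(dims)), dims)
    kv <- array(rnorm(prod(dims)), dims)
    got <- attention_fuse(q, kv, return_weights = TRUE)
    want <- brute_attention(q, kv)
    expect_equal(got$output, want$output, tolerance = 1e-5)
    expect_equal(got$weights, want$weights, tolerance = 1e-5)
  }
})

test_that("attention weights are a proper distribution per query", {
  set.seed(10)
  q <- array(rnorm(2 * 4 * 4 * 3), c(2, 4, 4, 3))
  kv <- array(rnorm(2 * 4 * 4 * 3), c(2, 4, 4, 3))
  got <- attention_fuse(q, kv, return_weights = TRUE)
  for (w in got$weights) {
    expect_true(all(w >= 0))
    expect_equal(rowSums(w), rep(1, nrow(w)), tolerance = 1e-9)
  }
})

test_that("attention degenerate cases: identical keys and single position", {
  set.seed(11)
  q <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
  kv <- array(rep(c(1, 2, 3), each = 4), c(2, 2, 3))  # all keys identical
  got <- attention_fuse(q, kv, return_weights = TRUE)
  expect_equal(got$weights, matrix(0.25, 4, 4), tolerance = 1e-12)
  expect_equal(got$output, kv, tolerance = 1e-12)
  # single spatial position: output equals the value exactly
  q1 <- array(rnorm(3), c(1, 1, 3))
  v1 <- array(c(5, -2, 7), c(1, 1, 3))
  expect_equal(attention_fuse(q1, v1), v1, tolerance = 1e-12)
  expect_error(attention_fuse(q1, array(0, c(2, 1, 3))), "shapes differ")
})

test_that("a branch maps 64x64x1 to a quarter-size map with its configured filters", {
  spec <- small_branch()
  model <- build_branch(spec, seed = 5)
  x <- array(runif(2 * 64 * 64), c(2, 64, 64, 1))
  out <- fundustruct:::net_forward(model$net, list(x = x))
  expect_identical(dim(out), c(2L, 16L, 16L, 5L))
  expect_identical(conv_filter_sequence(model), spec$conv_filters)
  tab <- nn_layer_table(model)
  expect_identical(sum(tab$type == "conv"), 4L)
  expect_identical(sum(tab$type == "bn"), 2L)
  expect_identical(sum(tab$type == "pool"), 2L)
  # all-zero input stays finite
  z <- fundustruct:::net_forward(model$net,
                                 list(x = array(0, c(1, 64, 64, 1))))
  expect_true(all(is.finite(z)))
})

test_that("fusion modes wire the documented channel counts", {
  att <- build_glaucoma_model(small_branch(), small_head(), "attention",
                              seed = 6)
  abl <- build_glaucoma_model(small_branch(), small_head(), "concat",
                              seed = 6)
  expect_identical(pre_head_channels(att), 2L * 5L)
  expect_identical(pre_head_channels(abl), 3L * 5L)
  tab <- nn_layer_table(att)
  expect_identical(sum(tab$role == "attention", na.rm = TRUE), 2L)
  head_convs <- tab[!is.na(tab$role) & tab$role == "head" &
                      tab$type == "conv", ]
  expect_identical(head_convs$filters, small_head()$conv_filters)
  expect_identical(utils::tail(head_convs$kernel, 1), 1L)
})

test_that("forward pass emits softmax probabilities over two classes", {
  model <- build_glaucoma_model(small_branch(), small_head(), "attention",
                                seed = 7)
  mk <- function(seed) {
    withr::with_seed(seed, array(runif(3 * 64 * 64), c(3, 64, 64, 1)))
  }
  ds <- structure(list(image = mk(1), vessel = mk(2), disc = mk(3),
                       labels = c("glaucoma", "normal", "normal"), size = 64L),
                  class = "classifier_dataset")
  p <- predict_proba(model, ds)
  expect_identical(dim(p), c(3L, 2L))
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-5)
  # batch prediction equals per-item prediction
  one <- structure(list(image = ds$image[2, , , , drop = FALSE],
                        vessel = ds$vessel[2, , , , drop = FALSE],
                        disc = ds$disc[2, , , , drop = FALSE]),
                   class = "classifier_dataset")
  expect_equal(predict_proba(model, one)[1, ], p[2, ], tolerance = 1e-9)
  # repeated calls on a frozen model are identical
  expect_identical(predict_proba(model, ds), p)
  # predict() wrapper
  pr <- predict(model, list(image = matrix(runif(64 * 64), 64),
                            vessel = matrix(runif(64 * 64), 64),
                            disc = matrix(runif(64 * 64), 64)))
  expect_true(pr$label %in% c("glaucoma", "normal"))
  expect_equal(sum(pr$probs), 1, tolerance = 1e-5)
})

test_that("classifier training is deterministic and rejects one-class data", {
  set.seed(20)
  n <- 12
  imgs <- lapply(1:n, function(i) matrix(runif(64 * 64), 64))
  labs <- rep(c("glaucoma", "normal"), each = n / 2)
  ds <- classifier_dataset(imgs, imgs, imgs, labs)
  cfg <- classifier_train_config(epochs = 2, batch_size = 4, seed = 3)
  f1 <- train_classifier(ds, cfg, "attention", small_branch(), small_head())
  f2 <- train_classifier(ds, cfg, "attention", small_branch(), small_head())
  expect_identical(f1$history, f2$history)
  expect_named(f1$history,
               c("epoch", "train_loss", "train_acc", "val_loss", "val_acc"))
  bad <- classifier_dataset(imgs, imgs, imgs, rep("normal", n))
  expect_error(train_classifier(bad, cfg, "attention", small_branch(),
                                small_head()),
               class = "fundustruct_param_error")
})
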