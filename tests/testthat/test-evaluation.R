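test_that("confusion counts match hand counts", {
  cc <- confusion_from_predictions(c("glaucoma", "glaucoma", "normal", "normal"),
                                   c("glaucoma", "normal", "normal", "normal"),
                                   positive = "glaucoma")
  expect_identical(c(cc$tp, cc$fp, cc$fn, cc$tn), c(1L, 0L, 1L, 2L))
  perfect <- confusion_from_predictions(c("glaucoma", "normal"),
                                        c("glaucoma", "normal"))
  expect_identical(c(perfect$fp, perfect$fn), c(0L, 0L))
  expect_error(confusion_from_predictions(character(), character()),
               class = "fundustruct_validation_error")
  expect_error(confusion_from_predictions("glaucoma", c("glaucoma", "normal")),
               class = "fundustruct_validation_error")
})

test_that("metrics follow their definitions and flag degenerate counts", {
  m <- eval_metrics(confusion_from_predictions(
    rep(c("glaucoma", "normal"), c(10, 10)),
    c(rep("glaucoma", 9), "normal", "glaucoma", rep("normal", 9))))
  expect_equal(unname(m), c(0.9, 0.9, 0.9))
  all1 <- eval_metrics(confusion_from_predictions(
    c("glaucoma", "glaucoma", "normal"), c("glaucoma", "glaucoma", "normal")))
  expect_equal(unname(all1), c(1, 1, 1))
  # tp = 0, fp = 0, fn > 0: sensitivity 0, precision undefined (not silently 0)
  deg <- confusion_from_predictions(c("glaucoma", "normal"),
                                    c("normal", "normal"))
  expect_warning(md <- eval_metrics(deg), "precision undefined")
  expect_equal(unname(md["sensitivity"]), 0)
  expect_true(is.nan(md["precision"]))
  expect_true(is.nan(md["f1"]))
})

test_that("metrics are invariant to sample order and class swap is coherent", {
  set.seed(30)
  labs <- sample(c("glaucoma", "normal"), 40, replace = TRUE)
  preds <- sample(c("glaucoma", "normal"), 40, replace = TRUE)
  a <- confusion_from_predictions(labs, preds, "glaucoma")
  perm <- sample(40)
  b <- confusion_from_predictions(labs[perm], preds[perm], "glaucoma")
  expect_identical(unclass(a), unclass(b))
  sw <- confusion_from_predictions(labs, preds, "normal")
  expect_identical(a$tp, sw$tn)
  expect_identical(a$fp, sw$fn)
  expect_identical(a$fn, sw$fp)
})

test_that("ROC/AUC reproduce the worked examples", {
  r <- roc_curve(c("glaucoma", "normal", "glaucoma", "normal"),
                 c(0.9, 0.8, 0.4, 0.3))
  expect_equal(r$auc, 0.75)  # 3 concordant pairs of 4
  expect_equal(r$roc_points[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(r$roc_points[nrow(r$roc_points), ]),
               c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$roc_points$fpr) >= 0))
  expect_true(all(diff(r$roc_points$tpr) >= 0))
  # perfectly separating scores
  expect_equal(roc_curve(c("glaucoma", "glaucoma", "normal", "normal"),
                         c(0.9, 0.8, 0.2, 0.1))$auc, 1)
  # all scores tied
  expect_equal(roc_curve(c("glaucoma", "normal"), c(0.5, 0.5))$auc, 0.5)
  expect_error(roc_curve(c("glaucoma", "glaucoma"), c(0.1, 0.9)),
               class = "fundustruct_validation_error")
  expect_error(roc_curve(c("glaucoma", "normal"), c(1.1, 0.5)),
               class = "fundustruct_validation_error")
})

test_that("trapezoidal AUC equals the concordance estimator and pROC", {
  skip_if_not_installed("pROC")
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(10:40, 1)
    labs <- c("glaucoma", "normal",
              sample(c("glaucoma", "normal"), n - 2, replace = TRUE))
    scores <- round(runif(n), 2)  # rounding forces ties
    r <- roc_curve(labs, scores)
    expect_equal(r$auc, auc_concordance(labs, scores), tolerance = 1e-9)
    proc_auc <- as.numeric(pROC::auc(pROC::roc(
      response = labs, predictor = scores, levels = c("normal", "glaucoma"),
      direction = "<", quiet = TRUE)))
    expect_equal(r$auc, proc_auc, tolerance = 1e-9)
  }
})

test_that("evaluate_model produces a coherent report on a frozen model", {
  model <- build_glaucoma_model(small_branch(), small_head(), "concat",
                                seed = 40)
  set.seed(41)
  n <- 8
  imgs <- lapply(1:n, function(i) matrix(runif(64 * 64), 64))
  ds <- classifier_dataset(imgs, imgs, imgs,
                           rep(c("glaucoma", "normal"), each = n / 2))
  rep_ <- evaluate_model(model, ds)
  expect_s3_class(rep_, "eval_report")
  expect_named(rep_$per_class, c("glaucoma", "normal"))
  expect_true(rep_$auc >= 0 && rep_$auc <= 1)
  # F1 satisfies the harmonic-mean identity wherever defined
  for (cl in names(rep_$per_class)) {
    m <- rep_$per_class[[cl]]
    if (!anyNA(m)) {
      expect_equal(m[["f1"]],
                   2 * m[["precision"]] * m[["sensitivity"]] /
                     (m[["precision"]] + m[["sensitivity"]]))
    }
  }
  p <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep_, p)
  parsed <- jsonlite::read_json(p)
  expect_equal(parsed$auc, rep_$auc, tolerance = 1e-12)
  expect_length(parsed$roc, nrow(rep_$roc_points))
})

test_that("a constant-class predictor yields prevalence precision and AUC 1/2", {
  labs <- rep(c("glaucoma", "normal"), c(6, 18))
  preds <- rep("glaucoma", 24)
  cc <- confusion_from_predictions(labs, preds, "glaucoma")
  m <- suppressWarnings(eval_metrics(cc))
  expect_equal(unname(m["sensitivity"]), 1)
  expect_equal(unname(m["precision"]), 6 / 24)  # prevalence
  expect_equal(roc_curve(labs, rep(0.7, 24))$auc, 0.5)
})
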