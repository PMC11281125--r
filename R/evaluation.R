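# Classifier evaluation: per-class confusion counts, sensitivity / precision
# / F1, and a threshold-sweep ROC curve with trapezoidal AUC. Degenerate
# denominators are reported as NaN with a warning, never silently coerced
# to zero.

#' Confusion counts for one positive class
#'
#' @param labels true labels (`"glaucoma"`/`"normal"`).
#' @param predictions predicted labels, same length and alphabet.
#' @param positive the class counted as positive.
#' @return a `confusion_counts` list (`tp`, `fp`, `fn`, `tn`, `positive`).
#' @export
confusion_from_predictions <- function(labels, predictions,
                                       positive = "glaucoma") {
  abort_if(length(labels) == 0L, "confusion_from_predictions: empty input",
           class = "fundustruct_validation_error")
  abort_if(length(labels) != length(predictions),
           "confusion_from_predictions: length mismatch",
           class = "fundustruct_validation_error")
  labels <- tolower(as.character(labels))
  predictions <- tolower(as.character(predictions))
  abort_if(!all(c(labels, predictions) %in% CLASS_LEVELS),
           "confusion_from_predictions: labels outside {glaucoma, normal}",
           class = "fundustruct_validation_error")
  pos_t <- labels == positive
  pos_p <- predictions == positive
  structure(list(tp = sum(pos_t & pos_p), fp = sum(!pos_t & pos_p),
                 fn = sum(pos_t & !pos_p), tn = sum(!pos_t & !pos_p),
                 positive = positive),
            class = "confusion_counts")
}

#' Sensitivity, precision, and F1 from confusion counts
#'
#' `sensitivity = tp / (tp + fn)`, `precision = tp / (tp + fp)`,
#' `f1 = 2 P S / (P + S)`. A zero denominator yields `NaN` and a warning.
#'
#' @param counts a `confusion_counts` object.
#' @return a named numeric vector `c(sensitivity, precision, f1)`.
#' @export
eval_metrics <- function(counts) {
  abort_if(!inherits(counts, "confusion_counts"),
           "eval_metrics: expected confusion_counts")
  sens <- if (counts$tp + counts$fn == 0) {
    warning("sensitivity undefined: no positive samples"); NaN
  } else counts$tp / (counts$tp + counts$fn)
  prec <- if (counts$tp + counts$fp == 0) {
    warning("precision undefined: no positive predictions"); NaN
  } else counts$tp / (counts$tp + counts$fp)
  f1 <- if (is.nan(sens) || is.nan(prec) || sens + prec == 0) {
    if (!is.nan(sens) && !is.nan(prec)) {
      warning("F1 undefined: sensitivity + precision is zero")
    }
    NaN
  } else 2 * prec * sens / (prec + sens)
  c(sensitivity = sens, precision = prec, f1 = f1)
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps every unique score as a threshold (predict positive when
#' `score >= t`), yielding a monotone staircase from (0, 0) to (1, 1); the
#' AUC is its trapezoidal integral, which equals the Mann-Whitney
#' concordance probability with ties counted 1/2.
#'
#' @param labels true labels (`"glaucoma"`/`"normal"`); both classes must be
#'   present.
#' @param scores positive-class probabilities in \[0, 1\].
#' @param positive the positive class (default `"glaucoma"`).
#' @return a list: `roc_points` (data.frame of `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(labels, scores, positive = "glaucoma") {
  labels <- tolower(as.character(labels))
  abort_if(length(labels) != length(scores),
           "roc_curve: length mismatch", class = "fundustruct_validation_error")
  abort_if(any(scores < 0 | scores > 1),
           "roc_curve: scores must lie in [0, 1]",
           class = "fundustruct_validation_error")
  pos <- labels == positive
  abort_if(!any(pos) || all(pos),
           "roc_curve: both classes must be present",
           class = "fundustruct_validation_error")
  np <- sum(pos); nn <- sum(!pos)
  pts <- lapply(sort(unique(scores), decreasing = TRUE), function(t) {
    call <- scores >= t
    c(fpr = sum(call & !pos) / nn, tpr = sum(call & pos) / np)
  })
  roc <- rbind(data.frame(fpr = 0, tpr = 0),
               as.data.frame(do.call(rbind, pts)))
  if (roc$fpr[nrow(roc)] != 1 || roc$tpr[nrow(roc)] != 1) {
    roc <- rbind(roc, data.frame(fpr = 1, tpr = 1))
  }
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  list(roc_points = roc, auc = auc)
}

#' Mann-Whitney concordance AUC
#'
#' The pairwise estimator: the probability that a random positive scores
#' above a random negative, ties counted 1/2. Mathematically identical to
#' the trapezoidal ROC integral; kept as an independent formulation.
#'
#' @inheritParams roc_curve
#' @return the concordance probability.
#' @export
auc_concordance <- function(labels, scores, positive = "glaucoma") {
  labels <- tolower(as.character(labels))
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  abort_if(length(sp) == 0L || length(sn) == 0L,
           "auc_concordance: both classes must be present",
           class = "fundustruct_validation_error")
  cmp <- outer(sp, sn, ">") + 0.5 * outer(sp, sn, "==")
  mean(cmp)
}

#' Evaluate a trained classifier on a labelled dataset
#'
#' Computes per-class sensitivity/precision/F1 for both classes and the ROC
#' curve and AUC with glaucoma as the positive class.
#'
#' @param model a trained `glaucoma_model`.
#' @param dataset a labelled [classifier_dataset].
#' @return an `eval_report` list: `per_class` (named list of metric vectors),
#'   `confusion` (per-class counts), `roc_points`, `auc`, `n`, `fusion`.
#' @export
evaluate_model <- function(model, dataset) {
  probs <- predict_proba(model, dataset)
  pred <- model$classes[max.col(probs)]
  per_class <- list(); confusion <- list()
  for (cl in CLASS_LEVELS) {
    cc <- confusion_from_predictions(dataset$labels, pred, positive = cl)
    confusion[[cl]] <- cc
    per_class[[cl]] <- suppressWarnings(eval_metrics(cc))
  }
  roc <- roc_curve(dataset$labels, probs[, "glaucoma"], positive = "glaucoma")
  structure(list(per_class = per_class, confusion = confusion,
                 roc_points = roc$roc_points, auc = roc$auc,
                 n = length(dataset$labels), fusion = model$fusion),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report n=%d fusion=%s AUC=%.2f>\n", x$n,
              x$fusion, x$auc))
  for (cl in names(x$per_class)) {
    m <- x$per_class[[cl]]
    cat(sprintf("  %-8s sensitivity %.2f  precision %.2f  F1 %.2f\n",
                cl, m["sensitivity"], m["precision"], m["f1"]))
  }
  invisible(x)
}

#' Serialise an evaluation report to JSON
#'
#' Full precision is retained in the JSON; the printed report rounds to two
#' decimals.
#'
#' @param report an `eval_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  out <- list(
    n = report$n, fusion = report$fusion, auc = report$auc,
    per_class = lapply(report$per_class, as.list),
    roc = unname(apply(report$roc_points, 1L, function(r)
      c(r[["fpr"]], r[["tpr"]]), simplify = FALSE)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
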