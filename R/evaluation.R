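#' @include AllClasses.R
NULL

#' Confusion counts for fall classification
#'
#' Falls (label 1) are the positive class: TP = fall windows predicted
#' fall, TN = not-fall predicted not-fall, FP = not-fall predicted fall,
#' FN = fall predicted not-fall.
#'
#' @param truth,pred equal-length 0/1 vectors (logical accepted).
#' @return Named integer vector `c(TP, TN, FP, FN)`.
#' @examples
#' confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusionCounts <- function(truth, pred) {
  if (length(truth) != length(pred))
    .stopf("truth and pred must have equal length (%d vs %d)",
           length(truth), length(pred))
  if (!length(truth)) .stopf("cannot compute a confusion matrix on 0 windows")
  truth <- as.integer(truth); pred <- as.integer(pred)
  if (!all(c(truth, pred) %in% c(0L, 1L)))
    .stopf("labels must be binary 0/1")
  c(TP = sum(truth == 1L & pred == 1L),
    TN = sum(truth == 0L & pred == 0L),
    FP = sum(truth == 0L & pred == 1L),
    FN = sum(truth == 1L & pred == 0L))
}

#' Precision, recall, F1 and accuracy from confusion counts
#'
#' Standard binary-classification metrics on the 0–100 percentage scale:
#' precision = TP/(TP+FP), recall = TP/(TP+FN), F1 their harmonic mean,
#' accuracy = (TP+TN)/(TP+TN+FP+FN). A metric whose denominator is zero is
#' reported as `NA` (undefined, never 0) and named in the `"undefined"`
#' attribute. With `average = "macro"` precision and recall are averaged
#' over both classes treated in turn as positive.
#'
#' @param TP,TN,FP,FN non-negative counts. `TP` may also be the named
#'   vector returned by [confusionCounts()].
#' @param average `"binary"` (fall is the positive class) or `"macro"`.
#' @return Named numeric vector `c(precision, recall, f1, accuracy)` in
#'   percent, with attribute `"undefined"`.
#' @examples
#' classificationMetrics(TP = 36, TN = 57, FP = 1, FN = 2)
#' @export
classificationMetrics <- function(TP, TN = NULL, FP = NULL, FN = NULL,
                                  average = c("binary", "macro")) {
  average <- match.arg(average)
  if (length(TP) == 4L && is.null(TN)) {
    cc <- TP
    TP <- cc[["TP"]]; TN <- cc[["TN"]]; FP <- cc[["FP"]]; FN <- cc[["FN"]]
  }
  stopifnot(all(c(TP, TN, FP, FN) >= 0))
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  if (average == "binary") {
    precision <- rate(TP, TP + FP)
    recall <- rate(TP, TP + FN)
  } else {
    # each class as positive in turn; for the negative class TN<->TP, FP<->FN
    precision <- mean(c(rate(TP, TP + FP), rate(TN, TN + FN)))
    recall <- mean(c(rate(TP, TP + FN), rate(TN, TN + FP)))
  }
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall)
  else NA_real_
  accuracy <- rate(TP + TN, TP + TN + FP + FN)
  out <- c(precision = precision, recall = recall, f1 = f1, accuracy = accuracy)
  attr(out, "undefined") <- names(out)[is.na(out)]
  out
}

#' F1 score from precision and recall
#'
#' The harmonic mean `2 * precision * recall / (precision + recall)`, on
#' whatever scale its inputs share (typically percent).
#'
#' @param precision,recall same-scale non-negative values.
#' @return The F1 score; `NA` when both inputs are zero.
#' @examples
#' f1Score(99.1, 97.3)  # 98.2 to one decimal place
#' @export
f1Score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), NA_real_)
}

#' Base-2 cross entropy of predicted scores
#'
#' Reporting loss in bits: `-sum over samples and both classes of
#' p * log2(q)`, where `p` is the one-hot truth and `q` the
#' `(score, 1 - score)` pair — i.e. the total `-log2` likelihood of the
#' true labels. Scores of exactly 0 or 1 are clipped to `eps` away from
#' the boundary with a warning. Note this is a sum, not a mean, and uses
#' log base 2; the training objective is the natural-log mean binary
#' cross entropy.
#'
#' @param truth 0/1 vector.
#' @param scores predicted fall probabilities in (0, 1).
#' @param eps clipping bound for degenerate scores.
#' @return Non-negative total cross entropy in bits.
#' @examples
#' crossEntropyBits(1, 0.5)  # 1 bit
#' @export
crossEntropyBits <- function(truth, scores, eps = 1e-12) {
  if (length(truth) != length(scores))
    .stopf("truth and scores must have equal length")
  truth <- as.integer(truth)
  if (any(scores <= 0 | scores >= 1)) {
    .warnf("crossEntropyBits: %d score(s) at or beyond {0, 1}; clipping to eps = %g",
           sum(scores <= 0 | scores >= 1), eps)
    scores <- pmin(pmax(scores, eps), 1 - eps)
  }
  -sum(truth * log2(scores) + (1 - truth) * log2(1 - scores))
}

#' Evaluate a model (or ready-made predictions) on labelled windows
#'
#' Computes confusion counts, the four percentage metrics and the base-2
#' cross entropy, and bundles them into an [EvalReport-class].
#'
#' @param truth 0/1 vector of true labels, or a [WindowSet-class] (its
#'   labels are used and, when `model` is given, its inputs are scored).
#' @param pred 0/1 predicted labels; omit when `model` is supplied.
#' @param scores predicted probabilities (enables the loss entry).
#' @param model optional trained [SafeModel-class] used to produce
#'   `pred`/`scores` from the [WindowSet-class] in `truth`.
#' @return An [EvalReport-class].
#' @export
evalReport <- function(truth, pred = NULL, scores = NULL, model = NULL) {
  if (is(truth, "WindowSet")) {
    ws <- truth
    truth <- windowLabels(ws)
    if (!is.null(model)) {
      p <- predictFalls(model, ws)
      pred <- p$labels
      scores <- p$scores
    }
  }
  if (is.null(pred)) .stopf("either pred or model must be supplied")
  cc <- confusionCounts(truth, pred)
  met <- classificationMetrics(cc)
  new("EvalReport", tp = unname(cc[["TP"]]), tn = unname(cc[["TN"]]),
      fp = unname(cc[["FP"]]), fn = unname(cc[["FN"]]),
      precision = unname(met[["precision"]]), recall = unname(met[["recall"]]),
      f1 = unname(met[["f1"]]), accuracy = unname(met[["accuracy"]]),
      lossBits = if (is.null(scores)) NA_real_
                 else crossEntropyBits(truth, scores),
      n = length(truth), undefined = attr(met, "undefined"))
}

#' Serialize an EvalReport
#'
#' `reportToList()` returns a plain list (used for JSON output);
#' `writeEvalReport()` writes the JSON file and, optionally, a confusion
#' matrix CSV next to it.
#'
#' @param report an [EvalReport-class].
#' @param path output JSON path.
#' @param confusionCsv optional path for a 2x2 confusion-matrix CSV.
#' @return The list (`reportToList`); `path` invisibly
#'   (`writeEvalReport`).
#' @export
reportToList <- function(report) {
  stopifnot(is(report, "EvalReport"))
  list(n = report@n,
       confusion = list(TP = report@tp, TN = report@tn,
                        FP = report@fp, FN = report@fn),
       metrics_percent = list(precision = report@precision,
                              recall = report@recall, f1 = report@f1,
                              accuracy = report@accuracy),
       cross_entropy_bits = report@lossBits,
       undefined = as.list(report@undefined))
}

#' @rdname reportToList
#' @export
writeEvalReport <- function(report, path, confusionCsv = NULL) {
  jsonlite::write_json(reportToList(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  if (!is.null(confusionCsv)) {
    mat <- data.frame(truth = c("fall", "fall", "not_fall", "not_fall"),
                      predicted = c("fall", "not_fall", "fall", "not_fall"),
                      count = c(report@tp, report@fn, report@fp, report@tn))
    utils::write.csv(mat, confusionCsv, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
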