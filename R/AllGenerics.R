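#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' `keypointFrames()` returns the per-frame table of a
#' [KeypointSequence-class]; `subjectId()`/`trialId()`/`nominalFps()` its
#' identifiers and frame rate; `nWindows()`, `windowLabels()`,
#' `windowInputs()` and `featureSetName()` the components of a
#' [WindowSet-class]; `modelWeights()`, `trainingHistory()` and
#' `isTrained()` the components of a [SafeModel-class].
#'
#' @param x the object.
#' @return The extracted component.
#' @name accessors
#' @aliases keypointFrames subjectId trialId nominalFps nWindows
#'   windowLabels windowInputs featureSetName modelWeights trainingHistory
#'   isTrained
#'   keypointFrames,KeypointSequence-method subjectId,KeypointSequence-method
#'   trialId,KeypointSequence-method nominalFps,KeypointSequence-method
#'   length,KeypointSequence-method nWindows,WindowSet-method
#'   windowLabels,WindowSet-method windowInputs,WindowSet-method
#'   featureSetName,WindowSet-method length,WindowSet-method
#'   featureSetName,SafeModel-method modelWeights,SafeModel-method
#'   trainingHistory,SafeModel-method isTrained,SafeModel-method
NULL

#' @rdname accessors
#' @export
setGeneric("keypointFrames", function(x) standardGeneric("keypointFrames"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("trialId", function(x) standardGeneric("trialId"))
#' @rdname accessors
#' @export
setGeneric("nominalFps", function(x) standardGeneric("nominalFps"))
#' @rdname accessors
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))
#' @rdname accessors
#' @export
setGeneric("windowLabels", function(x) standardGeneric("windowLabels"))
#' @rdname accessors
#' @export
setGeneric("windowInputs", function(x) standardGeneric("windowInputs"))
#' @rdname accessors
#' @export
setGeneric("featureSetName", function(x) standardGeneric("featureSetName"))
#' @rdname accessors
#' @export
setGeneric("modelWeights", function(x) standardGeneric("modelWeights"))
#' @rdname accessors
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))
#' @rdname accessors
#' @export
setGeneric("isTrained", function(x) standardGeneric("isTrained"))

setMethod("keypointFrames", "KeypointSequence", function(x) x@frames)
setMethod("subjectId", "KeypointSequence", function(x) x@subjectId)
setMethod("trialId", "KeypointSequence", function(x) x@trialId)
setMethod("nominalFps", "KeypointSequence", function(x) x@nominalFps)
setMethod("length", "KeypointSequence", function(x) nrow(x@frames))

setMethod("nWindows", "WindowSet", function(x) dim(x@inputs)[1L])
setMethod("windowLabels", "WindowSet", function(x) x@labels)
setMethod("windowInputs", "WindowSet", function(x) x@inputs)
setMethod("featureSetName", "WindowSet", function(x) x@featureSet)
setMethod("length", "WindowSet", function(x) dim(x@inputs)[1L])

setMethod("featureSetName", "SafeModel", function(x) x@featureSet)
setMethod("modelWeights", "SafeModel", function(x) x@weights)
setMethod("trainingHistory", "SafeModel", function(x) x@history)
setMethod("isTrained", "SafeModel", function(x) x@trained)

setMethod("show", "KeypointSequence", function(object) {
  fr <- object@frames
  cat(sprintf("KeypointSequence  subject=%s  trial=%s\n",
              object@subjectId, object@trialId))
  cat(sprintf("  %d frames @ %.3g fps nominal", nrow(fr), object@nominalFps))
  if (nrow(fr))
    cat(sprintf(", t in [%.3f, %.3f] s, %d excluded, %d post-impact",
                min(fr$t), max(fr$t), sum(fr$excluded), sum(fr$post_impact)))
  cat("\n")
})

setMethod("show", "FeatureSetSpec", function(object) {
  cat(sprintf("FeatureSetSpec '%s' (m = %d): %s\n", object@name, object@m,
              paste(object@columns, collapse = ", ")))
})

setMethod("show", "WindowSet", function(object) {
  d <- dim(object@inputs)
  cat(sprintf("WindowSet: %d windows of %d x %d ('%s' features)\n",
              d[1], d[2], d[3], object@featureSet))
  cat(sprintf("  labels: %d fall, %d not-fall\n",
              sum(object@labels == 1L), sum(object@labels == 0L)))
})

setMethod("show", "ModelConfig", function(object) {
  cat("ModelConfig:\n")
  cat(sprintf("  %d x LSTM(%d, %s cells) -> dropout(%.2g) -> dense(1, %s)\n",
              object@numLstmLayers, object@lstmUnits, object@hiddenActivation,
              object@dropout, object@outputActivation))
  cat(sprintf("  %s(lr = %g), %s, %d epochs, batch %d, threshold %.2g, %s, seed %d\n",
              object@optimizer, object@learningRate, object@loss,
              object@epochs, object@batchSize, object@decisionThreshold,
              if (object@shuffle) "shuffled" else "unshuffled", object@seed))
})

setMethod("show", "SafeModel", function(object) {
  cat(sprintf("SafeModel%s: input (*, %d), %s\n",
              if (nzchar(object@featureSet))
                paste0(" [", object@featureSet, "]") else "",
              object@m,
              if (object@trained)
                sprintf("trained %d epochs", nrow(object@history))
              else "untrained"))
  show(object@config)
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport on %d windows (positive class: fall)\n", object@n))
  cat(sprintf("  TP %d  FN %d\n  FP %d  TN %d\n",
              object@tp, object@fn, object@fp, object@tn))
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", v)
  cat(sprintf("  precision %s  recall %s  F1 %s  accuracy %s\n",
              fmt(object@precision), fmt(object@recall), fmt(object@f1),
              fmt(object@accuracy)))
  if (!is.na(object@lossBits))
    cat(sprintf("  cross entropy %.4f bits\n", object@lossBits))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %d trials x {%s} @ %g fps\n",
              object@nTrialsPerScenario,
              paste(object@scenarios, collapse = ", "), object@fps))
  cat(sprintf("  rods %.2f/%.2f, fall peak %g rad/s, ADL max %g rad/s, noise sd %g, seed %d\n",
              object@trunkLength, object@neckLength,
              object@fallPeakAngularRate, object@adlMaxAngularRate,
              object@noiseSd, object@seed))
})
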