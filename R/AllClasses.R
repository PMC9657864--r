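#' @import methods
NULL

# Columns every keypoint frame table must carry. `subject_id`/`trial_id`
# live in the sequence slots; `post_impact` is optional on disk but always
# present in memory.
.KP_COORD_COLS <- c("N_x", "N_y", "N_z", "LSh_x", "LSh_y", "LSh_z",
                    "LH_x", "LH_y", "LH_z")
.KP_FRAME_COLS <- c("t", "activity_id", "excluded", "post_impact",
                    .KP_COORD_COLS)

#' KeypointSequence: one trial of tracked skeleton key points
#'
#' Holds the time-stamped image-space coordinates of the three tracked body
#' key points (nose, left shoulder, left hip) for a single (subject, trial),
#' in the image coordinate frame whose origin is the outer left corner with
#' the positive y-axis pointing down towards the floor. Frames flagged
#' `excluded` (key points unreadable) or `post_impact` (after the fall
#' impact) are retained on input and removed by [applyFrameFilters()].
#'
#' @slot subjectId opaque subject identifier.
#' @slot trialId opaque trial identifier.
#' @slot nominalFps nominal frame rate in frames/second (default 18); used
#'   for time steps only when real timestamps are unavailable.
#' @slot frames data.frame with columns `t`, `activity_id`, `excluded`,
#'   `post_impact` and x/y/z coordinates of the three key points.
#' @export
setClass("KeypointSequence",
  representation(subjectId = "character", trialId = "character",
                 nominalFps = "numeric", frames = "data.frame"),
  validity = function(object) {
    msg <- character()
    fr <- object@frames
    missing <- setdiff(.KP_FRAME_COLS, names(fr))
    if (length(missing))
      msg <- c(msg, paste0("missing frame column(s): ",
                           paste(missing, collapse = ", ")))
    if (length(object@nominalFps) != 1L || !is.finite(object@nominalFps) ||
        object@nominalFps <= 0)
      msg <- c(msg, "nominalFps must be a single positive number")
    if (!length(missing) && nrow(fr)) {
      if (any(diff(fr$t) <= 0))
        msg <- c(msg, sprintf("timestamps not strictly increasing in trial '%s'",
                              object@trialId))
      ok <- !fr$excluded
      coords <- as.matrix(fr[ok, .KP_COORD_COLS, drop = FALSE])
      if (length(coords) && !all(is.finite(coords)))
        msg <- c(msg, "non-finite coordinates in frames not flagged excluded")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a KeypointSequence
#'
#' @param frames data.frame of per-frame observations (see
#'   [KeypointSequence-class]). A missing `post_impact` column is added as
#'   all-`FALSE`; frames with any non-finite coordinate are flagged
#'   `excluded`.
#' @param subjectId,trialId identifiers shared by all frames.
#' @param nominalFps nominal frame rate (frames/second).
#' @return A [KeypointSequence-class] object.
#' @export
KeypointSequence <- function(frames, subjectId, trialId, nominalFps = 18) {
  if (!is.data.frame(frames)) .stopf("frames must be a data.frame")
  if (!"post_impact" %in% names(frames)) frames$post_impact <- FALSE
  if (!"excluded" %in% names(frames)) frames$excluded <- FALSE
  frames$excluded <- as.logical(frames$excluded)
  frames$post_impact <- as.logical(frames$post_impact)
  have <- intersect(.KP_COORD_COLS, names(frames))
  if (length(have) && nrow(frames)) {
    bad <- !apply(is.finite(as.matrix(frames[have])), 1L, all)
    frames$excluded <- frames$excluded | bad
    # excluded frames may hold NA coordinates; park them at 0 so the table
    # stays numeric (they are dropped before any computation)
    for (cl in have) frames[[cl]][!is.finite(frames[[cl]])] <- 0
  }
  rownames(frames) <- NULL
  new("KeypointSequence", subjectId = as.character(subjectId),
      trialId = as.character(trialId), nominalFps = nominalFps,
      frames = frames)
}

#' FeatureSetSpec: one of the three model input feature sets
#'
#' The three classifier variants differ only in their input columns:
#' \describe{
#'   \item{4p}{N_x, N_y, dw_N, R (m = 4)}
#'   \item{5p}{N_x, N_y, dw_N, dw_LSh, dw_LH (m = 5)}
#'   \item{6p}{N_x, N_y, dw_N, dw_LSh, dw_LH, R (m = 6)}
#' }
#'
#' @slot name "4p", "5p" or "6p".
#' @slot columns ordered feature column names.
#' @slot m number of columns.
#' @export
setClass("FeatureSetSpec",
  representation(name = "character", columns = "character", m = "integer"),
  validity = function(object) {
    def <- .FEATURE_SETS[[object@name]]
    if (is.null(def))
      return(sprintf("unknown feature set '%s' (expected 4p, 5p or 6p)",
                     object@name))
    if (!identical(object@columns, def) || object@m != length(def))
      return("columns/m do not match the named feature set definition")
    TRUE
  })

.FEATURE_SETS <- list(
  "4p" = c("N_x", "N_y", "dw_N", "R"),
  "5p" = c("N_x", "N_y", "dw_N", "dw_LSh", "dw_LH"),
  "6p" = c("N_x", "N_y", "dw_N", "dw_LSh", "dw_LH", "R"))

#' Look up a model feature set by name
#'
#' @param name "4p", "5p" or "6p" (a [FeatureSetSpec-class] passes through).
#' @return A [FeatureSetSpec-class].
#' @examples
#' featureSetSpec("4p")@columns
#' @export
featureSetSpec <- function(name) {
  if (is(name, "FeatureSetSpec")) return(name)
  if (!is.character(name) || length(name) != 1L || !name %in% names(.FEATURE_SETS))
    .stopf("unknown feature set '%s' (expected one of: %s)",
           paste(name, collapse = ","), paste(names(.FEATURE_SETS), collapse = ", "))
  new("FeatureSetSpec", name = name, columns = .FEATURE_SETS[[name]],
      m = length(.FEATURE_SETS[[name]]))
}

#' WindowSet: fixed-length feature windows ready for the classifier
#'
#' An `n x windowLength x m` array of feature windows plus one binary label
#' per window (1 = fall, 0 = not-fall) and the provenance of each window.
#'
#' @slot inputs numeric array, dim `c(n, windowLength, m)`.
#' @slot labels integer vector of 0/1 labels.
#' @slot origin data.frame with `subject_id`, `trial_id`, `start_index`
#'   (1-based row index of the window start within its trial).
#' @slot featureSet feature set name ("4p"/"5p"/"6p").
#' @slot windowLength frames per window (default pipeline value 18).
#' @export
setClass("WindowSet",
  representation(inputs = "array", labels = "integer", origin = "data.frame",
                 featureSet = "character", windowLength = "integer"),
  validity = function(object) {
    d <- dim(object@inputs)
    msg <- character()
    if (length(d) != 3L) msg <- c(msg, "inputs must be a 3-d array")
    else {
      if (d[1] != length(object@labels))
        msg <- c(msg, "labels length must equal number of windows")
      if (d[1] != nrow(object@origin))
        msg <- c(msg, "origin must have one row per window")
      if (d[2] != object@windowLength)
        msg <- c(msg, "dim 2 of inputs must equal windowLength")
      if (length(object@inputs) && !all(is.finite(object@inputs)))
        msg <- c(msg, "window values must all be finite")
    }
    if (length(object@labels) && !all(object@labels %in% c(0L, 1L)))
      msg <- c(msg, "labels must be 0/1")
    if (length(msg)) msg else TRUE
  })

#' ModelConfig: LSTM classifier architecture and training hyperparameters
#'
#' Defaults are the published network setting: two stacked LSTM layers of
#' 100 units, dropout 0.3 after the second layer, a single sigmoid output
#' neuron, Adam at learning rate 0.001, binary cross-entropy loss, 50
#' epochs, batch size 64.
#'
#' @slot lstmUnits units per LSTM layer.
#' @slot numLstmLayers number of stacked LSTM layers.
#' @slot dropout dropout fraction applied after the last LSTM layer
#'   (training only).
#' @slot epochs training epochs.
#' @slot batchSize windows per gradient step.
#' @slot learningRate Adam step size.
#' @slot optimizer optimizer name (only "adam" is implemented).
#' @slot loss loss name (only "binary_crossentropy" is implemented).
#' @slot hiddenActivation cell/candidate activation inside the LSTM
#'   ("relu" or "tanh"); gates are always sigmoid.
#' @slot outputActivation output neuron activation ("sigmoid").
#' @slot decisionThreshold score threshold for labelling a window a fall
#'   (label 1 iff score >= threshold).
#' @slot clipNorm global gradient-norm bound per Adam step; a standard
#'   stabiliser for relu-cell LSTMs, whose unbounded cell activations can
#'   otherwise blow up late in training. `Inf` disables clipping.
#' @slot restoreBest after the final epoch, restore the weights of the
#'   epoch with the lowest validation loss (the validation split's role
#'   is model selection); `FALSE` keeps the last-epoch weights.
#' @slot shuffle reshuffle window order between epochs; `FALSE` preserves
#'   the temporal order of the data.
#' @slot seed RNG seed for weight initialisation, dropout masks and (if
#'   enabled) shuffling.
#' @export
setClass("ModelConfig",
  representation(lstmUnits = "integer", numLstmLayers = "integer",
                 dropout = "numeric", epochs = "integer", batchSize = "integer",
                 learningRate = "numeric", optimizer = "character",
                 loss = "character", hiddenActivation = "character",
                 outputActivation = "character", decisionThreshold = "numeric",
                 clipNorm = "numeric", restoreBest = "logical",
                 shuffle = "logical", seed = "integer"),
  validity = function(object) {
    msg <- character()
    for (s in c("lstmUnits", "numLstmLayers", "epochs", "batchSize"))
      if (!.isCount(slot(object, s))) msg <- c(msg, paste(s, "must be a positive integer"))
    if (!(length(object@dropout) == 1L && is.finite(object@dropout) &&
          object@dropout >= 0 && object@dropout < 1))
      msg <- c(msg, "dropout must lie in [0, 1)")
    if (!(length(object@learningRate) == 1L && is.finite(object@learningRate) &&
          object@learningRate > 0))
      msg <- c(msg, "learningRate must be positive")
    if (!identical(object@optimizer, "adam"))
      msg <- c(msg, "optimizer: only 'adam' is implemented")
    if (!identical(object@loss, "binary_crossentropy"))
      msg <- c(msg, "loss: only 'binary_crossentropy' is implemented")
    if (!object@hiddenActivation %in% c("relu", "tanh"))
      msg <- c(msg, "hiddenActivation must be 'relu' or 'tanh'")
    if (!identical(object@outputActivation, "sigmoid"))
      msg <- c(msg, "outputActivation: only 'sigmoid' is implemented")
    if (!.isProb(object@decisionThreshold))
      msg <- c(msg, "decisionThreshold must lie in [0, 1]")
    if (!(length(object@clipNorm) == 1L && !is.na(object@clipNorm) &&
          object@clipNorm > 0))
      msg <- c(msg, "clipNorm must be positive (Inf to disable)")
    if (length(msg)) msg else TRUE
  })

#' Construct a ModelConfig
#'
#' @param lstmUnits,numLstmLayers,dropout,epochs,batchSize,learningRate
#'   architecture/training hyperparameters; see [ModelConfig-class].
#' @param optimizer,loss,hiddenActivation,outputActivation component names.
#' @param decisionThreshold fall-decision score threshold.
#' @param clipNorm global gradient-norm bound (`Inf` disables).
#' @param restoreBest keep the best-validation-loss epoch's weights.
#' @param shuffle reshuffle window order between epochs.
#' @param seed RNG seed.
#' @return A [ModelConfig-class].
#' @examples
#' modelConfig(epochs = 15, seed = 7)
#' @export
modelConfig <- function(lstmUnits = 100, numLstmLayers = 2, dropout = 0.3,
                        epochs = 50, batchSize = 64, learningRate = 0.001,
                        optimizer = "adam", loss = "binary_crossentropy",
                        hiddenActivation = "relu", outputActivation = "sigmoid",
                        decisionThreshold = 0.5, clipNorm = 1.0,
                        restoreBest = TRUE, shuffle = FALSE, seed = 1) {
  new("ModelConfig", lstmUnits = as.integer(lstmUnits),
      numLstmLayers = as.integer(numLstmLayers), dropout = dropout,
      epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      learningRate = learningRate, optimizer = optimizer, loss = loss,
      hiddenActivation = hiddenActivation, outputActivation = outputActivation,
      decisionThreshold = decisionThreshold, clipNorm = clipNorm,
      restoreBest = isTRUE(restoreBest), shuffle = isTRUE(shuffle),
      seed = as.integer(seed))
}

#' SafeModel: an LSTM fall/not-fall classifier
#'
#' Stacked LSTM layers followed by dropout and a single sigmoid output
#' neuron. Built untrained by [buildModel()], fitted by [trainModel()].
#'
#' @slot config the [ModelConfig-class] used to build/train it.
#' @slot featureSet feature set name if built for a named variant, else "".
#' @slot m input feature count per time step.
#' @slot weights list of layer weight matrices.
#' @slot trained has [trainModel()] been run.
#' @slot history per-epoch training history (one row per epoch:
#'   `epoch`, `train_loss`, `train_acc`, `val_loss`, `val_acc`).
#' @export
setClass("SafeModel",
  representation(config = "ModelConfig", featureSet = "character",
                 m = "integer", weights = "list", trained = "logical",
                 history = "data.frame"))

#' EvalReport: confusion counts and classification metrics
#'
#' Falls (label 1) are the positive class. Percentages are on the 0–100
#' scale; a metric with a zero denominator is reported `NA` and listed in
#' `undefined`, never coerced to 0. `lossBits` is the base-2 cross entropy
#' summed over evaluated windows (`NA` when no scores were supplied).
#'
#' @slot tp,tn,fp,fn confusion counts.
#' @slot precision,recall,f1,accuracy percentages in [0, 100] (or `NA`).
#' @slot lossBits total base-2 cross entropy in bits.
#' @slot n number of evaluated windows.
#' @slot undefined names of metrics with zero denominators.
#' @export
setClass("EvalReport",
  representation(tp = "integer", tn = "integer", fp = "integer", fn = "integer",
                 precision = "numeric", recall = "numeric", f1 = "numeric",
                 accuracy = "numeric", lossBits = "numeric", n = "integer",
                 undefined = "character"),
  validity = function(object) {
    msg <- character()
    cnt <- c(object@tp, object@tn, object@fp, object@fn)
    if (any(cnt < 0L)) msg <- c(msg, "confusion counts must be non-negative")
    if (sum(cnt) != object@n)
      msg <- c(msg, "TP+TN+FP+FN must equal the number of evaluated windows")
    for (s in c("precision", "recall", "f1", "accuracy")) {
      v <- slot(object, s)
      if (!is.na(v) && (v < 0 || v > 100))
        msg <- c(msg, paste(s, "must lie in [0, 100]"))
    }
    if (length(msg)) msg else TRUE
  })

#' SimulationConfig: synthetic skeleton-motion study conditions
#'
#' Parameters of the two-rod (hip–shoulder, shoulder–nose) skeleton
#' simulator. Defaults define the package's standard synthetic study:
#' 18 Hz sampling, 40 trials per scenario over all seven scenarios,
#' fall trunk rotations peaking at 3.5 rad/s versus ADL trunk rates
#' bounded by 1 rad/s, and per-frame Gaussian coordinate jitter of
#' 0.004 image units (about 2.5 px at 640-px width) emulating
#' pose-estimation error.
#'
#' @slot fps frames per second.
#' @slot nTrialsPerScenario trials generated per scenario.
#' @slot scenarios subset of `c("stand", "walk", "sit", "bend_intentional",
#'   "fall_forward", "fall_sideward", "near_fall_recovered")`.
#' @slot trunkLength,neckLength rod lengths in image units (image height
#'   is 1).
#' @slot fallPeakAngularRate peak trunk angular rate of falls (rad/s).
#' @slot adlMaxAngularRate upper bound on ADL trunk angular rates (rad/s);
#'   must stay below `fallPeakAngularRate` (the separability knob).
#' @slot noiseSd coordinate jitter standard deviation (image units).
#' @slot seed RNG seed.
#' @export
setClass("SimulationConfig",
  representation(fps = "numeric", nTrialsPerScenario = "integer",
                 scenarios = "character", trunkLength = "numeric",
                 neckLength = "numeric", fallPeakAngularRate = "numeric",
                 adlMaxAngularRate = "numeric", noiseSd = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@fps <= 0) msg <- c(msg, "fps must be positive")
    if (!.isCount(object@nTrialsPerScenario))
      msg <- c(msg, "nTrialsPerScenario must be a positive integer")
    bad <- setdiff(object@scenarios, .SCENARIOS)
    if (length(bad))
      msg <- c(msg, paste0("unknown scenario(s): ", paste(bad, collapse = ", ")))
    if (!length(object@scenarios)) msg <- c(msg, "scenario mix must be non-empty")
    if (object@trunkLength <= 0 || object@neckLength <= 0)
      msg <- c(msg, "rod lengths must be positive")
    if (object@adlMaxAngularRate >= object@fallPeakAngularRate)
      msg <- c(msg, "adlMaxAngularRate must be < fallPeakAngularRate")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (length(msg)) msg else TRUE
  })

.SCENARIOS <- c("stand", "walk", "sit", "bend_intentional",
                "fall_forward", "fall_sideward", "near_fall_recovered")

#' Construct a SimulationConfig
#'
#' @param fps,nTrialsPerScenario,scenarios,trunkLength,neckLength see
#'   [SimulationConfig-class].
#' @param fallPeakAngularRate,adlMaxAngularRate,noiseSd,seed see
#'   [SimulationConfig-class].
#' @return A [SimulationConfig-class].
#' @examples
#' simulationConfig(nTrialsPerScenario = 2, noiseSd = 0)
#' @export
simulationConfig <- function(fps = 18, nTrialsPerScenario = 40,
                             scenarios = .SCENARIOS, trunkLength = 0.28,
                             neckLength = 0.14, fallPeakAngularRate = 3.5,
                             adlMaxAngularRate = 1.0, noiseSd = 0.004,
                             seed = 1) {
  new("SimulationConfig", fps = fps,
      nTrialsPerScenario = as.integer(nTrialsPerScenario),
      scenarios = scenarios, trunkLength = trunkLength,
      neckLength = neckLength, fallPeakAngularRate = fallPeakAngularRate,
      adlMaxAngularRate = adlMaxAngularRate, noiseSd = noiseSd,
      seed = as.integer(seed))
}
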