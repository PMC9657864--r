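#' @include AllClasses.R lstm-engine.R
NULL

#' Build an untrained LSTM fall classifier
#'
#' Architecture (defaults): `LSTM(100, return sequences) -> LSTM(100) ->
#' dropout(0.3) -> dense(1, sigmoid)`, taking `windowLength x m` feature
#' windows. Weight initialisation is Glorot-uniform, seeded by
#' `cfg@seed`, with forget-gate biases at 1; two builds with the same
#' seed yield identical weights.
#'
#' @param m number of input features per time step; pass a feature set
#'   name ("4p"/"5p"/"6p") or [FeatureSetSpec-class] to tag the model with
#'   its variant.
#' @param cfg a [ModelConfig-class].
#' @return An untrained [SafeModel-class].
#' @examples
#' countParams(buildModel("6p", modelConfig()))
#' @export
buildModel <- function(m, cfg = modelConfig()) {
  stopifnot(is(cfg, "ModelConfig"))
  fsName <- ""
  if (is.character(m) || is(m, "FeatureSetSpec")) {
    spec <- featureSetSpec(m)
    fsName <- spec@name
    m <- spec@m
  }
  if (!.isCount(m)) .stopf("m must be a positive integer feature count")
  weights <- .withSeed(cfg@seed,
                       .lstmInit(as.integer(m), cfg@lstmUnits, cfg@numLstmLayers))
  new("SafeModel", config = cfg, featureSet = fsName, m = as.integer(m),
      weights = weights, trained = FALSE,
      history = data.frame(epoch = integer(), train_loss = numeric(),
                           train_acc = numeric(), val_loss = numeric(),
                           val_acc = numeric()))
}

#' Number of trainable parameters
#'
#' @param model a [SafeModel-class].
#' @return Integer count of trainable weights.
#' @export
countParams <- function(model) {
  stopifnot(is(model, "SafeModel"))
  .countParams(model@weights)
}

.asTensors <- function(x, what = "input") {
  if (is(x, "WindowSet")) x <- toModelTensors(x)
  if (!is.list(x) || is.null(x$inputs) || is.null(x$labels))
    .stopf("%s must be a WindowSet or a list(inputs, labels)", what)
  if (length(dim(x$inputs)) != 3L)
    .stopf("%s inputs must be an n x windowLength x m array", what)
  if (dim(x$inputs)[1L] != length(x$labels))
    .stopf("%s labels length must match number of windows", what)
  x
}

#' Train the classifier
#'
#' Runs exactly `cfg@epochs` epochs of Adam on natural-log binary
#' cross entropy, batches taken in temporal order unless `cfg@shuffle`
#' (dropout masks and any shuffling are drawn from `cfg@seed`, so the run
#' is fully reproducible). Validation loss/accuracy are computed on the
#' validation tensors after every epoch with dropout disabled.
#'
#' @param model an untrained (or previously trained) [SafeModel-class].
#' @param train,val training and validation data: [WindowSet-class] or
#'   `list(inputs, labels)`.
#' @param epochs optional override of `cfg@epochs` (architecture
#'   unchanged).
#' @return The trained [SafeModel-class] with populated
#'   [trainingHistory()].
#' @export
trainModel <- function(model, train, val, epochs = NULL) {
  stopifnot(is(model, "SafeModel"))
  cfg <- model@config
  train <- .asTensors(train, "train")
  val <- .asTensors(val, "val")
  for (tens in list(train, val))
    if (dim(tens$inputs)[3L] != model@m)
      .stopf("tensor feature count %d does not match model input contract (m = %d)",
             dim(tens$inputs)[3L], model@m)
  nEpochs <- if (is.null(epochs)) cfg@epochs else as.integer(epochs)
  n <- dim(train$inputs)[1L]
  H <- cfg@lstmUnits
  act <- cfg@hiddenActivation
  weights <- model@weights
  adam <- .adamInit(weights)
  hist <- matrix(NA_real_, nEpochs, 4L)
  best <- list(loss = Inf, weights = weights, epoch = 0L)
  .withSeed(cfg@seed, {
    for (ep in seq_len(nEpochs)) {
      ord <- if (cfg@shuffle) sample(n) else seq_len(n)
      lossSum <- 0; correct <- 0L
      for (start in seq(1L, n, by = cfg@batchSize)) {
        idx <- ord[start:min(start + cfg@batchSize - 1L, n)]
        B <- length(idx)
        Xb <- train$inputs[idx, , , drop = FALSE]
        yb <- train$labels[idx]
        mask <- if (cfg@dropout > 0)
          matrix((stats::runif(B * H) >= cfg@dropout) / (1 - cfg@dropout), B, H)
        fwd <- .lstmForward(weights, Xb, act, mask = mask, cache = TRUE)
        grads <- .clipGrads(.lstmBackward(weights, fwd, Xb, yb, act),
                            cfg@clipNorm)
        upd <- .adamStep(weights, grads, adam, cfg@learningRate)
        weights <- upd$weights; adam <- upd$state
        lossSum <- lossSum + .bceLoss(fwd$scores, yb) * B
        correct <- correct + sum((fwd$scores >= cfg@decisionThreshold) == (yb == 1L))
      }
      vScores <- .lstmForward(weights, val$inputs, act)$scores
      vLoss <- .bceLoss(vScores, val$labels)
      hist[ep, ] <- c(lossSum / n, correct / n, vLoss,
                      mean((vScores >= cfg@decisionThreshold) == (val$labels == 1L)))
      if (vLoss < best$loss)
        best <- list(loss = vLoss, weights = weights, epoch = ep)
    }
  })
  model@weights <- if (cfg@restoreBest) best$weights else weights
  model@trained <- TRUE
  model@history <- data.frame(epoch = seq_len(nEpochs), train_loss = hist[, 1L],
                              train_acc = hist[, 2L], val_loss = hist[, 3L],
                              val_acc = hist[, 4L])
  model
}

#' Score windows and decide fall / not-fall
#'
#' Produces the sigmoid score of each window (strictly inside (0, 1)) and
#' the binary decision `label = 1` iff `score >= decisionThreshold`.
#'
#' @param model a trained [SafeModel-class].
#' @param inputs `n x windowLength x m` array, or a [WindowSet-class].
#' @return List with `scores` (numeric) and `labels` (integer 0/1).
#' @export
predictFalls <- function(model, inputs) {
  stopifnot(is(model, "SafeModel"))
  if (!model@trained)
    .stopf("model has not been trained; run trainModel() first")
  if (is(inputs, "WindowSet")) inputs <- windowInputs(inputs)
  if (length(dim(inputs)) != 3L || dim(inputs)[3L] != model@m)
    .stopf("inputs incompatible with model input contract (*, %d)", model@m)
  scores <- .lstmForward(model@weights, inputs,
                         model@config@hiddenActivation)$scores
  list(scores = scores,
       labels = as.integer(scores >= model@config@decisionThreshold))
}

#' @describeIn predictFalls S4 `predict` method; returns the same list.
#' @param object a trained [SafeModel-class].
#' @param ... passed through (`inputs`).
#' @export
setMethod("predict", "SafeModel",
          function(object, ...) predictFalls(object, ...))

# --- checkpointing ---------------------------------------------------------

.cfgToList <- function(cfg) {
  nm <- slotNames(class(cfg))
  stats::setNames(lapply(nm, function(s) slot(cfg, s)), nm)
}

#' Save / load a model checkpoint directory
#'
#' Writes `weights.json` (full-precision weights) and `model.json` (a
#' sidecar with the [ModelConfig-class], feature-set name, input contract
#' and training history) into `dir`.
#'
#' @param model a [SafeModel-class].
#' @param dir checkpoint directory (created if needed).
#' @return `dir` invisibly (save); the restored [SafeModel-class] (load).
#' @export
saveModel <- function(model, dir) {
  stopifnot(is(model, "SafeModel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  side <- list(package = "fallsafe",
               version = as.character(utils::packageVersion("fallsafe")),
               featureSet = model@featureSet, m = model@m,
               trained = model@trained, config = .cfgToList(model@config),
               history = model@history)
  jsonlite::write_json(side, file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(model@weights, file.path(dir, "weights.json"),
                       digits = NA, matrix = "columnmajor")
  invisible(dir)
}

#' @rdname saveModel
#' @export
loadModel <- function(dir) {
  sideFile <- file.path(dir, "model.json")
  wFile <- file.path(dir, "weights.json")
  if (!file.exists(sideFile) || !file.exists(wFile))
    .stopf("not a model checkpoint directory: %s", dir)
  side <- jsonlite::read_json(sideFile, simplifyVector = TRUE)
  cfg <- do.call(modelConfig, side$config)
  # weights were written column-major; rebuild each matrix from its columns
  raw <- jsonlite::read_json(wFile, simplifyVector = FALSE)
  H <- cfg@lstmUnits
  weights <- list(
    layers = lapply(raw$layers, function(l)
      list(Wx = matrix(unlist(l$Wx), ncol = 4L * H),
           Wh = matrix(unlist(l$Wh), ncol = 4L * H),
           b = as.numeric(unlist(l$b)))),
    dense = list(w = matrix(unlist(raw$dense$w), ncol = 1L),
                 b = as.numeric(unlist(raw$dense$b))))
  hist <- as.data.frame(side$history)
  new("SafeModel", config = cfg, featureSet = side$featureSet %||% "",
      m = as.integer(side$m), weights = weights,
      trained = isTRUE(side$trained), history = hist)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
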