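#' @include AllClasses.R
NULL

#' Default run configuration
#'
#' One nested list drives every pipeline command. The defaults are the
#' published network setting (Table-style hyperparameters: two 100-unit
#' LSTM layers, dropout 0.3, Adam at 0.001, binary cross entropy, 50
#' epochs, batch 64), an 18-frame non-overlapping window, the unshuffled
#' 69\%/20\% train/validation split, and the standard synthetic study
#' conditions of [simulationConfig()].
#'
#' @param path optional YAML/JSON file whose entries override the
#'   defaults (same nesting; partial files are fine).
#' @return Nested list with `simulation`, `dataset` and `model` sections.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- list(
    simulation = list(fps = 18, n_trials_per_scenario = 40,
                      scenarios = .SCENARIOS, trunk_length = 0.28,
                      neck_length = 0.14, fall_peak_angular_rate = 3.5,
                      adl_max_angular_rate = 1.0, noise_sd = 0.004, seed = 1),
    dataset = list(window_length = 18, label_rule = "any", balance = TRUE,
                   train_fraction = 0.69, val_fraction_of_train = 0.20,
                   shuffle = FALSE, seed = 1),
    model = list(lstm_units = 100, num_lstm_layers = 2, dropout = 0.3,
                 epochs = 50, batch_size = 64, learning_rate = 0.001,
                 optimizer = "adam", loss = "binary_crossentropy",
                 hidden_activation = "relu", output_activation = "sigmoid",
                 decision_threshold = 0.5, clip_norm = 1.0,
                 restore_best = TRUE, shuffle = FALSE, seed = 1),
    activity_map = NULL)
  if (!is.null(path)) {
    if (!file.exists(path)) .stopf("config file not found: %s", path)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    for (sec in intersect(names(user), c("simulation", "dataset", "model"))) {
      bad <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
      if (length(bad))
        .stopf("unknown %s config key(s): %s", sec, paste(bad, collapse = ", "))
      cfg[[sec]][names(user[[sec]])] <- user[[sec]]
    }
    if (!is.null(user$activity_map)) cfg$activity_map <- user$activity_map
  }
  cfg
}

.simConfigFrom <- function(cfg, seed = NULL) {
  s <- cfg$simulation
  simulationConfig(fps = s$fps, nTrialsPerScenario = s$n_trials_per_scenario,
                   scenarios = s$scenarios, trunkLength = s$trunk_length,
                   neckLength = s$neck_length,
                   fallPeakAngularRate = s$fall_peak_angular_rate,
                   adlMaxAngularRate = s$adl_max_angular_rate,
                   noiseSd = s$noise_sd,
                   seed = if (is.null(seed)) s$seed else seed)
}

.modelConfigFrom <- function(cfg, seed = NULL, epochs = NULL) {
  m <- cfg$model
  modelConfig(lstmUnits = m$lstm_units, numLstmLayers = m$num_lstm_layers,
              dropout = m$dropout,
              epochs = if (is.null(epochs)) m$epochs else epochs,
              batchSize = m$batch_size, learningRate = m$learning_rate,
              optimizer = m$optimizer, loss = m$loss,
              hiddenActivation = m$hidden_activation,
              outputActivation = m$output_activation,
              decisionThreshold = m$decision_threshold,
              clipNorm = m$clip_norm, restoreBest = m$restore_best,
              shuffle = m$shuffle,
              seed = if (is.null(seed)) m$seed else seed)
}

.activityMapFrom <- function(cfg) {
  am <- cfg$activity_map
  if (is.null(am)) return(defaultActivityMap())
  if (is.character(am) && length(am) == 1L && file.exists(am))
    return(readActivityMap(am))
  map <- stats::setNames(as.character(unlist(am)), names(unlist(am)))
  map
}

# Every artifact-producing command records how it was run.
.writeManifest <- function(path, command, config, seed, inputs, outputs) {
  man <- list(command = command, package = "fallsafe",
              version = as.character(utils::packageVersion("fallsafe")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = seed, inputs = as.list(inputs),
              outputs = as.list(outputs), config = config)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Pipeline commands
#'
#' Thin, manifest-writing entry points tying the modules together; the
#' `inst/cli/safe.R` script dispatches to them.
#' \describe{
#'   \item{runSimulate}{simulate a labelled key-point dataset and write
#'     the keypoint CSV.}
#'   \item{runFeaturize}{read a keypoint CSV, apply frame filters, compute
#'     kinematic features and write the feature CSV.}
#'   \item{runTrain}{balance, window, split and train one model variant;
#'     writes a checkpoint directory and per-epoch history CSV.}
#'   \item{runEvaluate}{score a feature CSV with a checkpoint and write an
#'     evaluation report.}
#'   \item{runEndToEnd}{simulate, featurize, then train and evaluate the
#'     4p/5p/6p variants in one pass.}
#' }
#'
#' @param out,outDir output file / directory.
#' @param config `NULL` (defaults), a YAML/JSON path, or a
#'   [readRunConfig()]-shaped list.
#' @param seed overrides the config seeds (one integer drives simulation
#'   and training).
#' @param input keypoint CSV path ([runFeaturize()]).
#' @param features feature CSV path or feature data.frame.
#' @param model feature-set name "4p"/"5p"/"6p" ([runTrain()]).
#' @param epochs optional override of the configured epoch count.
#' @param checkpoint checkpoint directory written by [runTrain()].
#' @param models variants to train in [runEndToEnd()].
#' @return `runSimulate`/`runFeaturize`: the output path (invisibly);
#'   `runTrain`: list with the trained model, split and paths;
#'   `runEvaluate`: the [EvalReport-class]; `runEndToEnd`: list with per
#'   variant reports, trained models, and test accuracies.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
runSimulate <- function(out, config = NULL, seed = NULL) {
  cfg <- if (is.list(config)) config else readRunConfig(config)
  sim <- .simConfigFrom(cfg, seed)
  ds <- simulateDataset(sim)
  writeKeypoints(ds$sequences, out)
  .writeManifest(paste0(out, ".manifest.json"), "simulate", cfg,
                 sim@seed, character(), out)
  invisible(out)
}

#' @rdname pipeline
#' @export
runFeaturize <- function(input, out, config = NULL) {
  cfg <- if (is.list(config)) config else readRunConfig(config)
  map <- .activityMapFrom(cfg)
  seqs <- readKeypoints(input)
  feats <- lapply(seqs, function(s) computeFeatures(applyFrameFilters(s), map))
  feats <- do.call(rbind, feats)
  if (is.null(feats) || !nrow(feats))
    .stopf("no usable frames in %s after filtering", input)
  writeFeatures(feats, out)
  .writeManifest(paste0(out, ".manifest.json"), "featurize", cfg,
                 NA_integer_, input, out)
  invisible(out)
}

# features path/data.frame -> balanced, windowed, split tensors
.prepareSplit <- function(features, model, cfg, seed = NULL) {
  if (is.character(features)) features <- readFeatures(features)
  d <- cfg$dataset
  dsSeed <- if (is.null(seed)) d$seed else seed
  if (isTRUE(d$balance))
    features <- balanceClasses(features, seed = dsSeed,
                               windowLength = d$window_length)
  ws <- makeWindows(features, model, windowLength = d$window_length,
                    labelRule = d$label_rule)
  splitWindows(ws, trainFraction = d$train_fraction,
               valFractionOfTrain = d$val_fraction_of_train,
               shuffle = isTRUE(d$shuffle), seed = dsSeed)
}

#' @rdname pipeline
#' @export
runTrain <- function(features, model = c("6p", "5p", "4p"), outDir,
                     config = NULL, seed = NULL, epochs = NULL) {
  model <- match.arg(model)
  cfg <- if (is.list(config)) config else readRunConfig(config)
  split <- .prepareSplit(features, model, cfg, seed)
  mcfg <- .modelConfigFrom(cfg, seed, epochs)
  fit <- buildModel(model, mcfg)
  fit <- trainModel(fit, split$train, split$validation)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  saveModel(fit, outDir)
  histPath <- file.path(outDir, "history.csv")
  utils::write.csv(trainingHistory(fit), histPath, row.names = FALSE,
                   quote = FALSE)
  .writeManifest(file.path(outDir, "manifest.json"), "train",
                 c(cfg, list(feature_set = model)), mcfg@seed,
                 if (is.character(features)) features else "<data.frame>",
                 outDir)
  list(model = fit, split = split, checkpoint = outDir, history = histPath)
}

#' @rdname pipeline
#' @export
runEvaluate <- function(checkpoint, features, out = NULL, config = NULL) {
  cfg <- if (is.list(config)) config else readRunConfig(config)
  fit <- loadModel(checkpoint)
  if (!nzchar(featureSetName(fit)))
    .stopf("checkpoint %s does not record its feature set", checkpoint)
  if (is.character(features)) features <- readFeatures(features)
  ws <- makeWindows(features, featureSetName(fit),
                    windowLength = cfg$dataset$window_length,
                    labelRule = cfg$dataset$label_rule)
  if (!nWindows(ws)) .stopf("no complete windows to evaluate")
  rep <- evalReport(ws, model = fit)
  if (!is.null(out)) {
    writeEvalReport(rep, out)
    .writeManifest(paste0(out, ".manifest.json"), "evaluate", cfg,
                   NA_integer_, c(checkpoint = checkpoint), out)
  }
  rep
}

#' @rdname pipeline
#' @export
runEndToEnd <- function(config = NULL, outDir = NULL, seed = NULL,
                        models = c("4p", "5p", "6p"), epochs = NULL) {
  cfg <- if (is.list(config)) config else readRunConfig(config)
  sim <- .simConfigFrom(cfg, seed)
  ds <- simulateDataset(sim)
  map <- .activityMapFrom(cfg)
  feats <- do.call(rbind, lapply(ds$sequences, function(s)
    computeFeatures(applyFrameFilters(s), map)))
  reports <- list(); fits <- list()
  for (mv in models) {
    split <- .prepareSplit(feats, mv, cfg, seed)
    mcfg <- .modelConfigFrom(cfg, seed, epochs)
    fit <- trainModel(buildModel(mv, mcfg), split$train, split$validation)
    reports[[mv]] <- evalReport(split$test, model = fit)
    fits[[mv]] <- fit
    if (!is.null(outDir)) {
      dir.create(file.path(outDir, mv), showWarnings = FALSE, recursive = TRUE)
      saveModel(fit, file.path(outDir, mv))
      writeEvalReport(reports[[mv]], file.path(outDir, mv, "eval.json"),
                      file.path(outDir, mv, "confusion.csv"))
    }
  }
  acc <- vapply(reports, function(r) r@accuracy, numeric(1L))
  if (!is.null(outDir))
    .writeManifest(file.path(outDir, "manifest.json"), "end_to_end", cfg,
                   if (is.null(seed)) NA_integer_ else seed,
                   character(), outDir)
  list(reports = reports, models = fits, accuracy = acc)
}
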