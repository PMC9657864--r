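#' @include AllClasses.R
NULL

#' Down-sample the majority class to balance a feature stream
#'
#' Removes majority-class rows until the two class counts agree to within
#' one window length, by repeatedly dropping a contiguous block from the
#' tail of a (seeded) randomly chosen majority-class trial. Dropping whole
#' trial tails — never isolated rows — keeps every retained stretch a
#' valid time series for windowing. The minority class is never touched
#' and no rows are ever synthesised.
#'
#' @param features feature data.frame with `subject_id`, `trial_id`,
#'   `label` columns (temporal order assumed).
#' @param seed RNG seed for the choice of trials to trim.
#' @param windowLength tolerance on the final count difference (and the
#'   block size removed per step).
#' @return The balanced feature data.frame, original row order preserved.
#' @export
balanceClasses <- function(features, seed = 1, windowLength = 18) {
  counts <- table(factor(features$label, levels = c("fall", "not_fall")))
  if (any(counts == 0L))
    .stopf("balanceClasses: class '%s' absent from the data",
           names(counts)[counts == 0L][1L])
  .withSeed(seed, {
    keep <- rep(TRUE, nrow(features))
    trialKey <- paste(features$subject_id, features$trial_id, sep = "\r")
    repeat {
      tab <- table(factor(features$label[keep], levels = c("fall", "not_fall")))
      excess <- max(tab) - min(tab)
      if (excess <= windowLength) break
      majority <- names(tab)[which.max(tab)]
      cand <- unique(trialKey[keep & features$label == majority])
      tk <- sample(cand, 1L)
      rows <- which(keep & trialKey == tk)
      drop <- utils::tail(rows, min(windowLength, excess, length(rows)))
      keep[drop] <- FALSE
    }
    out <- features[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Segment a feature stream into fixed-length non-overlapping windows
#'
#' Within each trial (in order of appearance), consecutive frames are cut
#' into non-overlapping blocks of `windowLength` rows; a trailing
#' remainder shorter than a full window is dropped. A window is labelled
#' fall if any of its frames carries a fall label (`labelRule = "any"`,
#' the default, which favours recall and hence timely alarms); set
#' `labelRule = "majority"` for a majority vote.
#'
#' @param features feature data.frame (typically balanced first).
#' @param spec feature set name or [FeatureSetSpec-class].
#' @param windowLength frames per window.
#' @param labelRule `"any"` or `"majority"`.
#' @return A [WindowSet-class].
#' @export
makeWindows <- function(features, spec, windowLength = 18,
                        labelRule = c("any", "majority")) {
  spec <- featureSetSpec(spec)
  labelRule <- match.arg(labelRule)
  if (!.isCount(windowLength)) .stopf("windowLength must be a positive integer")
  windowLength <- as.integer(windowLength)
  mat <- selectFeatures(features, spec)
  trialKey <- paste(features$subject_id, features$trial_id, sep = "\r")
  isFall <- features$label == "fall"

  blocks <- list(); labs <- integer(); orig <- list()
  for (tk in unique(trialKey)) {
    rows <- which(trialKey == tk)
    nW <- length(rows) %/% windowLength
    if (nW == 0L) next
    for (w in seq_len(nW)) {
      idx <- rows[((w - 1L) * windowLength + 1L):(w * windowLength)]
      blocks[[length(blocks) + 1L]] <- mat[idx, , drop = FALSE]
      nf <- sum(isFall[idx])
      labs <- c(labs, if (labelRule == "any") as.integer(nf > 0L)
                      else as.integer(nf * 2L > windowLength))
      orig[[length(orig) + 1L]] <-
        data.frame(subject_id = features$subject_id[idx[1L]],
                   trial_id = features$trial_id[idx[1L]],
                   start_index = (w - 1L) * windowLength + 1L,
                   stringsAsFactors = FALSE)
    }
  }
  n <- length(blocks)
  inputs <- array(0, dim = c(n, windowLength, spec@m),
                  dimnames = list(NULL, NULL, spec@columns))
  for (i in seq_len(n)) inputs[i, , ] <- blocks[[i]]
  origin <- if (n) do.call(rbind, orig)
            else data.frame(subject_id = character(), trial_id = character(),
                            start_index = integer(), stringsAsFactors = FALSE)
  new("WindowSet", inputs = inputs, labels = labs, origin = origin,
      featureSet = spec@name, windowLength = windowLength)
}

.subsetWindows <- function(ws, idx) {
  new("WindowSet", inputs = ws@inputs[idx, , , drop = FALSE],
      labels = ws@labels[idx], origin = ws@origin[idx, , drop = FALSE],
      featureSet = ws@featureSet, windowLength = ws@windowLength)
}

#' Split windows into train / validation / test sets
#'
#' With `shuffle = FALSE` (the default, preserving temporal order), the
#' first `round(trainFraction * n)` windows form the train+validation
#' block — of which the last `valFractionOfTrain` are validation — and the
#' remaining windows are the test set. Fractional sizes round half up.
#' The published split allocates about 69\% of windows to
#' train+validation and holds 20\% of that block out for validation.
#'
#' @param ws a [WindowSet-class].
#' @param trainFraction fraction of windows in train+validation.
#' @param valFractionOfTrain fraction of the train block used for
#'   validation.
#' @param shuffle permute windows (seeded) before splitting; the split is
#'   seed-independent when `FALSE`.
#' @param seed RNG seed, used only when `shuffle = TRUE`.
#' @return Named list of three [WindowSet-class]: `train`, `validation`,
#'   `test`; together they partition the input.
#' @export
splitWindows <- function(ws, trainFraction = 0.69, valFractionOfTrain = 0.20,
                         shuffle = FALSE, seed = 1) {
  stopifnot(is(ws, "WindowSet"))
  n <- nWindows(ws)
  if (n < 3L) .stopf("need at least 3 windows to split, got %d", n)
  for (f in c(trainFraction, valFractionOfTrain))
    if (!(is.finite(f) && f > 0 && f < 1))
      .stopf("split fractions must lie strictly in (0, 1)")
  ord <- seq_len(n)
  if (shuffle) ord <- .withSeed(seed, sample(n))
  nTrainVal <- .roundHalfUp(trainFraction * n)
  nVal <- .roundHalfUp(valFractionOfTrain * nTrainVal)
  nTrain <- nTrainVal - nVal
  nTest <- n - nTrainVal
  if (nTrain < 1L || nVal < 1L || nTest < 1L)
    .stopf("split produced an empty set (train %d / val %d / test %d)",
           nTrain, nVal, nTest)
  list(train = .subsetWindows(ws, ord[seq_len(nTrain)]),
       validation = .subsetWindows(ws, ord[nTrain + seq_len(nVal)]),
       test = .subsetWindows(ws, ord[nTrainVal + seq_len(nTest)]))
}

#' Stack windows into model tensors
#'
#' Converts one [WindowSet-class] (or a list of them, concatenated in
#' order) into the `n x windowLength x m` input array and 0/1 label vector
#' consumed by the classifier (fall = 1). Stacking preserves order.
#'
#' @param windows a [WindowSet-class] or list of them sharing `m` and
#'   `windowLength`.
#' @return List with `inputs` (array) and `labels` (integer vector).
#' @export
toModelTensors <- function(windows) {
  if (is(windows, "WindowSet")) windows <- list(windows)
  stopifnot(length(windows) > 0L,
            all(vapply(windows, is, logical(1L), "WindowSet")))
  ms <- vapply(windows, function(w) dim(w@inputs)[3L], integer(1L))
  ls <- vapply(windows, function(w) w@windowLength, integer(1L))
  if (length(unique(ms)) != 1L || length(unique(ls)) != 1L)
    .stopf("windows have heterogeneous shapes (m: %s; length: %s)",
           paste(unique(ms), collapse = ","), paste(unique(ls), collapse = ","))
  n <- sum(vapply(windows, nWindows, integer(1L)))
  inputs <- array(0, dim = c(n, ls[1L], ms[1L]),
                  dimnames = dimnames(windows[[1L]]@inputs))
  labels <- integer(n)
  at <- 0L
  for (w in windows) {
    k <- nWindows(w)
    if (k) {
      inputs[at + seq_len(k), , ] <- w@inputs
      labels[at + seq_len(k)] <- w@labels
      at <- at + k
    }
  }
  list(inputs = inputs, labels = labels)
}
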