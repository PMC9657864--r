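# Small architectures keep these tests fast; the closed-form parameter
# count below is the independent oracle for the default-sized network.

toyTensors <- function(n, T = 6, m = 2, sep = 1.0, seed = 1) {
  set.seed(seed)
  y <- rep(c(1L, 0L), length.out = n)
  X <- array(rnorm(n * T * m, 0, 0.3), c(n, T, m))
  X[y == 1L, , 1] <- X[y == 1L, , 1] + sep
  list(inputs = X, labels = y)
}

toyConfig <- function(epochs = 5, ...) {
  modelConfig(lstmUnits = 8, epochs = epochs, batchSize = 8, ...)
}

test_that("trainable parameter count matches the closed-form LSTM oracle", {
  for (m in c(4L, 5L, 6L)) {
    model <- buildModel(m, modelConfig())
    # layer 1: 4 gates x (units x (units + m + 1)); layer 2 stacks on 100
    # inputs; dense: units weights + bias
    oracle <- 4 * (100 * (100 + m + 1)) + 4 * (100 * (100 + 100 + 1)) +
      (100 + 1)
    expect_equal(countParams(model), oracle)
  }
  small <- buildModel(3L, modelConfig(lstmUnits = 7, numLstmLayers = 2))
  expect_equal(countParams(small),
               4 * (7 * (7 + 3 + 1)) + 4 * (7 * (7 + 7 + 1)) + 8)
})

test_that("identical seeds build identical initial weights", {
  a <- buildModel("6p", modelConfig(seed = 42))
  b <- buildModel("6p", modelConfig(seed = 42))
  expect_identical(modelWeights(a), modelWeights(b))
  c <- buildModel("6p", modelConfig(seed = 43))
  expect_false(identical(modelWeights(a), modelWeights(c)))
  # recurrent kernels are orthogonal by construction
  Wh <- modelWeights(a)$layers[[1]]$Wh[, 1:100]
  expect_equal(crossprod(Wh), diag(100), tolerance = 1e-10)
})

test_that("backpropagation matches finite-difference gradients", {
  set.seed(31)
  m <- 2L; H <- 4L; T <- 5L; B <- 3L
  w <- fallsafe:::.lstmInit(m, H, 2L)
  X <- array(rnorm(B * T * m), c(B, T, m))
  y <- c(1, 0, 1)
  # tanh cells: smooth everywhere, so central differences are exact to
  # O(eps^2); relu kink-crossings would blur the comparison
  act <- "tanh"
  mask <- matrix(ifelse(runif(B * H) > 0.3, 1 / 0.7, 0), B, H)
  fwd <- fallsafe:::.lstmForward(w, X, act, mask = mask, cache = TRUE)
  gr <- fallsafe:::.lstmBackward(w, fwd, X, y, act)
  lossAt <- function(wmod) {
    f <- fallsafe:::.lstmForward(wmod, X, act, mask = mask)
    fallsafe:::.bceLoss(f$scores, y)
  }
  eps <- 1e-6
  checkSlot <- function(get, set, ganal) {
    for (k in sample(length(ganal), min(4, length(ganal)))) {
      vp <- get(w); vp[k] <- vp[k] + eps
      vm <- get(w); vm[k] <- vm[k] - eps
      gnum <- (lossAt(set(w, vp)) - lossAt(set(w, vm))) / (2 * eps)
      expect_equal(ganal[k], gnum, tolerance = 1e-4)
    }
  }
  for (l in 1:2) {
    checkSlot(function(w) w$layers[[l]]$Wx,
              function(w, v) { w$layers[[l]]$Wx[] <- v; w }, gr$layers[[l]]$Wx)
    checkSlot(function(w) w$layers[[l]]$Wh,
              function(w, v) { w$layers[[l]]$Wh[] <- v; w }, gr$layers[[l]]$Wh)
    checkSlot(function(w) w$layers[[l]]$b,
              function(w, v) { w$layers[[l]]$b <- v; w }, gr$layers[[l]]$b)
  }
  checkSlot(function(w) w$dense$w, function(w, v) { w$dense$w[] <- v; w },
            gr$dense$w)
  checkSlot(function(w) w$dense$b, function(w, v) { w$dense$b <- v; w },
            gr$dense$b)
})

test_that("training runs the requested epochs and fills the history", {
  tens <- toyTensors(8)
  fit <- trainModel(buildModel(2L, toyConfig(epochs = 1)), tens, tens)
  expect_equal(nrow(trainingHistory(fit)), 1L)
  expect_true(isTrained(fit))
  fit3 <- trainModel(buildModel(2L, toyConfig()), tens, tens, epochs = 3)
  h <- trainingHistory(fit3)
  expect_equal(h$epoch, 1:3)
  expect_true(all(is.finite(unlist(h))))
})

test_that("training loss decreases on a separable toy set for most seeds", {
  improved <- 0L
  for (s in 1:10) {
    tens <- toyTensors(24, sep = 1.5, seed = s)
    cfg <- toyConfig(epochs = 12, seed = s, restoreBest = FALSE)
    fit <- trainModel(buildModel(2L, cfg), tens, tens)
    h <- trainingHistory(fit)
    if (h$train_loss[12] < h$train_loss[1]) improved <- improved + 1L
  }
  expect_gte(improved, 9L)
})

test_that("validation metrics are computed on exactly the validation tensors", {
  tens <- toyTensors(16, seed = 5)
  val <- toyTensors(8, seed = 6)
  fit1 <- trainModel(buildModel(2L, toyConfig(seed = 2)), tens, val)
  valShift <- val; valShift$inputs <- valShift$inputs + 0.5
  fit2 <- trainModel(buildModel(2L, toyConfig(seed = 2)), tens, valShift)
  expect_false(identical(trainingHistory(fit1)$val_loss,
                         trainingHistory(fit2)$val_loss))
  # training metrics untouched by the perturbation
  expect_equal(trainingHistory(fit1)$train_loss,
               trainingHistory(fit2)$train_loss)
})

test_that("prediction contracts: range, threshold boundary, shapes, errors", {
  tens <- toyTensors(12, seed = 7)
  fit <- trainModel(buildModel(2L, toyConfig(seed = 3)), tens, tens)
  p <- predictFalls(fit, tens$inputs)
  expect_length(p$scores, 12L)
  expect_true(all(p$scores > 0 & p$scores < 1))
  expect_equal(p$labels, as.integer(p$scores >= 0.5))
  expect_equal(predict(fit, tens$inputs), p)

  # score exactly at the threshold labels fall (>= convention)
  expect_equal(as.integer(0.5 >= fit@config@decisionThreshold), 1L)

  expect_error(predictFalls(buildModel(2L, toyConfig()), tens$inputs),
               "not been trained")
  bad <- array(0, c(3, 6, 5))
  expect_error(predictFalls(fit, bad), "input contract")
  expect_error(trainModel(buildModel(4L, toyConfig()), tens, tens),
               "input contract")
})

test_that("training is reproducible and checkpoints restore the model", {
  tens <- toyTensors(16, seed = 8)
  fit1 <- trainModel(buildModel(2L, toyConfig(seed = 9)), tens, tens)
  fit2 <- trainModel(buildModel(2L, toyConfig(seed = 9)), tens, tens)
  expect_identical(predictFalls(fit1, tens$inputs)$scores,
                   predictFalls(fit2, tens$inputs)$scores)

  dir <- withr::local_tempdir()
  fit1@featureSet <- "6p"  # tag so the checkpoint records a variant
  saveModel(fit1, dir)
  back <- loadModel(dir)
  expect_equal(featureSetName(back), "6p")
  expect_equal(trainingHistory(back)$val_loss, trainingHistory(fit1)$val_loss)
  expect_equal(predictFalls(back, tens$inputs)$scores,
               predictFalls(fit1, tens$inputs)$scores, tolerance = 1e-12)
  expect_error(loadModel(withr::local_tempdir()), "checkpoint")
})

test_that("model config validity catches bad fields", {
  expect_error(modelConfig(dropout = 1), "dropout")
  expect_error(modelConfig(epochs = 0), "positive integer")
  expect_error(modelConfig(optimizer = "sgd"), "adam")
  expect_error(modelConfig(hiddenActivation = "elu"), "relu")
  expect_error(modelConfig(decisionThreshold = 1.5), "0, 1")
})
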