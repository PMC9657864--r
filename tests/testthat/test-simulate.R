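test_that("noiseless standing has identically zero angular rates", {
  f <- computeFeatures(applyFrameFilters(noiselessTrial("stand")))
  expect_true(all(f$dw_N == 0))
  expect_true(all(f$dw_LSh == 0))
  expect_true(all(f$dw_LH == 0))
})

test_that("noiseless falls rotate at the configured peak rate and drive R past 1", {
  for (sc in c("fall_forward", "fall_sideward")) {
    cfg <- simulationConfig(noiseSd = 0)
    s <- applyFrameFilters(simulateTrial(sc, cfg, seed = 5))
    fr <- keypointFrames(s)
    # independent trunk-angle oracle: finite differences of the
    # shoulder-to-hip line's inclination from vertical
    trunk <- atan2(fr$LSh_x - fr$LH_x, -(fr$LSh_y - fr$LH_y))
    peak <- max(abs(diff(trunk) / diff(fr$t)))
    expect_lt(abs(peak - cfg@fallPeakAngularRate) / cfg@fallPeakAngularRate,
              0.10)
    # head passes hip height strictly before the last retained frame
    f <- computeFeatures(s)
    expect_gt(max(f$R), 1)
    expect_lt(min(which(f$R > 1)), nrow(f))
    # monotone increase of R through the crossing
    ramp <- which(f$R > 0.9 & f$R < 1.1)
    expect_true(all(diff(f$R[ramp]) > 0))
  }
})

test_that("post-impact frames are flagged and removed by the filters", {
  raw <- simulateTrial("fall_forward", simulationConfig(noiseSd = 0), seed = 5)
  fr <- keypointFrames(raw)
  expect_gt(sum(fr$post_impact), 0)
  kept <- keypointFrames(applyFrameFilters(raw))
  expect_equal(sum(kept$post_impact), 0)
  expect_lt(nrow(kept), nrow(fr))
})

test_that("noiseless intentional bends stay below fall dynamics with R < 1", {
  cfg <- simulationConfig(noiseSd = 0)
  f <- computeFeatures(applyFrameFilters(simulateTrial("bend_intentional",
                                                       cfg, seed = 5)))
  expect_true(all(f$R < 1))
  expect_lt(max(abs(f$dw_N)), cfg@fallPeakAngularRate)
  # the bend moves the nose appreciably while the hip barely turns
  expect_gt(max(abs(f$dw_N)), 10 * max(abs(f$dw_LH)) - 1e-12)
})

test_that("recovered near-falls rise, keep R < 1 and return upright", {
  f <- computeFeatures(applyFrameFilters(
    noiselessTrial("near_fall_recovered")))
  expect_true(all(f$R < 1))
  # nose dips (N_y grows) then comes back near its starting height
  expect_gt(max(f$N_y) - f$N_y[1], 0.1)
  expect_lt(abs(f$N_y[nrow(f)] - f$N_y[1]), 0.05)
})

test_that("trials are reproducible under a seed and sized by the scenario mix", {
  cfg <- testSimConfig()
  a <- simulateTrial("walk", cfg, seed = 3)
  b <- simulateTrial("walk", cfg, seed = 3)
  expect_identical(keypointFrames(a), keypointFrames(b))

  ds <- simulateDataset(simulationConfig(nTrialsPerScenario = 3,
                                         scenarios = c("stand", "fall_forward"),
                                         seed = 2))
  expect_length(ds$sequences, 6L)
  expect_setequal(unique(vapply(ds$sequences,
                                function(s) keypointFrames(s)$activity_id[1],
                                integer(1))), c(7L, 1L))
  expect_error(simulateTrial("cartwheel", cfg), "unknown scenario")
  expect_error(simulationConfig(adlMaxAngularRate = 4), "adlMaxAngularRate")
})

test_that("simulated datasets survive the CSV round trip", {
  f <- withr::local_tempfile(fileext = ".csv")
  ds <- simulateDataset(testSimConfig())
  writeKeypoints(ds$sequences, f)
  back <- readKeypoints(f)
  expect_length(back, length(ds$sequences))
  expect_equal(keypointFrames(back[[3]])$N_y,
               keypointFrames(ds$sequences[[3]])$N_y, tolerance = 1e-8)
  expect_equal(trialId(back[[5]]), trialId(ds$sequences[[5]]))
})

test_that("windows from the default pipeline contain both classes", {
  ds <- simulateDataset(simulationConfig(nTrialsPerScenario = 4, seed = 3))
  feats <- do.call(rbind, lapply(ds$sequences, function(s)
    computeFeatures(applyFrameFilters(s), ds$activityMap)))
  ws <- makeWindows(balanceClasses(feats, seed = 3), "6p")
  expect_gt(sum(windowLabels(ws) == 1L), 0L)
  expect_gt(sum(windowLabels(ws) == 0L), 0L)
})

test_that("a max|dw_N| threshold separates fall from ADL windows at >= 90%", {
  # lower bound the trained models should beat: one scalar summary per
  # window, best split found on the data itself
  ds <- simulateDataset(simulationConfig(nTrialsPerScenario = 10, seed = 4))
  feats <- do.call(rbind, lapply(ds$sequences, function(s)
    computeFeatures(applyFrameFilters(s), ds$activityMap)))
  ws <- makeWindows(balanceClasses(feats, seed = 4), "6p")
  stat <- apply(abs(windowInputs(ws)[, , "dw_N"]), 1L, max)
  y <- windowLabels(ws)
  acc <- vapply(sort(stat), function(th) mean((stat >= th) == (y == 1L)),
                numeric(1))
  expect_gte(max(acc), 0.90)
})
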