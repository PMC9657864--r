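test_that("angleToOrigin matches arctan(y/x) and its worked values", {
  expect_equal(angleToOrigin(1.0, 1.0), pi / 4)
  expect_equal(angleToOrigin(1.0, 0.0), 0.0)
  # high-precision oracle value for atan(0.4 / 0.3)
  expect_equal(angleToOrigin(0.3, 0.4), 0.9272952180016122, tolerance = 1e-12)
  # vectorised over frames
  x <- c(0.2, 0.5, 1.2); y <- c(0.1, -0.4, 0.9)
  expect_equal(angleToOrigin(x, y), atan(y / x))
})

test_that("angleToOrigin guards the x -> 0 degeneracy with the limit value", {
  expect_warning(a <- angleToOrigin(0, 0.7), "limit")
  expect_equal(a, pi / 2)
  expect_warning(a2 <- angleToOrigin(1e-12, -0.7), "limit")
  expect_equal(a2, -pi / 2)
})

test_that("angularRate is the first difference quotient with dw[1] = 0", {
  expect_equal(angularRate(c(0.5, 0.6), c(0.00, 0.05)), c(0, 2.0))
  expect_equal(angularRate(rep(0.3, 7), seq(0, 0.3, by = 0.05)), rep(0, 7))
  expect_equal(angularRate(0.9, 0.0), 0)  # single frame: convention

  # brute-force per-pair loop oracle on a random series
  set.seed(1)
  a <- rnorm(10); tt <- cumsum(runif(10, 0.03, 0.08))
  expected <- numeric(10)
  for (k in 2:10) expected[k] <- (a[k] - a[k - 1]) / (tt[k] - tt[k - 1])
  expect_equal(angularRate(a, tt), expected, tolerance = 1e-15)

  expect_error(angularRate(c(1, 2), c(0.1, 0.1)), "strictly increasing")
  expect_error(angularRate(c(1, 2), 0.1), "equal length")
})

test_that("noseHipRatio reflects posture: < 1 upright, > 1 head below hip", {
  expect_equal(noseHipRatio(0.5, 0.5), 1.0)
  expect_equal(noseHipRatio(0.8, 0.4), 2.0)
  expect_equal(noseHipRatio(0.2, 0.5), 0.4)  # standing: nose above hip
  expect_warning(r <- noseHipRatio(0.3, 0), "NA")
  expect_true(is.na(r))
})

test_that("standing frames from the simulator keep R below 1", {
  f <- computeFeatures(applyFrameFilters(noiselessTrial("stand")))
  expect_true(all(f$R < 1))
})

test_that("computeFeatures reproduces a step-by-step hand computation", {
  fr <- makeFrames(3, t = c(0, 0.05, 0.11))
  fr$N_x <- c(0.40, 0.42, 0.45); fr$N_y <- c(0.20, 0.23, 0.30)
  fr$LSh_x <- c(0.41, 0.42, 0.44); fr$LSh_y <- c(0.33, 0.35, 0.40)
  fr$LH_x <- c(0.44, 0.44, 0.45); fr$LH_y <- c(0.62, 0.62, 0.63)
  out <- computeFeatures(KeypointSequence(fr, "S01", "T001", 18),
                         c("7" = "not_fall"))
  # manual application of the three defining formulas, frame by frame
  aN <- c(atan(0.20 / 0.40), atan(0.23 / 0.42), atan(0.30 / 0.45))
  aLSh <- c(atan(0.33 / 0.41), atan(0.35 / 0.42), atan(0.40 / 0.44))
  aLH <- c(atan(0.62 / 0.44), atan(0.62 / 0.44), atan(0.63 / 0.45))
  expect_equal(out$A_N, aN)
  expect_equal(out$dw_N, c(0, (aN[2] - aN[1]) / 0.05, (aN[3] - aN[2]) / 0.06))
  expect_equal(out$dw_LSh,
               c(0, (aLSh[2] - aLSh[1]) / 0.05, (aLSh[3] - aLSh[2]) / 0.06))
  expect_equal(out$dw_LH,
               c(0, (aLH[2] - aLH[1]) / 0.05, (aLH[3] - aLH[2]) / 0.06))
  expect_equal(out$R, c(0.20 / 0.62, 0.23 / 0.62, 0.30 / 0.63))
  expect_equal(out$label, rep("not_fall", 3))
})

test_that("computeFeatures conventions: row counts, first frame, determinism", {
  s1 <- makeSeq(1)
  one <- computeFeatures(s1)
  expect_equal(nrow(one), 1L)
  expect_equal(unlist(one[c("dw_N", "dw_LSh", "dw_LH")], use.names = FALSE),
               c(0, 0, 0))

  s <- makeSeq(12)
  expect_equal(nrow(computeFeatures(s)), 12L)
  expect_identical(computeFeatures(s), computeFeatures(s))

  empty <- KeypointSequence(makeFrames(0), "S01", "T0")
  expect_equal(nrow(computeFeatures(empty)), 0L)

  expect_error(computeFeatures(s, c("1" = "fall")), "not in activity map")
})

test_that("feature selection yields the fixed column sets in order", {
  set.seed(3)
  rows <- makeFeatureTable(c(20, 20), c("fall", "not_fall"))
  m4 <- selectFeatures(rows, "4p")
  m5 <- selectFeatures(rows, "5p")
  m6 <- selectFeatures(rows, featureSetSpec("6p"))
  expect_equal(colnames(m4), c("N_x", "N_y", "dw_N", "R"))
  expect_equal(ncol(m4), 4L)
  expect_equal(ncol(m5), 5L)
  expect_equal(ncol(m6), 6L)
  # 5p equals 6p with the R column removed, order preserved
  expect_equal(m5, m6[, setdiff(colnames(m6), "R")])
  expect_error(featureSetSpec("7p"), "unknown feature set")
})

test_that("feature table CSV round-trips through write/read", {
  set.seed(4)
  f <- withr::local_tempfile(fileext = ".csv")
  rows <- makeFeatureTable(c(10, 10), c("fall", "not_fall"))
  writeFeatures(rows, f)
  back <- readFeatures(f)
  expect_equal(nrow(back), 20L)
  expect_equal(back$label, rows$label)
  expect_equal(back$dw_N, rows$dw_N, tolerance = 1e-8)
})
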