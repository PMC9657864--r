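test_that("balanceClasses down-samples the majority class to within one window", {
  set.seed(7)
  # 200 not-fall rows in 4 trials + 100 fall rows in 5 trials
  tab <- makeFeatureTable(c(rep(50, 4), rep(20, 5)),
                          c(rep("not_fall", 4), rep("fall", 5)))
  out <- balanceClasses(tab, seed = 1, windowLength = 18)
  nf <- sum(out$label == "not_fall")
  expect_equal(sum(out$label == "fall"), 100L)     # minority untouched
  expect_true(nf >= 100 - 18 && nf <= 100 + 18)
  expect_true(nf <= 200)                            # never synthesises rows
  # relative temporal order preserved within every trial
  for (tr in unique(out$trial_id)) {
    tt <- out$t[out$trial_id == tr]
    expect_true(all(diff(tt) > 0))
  }
})

test_that("balanceClasses is a seeded deterministic identity on balanced data", {
  set.seed(8)
  tab <- makeFeatureTable(c(36, 36), c("fall", "not_fall"))
  expect_identical(balanceClasses(tab, seed = 3), tab)  # already balanced

  tab2 <- makeFeatureTable(c(rep(40, 3), 40), c(rep("not_fall", 3), "fall"))
  expect_identical(balanceClasses(tab2, seed = 5), balanceClasses(tab2, seed = 5))

  oneClass <- makeFeatureTable(c(30, 30), c("fall", "fall"))
  expect_error(balanceClasses(oneClass, seed = 1), "absent")
})

test_that("windowing counts: 7614 rows form 423 windows of 18", {
  set.seed(9)
  tab <- makeFeatureTable(7614, "not_fall")
  ws <- makeWindows(tab, "6p", windowLength = 18)
  expect_equal(nWindows(ws), 423L)
  expect_equal(dim(windowInputs(ws)), c(423L, 18L, 6L))
})

test_that("windowing drops sub-window remainders per trial", {
  set.seed(10)
  expect_equal(nWindows(makeWindows(makeFeatureTable(17, "fall"), "4p")), 0L)
  ws <- makeWindows(makeFeatureTable(36, "fall"), "4p")
  expect_equal(nWindows(ws), 2L)
  expect_equal(ws@origin$start_index, c(1L, 19L))
  # two trials of 27 -> one window each, never spanning the boundary
  ws2 <- makeWindows(makeFeatureTable(c(27, 27), c("fall", "not_fall")), "4p")
  expect_equal(nWindows(ws2), 2L)
  expect_equal(ws2@origin$trial_id, c("T001", "T002"))
})

test_that("window labels follow the any-fall rule (majority available)", {
  set.seed(11)
  tab <- makeFeatureTable(36, "not_fall")
  tab$label[20] <- "fall"  # one fall frame inside window 2
  ws <- makeWindows(tab, "5p")
  expect_equal(windowLabels(ws), c(0L, 1L))
  wsMaj <- makeWindows(tab, "5p", labelRule = "majority")
  expect_equal(windowLabels(wsMaj), c(0L, 0L))
})

test_that("windowing then concatenating reproduces the retained rows in order", {
  set.seed(12)
  tab <- makeFeatureTable(c(40, 25), c("fall", "not_fall"))
  ws <- makeWindows(tab, "6p", windowLength = 18)
  flat <- do.call(rbind, lapply(seq_len(nWindows(ws)),
                                function(i) windowInputs(ws)[i, , ]))
  kept <- rbind(selectFeatures(tab, "6p")[1:36, ],    # trial 1: 2 windows
                selectFeatures(tab, "6p")[41:58, ])   # trial 2: 1 window
  dimnames(flat) <- NULL; dimnames(kept) <- NULL
  expect_equal(flat, kept)
})

test_that("temporal split reproduces the published pack counts", {
  set.seed(13)
  tab <- makeFeatureTable(7614, "not_fall")
  tab$label[1:3600] <- "fall"  # both classes present, label irrelevant here
  ws <- makeWindows(tab, "6p")
  sp <- splitWindows(ws, trainFraction = 327 / 423)
  expect_equal(nWindows(sp$train) + nWindows(sp$validation), 327L)
  expect_equal(nWindows(sp$test), 96L)
})

test_that("split rounding, partition and order properties hold", {
  set.seed(14)
  tab <- makeFeatureTable(18 * 10, "not_fall")
  ws <- makeWindows(tab, "4p")
  sp <- splitWindows(ws, 0.7, 0.2)
  expect_equal(vapply(sp, nWindows, integer(1)),
               c(train = 6L, validation = 1L, test = 3L))
  # partition: counts conserve and provenance rows are disjoint
  starts <- unlist(lapply(sp, function(w) w@origin$start_index),
                   use.names = FALSE)
  expect_equal(sort(starts), ws@origin$start_index)
  # unshuffled split is seed-independent and ordered: validation is the
  # 7th of the 10 windows (last fifth of the train+validation block)
  sp2 <- splitWindows(ws, 0.7, 0.2, seed = 999)
  expect_equal(sp$train@origin, sp2$train@origin)
  expect_equal(sp$validation@origin$start_index, 7L * 18L - 17L)

  expect_error(splitWindows(ws, 0.99, 0.0001), "empty")
  expect_error(splitWindows(sp$validation, 0.7, 0.2), "at least 3")
})

test_that("model tensors stack windows in order with fall encoded 1", {
  set.seed(15)
  tab <- makeFeatureTable(c(18 * 3, 18 * 2), c("fall", "not_fall"))
  ws <- makeWindows(tab, "6p")
  tens <- toModelTensors(ws)
  expect_equal(dim(tens$inputs), c(5L, 18L, 6L))
  expect_equal(sum(tens$labels), 3L)
  expect_equal(tens$inputs[1, , ], windowInputs(ws)[1, , ])

  one <- toModelTensors(fallsafe:::.subsetWindows(ws, 2L))
  expect_equal(dim(one$inputs), c(1L, 18L, 6L))

  ws4 <- makeWindows(tab, "4p")
  expect_error(toModelTensors(list(ws, ws4)), "heterogeneous")
})
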