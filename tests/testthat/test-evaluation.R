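test_that("confusion matrix counts exactly", {
  cm <- confusionMatrix(c(1, 1, 2, 2), c(1, 2, 2, 2), k = 2)
  expect_equal(unname(cm), rbind(c(1L, 1L), c(0L, 2L)))
  perfect <- confusionMatrix(1:4, 1:4, k = 4)
  expect_equal(unname(perfect), diag(1L, 4))
  empty <- confusionMatrix(integer(0), integer(0), k = 3)
  expect_true(all(empty == 0L))
  expect_error(confusionMatrix(c(1, 5), c(1, 1), k = 4), "out of range")
  expect_error(confusionMatrix(1:3, 1:2, k = 3))
})

test_that("accuracy is the trace fraction", {
  cm <- confusionMatrix(c(1, 1, 2, 2), c(1, 2, 2, 2), k = 2)
  expect_equal(cmAccuracy(cm), 0.75)
  expect_equal(cmAccuracy(diag(5L, 3)), 1)
  expect_equal(cmAccuracy(rbind(c(0L, 3L), c(2L, 0L))), 0)
  expect_error(cmAccuracy(matrix(0L, 2, 2)), "empty")
})

test_that("recall handles the zero-diagonal and zero-row cases distinctly", {
  cm <- confusionMatrix(c(1, 1, 2, 2), c(1, 2, 2, 2), k = 2)
  expect_equal(cmRecall(cm, 1), 0.5)
  expect_equal(cmRecall(cm, 2), 1)
  expect_equal(unname(cmRecall(rbind(c(0L, 4L), c(0L, 4L)), 1)), 0)
  expect_error(cmRecall(rbind(c(2L, 0L), c(0L, 0L)), 2), "undefined-recall")
})

test_that("G-mean is the geometric mean of recalls", {
  expect_equal(gMean(diag(7L, 4)), 1)
  cm <- rbind(c(8L, 2L), c(5L, 5L))
  expect_equal(gMean(cm), sqrt(0.8 * 0.5), tolerance = 1e-9)
  expect_equal(round(gMean(cm), 5), 0.63246)
  zero <- rbind(c(0L, 4L), c(1L, 3L))
  expect_equal(gMean(zero), 0)
})

test_that("imbalance ratio reproduces the schedule arithmetic", {
  cond1 <- c(20000, 20000, 200, 200, 200, 20000, 20000, 200)
  expect_equal(imbalanceRatio(cond1), 100.0)
  expect_equal(imbalanceRatio(rep(20000, 8)), 1.0)
  cond9 <- c(20000, 20000, 12000, 12000, 12000, 20000, 20000, 12000)
  expect_equal(imbalanceRatio(cond9), 1.7)   # 1-decimal table rounding
  expect_equal(imbalanceRatio(cond9, digits = NULL), 5 / 3)
  expect_error(imbalanceRatio(c(1, 0)), "positive")
})

test_that("metric identities hold on random confusion matrices", {
  gen <- LCG(12)
  for (rep in 1:25) {
    k <- 2 + (rep %% 4)
    cm <- matrix(1L + floor(lcgNext(gen, k * k) * 20), k, k)
    r <- cmRecall(cm)
    # AM-GM and the recall envelope
    expect_lte(gMean(cm), mean(r) + 1e-12)
    expect_lte(min(r), gMean(cm) + 1e-12)
    expect_lte(gMean(cm), max(r) + 1e-12)
    # accuracy invariant under simultaneous class permutation
    p <- order(lcgNext(gen, k))
    expect_equal(cmAccuracy(cm[p, p]), cmAccuracy(cm))
  }
  # balanced test counts: accuracy equals mean recall
  cmb <- rbind(c(6L, 2L, 2L), c(1L, 8L, 1L), c(0L, 3L, 7L))
  expect_equal(cmAccuracy(cmb), mean(cmRecall(cmb)))
})
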