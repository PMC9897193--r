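test_that("stratified splitting hits the exact per-class counts deterministically", {
  labels <- rep(c("N", "D0.25", "D0.5"), each = 300)
  sp <- splitDataset(labels, c(0.8, 0.1, 0.1), seed = 1)
  for (cl in c("N", "D0.25", "D0.5")) {
    expect_equal(sum(labels[sp$train] == cl), 240)
    expect_equal(sum(labels[sp$validation] == cl), 30)
    expect_equal(sum(labels[sp$test] == cl), 30)
  }
  expect_equal(sort(c(sp$train, sp$validation, sp$test)), seq_along(labels))
  expect_identical(sp, splitDataset(labels, c(0.8, 0.1, 0.1), seed = 1))
  expect_false(identical(sp, splitDataset(labels, c(0.8, 0.1, 0.1), seed = 2)))
})

test_that("a class too small to populate all three sets is an error", {
  labels <- c(rep("N", 50), rep("D0.25", 50), rep("D0.5", 2))
  expect_error(splitDataset(labels, c(0.8, 0.1, 0.1), seed = 1), "insufficient-data")
})

test_that("confusion matrices count true-by-predicted and conserve the test size", {
  lev <- c("N", "D0.25", "D0.5")
  cm <- confusionMatrix(c("N", "N", "D0.25", "D0.5"),
                        c("N", "D0.25", "D0.25", "D0.5"), lev)
  expect_equal(unname(cm), rbind(c(1, 1, 0), c(0, 1, 0), c(0, 0, 1)), ignore_attr = TRUE)
  expect_equal(sum(cm), 4)
  expect_equal(sum(diag(cm)) / sum(cm), 0.75)
})

test_that("pairwise weak-vs-moderate accuracy restricts to the two selected classes", {
  cm <- rbind(c(9, 1, 0), c(0, 8, 2), c(0, 3, 7))
  expect_equal(pairwiseAccuracy(cm), 15 / 20)
  expect_equal(pairwiseAccuracy(diag(c(5, 5, 5))), 1)
})

test_that("zero learning rate freezes the loss", {
  d <- tinyPackedData(nTrain = 12, nVal = 6, nTest = 6)
  tc <- TrainConfig(batchSize = 12, learningRate = 0, maxEpochs = 4,
                    patience = 0, nRepeats = 1)
  fit <- trainModel(NetworkSpec(nFilters = 4, embeddingDim = 4, dropout = 0), tc, d)
  expect_equal(diff(range(fit$history$trainLoss)), 0, tolerance = 1e-12)
})

test_that("training is reproducible in deterministic mode", {
  d <- tinyPackedData(nTrain = 12, nVal = 6, nTest = 6)
  tc <- TrainConfig(batchSize = 6, learningRate = 1e-3, maxEpochs = 3,
                    patience = 0, nRepeats = 1)
  sp <- NetworkSpec(nFilters = 4, embeddingDim = 4)
  f1 <- trainModel(sp, tc, d, seed = 9)
  f2 <- trainModel(sp, tc, d, seed = 9)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model@params, f2$model@params)
})

test_that("the repeat protocol aggregates matrices, accuracy and a t-interval", {
  d <- tinyPackedData(nTrain = 24, nVal = 9, nTest = 12)
  tc <- TrainConfig(batchSize = 12, learningRate = 2e-3, maxEpochs = 4,
                    patience = 0, nRepeats = 3, baseSeed = 11)
  rep3 <- repeatProtocol(NetworkSpec(nFilters = 4, embeddingDim = 4), tc, d)
  expect_s4_class(rep3, "EvalReport")
  expect_length(rep3@matrices, 3)
  for (m in rep3@matrices) expect_equal(sum(m), 12)
  expect_equal(rowSums(rep3@normalized), rep(1, 3), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(rep3@meanAccuracy, mean(rep3@accuracies))
  expect_true(rep3@ci[1] <= rep3@meanAccuracy && rep3@meanAccuracy <= rep3@ci[2])
})

test_that("interval degenerates correctly at the edges", {
  cm <- diag(c(4L, 4L, 4L))
  r1 <- tempoSel:::.makeEvalReport("both", list(cm), 1.0)
  expect_true(anyNA(r1@ci))                      # single repeat: undefined
  r3 <- tempoSel:::.makeEvalReport("both", list(cm, cm, cm), c(0.8, 0.8, 0.8))
  expect_equal(r3@ci, c(0.8, 0.8))               # zero variance: width 0
})

test_that("the ablation comparison trains one report per mode on shared splits", {
  d <- tinyPackedData(nTrain = 24, nVal = 9, nTest = 12)
  tc <- TrainConfig(batchSize = 12, learningRate = 2e-3, maxEpochs = 3,
                    patience = 0, nRepeats = 1, baseSeed = 5)
  cmp <- ablationCompare(NetworkSpec(nFilters = 4, embeddingDim = 4), tc, d)
  expect_named(cmp$reports, c("both", "present_only", "ancient_only"))
  expect_equal(nrow(cmp$table), 3)
  expect_true(all(c("meanAccuracy", "pairwiseD") %in% names(cmp$table)))
})
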