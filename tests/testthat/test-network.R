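shapeSmall <- list(presentRows = 12, ancientRows = 4, nTimes = 2, width = 16)

test_that("the two-branch model emits normalized ternary probabilities", {
  d <- tinyPackedData()
  model <- buildNetwork(NetworkSpec(nFilters = 8, embeddingDim = 8), shapeSmall, seed = 1)
  p <- predictProb(model, d$test)
  expect_equal(dim(p), c(15, 3))
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(rowSums(p), rep(1, 15), tolerance = 1e-6)
  # S4 predict method routes to the same computation
  expect_identical(predict(model, d$test), p)
})

test_that("identical seeds build identical parameters, different seeds do not", {
  sp <- NetworkSpec(nFilters = 4, embeddingDim = 4)
  m1 <- buildNetwork(sp, shapeSmall, seed = 5)
  m2 <- buildNetwork(sp, shapeSmall, seed = 5)
  m3 <- buildNetwork(sp, shapeSmall, seed = 6)
  expect_identical(m1@params, m2@params)
  expect_false(identical(m1@params, m3@params))
})

test_that("an ancient-only model ignores the present-day matrix entirely", {
  d <- tinyPackedData()
  model <- buildNetwork(NetworkSpec(mode = "ancient_only", nFilters = 4,
                                    embeddingDim = 4), shapeSmall, seed = 2)
  p1 <- predictProb(model, d$test)
  alt <- d$test
  alt$present <- array(rbinom(length(alt$present), 1, 0.5), dim(alt$present))
  expect_identical(predictProb(model, alt), p1)
})

test_that("invalid modes are rejected", {
  expect_error(NetworkSpec(mode = "nonsense"), "mode")
})

test_that("end-to-end predictions are invariant to raw haplotype permutations", {
  set.seed(41)
  s <- randomSerialSample(nSites = 40)
  sh <- s
  sh@blocks <- lapply(s@blocks, function(m) m[sample(nrow(m)), , drop = FALSE])
  for (mode in c("both", "present_only", "ancient_only")) {
    model <- buildNetwork(NetworkSpec(mode = mode, nFilters = 4, embeddingDim = 4),
                          list(presentRows = 40, ancientRows = 10, nTimes = 4,
                               width = 16), seed = 3)
    expect_identical(predictProb(model, buildFeatureTensor(sh, 16)),
                     predictProb(model, buildFeatureTensor(s, 16)))
  }
})

test_that("zeroing the ancient embedding equals the head applied to (present, 0)", {
  d <- tinyPackedData()
  spec <- NetworkSpec(nFilters = 4, embeddingDim = 6)
  model <- buildNetwork(spec, shapeSmall, seed = 4)
  pSil <- predictProb(model, d$test, silence = "ancient")
  # independent route: present embedding computed alone, zeros for ancient
  embP <- tempoSel:::.branchForward(d$test$present, model@params, "p", spec)$emb
  logits <- model@params$hW %*% rbind(embP, matrix(0, 6, ncol(embP))) + model@params$hb
  expect_equal(pSil, t(tempoSel:::.softmax(logits)), tolerance = 1e-12)
  expect_error(predictProb(buildNetwork(NetworkSpec(mode = "present_only",
                                                    nFilters = 4, embeddingDim = 6),
                                        shapeSmall, seed = 4),
                           d$test, silence = "ancient"), "both")
})

test_that("the exchangeable variant predicts, is permutation-invariant and trains", {
  d <- tinyPackedData()
  spE <- NetworkSpec(nFilters = 4, embeddingDim = 4, variant = "exchangeable")
  model <- buildNetwork(spE, shapeSmall, seed = 7)
  p <- predictProb(model, d$test)
  expect_equal(dim(p), c(15, 3))
  expect_equal(rowSums(p), rep(1, 15), tolerance = 1e-6)

  set.seed(43)
  s <- randomSerialSample(nSites = 40)
  sh <- s
  sh@blocks <- lapply(s@blocks, function(m) m[sample(nrow(m)), , drop = FALSE])
  mSer <- buildNetwork(spE, list(presentRows = 40, ancientRows = 10, nTimes = 4,
                                 width = 16), seed = 8)
  expect_identical(predictProb(mSer, buildFeatureTensor(sh, 16)),
                   predictProb(mSer, buildFeatureTensor(s, 16)))

  dm <- tinyPackedData(nTrain = 20, nVal = 6, nTest = 6)
  tc <- TrainConfig(batchSize = 10, learningRate = 3e-3, maxEpochs = 40,
                    patience = 0, nRepeats = 1, baseSeed = 1)
  fit <- trainModel(NetworkSpec(nFilters = 8, embeddingDim = 8, dropout = 0,
                                variant = "exchangeable"), tc, dm, seed = 2)
  expect_gt(max(fit$history$trainAcc), 0.9)
  expect_error(NetworkSpec(variant = "nonsense"), "variant")
})

test_that("freshly initialized models predict near-uniform class frequencies", {
  d <- tinyPackedData(nTest = 30)
  sp <- NetworkSpec(nFilters = 4, embeddingDim = 4)
  nInit <- 120
  meanP <- matrix(0, nInit, 3)
  for (k in seq_len(nInit)) {
    m <- buildNetwork(sp, shapeSmall, seed = 100 + k)
    meanP[k, ] <- colMeans(predictProb(m, d$test))
  }
  # initialization is sign-symmetric, so over many seeds each class mean
  # should sit within a 3-standard-error Monte-Carlo band of 1/3
  for (cl in 1:3)
    expect_lt(abs(mean(meanP[, cl]) - 1 / 3),
              3 * sd(meanP[, cl]) / sqrt(nInit) + 1e-3)
})

test_that("the model can memorize a small labeled set (capacity check)", {
  d <- tinyPackedData(nTrain = 20, nVal = 6, nTest = 6)
  tc <- TrainConfig(batchSize = 10, learningRate = 3e-3, maxEpochs = 60,
                    patience = 0, nRepeats = 1, baseSeed = 1)
  spec <- NetworkSpec(nFilters = 8, embeddingDim = 8, dropout = 0)
  fit <- trainModel(spec, tc, d, seed = 2)
  expect_equal(max(fit$history$trainAcc), 1.0)
})
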