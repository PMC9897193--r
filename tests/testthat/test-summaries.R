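test_that("summaries are computed on the selected block only", {
  b0 <- matrix(c(0, 1, 1,
                 1, 0, 1), nrow = 2, byrow = TRUE)   # 2 haplotypes, 3 sites
  bAnc <- matrix(0, nrow = 2, ncol = 3)
  s <- makeSample(list(bAnc, b0), ages = c(1000, 0),
                  positions = c(100, 200, 300))
  atPresent <- computeSummaries(s, 0)
  expect_equal(atPresent$S, 2)          # third site is fixed derived in-block
  atAncient <- computeSummaries(s, 1000)
  expect_equal(atAncient$S, 0)
  expect_equal(atAncient$pi, 0)
})

test_that("two haplotypes differing at three sites have mean pairwise difference 3", {
  b <- rbind(c(0, 1, 0), c(1, 0, 1))
  s <- makeSample(list(b), ages = 0, positions = c(10, 20, 30))
  expect_equal(computeSummaries(s, 0)$pi, 3)
  expect_equal(computeSummaries(s, 0)$S, 3)
})

test_that("identical haplotypes give zero diversity and neutral samples no focal frequency", {
  b <- matrix(1, nrow = 5, ncol = 4)
  s <- makeSample(list(b), ages = 0, positions = c(1, 2, 3, 4))
  out <- computeSummaries(s, 0)
  expect_equal(out$S, 0)
  expect_equal(out$pi, 0)
  expect_true(is.na(out$focalFreq))
})

test_that("focal frequency is count over rows", {
  b <- matrix(0L, nrow = 40, ncol = 2)
  b[1:12, 2] <- 1L
  b[1, 1] <- 1L
  s <- makeSample(list(b), ages = 0, positions = c(100, 200), focal = 2L,
                  label = "D0.5")
  expect_equal(computeSummaries(s, 0)$focalFreq, 0.3)
})

test_that("an unknown age is a lookup error", {
  s <- makeSample(list(matrix(0L, 2, 1)), ages = 0, positions = 5)
  expect_error(computeSummaries(s, 123), "unknown age")
})
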