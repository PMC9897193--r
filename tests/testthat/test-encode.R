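test_that("frequency sorting groups rows and is canonical under permutation", {
  A <- c(1L, 0L, 1L)
  B <- c(0L, 1L, 0L)
  M <- rbind(B, A, A, A)
  expect_equal(unname(sortByFrequency(M)), rbind(A, A, A, B), ignore_attr = TRUE)

  same <- matrix(1L, 4, 3)
  expect_equal(sortByFrequency(same), same)

  set.seed(21)
  for (i in 1:20) {
    M <- matrix(rbinom(8 * 6, 1, 0.5), 8, 6)
    ref <- sortByFrequency(M)
    perm <- M[sample(nrow(M)), , drop = FALSE]
    expect_identical(sortByFrequency(perm), ref)
  }
})

test_that("tied haplotype groups are ordered by descending lexicographic bits", {
  M <- rbind(c(0L, 1L, 1L), c(1L, 0L, 1L))   # equal multiplicity
  out <- sortByFrequency(M)
  expect_equal(out[1, ], c(1L, 0L, 1L))      # "101" > "011"
})

test_that("windowing anchors the focal site and keeps flanking columns", {
  b <- matrix(rbinom(5 * 4, 1, 0.5), nrow = 4)
  s <- makeSample(list(b), ages = 0, positions = c(1, 2, 25, 48, 49) * 1000,
                  L = 50000, focal = 3L, label = "D0.5")
  w <- windowAndPad(s, 3)
  expect_equal(w@positions, c(2, 25, 48) * 1000)
  expect_equal(w@focalIndex, 2L)
  expect_equal(w@blocks[[1]], b[, 2:4])

  # n_sites == W is the identity
  expect_equal(windowAndPad(s, 5)@blocks[[1]], b)

  # neutral samples center on the locus midpoint
  sn <- makeSample(list(b), ages = 0, positions = c(1, 2, 25, 48, 49) * 1000,
                   L = 50000)
  expect_equal(windowAndPad(sn, 3)@positions, c(2, 25, 48) * 1000)
})

test_that("the anchor lands at the same column regardless of flank density", {
  # 1 site left of focal, 6 right; W = 6 (nL = 2, nR = 3): one left zero-pad
  b <- matrix(rbinom(8 * 5, 1, 0.5), nrow = 5)
  s <- makeSample(list(b), ages = 0,
                  positions = c(10000, 24000, 26000, 27000, 28000, 29000, 30000, 40000),
                  L = 50000, focal = 2L, label = "D0.25")
  w <- windowAndPad(s, 6)
  expect_equal(w@focalIndex, 3L)                  # (6-1) %/% 2 + 1
  expect_true(all(w@blocks[[1]][, 1] == 0))       # left pad
  expect_equal(w@blocks[[1]][, 2:6], b[, 1:5])
  # dense both sides: focal still at column 3
  s2 <- makeSample(list(b), ages = 0,
                   positions = c(21:28) * 1000, L = 50000, focal = 4L,
                   label = "D0.25")
  expect_equal(windowAndPad(s2, 6)@focalIndex, 3L)
})

test_that("padding is symmetric when fewer sites than the window exist", {
  b <- matrix(1L, nrow = 3, ncol = 2)
  s <- makeSample(list(b), ages = 0, positions = c(400, 600))
  w <- windowAndPad(s, 4)
  expect_equal(ncol(w@blocks[[1]]), 4)
  expect_equal(w@blocks[[1]][, 2:3], b)
  expect_true(all(w@blocks[[1]][, c(1, 4)] == 0))
})

test_that("feature tensors have the declared shapes for the serial design", {
  set.seed(31)
  s <- randomSerialSample(nSites = 150)
  ft <- buildFeatureTensor(s, 128)
  expect_equal(dim(ft@present), c(40, 128))
  expect_equal(dim(ft@ancient), c(4, 10, 128))
  expect_equal(ft@label, "N")
})

test_that("a sample with no segregating sites encodes to all-zero tensors", {
  blocks <- lapply(c(3, 6), function(n) matrix(integer(), n, 0))
  s <- makeSample(blocks, ages = c(1000, 0), positions = numeric())
  ft <- buildFeatureTensor(s, 8)
  expect_equal(dim(ft@present), c(6, 8))
  expect_true(all(ft@present == 0))
  expect_true(all(ft@ancient == 0))
})

test_that("encoding is invariant to haplotype order within every block", {
  set.seed(32)
  s <- randomSerialSample(nSites = 40)
  ref <- buildFeatureTensor(s, 32)
  sh <- s
  sh@blocks <- lapply(s@blocks, function(m) m[sample(nrow(m)), , drop = FALSE])
  expect_identical(buildFeatureTensor(sh, 32), ref)
})

test_that("shape errors are reported for malformed samples", {
  s <- randomSerialSample(nSites = 10)
  bad <- s
  bad@blocks[[2]] <- bad@blocks[[2]][1:5, , drop = FALSE]  # unequal ancient rows
  expect_error(buildFeatureTensor(bad, 8), "equal row counts")
  noPresent <- makeSample(list(matrix(0L, 3, 1)), ages = 1000, positions = 5)
  expect_error(buildFeatureTensor(noPresent, 8), "age-0")
})

test_that("ms round trip reproduces the identical feature tensor", {
  cfg <- neutralConfig(N = 80, burnin = 5)
  set.seed(33)
  samples <- lapply(1:3, function(i) simulateLocus(cfg))
  path <- tempfile(fileext = ".ms")
  writeMsLike(samples, path)
  back <- readMsLike(path)
  for (i in seq_along(samples))
    expect_identical(buildFeatureTensor(back[[i]], 16),
                     buildFeatureTensor(samples[[i]], 16))
})
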