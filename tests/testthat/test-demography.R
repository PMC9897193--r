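test_that("rescaling is the identity at lambda 1 and follows the scaling rules", {
  dem <- DemographicModel(data.frame(start = 400, size = 10000), generationTime = 25)
  cfg <- SimConfig(locusLength = 50e3, mu = 1.25e-8, rho = 1.25e-8, demography = dem,
                   selection = SelectionModel(0.005, 10000, 25000),
                   samplingScheme = data.frame(age = c(1000, 0), n = c(10, 40)))
  expect_identical(rescaleParameters(cfg, 1), cfg)

  r <- rescaleParameters(cfg, 10)
  expect_equal(r@demography@epochs$size, 1000)
  expect_equal(r@demography@epochs$start, 40)
  expect_equal(r@selection@s, 0.05)
  expect_equal(r@mu, 1.25e-7)
  expect_equal(r@rho, 1.25e-7)
  # onset of 10k years maps to 400 generations unscaled, 40 scaled
  expect_equal(r@selection@onsetTime / r@demography@generationTime, 40)
  # compound parameters preserved
  expect_equal(r@demography@epochs$size * r@selection@s,
               cfg@demography@epochs$size * cfg@selection@s)
  expect_equal(r@demography@epochs$size * r@mu * r@locusLength,
               cfg@demography@epochs$size * cfg@mu * cfg@locusLength)
})

test_that("rescaling rejects invalid fitness and over-rescaled sizes", {
  dem <- DemographicModel(data.frame(start = 400, size = 10000))
  strong <- SimConfig(50e3, 1.25e-8, 1.25e-8, dem,
                      selection = SelectionModel(0.5, 10000, 25000),
                      samplingScheme = data.frame(age = 0, n = 40))
  expect_error(rescaleParameters(strong, 10), "invalid-fitness")
  small <- SimConfig(50e3, 1.25e-8, 1.25e-8,
                     DemographicModel(data.frame(start = 400, size = 10)),
                     samplingScheme = data.frame(age = 0, n = 4))
  expect_error(rescaleParameters(small, 10), "over-rescaled")
  # s*lambda >= 1 is also rejected at construction time via rescaleFactor
  expect_error(SimConfig(50e3, 1.25e-8, 1.25e-8, dem,
                         selection = SelectionModel(0.5, 10000, 25000),
                         samplingScheme = data.frame(age = 0, n = 40),
                         rescaleFactor = 2))
})

test_that("deterministic overdominance update matches an independent mean-fitness computation", {
  # independent oracle: full genotype bookkeeping under fitnesses 1 : 1+s : 1
  oracle <- function(p, s) {
    q <- 1 - p
    w <- c(AA = 1 + s * 0, Aa = 1 + s, aa = 1)  # derived hom, het, ancestral hom
    freq <- c(p^2, 2 * p * q, q^2)
    wbar <- sum(freq * c(1, 1 + s, 1))
    (p^2 * 1 + p * q * (1 + s)) / wbar
  }
  for (p in c(0.05, 0.1, 0.3, 0.7, 0.9)) for (s in c(0, 0.1, 0.5))
    expect_equal(deterministicUpdate(p, s), oracle(p, s), tolerance = 1e-12)
  expect_equal(deterministicUpdate(0.1, 0.5), 0.13303, tolerance = 1e-4)
})

test_that("deterministic update has fixed points at 0, 1/2 and 1 and checks its domain", {
  for (s in c(0, 0.01, 0.3, 0.9)) {
    expect_equal(deterministicUpdate(0.5, s), 0.5)
    expect_equal(deterministicUpdate(0, s), 0)
    expect_equal(deterministicUpdate(1, s), 1)
  }
  # symmetric equilibrium attracts from both sides
  expect_gt(deterministicUpdate(0.2, 0.3), 0.2)
  expect_lt(deterministicUpdate(0.8, 0.3), 0.8)
  expect_error(deterministicUpdate(-0.1, 0.1), "domain")
  expect_error(deterministicUpdate(0.5, 1), "domain")
})

test_that("demographic model validity enforces epoch ordering and sizes", {
  expect_error(DemographicModel(data.frame(start = c(100, 200), size = c(50, 50))),
               "decreasing")
  expect_error(DemographicModel(data.frame(start = 100, size = 1)), ">= 2")
  expect_error(DemographicModel(data.frame(start = 100, size = 100),
                                generationTime = -1), "positive")
})
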