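# Small builders shared across test files. Everything is generated in code;
# sizes are kept tiny so the whole suite runs on one CPU in minutes.

# A hand-built TemporalSample (blocks oldest first, present last).
makeSample <- function(blocks, ages, positions, L = 1000, focal = NA_integer_,
                       label = "N") {
  blocks <- lapply(blocks, function(m) { storage.mode(m) <- "integer"; m })
  new("TemporalSample", ages = ages, blocks = blocks, positions = positions,
      locusLength = L, focalIndex = as.integer(focal), label = label,
      provenance = list(seed = NA_integer_, attempts = 1L))
}

# Random sample with the full serial scheme (10,10,10,10,40).
randomSerialSample <- function(nSites = 30, label = "N", L = 10000) {
  pos <- sort(runif(nSites)) * L
  blocks <- lapply(c(10, 10, 10, 10, 40), function(n)
    matrix(rbinom(n * nSites, 1, 0.4), nrow = n))
  makeSample(blocks, ages = c(8000, 4000, 2000, 1000, 0), positions = pos,
             L = L, label = label)
}

# Constant-size neutral configuration for simulator checks.
neutralConfig <- function(N = 200, L = 10000, mu = 5e-7, rho = 5e-7,
                          ages = c(250, 0), ns = c(10, 40), burnin = 10) {
  SimConfig(locusLength = L, mu = mu, rho = rho,
            demography = DemographicModel(data.frame(start = 10, size = N)),
            samplingScheme = data.frame(age = ages, n = ns),
            burninFactor = burnin)
}

# Tiny encoded dataset with a planted linear signal, for fast training tests.
tinyPackedData <- function(nTrain = 30, nVal = 9, nTest = 15, W = 16, seed = 99) {
  set.seed(seed)
  mk <- function(n) {
    y <- rep(1:3, length.out = n)
    present <- array(0, c(12, W, 1, n))
    ancient <- array(0, c(4, W, 2, n))
    for (i in seq_len(n)) {
      p <- c(0.15, 0.5, 0.85)[y[i]]
      present[, , 1, i] <- rbinom(12 * W, 1, p)
      ancient[, , , i] <- rbinom(4 * W * 2, 1, p)
    }
    list(present = present, ancient = ancient, y = y,
         levels = c("N", "D0.25", "D0.5"))
  }
  list(train = mk(nTrain), validation = mk(nVal), test = mk(nTest))
}
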