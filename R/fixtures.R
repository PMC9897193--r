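# Random TemporalSample with the desk sampling scheme; columnFreqs gives the
# expected derived-allele frequency of each column (all blocks share them).
.randomSample <- function(label, nSites, columnFreqs, L = 10000,
                          ages = c(4000, 3000, 2000, 1000, 0),
                          ns = c(10, 10, 10, 10, 40)) {
  pos <- sort(sample.int(L * 10, nSites)) / 10
  blocks <- lapply(ns, function(n) {
    m <- matrix(rbinom(n * nSites, 1, rep(columnFreqs, each = n)), nrow = n)
    storage.mode(m) <- "integer"
    m
  })
  new("TemporalSample", ages = ages, blocks = blocks, positions = pos,
      locusLength = L, focalIndex = NA_integer_, label = label,
      provenance = list(seed = NA_integer_, attempts = 1L))
}

#' Generate an on-disk test dataset
#'
#' Three kinds: \code{"separable"} plants trivially distinguishable
#' haplotype-frequency structure per class (class-specific column
#' frequencies, so even a linear classifier on column means separates
#' them); \code{"null"} draws the three classes from one identical
#' distribution (no signal, for calibration checks); \code{"tiny"} is six
#' samples, two per class, for format tests. Deterministic given the seed.
#'
#' @param kind one of \code{"separable"}, \code{"null"}, \code{"tiny"}.
#' @param seed RNG seed.
#' @param dir output directory (created if needed).
#' @param nPerClass samples per class (ignored for \code{"tiny"}; defaults
#'   100 for \code{"separable"}, 200 for \code{"null"}).
#' @return List with \code{ms} and \code{meta} paths and (invisibly read
#'   back) \code{samples}.
#' @export
makeFixture <- function(kind = c("separable", "null", "tiny"), seed = 1, dir,
                        nPerClass = NULL) {
  kind <- match.arg(kind)
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- c("N", "D0.25", "D0.5")
  nSites <- 40
  samples <- switch(kind,
    tiny = {
      unlist(lapply(labels, function(l) lapply(1:2, function(i)
        .randomSample(l, 8, rep(0.3, 8), L = 1000,
                      ages = c(2000, 1000, 0), ns = c(3, 3, 6)))),
        recursive = FALSE)
    },
    null = {
      n <- if (is.null(nPerClass)) 200 else nPerClass
      out <- vector("list", 3 * n)
      for (i in seq_len(3 * n)) {
        f <- rbeta(nSites, 0.7, 0.7)  # same frequency law for every class
        out[[i]] <- .randomSample(labels[(i - 1) %% 3 + 1], nSites, f)
      }
      out
    },
    separable = {
      n <- if (is.null(nPerClass)) 100 else nPerClass
      base <- c(N = 0.15, `D0.25` = 0.5, `D0.5` = 0.85)
      out <- vector("list", 3 * n)
      for (i in seq_len(3 * n)) {
        l <- labels[(i - 1) %% 3 + 1]
        f <- pmin(0.95, pmax(0.05, rnorm(nSites, base[[l]], 0.05)))
        out[[i]] <- .randomSample(l, nSites, f)
      }
      out
    })
  ms <- file.path(dir, paste0("fixture-", kind, ".ms"))
  writeMsLike(samples, ms)
  structure(list(ms = ms, meta = paste0(ms, ".meta.tsv"), samples = samples),
            class = "temposelFixture")
}
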