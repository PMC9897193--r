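#' Canonical frequency sort of a haplotype matrix
#'
#' Groups identical rows, orders groups by descending multiplicity and
#' breaks ties between equally frequent distinct haplotypes by descending
#' lexicographic order of the row bits. The result is a canonical form:
#' any row permutation of the input yields the same output.
#'
#' @param M binary haplotype matrix (rows = haplotypes).
#' @return The row-sorted matrix.
#' @examples
#' M <- rbind(c(0, 1), c(1, 0), c(1, 0))
#' sortByFrequency(M)  # the two (1,0) rows first
#' @export
sortByFrequency <- function(M) {
  stopifnot(is.matrix(M), nrow(M) >= 1)
  if (ncol(M) == 0) return(M)
  key <- apply(M, 1, paste, collapse = "")
  cnt <- table(key)
  freq <- as.vector(cnt[key])
  ord <- order(-freq, key, method = "radix", decreasing = c(FALSE, TRUE))
  M[ord, , drop = FALSE]
}

#' Window a temporal sample to a fixed number of SNP columns
#'
#' Anchors the window on the focal site (for neutral samples: the
#' segregating site nearest the locus center, ties toward the left) and
#' keeps the \code{(W-1) \%/\% 2} nearest sites to its left and the
#' remaining \code{W - 1 - (W-1) \%/\% 2} nearest to its right, so the
#' anchor always occupies the same column, \code{(W-1) \%/\% 2 + 1}. A
#' classifier therefore never has to localize the candidate site within the
#' window. Sides with too few sites are padded with zero-columns; a sample
#' with no segregating sites encodes to all-zero columns. Column selection
#' is identical across all blocks, and uses only the positions (never the
#' label), so the rule is the same for neutral and selected samples.
#'
#' @param sample a \code{\linkS4class{TemporalSample}}.
#' @param W window width (columns).
#' @return A \code{\linkS4class{TemporalSample}} with exactly \code{W} columns.
#' @export
windowAndPad <- function(sample, W) {
  stopifnot(is(sample, "TemporalSample"), W >= 1)
  S <- length(sample@positions)
  nL <- (W - 1L) %/% 2L          # columns left of the anchor
  nR <- W - 1L - nL              # columns right of the anchor
  if (S == 0) {
    a <- 0L
    keep <- integer()
    padL <- nL; padR <- nR + 1L  # no anchor column either
  } else {
    a <- if (!is.na(sample@focalIndex)) sample@focalIndex
         else order(abs(sample@positions - sample@locusLength / 2),
                    sample@positions)[1]
    lo <- max(1L, a - nL)
    hi <- min(S, a + nR)
    keep <- lo:hi
    padL <- nL - (a - lo)
    padR <- nR - (hi - a)
  }
  blocks <- lapply(sample@blocks, function(m) {
    cbind(matrix(0L, nrow(m), padL), m[, keep, drop = FALSE],
          matrix(0L, nrow(m), padR))
  })
  kpos <- sample@positions[keep]
  lo <- if (length(keep)) min(kpos) else sample@locusLength
  hi <- if (length(keep)) max(kpos) else 0
  posL <- if (padL > 0) seq(min(0, lo), lo, length.out = padL + 2)[seq_len(padL) + 1] else numeric()
  posR <- if (padR > 0) {
    seq(hi, max(hi, sample@locusLength), length.out = padR + 2)[seq_len(padR) + 1]
  } else numeric()
  pos <- c(posL, kpos, posR)
  if (hi < lo) pos <- sort(pos)  # S == 0: spread pads over the locus
  focal <- if (is.na(sample@focalIndex) || S == 0) NA_integer_ else nL + 1L
  # guard against degenerate equal positions from padding
  if (length(pos) > 1)
    for (i in 2:length(pos)) if (pos[i] <= pos[i - 1]) pos[i] <- pos[i - 1] + 1e-9
  new("TemporalSample", ages = sample@ages, blocks = blocks, positions = pos,
      locusLength = sample@locusLength, focalIndex = as.integer(focal),
      label = sample@label, provenance = sample@provenance)
}

#' Encode a temporal sample as fixed-shape network input
#'
#' Windows the sample to width \code{W}, sorts every block by haplotype
#' frequency (canonical, permutation-invariant) and assembles the
#' present-day matrix plus the stacked ancient tensor (time points as
#' channels, oldest first).
#'
#' @param sample a \code{\linkS4class{TemporalSample}} with exactly one
#'   age-0 block; all ancient blocks must have equal row counts.
#' @param W window width.
#' @return A \code{\linkS4class{FeatureTensor}}.
#' @export
buildFeatureTensor <- function(sample, W) {
  stopifnot(is(sample, "TemporalSample"))
  if (sum(sample@ages == 0) != 1) stop("missing-block: sample needs exactly one age-0 block")
  w <- windowAndPad(sample, W)
  presentIdx <- which(w@ages == 0)
  ancientIdx <- which(w@ages > 0)
  nAnc <- vapply(w@blocks[ancientIdx], nrow, integer(1))
  if (length(unique(nAnc)) > 1)
    stop("shape error: ancient blocks must have equal row counts")
  present <- sortByFrequency(w@blocks[[presentIdx]])
  storage.mode(present) <- "integer"
  Tn <- length(ancientIdx)
  na <- if (Tn > 0) nAnc[1] else 0L
  ancient <- array(0L, dim = c(Tn, na, W))
  if (Tn > 0) for (t in seq_len(Tn))
    ancient[t, , ] <- sortByFrequency(w@blocks[[ancientIdx[t]]])
  new("FeatureTensor", present = present, ancient = ancient,
      label = sample@label, focalColumn = w@focalIndex)
}

#' Encode a list of temporal samples
#'
#' @param samples list of \code{\linkS4class{TemporalSample}} objects.
#' @param W window width.
#' @return List of \code{\linkS4class{FeatureTensor}} objects.
#' @export
encodeDataset <- function(samples, W) lapply(samples, buildFeatureTensor, W = W)

#' Class label ordering used throughout
#'
#' Neutral first, then selected classes by increasing coefficient.
#' @param labels character vector of labels.
#' @export
labelLevels <- function(labels) {
  u <- unique(labels)
  d <- sort(as.numeric(sub("^D", "", u[u != "N"])))
  c(if ("N" %in% u) "N", if (length(d)) paste0("D", d))
}

#' Pack feature tensors into batched arrays for training
#'
#' @param tensors list of \code{\linkS4class{FeatureTensor}} objects with
#'   identical shapes.
#' @param levels label levels (default: \code{\link{labelLevels}} of the data).
#' @return List with \code{present} (H, W, 1, B), \code{ancient}
#'   (Ha, W, T, B), \code{y} (integer classes) and \code{levels}.
#' @export
packTensors <- function(tensors, levels = NULL) {
  stopifnot(length(tensors) > 0)
  lab <- vapply(tensors, function(t) t@label, character(1))
  if (is.null(levels)) levels <- labelLevels(lab)
  B <- length(tensors)
  Hp <- nrow(tensors[[1]]@present); W <- ncol(tensors[[1]]@present)
  da <- dim(tensors[[1]]@ancient)  # (T, Ha, W)
  present <- array(0, dim = c(Hp, W, 1, B))
  ancient <- array(0, dim = c(max(da[2], 1), W, max(da[1], 1), B))
  for (b in seq_len(B)) {
    present[, , 1, b] <- tensors[[b]]@present
    if (da[1] > 0) ancient[, , , b] <- aperm(tensors[[b]]@ancient, c(2, 3, 1))
  }
  y <- match(lab, levels)
  if (anyNA(y)) stop("label not in levels: ", paste(setdiff(lab, levels), collapse = ", "))
  list(present = present, ancient = ancient, y = y, levels = levels)
}
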