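#' Diversity summaries for one sampling block
#'
#' Computes, on the block sampled at \code{age} only: the number of
#' segregating sites S (columns polymorphic within the block), the mean
#' pairwise difference pi, and the focal-allele sample frequency (NA for
#' neutral samples).
#'
#' @param sample a \code{\linkS4class{TemporalSample}}.
#' @param age a sampling age present in the sample (years before present).
#' @return Named list with \code{S}, \code{pi} and \code{focalFreq}.
#' @examples
#' \dontrun{computeSummaries(x, age = 0)}
#' @export
computeSummaries <- function(sample, age) {
  stopifnot(is(sample, "TemporalSample"))
  i <- match(age, sample@ages)
  if (is.na(i)) stop("unknown age: ", age, " (available: ",
                     paste(sample@ages, collapse = ", "), ")")
  m <- sample@blocks[[i]]
  n <- nrow(m)
  cnt <- colSums(m)
  seg <- cnt > 0 & cnt < n
  S <- sum(seg)
  # mean pairwise difference: sum over sites of 2*k*(n-k) / (n*(n-1))
  pi <- if (n < 2) 0 else sum(2 * cnt[seg] * (n - cnt[seg])) / (n * (n - 1))
  ff <- if (is.na(sample@focalIndex)) NA_real_ else cnt[sample@focalIndex] / n
  list(S = S, pi = pi, focalFreq = ff)
}
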