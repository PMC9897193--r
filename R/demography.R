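#' Construct a demographic model
#'
#' @param epochs data.frame with columns \code{start} (generations before
#'   present, strictly decreasing, oldest first), \code{size} (diploid) and
#'   optionally \code{growth} (per-generation exponential rate, default 0).
#' @param generationTime years per generation (default 25).
#' @return A \code{\linkS4class{DemographicModel}}.
#' @examples
#' DemographicModel(data.frame(start = c(2000, 400), size = c(10000, 5000)))
#' @export
DemographicModel <- function(epochs, generationTime = 25) {
  if (is.null(epochs$growth)) epochs$growth <- 0
  epochs <- epochs[, c("start", "size", "growth")]
  new("DemographicModel", epochs = epochs, generationTime = generationTime)
}

#' Construct an overdominant selection model
#'
#' Fitness scheme is fixed at 1 : 1+s : 1 (symmetric heterozygote advantage).
#'
#' @param s heterozygote selection coefficient, 0 <= s < 1.
#' @param onsetTime years before present at which the de novo mutation arises.
#' @param focalPosition bp offset of the selected site within the locus.
#' @export
SelectionModel <- function(s, onsetTime, focalPosition) {
  new("SelectionModel", s = s, onsetTime = onsetTime, focalPosition = focalPosition)
}

#' Construct a simulation configuration
#'
#' @param locusLength locus length in bp.
#' @param mu,rho per-bp per-generation mutation and crossover rates.
#' @param demography a \code{\linkS4class{DemographicModel}}.
#' @param selection a \code{\linkS4class{SelectionModel}} or \code{NULL} for
#'   the neutral class.
#' @param samplingScheme data.frame with columns \code{age} (years) and
#'   \code{n} (haplotypes); must include age 0.
#' @param rescaleFactor rescaling factor lambda >= 1.
#' @param burninFactor burn-in length in units of the ancestral diploid size.
#' @param maxConditionAttempts retry cap for conditioning on segregation.
#' @export
SimConfig <- function(locusLength, mu, rho, demography, selection = NULL,
                      samplingScheme, rescaleFactor = 1, burninFactor = 10,
                      maxConditionAttempts = 100) {
  samplingScheme <- samplingScheme[order(-samplingScheme$age), , drop = FALSE]
  new("SimConfig", locusLength = locusLength, mu = mu, rho = rho,
      demography = demography, selection = selection,
      samplingScheme = samplingScheme, rescaleFactor = rescaleFactor,
      burninFactor = burninFactor, maxConditionAttempts = maxConditionAttempts)
}

#' Rescale a simulation configuration
#'
#' Standard population-genetic rescaling by a factor \code{lam}: population
#' sizes are divided by \code{lam}, the selection coefficient, mutation,
#' recombination and growth rates are multiplied by \code{lam}, and all times
#' measured in generations are divided by \code{lam} (epoch boundaries are
#' divided directly; times stored in years are handled by multiplying
#' \code{generationTime} by \code{lam}, so the same calendar age maps to a
#' \code{lam}-fold smaller number of generations). The compound parameters
#' N*s, N*mu*L, N*rho*L and times in units of N generations are preserved.
#'
#' @param cfg a \code{\linkS4class{SimConfig}}.
#' @param lam rescaling factor, >= 1.
#' @return A rescaled \code{\linkS4class{SimConfig}} with
#'   \code{rescaleFactor} reset to 1 (the factor is folded in).
#' @examples
#' dem <- DemographicModel(data.frame(start = 400, size = 10000))
#' cfg <- SimConfig(50e3, 1.25e-8, 1.25e-8, dem,
#'                  samplingScheme = data.frame(age = 0, n = 40))
#' rescaleParameters(cfg, 10)
#' @export
rescaleParameters <- function(cfg, lam) {
  stopifnot(is(cfg, "SimConfig"), lam >= 1)
  if (lam == 1) return(cfg)
  sel <- cfg@selection
  if (!is.null(sel)) {
    if (sel@s * lam >= 1)
      stop("invalid-fitness: rescaled selection coefficient s*lam = ",
           sel@s * lam, " >= 1")
    sel <- SelectionModel(sel@s * lam, sel@onsetTime, sel@focalPosition)
  }
  e <- cfg@demography@epochs
  e$size <- round(e$size / lam)
  if (any(e$size < 2))
    stop("over-rescaled: an epoch size fell below 2 diploids after rescaling")
  e$start <- pmax(1, round(e$start / lam))
  if (any(diff(e$start) >= 0))
    stop("over-rescaled: epoch boundaries collide after rescaling")
  e$growth <- e$growth * lam
  dem <- DemographicModel(e, generationTime = cfg@demography@generationTime * lam)
  SimConfig(cfg@locusLength, cfg@mu * lam, cfg@rho * lam, dem, sel,
            cfg@samplingScheme, rescaleFactor = 1,
            burninFactor = cfg@burninFactor,
            maxConditionAttempts = cfg@maxConditionAttempts)
}

#' Expected next-generation frequency under symmetric overdominance
#'
#' Deterministic (infinite-population) update of the derived-allele frequency
#' under genotype fitnesses 1 : 1+s : 1:
#' \deqn{p' = \frac{p^2 + p(1-p)(1+s)}{1 + 2p(1-p)s}}
#' Fixed points are p = 0, 1 (absorbing) and p = 0.5 (the symmetric
#' polymorphic equilibrium).
#'
#' @param p derived-allele frequency in [0, 1].
#' @param s heterozygote selection coefficient in [0, 1).
#' @return The expected frequency in the next generation.
#' @examples
#' deterministicUpdate(0.1, 0.5)   # approx 0.13303
#' deterministicUpdate(0.5, 0.3)   # 0.5, equilibrium
#' @export
deterministicUpdate <- function(p, s) {
  if (any(p < 0 | p > 1)) stop("domain error: p must lie in [0, 1]")
  if (any(s < 0 | s >= 1)) stop("domain error: s must lie in [0, 1)")
  (p^2 + p * (1 - p) * (1 + s)) / (1 + 2 * p * (1 - p) * s)
}

# Diploid size at each generation before present, index [genBP + 1].
# Includes the neutral burn-in at the ancestral size before the first epoch.
# Returns list(sizes, totalGens): sizes[1] = present, sizes[totalGens] = oldest.
.popSizeVector <- function(dem, burninFactor, minSpanGens) {
  e <- dem@epochs
  oldest <- max(e$start[1], minSpanGens)
  burnin <- round(burninFactor * e$size[1])
  total <- oldest + burnin
  genBP <- 0:(total - 1)
  sizes <- numeric(total)
  for (i in seq_len(nrow(e))) {
    lo <- if (i == nrow(e)) -1 else e$start[i + 1]   # epoch covers (lo, start]
    sel <- genBP <= e$start[i] & genBP > lo
    sizes[sel] <- e$size[i] * exp(e$growth[i] * (e$start[i] - genBP[sel]))
  }
  sizes[genBP > e$start[1]] <- e$size[1]
  list(sizes = pmax(2L, as.integer(round(sizes))), totalGens = total)
}
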