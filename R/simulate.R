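#' Forward-simulate one locus with serial sampling
#'
#' Runs the diploid Wright-Fisher engine under the configuration: a neutral
#' burn-in of \code{burninFactor * ancestralSize} generations at the
#' ancestral size, the demographic epochs, an optional overdominant de novo
#' mutation injected on one random haplotype at the onset generation, and
#' haplotype sampling (without replacement, non-destructive) at each
#' requested age. For selected classes the run is conditioned on the focal
#' allele segregating (population frequency strictly in (0, 1)) at present;
#' failed runs restart with a fresh random stream up to
#' \code{maxConditionAttempts}.
#'
#' The configuration's \code{rescaleFactor} is applied internally via
#' \code{\link{rescaleParameters}} before simulation.
#'
#' @param cfg a \code{\linkS4class{SimConfig}}.
#' @param seed optional integer seed (calls \code{set.seed}).
#' @return A \code{\linkS4class{TemporalSample}} with blocks ordered oldest
#'   first, present last.
#' @export
simulateLocus <- function(cfg, seed = NULL) {
  stopifnot(is(cfg, "SimConfig"))
  if (!is.null(seed)) set.seed(seed)
  label <- simClassLabel(cfg)
  ecfg <- rescaleParameters(cfg, cfg@rescaleFactor)

  gt <- ecfg@demography@generationTime
  ss <- ecfg@samplingScheme
  sampleGens <- as.integer(round(ss$age / gt))
  selected <- !is.null(ecfg@selection)
  onsetGen <- if (selected) max(1L, as.integer(round(ecfg@selection@onsetTime / gt))) else -1L
  minSpan <- max(sampleGens, onsetGen) + 1L

  pv <- .popSizeVector(ecfg@demography, ecfg@burninFactor, minSpan)
  if (any(ss$n > 2 * pv$sizes[sampleGens + 1]))
    stop("sampling scheme requests more haplotypes than the population holds")

  L <- ecfg@locusLength
  res <- .wfSimulateCpp(pv$sizes, ecfg@mu * L, ecfg@rho * L,
                        if (selected) ecfg@selection@s else 0,
                        onsetGen,
                        if (selected) ecfg@selection@focalPosition / L else 0.5,
                        sampleGens, as.integer(ss$n),
                        as.integer(ecfg@maxConditionAttempts))
  if (!isTRUE(res$success))
    stop(structure(class = c("temposel_conditioning_error", "error", "condition"),
                   list(message = paste0("conditioning failed: focal allele not segregating ",
                                         "at present after ", res$attempts, " attempts"),
                        call = sys.call())))
  .assembleSample(res, ss$age, L, label, seed)
}

# Turn the raw engine output into a TemporalSample: round positions to the
# 6-decimal precision of the ms-style dialect, enforce strict ordering and
# reorder columns by position.
.assembleSample <- function(res, ages, L, label, seed) {
  frac <- round(res$positions, 6)
  ord <- order(frac)
  frac <- frac[ord]
  if (length(frac) > 1)  # resolve rounding collisions, keep strictly increasing
    for (i in 2:length(frac))
      if (frac[i] <= frac[i - 1]) frac[i] <- frac[i - 1] + 1e-6
  blocks <- lapply(res$blocks, function(m) {
    m <- m[, ord, drop = FALSE]
    storage.mode(m) <- "integer"
    m
  })
  focal <- if (res$focalIndex >= 1) match(res$focalIndex, ord) else NA_integer_
  new("TemporalSample", ages = as.numeric(ages), blocks = blocks,
      positions = frac * L, locusLength = L,
      focalIndex = as.integer(focal), label = label,
      provenance = list(seed = if (is.null(seed)) NA_integer_ else seed,
                        attempts = res$attempts))
}

#' Class label implied by a simulation configuration
#'
#' \code{"N"} for neutral configurations, otherwise \code{"D<100*s>"} from
#' the unrescaled selection coefficient (so s = 0.0025 gives \code{"D0.25"},
#' s = 0.005 gives \code{"D0.5"}).
#' @param cfg a \code{\linkS4class{SimConfig}}.
#' @export
simClassLabel <- function(cfg) {
  if (is.null(cfg@selection)) "N" else sprintf("D%g", cfg@selection@s * 100)
}

#' Advance a population state by one Wright-Fisher generation
#'
#' One cycle of genotype-proportional viability selection at the focal site,
#' random mating, Poisson recombination and Poisson infinite-sites mutation,
#' using the same engine code as \code{\link{simulateLocus}}. Lost and fixed
#' non-focal columns are pruned from the returned state.
#'
#' @param state a \code{\linkS4class{PopulationState}}.
#' @param cfg a \code{\linkS4class{SimConfig}} supplying \code{mu},
#'   \code{rho}, \code{locusLength} and the selection coefficient (applied at
#'   face value, without rescaling).
#' @param nextN diploid size of the offspring generation (default: current).
#' @return The next \code{\linkS4class{PopulationState}}.
#' @export
evolveGeneration <- function(state, cfg, nextN = NULL) {
  stopifnot(is(state, "PopulationState"), is(cfg, "SimConfig"))
  if (is.null(nextN)) nextN <- nrow(state@haplotypes) %/% 2
  L <- cfg@locusLength
  s <- if (is.null(cfg@selection)) 0 else cfg@selection@s
  res <- .wfEvolveOnceCpp(state@haplotypes, state@positions / L,
                          if (is.na(state@focalIndex)) 0L else state@focalIndex,
                          as.integer(nextN), s, cfg@mu * L, cfg@rho * L)
  m <- res$haplotypes
  pos <- res$positions
  focal <- res$focalIndex
  # prune lost/fixed non-focal columns (focal kept so it stays reportable)
  cnt <- colSums(m)
  keep <- (cnt > 0 & cnt < nrow(m)) | seq_along(pos) == focal
  m <- m[, keep, drop = FALSE]
  newFocal <- if (focal >= 1 && keep[focal]) sum(keep[seq_len(focal)]) else NA_integer_
  storage.mode(m) <- "integer"
  new("PopulationState", haplotypes = m, positions = pos[keep] * L,
      focalIndex = as.integer(newFocal))
}

#' Build a single-site population state at a given allele frequency
#'
#' Utility for selection-response experiments: 2N haplotypes with exactly
#' \code{round(2N p)} derived alleles at one focal column, randomly assigned
#' to haplotypes (so diploid genotypes are formed by random pairing).
#'
#' @param N diploid population size.
#' @param p derived-allele frequency.
#' @param position bp position of the site.
#' @export
initPopulationState <- function(N, p, position = 0.5) {
  k <- round(2 * N * p)
  hap <- matrix(0L, nrow = 2 * N, ncol = 1)
  hap[sample.int(2 * N, k), 1] <- 1L
  new("PopulationState", haplotypes = hap, positions = position,
      focalIndex = 1L)
}

#' Simulate a labeled multi-class dataset
#'
#' Draws per-sample seeds from the base seed and runs
#' \code{\link{simulateLocus}} for each configuration in turn, interleaving
#' classes so partial runs stay balanced.
#'
#' @param configs named list of \code{\linkS4class{SimConfig}} objects, one
#'   per class; names are ignored (labels come from the configs).
#' @param nPerClass replicates per class.
#' @param seed base seed; per-sample seeds are drawn from it.
#' @return List of \code{\linkS4class{TemporalSample}} objects.
#' @export
simulateDataset <- function(configs, nPerClass, seed = 1) {
  set.seed(seed)
  total <- nPerClass * length(configs)
  seeds <- sample.int(.Machine$integer.max, total)
  out <- vector("list", total)
  i <- 0
  for (r in seq_len(nPerClass)) {
    for (cfg in configs) {
      i <- i + 1
      out[[i]] <- simulateLocus(cfg, seed = seeds[i])
    }
  }
  out
}
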