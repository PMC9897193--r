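#' Piecewise population-size history
#'
#' A demographic model is an ordered set of epochs, oldest first. Each epoch
#' starts at \code{start} generations before present and runs toward the
#' present (until the next epoch begins) with diploid size \code{size} and an
#' optional per-generation exponential growth rate \code{growth} (size at
#' \code{t} generations before present within the epoch is
#' \code{size * exp(growth * (start - t))}). History before the first epoch is
#' the first epoch's size (the ancestral population, also used for burn-in).
#'
#' @slot epochs data.frame with columns \code{start} (generations before
#'   present, strictly decreasing), \code{size} (diploid individuals) and
#'   \code{growth} (per-generation rate).
#' @slot generationTime years per generation.
#' @exportClass DemographicModel
setClass("DemographicModel",
  representation(epochs = "data.frame", generationTime = "numeric"),
  validity = function(object) {
    e <- object@epochs
    msg <- character()
    if (!all(c("start", "size", "growth") %in% names(e)))
      msg <- c(msg, "epochs must have columns start, size, growth")
    else {
      if (nrow(e) < 1) msg <- c(msg, "at least one epoch required")
      if (any(diff(e$start) >= 0)) msg <- c(msg, "epoch start times must be strictly decreasing toward present")
      if (any(e$size < 2)) msg <- c(msg, "all diploid sizes must be >= 2")
    }
    if (length(object@generationTime) != 1 || object@generationTime <= 0)
      msg <- c(msg, "generationTime must be a single positive number")
    if (length(msg)) msg else TRUE
  }
)

#' Overdominant selection model
#'
#' Symmetric heterozygote advantage at a single focal site: genotype
#' fitnesses 1 : 1+s : 1 (ancestral homozygote, heterozygote, derived
#' homozygote). The derived allele arises de novo at \code{onsetTime} years
#' before present at \code{focalPosition} bp within the locus.
#'
#' @slot s heterozygote selection coefficient (dimensionless, in [0, 1)).
#' @slot onsetTime years before present at which the mutation arises.
#' @slot focalPosition bp offset of the selected site within the locus.
#' @exportClass SelectionModel
setClass("SelectionModel",
  representation(s = "numeric", onsetTime = "numeric", focalPosition = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@s < 0 || object@s >= 1) msg <- c(msg, "s must satisfy 0 <= s < 1")
    if (object@onsetTime <= 0) msg <- c(msg, "onsetTime must be positive")
    if (object@focalPosition < 0) msg <- c(msg, "focalPosition must be non-negative")
    if (length(msg)) msg else TRUE
  }
)

setClassUnion("SelectionModelOrNULL", c("SelectionModel", "NULL"))

#' Simulation run configuration
#'
#' Everything one forward-simulated locus needs: locus length, per-bp
#' mutation and crossover rates, demography, an optional selection model
#' (absent = neutral class), the serial sampling scheme, the rescaling
#' factor lambda, the neutral burn-in length (in multiples of the ancestral
#' diploid size) and the conditioning retry cap.
#'
#' @slot locusLength locus length in bp.
#' @slot mu mutation rate per bp per generation.
#' @slot rho crossover rate per bp per generation.
#' @slot demography a \code{\linkS4class{DemographicModel}}.
#' @slot selection a \code{\linkS4class{SelectionModel}} or \code{NULL}.
#' @slot samplingScheme data.frame with columns \code{age} (years before
#'   present; must include 0) and \code{n} (haplotypes to draw).
#' @slot rescaleFactor rescaling factor lambda (>= 1) applied at simulation
#'   time via \code{\link{rescaleParameters}}.
#' @slot burninFactor neutral burn-in length, in units of the ancestral
#'   diploid size (default 10).
#' @slot maxConditionAttempts retry cap for the segregation conditioning.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    locusLength = "numeric", mu = "numeric", rho = "numeric",
    demography = "DemographicModel", selection = "SelectionModelOrNULL",
    samplingScheme = "data.frame", rescaleFactor = "numeric",
    burninFactor = "numeric", maxConditionAttempts = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    if (object@locusLength <= 0) msg <- c(msg, "locusLength must be positive")
    if (object@mu < 0) msg <- c(msg, "mu must be non-negative")
    if (object@rho < 0) msg <- c(msg, "rho must be non-negative")
    ss <- object@samplingScheme
    if (!all(c("age", "n") %in% names(ss)))
      msg <- c(msg, "samplingScheme must have columns age, n")
    else {
      if (any(ss$age < 0)) msg <- c(msg, "sampling ages must be non-negative")
      if (!any(ss$age == 0)) msg <- c(msg, "samplingScheme must include age 0 (present)")
      if (any(ss$n < 1)) msg <- c(msg, "sampling sizes must be >= 1")
    }
    if (object@rescaleFactor < 1) msg <- c(msg, "rescaleFactor must be >= 1")
    if (!is.null(object@selection) && object@selection@s * object@rescaleFactor >= 1)
      msg <- c(msg, "rescaled selection coefficient s*lambda must be < 1")
    if (!is.null(object@selection) &&
        object@selection@focalPosition > object@locusLength)
      msg <- c(msg, "focalPosition must lie within the locus")
    if (object@burninFactor < 0) msg <- c(msg, "burninFactor must be non-negative")
    if (object@maxConditionAttempts < 1) msg <- c(msg, "maxConditionAttempts must be >= 1")
    if (length(msg)) msg else TRUE
  }
)

#' Serially sampled haplotypes from one simulated locus
#'
#' Blocks of 0/1 haplotype matrices (rows = haplotypes, columns = shared
#' segregating sites) drawn at decreasing ages, oldest first, present (age 0)
#' last. Entry 0 is the ancestral and 1 the derived allele. Positions are bp
#' coordinates shared by all blocks.
#'
#' @slot ages numeric vector of block ages in years before present,
#'   strictly decreasing, last element 0.
#' @slot blocks list of binary matrices, one per age, equal column counts.
#' @slot positions strictly increasing bp positions of the columns.
#' @slot locusLength locus length in bp.
#' @slot focalIndex column index of the selected variant, or \code{NA}.
#' @slot label class label: \code{"N"}, \code{"D0.25"} or \code{"D0.5"}.
#' @slot provenance list with \code{seed} and \code{attempts}.
#' @exportClass TemporalSample
setClass("TemporalSample",
  representation(
    ages = "numeric", blocks = "list", positions = "numeric",
    locusLength = "numeric", focalIndex = "integer", label = "character",
    provenance = "list"
  ),
  validity = function(object) {
    msg <- character()
    nc <- vapply(object@blocks, ncol, integer(1))
    if (length(object@blocks) != length(object@ages))
      msg <- c(msg, "one block per age required")
    if (length(unique(nc)) > 1) msg <- c(msg, "all blocks must share the column count")
    if (length(nc) && nc[1] != length(object@positions))
      msg <- c(msg, "positions must match the block column count")
    if (length(object@positions) > 1 && any(diff(object@positions) <= 0))
      msg <- c(msg, "positions must be strictly increasing")
    for (b in object@blocks)
      if (!all(b %in% c(0L, 1L))) { msg <- c(msg, "haplotype entries must be 0/1"); break }
    if (is.unsorted(rev(object@ages), strictly = TRUE))
      msg <- c(msg, "ages must be strictly decreasing (oldest first)")
    if (!grepl("^(N|D[0-9]*\\.?[0-9]+)$", object@label))
      msg <- c(msg, "label must be N or D<percent s> (e.g. D0.25, D0.5)")
    if (length(msg)) msg else TRUE
  }
)

#' Explicit population state for single-generation updates
#'
#' @slot haplotypes binary matrix, 2N rows (haplotypes; diploid i owns rows
#'   2i-1, 2i) by S segregating-site columns.
#' @slot positions bp positions of the columns.
#' @slot focalIndex focal column index or \code{NA}.
#' @exportClass PopulationState
setClass("PopulationState",
  representation(haplotypes = "matrix", positions = "numeric", focalIndex = "integer"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@haplotypes) %% 2 != 0) msg <- c(msg, "haplotype count must be even (2N)")
    if (ncol(object@haplotypes) != length(object@positions))
      msg <- c(msg, "positions must match columns")
    if (length(msg)) msg else TRUE
  }
)

#' Fixed-shape network input built from a temporal sample
#'
#' @slot present binary matrix, present-day haplotypes by W windowed columns,
#'   rows sorted by descending haplotype frequency.
#' @slot ancient binary array T x nAncient x W; time points as channels,
#'   oldest first.
#' @slot label class label.
#' @slot focalColumn focal column index within the window, or \code{NA}.
#' @exportClass FeatureTensor
setClass("FeatureTensor",
  representation(present = "matrix", ancient = "array",
                 label = "character", focalColumn = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@ancient)) != 3) msg <- c(msg, "ancient must be a 3-d array")
    else if (dim(object@ancient)[3] != ncol(object@present))
      msg <- c(msg, "present and ancient must share width W")
    if (!all(object@present %in% c(0, 1))) msg <- c(msg, "entries must be 0/1")
    if (length(msg)) msg else TRUE
  }
)

#' Network architecture specification
#'
#' Two-branch residual convolutional classifier: the present branch takes the
#' frequency-sorted present-day matrix, the ancient branch the stacked
#' ancient tensor (time points as input channels); each branch applies an
#' input convolution, residual 3x3 convolution blocks with 2x2 max-pooling
#' between them, a mean reduction over the haplotype axis and a dense
#' embedding; embeddings are concatenated and a single dense layer produces
#' the 3 class logits. Modes \code{present_only} / \code{ancient_only} build
#' just one branch feeding the same head.
#'
#' @slot mode one of \code{"both"}, \code{"present_only"}, \code{"ancient_only"}.
#' @slot nFilters convolution filters per layer (default 64).
#' @slot kernel kernel size, c(3, 3).
#' @slot padding zero padding, c(1, 1).
#' @slot nResidualBlocks residual blocks per branch (default 2).
#' @slot embeddingDim per-branch embedding length.
#' @slot nClasses number of classes (fixed at 3).
#' @slot dropout dropout rate before the dense head.
#' @slot variant \code{"residual2d"} (default: 2-D residual convolutions on
#'   the sorted matrices) or \code{"exchangeable"} (row-shared 1-D
#'   convolutions, mean reduction over the haplotype axis, then residual 1-D
#'   convolutions on the pooled frequency map -- an exchangeable,
#'   permutation-respecting branch).
#' @exportClass NetworkSpec
setClass("NetworkSpec",
  representation(mode = "character", nFilters = "numeric", kernel = "numeric",
                 padding = "numeric", nResidualBlocks = "numeric",
                 embeddingDim = "numeric", nClasses = "numeric", dropout = "numeric",
                 variant = "character"),
  validity = function(object) {
    msg <- character()
    if (!object@mode %in% c("both", "present_only", "ancient_only"))
      msg <- c(msg, "mode must be one of both, present_only, ancient_only")
    if (object@nClasses != 3) msg <- c(msg, "nClasses must be 3")
    if (length(object@kernel) != 2 || any(object@kernel < 1))
      msg <- c(msg, "kernel must be two positive integers")
    if (length(object@padding) != 2 || any(object@padding < 0))
      msg <- c(msg, "padding must be two non-negative integers")
    if (object@nFilters < 1) msg <- c(msg, "nFilters must be >= 1")
    if (object@dropout < 0 || object@dropout >= 1) msg <- c(msg, "dropout must be in [0, 1)")
    if (!object@variant %in% c("residual2d", "exchangeable"))
      msg <- c(msg, "variant must be residual2d or exchangeable")
    if (length(msg)) msg else TRUE
  }
)

#' Trained two-branch classifier
#'
#' @slot spec the \code{\linkS4class{NetworkSpec}}.
#' @slot shape list of input dimensions (presentRows, ancientRows, nTimes, width).
#' @slot params named list of parameter matrices/vectors.
#' @slot seed the initialization seed.
#' @exportClass TemporalNet
setClass("TemporalNet",
  representation(spec = "NetworkSpec", shape = "list", params = "list", seed = "numeric"))

#' Training protocol configuration
#'
#' @slot fractions train/validation/test fractions summing to 1.
#' @slot batchSize minibatch size.
#' @slot learningRate Adam learning rate.
#' @slot optimizer optimizer name (only \code{"adam"} implemented).
#' @slot maxEpochs epoch cap.
#' @slot patience early-stopping patience on validation accuracy (0 disables).
#' @slot nRepeats number of independent trainings (default 10).
#' @slot baseSeed seed of the first repeat; repeat k uses baseSeed + k - 1.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(fractions = "numeric", batchSize = "numeric", learningRate = "numeric",
                 optimizer = "character", maxEpochs = "numeric", patience = "numeric",
                 nRepeats = "numeric", baseSeed = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@fractions) != 3 || abs(sum(object@fractions) - 1) > 1e-9)
      msg <- c(msg, "fractions must be three numbers summing to 1")
    if (any(object@fractions <= 0)) msg <- c(msg, "all fractions must be positive")
    if (object@nRepeats < 1) msg <- c(msg, "nRepeats must be >= 1")
    if (!object@optimizer %in% c("adam", "sgd")) msg <- c(msg, "optimizer must be adam or sgd")
    if (length(msg)) msg else TRUE
  }
)

#' Repeated-training evaluation report
#'
#' @slot mode network mode the report belongs to.
#' @slot matrices list of 3x3 integer confusion matrices (rows = true class
#'   N, D0.25, D0.5; columns = predicted), one per repeat.
#' @slot accuracies per-repeat test accuracy.
#' @slot meanAccuracy mean accuracy over repeats.
#' @slot ci 95 percent t-interval over repeats (NA when nRepeats = 1).
#' @slot normalized row-stochastic mean confusion matrix.
#' @exportClass EvalReport
setClass("EvalReport",
  representation(mode = "character", matrices = "list", accuracies = "numeric",
                 meanAccuracy = "numeric", ci = "numeric", normalized = "matrix"),
  validity = function(object) {
    msg <- character()
    tot <- vapply(object@matrices, sum, numeric(1))
    if (length(unique(tot)) > 1) msg <- c(msg, "all confusion matrices must have equal totals")
    if (length(object@matrices) &&
        any(abs(rowSums(object@normalized) - 1) > 1e-9))
      msg <- c(msg, "normalized rows must sum to 1")
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "DemographicModel", function(object) {
  cat("DemographicModel:", nrow(object@epochs), "epoch(s),",
      object@generationTime, "years/generation\n")
  print(object@epochs, row.names = FALSE)
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: locus", object@locusLength, "bp, mu", object@mu, ", rho", object@rho,
      ", lambda", object@rescaleFactor, "\n")
  if (is.null(object@selection)) cat("  neutral (no selection)\n")
  else cat("  overdominance s =", object@selection@s, ", onset",
           object@selection@onsetTime, "years BP\n")
  cat("  sampling:", paste(sprintf("%d@%gy", object@samplingScheme$n,
                                   object@samplingScheme$age), collapse = ", "), "\n")
})

setMethod("show", "TemporalSample", function(object) {
  cat("TemporalSample [", object@label, "]: ",
      length(object@blocks), " blocks, ", length(object@positions),
      " segregating sites\n", sep = "")
  for (i in seq_along(object@blocks))
    cat(sprintf("  age %6g y: %d haplotypes\n", object@ages[i], nrow(object@blocks[[i]])))
})

setMethod("show", "FeatureTensor", function(object) {
  d <- dim(object@ancient)
  cat("FeatureTensor [", object@label, "]: present ", nrow(object@present),
      "x", ncol(object@present), ", ancient ", d[1], " time point(s) x ",
      d[2], "x", d[3], sep = "")
  if (!is.na(object@focalColumn)) cat(", focal column ", object@focalColumn, sep = "")
  cat("\n")
})

setMethod("show", "TemporalNet", function(object) {
  np <- sum(vapply(object@params, length, numeric(1)))
  cat("TemporalNet mode=", object@spec@mode, ", ", object@spec@nFilters,
      " filters, ", np, " parameters\n", sep = "")
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport [", object@mode, "]: ", length(object@matrices),
      " repeat(s), mean accuracy ", round(object@meanAccuracy, 4), sep = "")
  if (!anyNA(object@ci))
    cat(" (95% CI ", round(object@ci[1], 4), "-", round(object@ci[2], 4), ")", sep = "")
  cat("\nMean normalized confusion matrix (rows = true):\n")
  print(round(object@normalized, 3))
})
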