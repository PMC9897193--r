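.schema <- list(
  run = c("name"),
  simulation = c("locus_length", "mu", "rho", "rescale_factor", "burnin_factor",
                 "max_condition_attempts", "generation_time", "demography",
                 "selection", "sampling", "n_per_class"),
  demography = c("epochs"),
  epoch = c("start", "size", "growth"),
  selection = c("onset_time", "focal_position", "s_classes"),
  samplingEntry = c("age", "n_haplotypes"),
  encoding = c("width"),
  network = c("n_filters", "kernel", "padding", "n_residual_blocks",
              "embedding_dim", "dropout", "variant"),
  training = c("fractions", "batch_size", "learning_rate", "optimizer",
               "max_epochs", "patience", "n_repeats")
)

.validationError <- function(...) {
  stop(structure(class = c("temposel_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

.checkFields <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    .validationError("config field not consumed by the pipeline: ",
                     where, ".", extra[1])
}

#' Read and validate a YAML run configuration
#'
#' Strict schema validation: any field the pipeline does not consume is
#' rejected (with its path) rather than silently ignored. Returns the
#' materialized objects: one \code{\linkS4class{SimConfig}} per class
#' (neutral plus one per selection coefficient), the encoding width, the
#' \code{\linkS4class{NetworkSpec}} and the \code{\linkS4class{TrainConfig}}.
#'
#' @param path YAML file (see the bundled \code{config-default.yaml} and
#'   \code{config-desk.yaml} under \code{inst/extdata}).
#' @return List with \code{simConfigs}, \code{width}, \code{spec},
#'   \code{trainCfg}, \code{nPerClass}, \code{name} and \code{raw}.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) .validationError("config file not found: ", path)
  y <- yaml::read_yaml(path)
  .checkFields(y, c("run", "simulation", "encoding", "network", "training"), "<top>")
  for (sec in c("simulation", "encoding", "network", "training"))
    if (is.null(y[[sec]])) .validationError("missing config section: ", sec)
  if (!is.null(y$run)) .checkFields(y$run, .schema$run, "run")
  sim <- y$simulation
  .checkFields(sim, .schema$simulation, "simulation")
  .checkFields(sim$demography, .schema$demography, "simulation.demography")
  for (e in sim$demography$epochs)
    .checkFields(e, .schema$epoch, "simulation.demography.epochs[]")
  if (!is.null(sim$selection))
    .checkFields(sim$selection, .schema$selection, "simulation.selection")
  for (e in sim$sampling) .checkFields(e, .schema$samplingEntry, "simulation.sampling[]")
  .checkFields(y$encoding, .schema$encoding, "encoding")
  .checkFields(y$network, .schema$network, "network")
  .checkFields(y$training, .schema$training, "training")

  epochs <- do.call(rbind, lapply(sim$demography$epochs, function(e)
    data.frame(start = e$start, size = e$size,
               growth = if (is.null(e$growth)) 0 else e$growth)))
  dem <- DemographicModel(epochs,
                          generationTime = if (is.null(sim$generation_time)) 25
                                           else sim$generation_time)
  scheme <- do.call(rbind, lapply(sim$sampling, function(e)
    data.frame(age = e$age, n = e$n_haplotypes)))
  mk <- function(selModel) SimConfig(
    locusLength = sim$locus_length, mu = sim$mu, rho = sim$rho,
    demography = dem, selection = selModel, samplingScheme = scheme,
    rescaleFactor = if (is.null(sim$rescale_factor)) 1 else sim$rescale_factor,
    burninFactor = if (is.null(sim$burnin_factor)) 10 else sim$burnin_factor,
    maxConditionAttempts = if (is.null(sim$max_condition_attempts)) 100
                           else sim$max_condition_attempts)
  simConfigs <- list(N = mk(NULL))
  if (!is.null(sim$selection)) {
    for (nm in names(sim$selection$s_classes)) {
      selObj <- SelectionModel(sim$selection$s_classes[[nm]],
                               sim$selection$onset_time,
                               sim$selection$focal_position)
      simConfigs[[nm]] <- mk(selObj)
    }
  }
  net <- y$network
  spec <- NetworkSpec(
    mode = "both",
    nFilters = if (is.null(net$n_filters)) 64 else net$n_filters,
    kernel = if (is.null(net$kernel)) c(3, 3) else unlist(net$kernel),
    padding = if (is.null(net$padding)) c(1, 1) else unlist(net$padding),
    nResidualBlocks = if (is.null(net$n_residual_blocks)) 2 else net$n_residual_blocks,
    embeddingDim = if (is.null(net$embedding_dim)) 64 else net$embedding_dim,
    dropout = if (is.null(net$dropout)) 0.25 else net$dropout,
    variant = if (is.null(net$variant)) "residual2d" else net$variant)
  tr <- y$training
  trainCfg <- TrainConfig(
    fractions = if (is.null(tr$fractions)) c(0.8, 0.1, 0.1) else unlist(tr$fractions),
    batchSize = if (is.null(tr$batch_size)) 32 else tr$batch_size,
    learningRate = if (is.null(tr$learning_rate)) 1e-3 else tr$learning_rate,
    optimizer = if (is.null(tr$optimizer)) "adam" else tr$optimizer,
    maxEpochs = if (is.null(tr$max_epochs)) 50 else tr$max_epochs,
    patience = if (is.null(tr$patience)) 10 else tr$patience,
    nRepeats = if (is.null(tr$n_repeats)) 10 else tr$n_repeats)
  list(simConfigs = simConfigs,
       width = if (is.null(y$encoding$width)) 128 else y$encoding$width,
       spec = spec, trainCfg = trainCfg,
       nPerClass = if (is.null(sim$n_per_class)) 2000 else sim$n_per_class,
       name = if (is.null(y$run$name)) "run" else y$run$name,
       raw = y)
}

#' Bundled run configurations
#'
#' \code{defaultConfig()} is the full-scale study design: 50 kbp loci under
#' a European-like piecewise demography (a documented stand-in, not a
#' reproduction of any published fit), a de novo overdominant mutation at
#' the locus center arising 10,000 years ago with s = 0.25 or 0.5 percent,
#' sampling 40 present-day haplotypes plus 10 at each of 8, 4, 2 and 1 kya,
#' 2,000 loci per class, a 64-filter 3x3/1x1 two-branch network and a
#' 10-repeat training protocol.
#'
#' \code{deskConfig()} is a rescaled, desk-scale scenario (lambda = 50,
#' stronger scaled selection, smaller locus and training set) used by the
#' validation suite; it runs in minutes on one CPU.
#'
#' @return See \code{\link{readRunConfig}}.
#' @export
defaultConfig <- function() {
  readRunConfig(system.file("extdata", "config-default.yaml", package = "tempoSel"))
}

#' @rdname defaultConfig
#' @export
deskConfig <- function() {
  readRunConfig(system.file("extdata", "config-desk.yaml", package = "tempoSel"))
}
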