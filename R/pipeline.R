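.dependencyError <- function(...) {
  stop(structure(class = c("temposel_dependency_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

.manifestAdd <- function(outDir, stage, cfgHash, seed, inputs, outputs) {
  path <- file.path(outDir, "manifest.json")
  entries <- if (file.exists(path)) jsonlite::read_json(path) else list()
  entries[[length(entries) + 1]] <- list(
    stage = stage, config_hash = cfgHash, seed = seed,
    inputs = inputs, outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    version = as.character(utils::packageVersion("tempoSel")))
  jsonlite::write_json(entries, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run one pipeline stage (or the whole pipeline)
#'
#' Stages: \code{simulate} (labeled loci to ms-style text + metadata),
#' \code{encode} (feature tensors + index TSV), \code{train} (both-branch
#' repeat protocol, checkpoint + report), \code{evaluate} (re-evaluate the
#' saved checkpoint on the test split), \code{ablate} (three-mode
#' comparison), \code{all} (simulate, encode, ablate). Every stage writes a
#' manifest entry carrying the config hash and seed; reruns with unchanged
#' config and seed reproduce outputs exactly.
#'
#' @param stage stage name.
#' @param configPath YAML run configuration (see \code{\link{readRunConfig}}).
#' @param outDir output directory.
#' @param seed base seed for the stage.
#' @return Named list of artifact paths, invisibly.
#' @export
runStage <- function(stage, configPath, outDir, seed = 1) {
  if (!stage %in% c("simulate", "encode", "train", "evaluate", "ablate", "all"))
    .validationError("unknown stage: ", stage)
  cfg <- readRunConfig(configPath)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cfgHash <- rlang::hash(cfg$raw)
  msPath <- file.path(outDir, "sims.ms")
  encPath <- file.path(outDir, "encoded.rds")
  ckptPath <- file.path(outDir, "model.rds")
  arts <- list()

  if (stage %in% c("simulate", "all")) {
    samples <- simulateDataset(cfg$simConfigs, cfg$nPerClass, seed = seed)
    writeMsLike(samples, msPath)
    .manifestAdd(outDir, "simulate", cfgHash, seed, list(config = configPath),
                 list(ms = msPath))
    arts$ms <- msPath
  }
  if (stage %in% c("encode", "all")) {
    if (!file.exists(msPath)) .dependencyError("encode needs ", msPath, "; run simulate first")
    samples <- readMsLike(msPath)
    tensors <- encodeDataset(samples, cfg$width)
    idx <- data.frame(sample_id = seq_along(tensors),
                      label = vapply(tensors, function(t) t@label, character(1)),
                      path = encPath, seed = seed)
    saveRDS(tensors, encPath)
    write.table(idx, file.path(outDir, "encoded.index.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    .manifestAdd(outDir, "encode", cfgHash, seed, list(ms = msPath),
                 list(encoded = encPath))
    arts$encoded <- encPath
  }
  if (stage %in% c("train", "evaluate", "ablate", "all")) {
    if (!file.exists(encPath)) .dependencyError("stage '", stage, "' needs ", encPath)
    tensors <- readRDS(encPath)
    labels <- vapply(tensors, function(t) t@label, character(1))
    trainCfg <- cfg$trainCfg
    trainCfg@baseSeed <- seed
    split <- splitDataset(labels, trainCfg@fractions, seed = seed)
    lev <- labelLevels(labels)
    data <- list(train = packTensors(tensors[split$train], lev),
                 validation = packTensors(tensors[split$validation], lev),
                 test = packTensors(tensors[split$test], lev))
    if (stage == "train") {
      report <- repeatProtocol(cfg$spec, trainCfg, data)
      set.seed(seed)
      fit <- trainModel(cfg$spec, trainCfg, data, seed = seed)
      saveCheckpoint(fit$model, ckptPath)
      writeEvalReport(report, file.path(outDir, "report-both"))
      .manifestAdd(outDir, "train", cfgHash, seed, list(encoded = encPath),
                   list(checkpoint = ckptPath))
      arts$checkpoint <- ckptPath
    }
    if (stage == "evaluate") {
      if (!file.exists(ckptPath)) .dependencyError("evaluate needs ", ckptPath)
      model <- loadCheckpoint(ckptPath)
      ev <- evaluateModel(model, data$test)
      rep1 <- .makeEvalReport(model@spec@mode, list(ev$confusion), ev$accuracy)
      writeEvalReport(rep1, file.path(outDir, "report-eval"))
      .manifestAdd(outDir, "evaluate", cfgHash, seed,
                   list(checkpoint = ckptPath), list(report = file.path(outDir, "report-eval.json")))
      arts$report <- file.path(outDir, "report-eval.json")
    }
    if (stage %in% c("ablate", "all")) {
      cmp <- ablationCompare(cfg$spec, trainCfg, data)
      for (m in names(cmp$reports))
        writeEvalReport(cmp$reports[[m]], file.path(outDir, paste0("report-", m)))
      write.table(cmp$table, file.path(outDir, "ablation.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      .manifestAdd(outDir, "ablate", cfgHash, seed, list(encoded = encPath),
                   list(ablation = file.path(outDir, "ablation.tsv")))
      arts$ablation <- file.path(outDir, "ablation.tsv")
    }
  }
  invisible(arts)
}
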