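#' Construct a training configuration
#'
#' @param fractions train/validation/test fractions (sum to 1).
#' @param batchSize minibatch size (default 32).
#' @param learningRate Adam step size (default 1e-3).
#' @param optimizer \code{"adam"} (default) or \code{"sgd"}.
#' @param maxEpochs epoch cap (default 50).
#' @param patience early-stopping patience on validation accuracy, in
#'   epochs; 0 disables early stopping (default 10).
#' @param nRepeats independent trainings for the confidence interval
#'   (default 10).
#' @param baseSeed seed of the first repeat (default 1).
#' @export
TrainConfig <- function(fractions = c(0.8, 0.1, 0.1), batchSize = 32,
                        learningRate = 1e-3, optimizer = "adam",
                        maxEpochs = 50, patience = 10, nRepeats = 10,
                        baseSeed = 1) {
  new("TrainConfig", fractions = fractions, batchSize = batchSize,
      learningRate = learningRate, optimizer = optimizer,
      maxEpochs = maxEpochs, patience = patience, nRepeats = nRepeats,
      baseSeed = baseSeed)
}

#' Label-stratified train/validation/test split
#'
#' Within every class the three subsets receive \code{floor(f * n)} samples
#' plus largest-remainder rounding, so per-class proportions are within one
#' sample of the requested fractions. Deterministic given the seed.
#'
#' @param labels character vector of sample labels.
#' @param fractions three positive fractions summing to 1.
#' @param seed RNG seed.
#' @return List of index vectors \code{train}, \code{validation}, \code{test}.
#' @export
splitDataset <- function(labels, fractions, seed = 1) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-9)
  set.seed(seed)
  out <- list(train = integer(), validation = integer(), test = integer())
  for (cl in labelLevels(labels)) {
    idx <- which(labels == cl)
    n <- length(idx)
    raw <- fractions * n
    k <- floor(raw)
    rem <- raw - k
    short <- n - sum(k)
    if (short > 0) k[order(-rem)[seq_len(short)]] <- k[order(-rem)[seq_len(short)]] + 1
    if (any(k < 1))
      stop("insufficient-data: class ", cl, " has ", n,
           " samples, cannot populate train/validation/test")
    idx <- sample(idx)
    out$train <- c(out$train, idx[seq_len(k[1])])
    out$validation <- c(out$validation, idx[k[1] + seq_len(k[2])])
    out$test <- c(out$test, idx[k[1] + k[2] + seq_len(k[3])])
  }
  out
}

.adamStep <- function(par, g, state, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(g)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

.datasetAccuracy <- function(model, data, batchSize = 128) {
  n <- length(data$y)
  correct <- 0; loss <- 0
  for (start in seq(1, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1, n)
    b <- .sliceBatch(data, idx)
    p <- .netForward(model, b, train = FALSE)$probs
    correct <- correct + sum(max.col(t(p)) == b$y)
    loss <- loss - sum(log(pmax(p[cbind(b$y, seq_along(idx))], 1e-12)))
  }
  list(acc = correct / n, loss = loss / n)
}

#' Train a classifier by minibatch cross-entropy
#'
#' Minimizes multiclass cross-entropy with Adam; tracks validation accuracy
#' each epoch and returns the parameters of the best validation epoch
#' (early-stopped after \code{patience} epochs without improvement).
#' Fully reproducible: the seed drives initialization, batch order and
#' dropout.
#'
#' @param spec a \code{\linkS4class{NetworkSpec}}.
#' @param trainCfg a \code{\linkS4class{TrainConfig}}.
#' @param data list with packed datasets \code{train} and \code{validation}
#'   (see \code{\link{packTensors}}).
#' @param seed training seed (default \code{trainCfg@baseSeed}).
#' @return List with \code{model} (\code{\linkS4class{TemporalNet}}) and
#'   \code{history} (data.frame epoch/trainLoss/trainAcc/valLoss/valAcc).
#' @export
trainModel <- function(spec, trainCfg, data, seed = trainCfg@baseSeed) {
  stopifnot(is(spec, "NetworkSpec"), is(trainCfg, "TrainConfig"))
  tr <- data$train
  shape <- list(presentRows = dim(tr$present)[1], ancientRows = dim(tr$ancient)[1],
                nTimes = dim(tr$ancient)[3], width = dim(tr$present)[2])
  model <- buildNetwork(spec, shape, seed = seed)
  par <- model@params
  state <- list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0))
  n <- length(tr$y)
  bs <- trainCfg@batchSize
  bestVal <- -Inf; bestPar <- par; sinceBest <- 0; t <- 0
  hist <- data.frame()
  for (epoch in seq_len(trainCfg@maxEpochs)) {
    ord <- sample.int(n)
    epLoss <- 0; epAcc <- 0; nb <- 0
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n)]
      lg <- .lossGrads(model, .sliceBatch(tr, idx))
      if (!is.finite(lg$loss)) stop("training-failure: non-finite loss at epoch ", epoch)
      t <- t + 1
      if (trainCfg@optimizer == "adam") {
        up <- .adamStep(par, lg$grads, state, trainCfg@learningRate, t)
        par <- up$par; state <- up$state
      } else {
        for (nm in names(lg$grads)) par[[nm]] <- par[[nm]] - trainCfg@learningRate * lg$grads[[nm]]
      }
      model@params <- par
      epLoss <- epLoss + lg$loss; epAcc <- epAcc + lg$acc; nb <- nb + 1
    }
    val <- .datasetAccuracy(model, data$validation)
    hist <- rbind(hist, data.frame(epoch = epoch, trainLoss = epLoss / nb,
                                   trainAcc = epAcc / nb, valLoss = val$loss,
                                   valAcc = val$acc))
    if (val$acc > bestVal) { bestVal <- val$acc; bestPar <- par; sinceBest <- 0 }
    else sinceBest <- sinceBest + 1
    if (trainCfg@patience > 0 && sinceBest >= trainCfg@patience) break
  }
  model@params <- bestPar
  list(model = model, history = hist)
}

#' Confusion matrix from true and predicted class indices
#'
#' Entry (i, j) counts samples with true class i predicted as class j.
#'
#' @param true,predicted integer class indices (1-based) or values matching
#'   \code{levels}.
#' @param levels class labels, in order.
#' @export
confusionMatrix <- function(true, predicted, levels) {
  k <- length(levels)
  if (!is.numeric(true)) true <- match(true, levels)
  if (!is.numeric(predicted)) predicted <- match(predicted, levels)
  cm <- matrix(0L, k, k, dimnames = list(true = levels, predicted = levels))
  for (i in seq_along(true)) cm[true[i], predicted[i]] <- cm[true[i], predicted[i]] + 1L
  cm
}

#' Confusion matrix and accuracy on a test set
#'
#' Entry (i, j) counts samples of true class i predicted as class j; rows
#' and columns follow the dataset's label levels (N first).
#'
#' @param model a \code{\linkS4class{TemporalNet}}.
#' @param testData packed dataset (see \code{\link{packTensors}}).
#' @return List with \code{confusion} (3x3 integer matrix) and \code{accuracy}.
#' @export
evaluateModel <- function(model, testData) {
  n <- length(testData$y)
  stopifnot(n > 0)
  lev <- testData$levels
  pred <- integer(n)
  for (start in seq(1, n, by = 128)) {
    idx <- start:min(start + 127, n)
    p <- .netForward(model, .sliceBatch(testData, idx), train = FALSE)$probs
    pred[idx] <- max.col(t(p))
  }
  cm <- confusionMatrix(testData$y, pred, lev)
  list(confusion = cm, accuracy = sum(diag(cm)) / n)
}

#' Pairwise discrimination accuracy between two classes
#'
#' Restricts a confusion matrix to the rows and columns of two classes and
#' returns the fraction of those true samples predicted within and onto the
#' correct one of the two.
#'
#' @param cm square confusion matrix.
#' @param classes indices or names of the two classes (default D0.25/D0.5,
#'   rows 2 and 3).
#' @export
pairwiseAccuracy <- function(cm, classes = c(2, 3)) {
  sub <- cm[classes, classes, drop = FALSE]
  sum(diag(sub)) / sum(sub)
}

#' Repeated-training protocol
#'
#' Runs \code{nRepeats} independent trainings (seeds \code{baseSeed} ..
#' \code{baseSeed + nRepeats - 1}; initialization, batch order and dropout
#' vary, the data split is fixed) and aggregates test confusion matrices,
#' mean accuracy and a t-based 95 percent confidence interval.
#'
#' @param spec a \code{\linkS4class{NetworkSpec}}.
#' @param trainCfg a \code{\linkS4class{TrainConfig}}.
#' @param data list with packed \code{train}, \code{validation}, \code{test}.
#' @return An \code{\linkS4class{EvalReport}}.
#' @export
repeatProtocol <- function(spec, trainCfg, data) {
  nR <- trainCfg@nRepeats
  mats <- vector("list", nR)
  accs <- numeric(nR)
  for (k in seq_len(nR)) {
    fit <- trainModel(spec, trainCfg, data, seed = trainCfg@baseSeed + k - 1)
    ev <- evaluateModel(fit$model, data$test)
    mats[[k]] <- ev$confusion
    accs[k] <- ev$accuracy
  }
  .makeEvalReport(spec@mode, mats, accs)
}

.makeEvalReport <- function(mode, mats, accs) {
  nR <- length(accs)
  m <- mean(accs)
  ci <- if (nR >= 2) m + c(-1, 1) * qt(0.975, nR - 1) * sd(accs) / sqrt(nR)
        else c(NA_real_, NA_real_)
  norm <- Reduce(`+`, lapply(mats, function(x) x / rowSums(x))) / nR
  new("EvalReport", mode = mode, matrices = mats, accuracies = accs,
      meanAccuracy = m, ci = ci, normalized = norm)
}

#' Train and compare both-branch and single-branch classifiers
#'
#' Runs \code{\link{repeatProtocol}} for modes \code{both},
#' \code{present_only} and \code{ancient_only} on identical splits and seed
#' streams (the ablations are independently trained single-branch models)
#' and tabulates mean accuracy, its interval and the weak-vs-moderate
#' (D0.25 vs D0.5) pairwise discrimination accuracy.
#'
#' @param spec a \code{\linkS4class{NetworkSpec}} used as the template (its
#'   mode is overridden per arm).
#' @param trainCfg a \code{\linkS4class{TrainConfig}}.
#' @param data list with packed \code{train}, \code{validation}, \code{test}.
#' @param modes modes to run (default all three).
#' @return List with \code{reports} (named \code{\linkS4class{EvalReport}}s)
#'   and \code{table} (one row per mode).
#' @export
ablationCompare <- function(spec, trainCfg, data,
                            modes = c("both", "present_only", "ancient_only")) {
  reports <- list()
  rows <- list()
  for (mode in modes) {
    sp <- spec
    sp@mode <- mode
    rep <- repeatProtocol(sp, trainCfg, data)
    reports[[mode]] <- rep
    pw <- mean(vapply(rep@matrices, pairwiseAccuracy, numeric(1)))
    rows[[mode]] <- data.frame(mode = mode, meanAccuracy = rep@meanAccuracy,
                               ciLow = rep@ci[1], ciHigh = rep@ci[2],
                               pairwiseD = pw)
  }
  list(reports = reports, table = do.call(rbind, c(rows, make.row.names = FALSE)))
}

#' Write an evaluation report to disk
#'
#' Long-format TSV of per-repeat confusion matrices (repeat, true,
#' predicted, count) plus a JSON summary (mode, per-repeat and mean
#' accuracy, interval).
#'
#' @param report an \code{\linkS4class{EvalReport}}.
#' @param prefix output path prefix; writes \code{<prefix>.tsv} and
#'   \code{<prefix>.json}.
#' @export
writeEvalReport <- function(report, prefix) {
  rows <- do.call(rbind, lapply(seq_along(report@matrices), function(k) {
    cm <- report@matrices[[k]]
    lev <- rownames(cm)
    expand <- expand.grid(true = lev, predicted = lev, stringsAsFactors = FALSE)
    expand$repeatId <- k
    expand$count <- as.vector(cm[cbind(expand$true, expand$predicted)])
    expand[, c("repeatId", "true", "predicted", "count")]
  }))
  write.table(rows, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(mode = report@mode, accuracies = report@accuracies,
         meanAccuracy = report@meanAccuracy, ci95 = report@ci,
         normalized = report@normalized),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
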