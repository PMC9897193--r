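#' Construct a network specification
#'
#' Defaults follow the reference design: 64 filters, 3x3 kernels, 1x1 zero
#' padding, two residual blocks per branch, ternary output.
#'
#' @param mode \code{"both"} (two branches), \code{"present_only"} or
#'   \code{"ancient_only"} (independently trained single-branch ablations).
#' @param nFilters convolution filters (default 64).
#' @param kernel kernel size (default c(3, 3)).
#' @param padding zero padding (default c(1, 1)).
#' @param nResidualBlocks residual blocks per branch (default 2).
#' @param embeddingDim per-branch embedding length (default 64).
#' @param dropout dropout rate before the dense head (default 0.25).
#' @param variant \code{"residual2d"} (default) or \code{"exchangeable"}
#'   (row-shared 1-D convolutions with a mean reduction over the haplotype
#'   axis before residual 1-D convolutions on the pooled frequency map).
#' @export
NetworkSpec <- function(mode = "both", nFilters = 64, kernel = c(3, 3),
                        padding = c(1, 1), nResidualBlocks = 2,
                        embeddingDim = 64, dropout = 0.25,
                        variant = "residual2d") {
  new("NetworkSpec", mode = mode, nFilters = nFilters, kernel = kernel,
      padding = padding, nResidualBlocks = nResidualBlocks,
      embeddingDim = embeddingDim, nClasses = 3, dropout = dropout,
      variant = variant)
}

# Width/height after the pools between residual blocks (R-1 pools).
.branchOutWidth <- function(w, nBlocks) {
  if (nBlocks > 1) for (i in seq_len(nBlocks - 1)) w <- w %/% 2
  w
}

.initMat <- function(nr, nc, sd) matrix(rnorm(nr * nc, sd = sd), nr, nc)

#' Build a two-branch (or single-branch) residual convolutional classifier
#'
#' Each branch: an input convolution, then \code{nResidualBlocks} residual
#' blocks (y = x + relu(conv(x))) with 2x2 max-pooling between consecutive
#' blocks, a mean reduction over the haplotype axis, and a dense ReLU
#' embedding. Branch embeddings are concatenated (or used alone in ablation
#' modes) and one dense layer produces the three class logits.
#'
#' @param spec a \code{\linkS4class{NetworkSpec}}.
#' @param shape list with \code{presentRows}, \code{ancientRows},
#'   \code{nTimes} and \code{width} describing the encoded inputs.
#' @param seed initialization seed; two builds with the same seed have
#'   identical parameters.
#' @return A \code{\linkS4class{TemporalNet}}.
#' @export
buildNetwork <- function(spec, shape, seed = 1) {
  stopifnot(is(spec, "NetworkSpec"))
  validObject(spec)
  need <- c("presentRows", "ancientRows", "nTimes", "width")
  if (!all(need %in% names(shape))) stop("shape must supply ", paste(need, collapse = ", "))
  set.seed(seed)
  F <- spec@nFilters; kh <- spec@kernel[1]; kw <- spec@kernel[2]
  E <- spec@embeddingDim; R <- spec@nResidualBlocks
  par <- list()
  exch <- spec@variant == "exchangeable"
  kh0 <- if (exch) 1L else kh   # exchangeable: row-shared 1-D kernels
  addBranch <- function(par, pre, cin, width) {
    par[[paste0(pre, "W0")]] <- .initMat(F, cin * kh0 * kw, sqrt(2 / (cin * kh0 * kw)))
    par[[paste0(pre, "b0")]] <- numeric(F)
    if (R > 0) for (r in seq_len(R)) {
      par[[paste0(pre, "W", r)]] <- .initMat(F, F * kh0 * kw, sqrt(2 / (F * kh0 * kw)))
      par[[paste0(pre, "b", r)]] <- numeric(F)
    }
    featLen <- F * (if (exch) width else .branchOutWidth(width, R))
    par[[paste0(pre, "Wd")]] <- .initMat(E, featLen, sqrt(2 / featLen))
    par[[paste0(pre, "bd")]] <- numeric(E)
    par
  }
  if (spec@mode %in% c("both", "present_only"))
    par <- addBranch(par, "p", 1L, shape$width)
  if (spec@mode %in% c("both", "ancient_only"))
    par <- addBranch(par, "a", shape$nTimes, shape$width)
  eTot <- if (spec@mode == "both") 2 * E else E
  par$hW <- .initMat(3, eTot, sqrt(1 / eTot))
  par$hb <- numeric(3)
  new("TemporalNet", spec = spec, shape = shape, params = par, seed = seed)
}

.relu <- function(x) { x[x < 0] <- 0; x }

.branchForward <- function(x, par, pre, spec) {
  if (spec@variant == "exchangeable") return(.branchForwardExch(x, par, pre, spec))
  kh <- spec@kernel[1]; kw <- spec@kernel[2]
  ph <- spec@padding[1]; pw <- spec@padding[2]
  R <- spec@nResidualBlocks
  x <- x - 0.5   # center the 0/1 alleles; padding stays neutral relative to He init
  cache <- list(x = x)
  z <- .convForwardCpp(x, par[[paste0(pre, "W0")]], par[[paste0(pre, "b0")]],
                       kh, kw, ph, pw)
  cache$mask0 <- z > 0
  h <- .relu(z)
  if (R > 0) for (r in seq_len(R)) {
    cache[[paste0("hin", r)]] <- h
    z <- .convForwardCpp(h, par[[paste0(pre, "W", r)]], par[[paste0(pre, "b", r)]],
                         kh, kw, ph, pw)
    cache[[paste0("mask", r)]] <- z > 0
    h <- h + .relu(z)
    if (r < R) {
      cache[[paste0("pdim", r)]] <- dim(h)
      mp <- .maxPoolForwardCpp(h)
      cache[[paste0("parg", r)]] <- mp$argmax
      h <- mp$y
    }
  }
  cache$hdim <- dim(h)
  m <- colMeans(h, dims = 1)                       # (W, F, B)
  flat <- m; dim(flat) <- c(prod(dim(m)[1:2]), dim(m)[3])
  cache$flat <- flat
  zd <- par[[paste0(pre, "Wd")]] %*% flat + par[[paste0(pre, "bd")]]
  cache$maskd <- zd > 0
  cache$emb <- .relu(zd)
  cache
}

# Exchangeable branch: a row-shared 1-D convolution embeds every haplotype
# row identically; the mean over the haplotype axis then yields a
# channel-resolved local-frequency map (1, W, F) on which residual 1-D
# convolutions operate. For the ancient tensor this exposes per-time-point
# column frequencies -- the allele-trajectory signal -- directly.
.branchForwardExch <- function(x, par, pre, spec) {
  kw <- spec@kernel[2]; pw <- spec@padding[2]
  R <- spec@nResidualBlocks
  x <- x - 0.5
  cache <- list(x = x, exch = TRUE)
  z <- .convForwardCpp(x, par[[paste0(pre, "W0")]], par[[paste0(pre, "b0")]],
                       1L, kw, 0L, pw)
  cache$mask0 <- z > 0
  h <- .relu(z)                                   # (H, W, F, B)
  cache$hdim <- dim(h)
  m <- colMeans(h, dims = 1)                      # (W, F, B)
  g <- m; dim(g) <- c(1, dim(m))                  # (1, W, F, B)
  if (R > 0) for (r in seq_len(R)) {
    cache[[paste0("hin", r)]] <- g
    z <- .convForwardCpp(g, par[[paste0(pre, "W", r)]], par[[paste0(pre, "b", r)]],
                         1L, kw, 0L, pw)
    cache[[paste0("mask", r)]] <- z > 0
    g <- g + .relu(z)
  }
  flat <- g; dim(flat) <- c(prod(dim(g)[1:3]), dim(g)[4])
  cache$flat <- flat
  zd <- par[[paste0(pre, "Wd")]] %*% flat + par[[paste0(pre, "bd")]]
  cache$maskd <- zd > 0
  cache$emb <- .relu(zd)
  cache
}

.branchBackwardExch <- function(dEmb, cache, par, pre, spec) {
  kw <- spec@kernel[2]; pw <- spec@padding[2]
  R <- spec@nResidualBlocks
  g <- list()
  dzd <- dEmb * cache$maskd
  g[[paste0(pre, "Wd")]] <- dzd %*% t(cache$flat)
  g[[paste0(pre, "bd")]] <- rowSums(dzd)
  dflat <- t(par[[paste0(pre, "Wd")]]) %*% dzd
  lastDim <- dim(cache[[if (R > 0) paste0("hin", R) else "x"]])
  dg <- dflat
  if (R > 0) {
    dim(dg) <- dim(cache$hin1)
  } else {
    dim(dg) <- c(1, cache$hdim[2], cache$hdim[3], cache$hdim[4])
  }
  if (R > 0) for (r in rev(seq_len(R))) {
    dz <- dg * cache[[paste0("mask", r)]]
    cb <- .convBackwardCpp(cache[[paste0("hin", r)]], par[[paste0(pre, "W", r)]],
                           dz, 1L, kw, 0L, pw)
    g[[paste0(pre, "W", r)]] <- cb$dw
    g[[paste0(pre, "b", r)]] <- cb$db
    dg <- dg + cb$dx
  }
  # back through the mean over the haplotype axis
  hd <- cache$hdim
  dm <- dg; dim(dm) <- hd[2:4]                    # (W, F, B)
  dh <- array(rep(dm, each = hd[1]) / hd[1], dim = hd)
  dz0 <- dh * cache$mask0
  cb0 <- .convBackwardCpp(cache$x, par[[paste0(pre, "W0")]], dz0, 1L, kw, 0L, pw)
  g[[paste0(pre, "W0")]] <- cb0$dw
  g[[paste0(pre, "b0")]] <- cb0$db
  g
}

.branchBackward <- function(dEmb, cache, par, pre, spec) {
  if (isTRUE(cache$exch)) return(.branchBackwardExch(dEmb, cache, par, pre, spec))
  kh <- spec@kernel[1]; kw <- spec@kernel[2]
  ph <- spec@padding[1]; pw <- spec@padding[2]
  R <- spec@nResidualBlocks
  g <- list()
  dzd <- dEmb * cache$maskd
  g[[paste0(pre, "Wd")]] <- dzd %*% t(cache$flat)
  g[[paste0(pre, "bd")]] <- rowSums(dzd)
  dflat <- t(par[[paste0(pre, "Wd")]]) %*% dzd
  hd <- cache$hdim
  dh <- array(rep(dflat, each = hd[1]) / hd[1], dim = hd)
  if (R > 0) for (r in rev(seq_len(R))) {
    if (r < R)
      dh <- .maxPoolBackwardCpp(dh, cache[[paste0("parg", r)]],
                                cache[[paste0("pdim", r)]])
    dz <- dh * cache[[paste0("mask", r)]]
    cb <- .convBackwardCpp(cache[[paste0("hin", r)]], par[[paste0(pre, "W", r)]],
                           dz, kh, kw, ph, pw)
    g[[paste0(pre, "W", r)]] <- cb$dw
    g[[paste0(pre, "b", r)]] <- cb$db
    dh <- dh + cb$dx
  }
  dz0 <- dh * cache$mask0
  cb0 <- .convBackwardCpp(cache$x, par[[paste0(pre, "W0")]], dz0, kh, kw, ph, pw)
  g[[paste0(pre, "W0")]] <- cb0$dw
  g[[paste0(pre, "b0")]] <- cb0$db
  g
}

.softmax <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# Full forward pass on a packed batch. silence: "none", "present", "ancient"
# (zero that branch's embedding before the head; mode "both" only).
.netForward <- function(model, batch, train = FALSE, dropMask = NULL,
                        silence = "none") {
  spec <- model@spec
  par <- model@params
  caches <- list()
  embs <- list()
  if (spec@mode %in% c("both", "present_only")) {
    caches$p <- .branchForward(batch$present, par, "p", spec)
    embs$p <- caches$p$emb
  }
  if (spec@mode %in% c("both", "ancient_only")) {
    caches$a <- .branchForward(batch$ancient, par, "a", spec)
    embs$a <- caches$a$emb
  }
  if (silence != "none") {
    if (spec@mode != "both") stop("branch silencing requires mode 'both'")
    if (silence == "present") embs$p <- embs$p * 0
    if (silence == "ancient") embs$a <- embs$a * 0
  }
  emb <- do.call(rbind, unname(embs))
  if (train && spec@dropout > 0) {
    if (is.null(dropMask))
      dropMask <- matrix(rbinom(length(emb), 1, 1 - spec@dropout), nrow(emb)) /
        (1 - spec@dropout)
    emb <- emb * dropMask
  }
  logits <- par$hW %*% emb + par$hb
  list(probs = .softmax(logits), emb = emb, caches = caches, dropMask = dropMask)
}

# Cross-entropy loss, accuracy and full gradient on a packed batch.
.lossGrads <- function(model, batch) {
  spec <- model@spec
  fw <- .netForward(model, batch, train = TRUE)
  B <- length(batch$y)
  P <- fw$probs
  Y <- matrix(0, 3, B); Y[cbind(batch$y, seq_len(B))] <- 1
  loss <- -mean(log(pmax(P[cbind(batch$y, seq_len(B))], 1e-12)))
  acc <- mean(max.col(t(P)) == batch$y)
  dlog <- (P - Y) / B
  g <- list(hW = dlog %*% t(fw$emb), hb = rowSums(dlog))
  dEmb <- t(model@params$hW) %*% dlog
  if (!is.null(fw$dropMask)) dEmb <- dEmb * fw$dropMask
  E <- spec@embeddingDim
  if (spec@mode == "both") {
    g <- c(g, .branchBackward(dEmb[seq_len(E), , drop = FALSE],
                              fw$caches$p, model@params, "p", spec))
    g <- c(g, .branchBackward(dEmb[E + seq_len(E), , drop = FALSE],
                              fw$caches$a, model@params, "a", spec))
  } else if (spec@mode == "present_only") {
    g <- c(g, .branchBackward(dEmb, fw$caches$p, model@params, "p", spec))
  } else {
    g <- c(g, .branchBackward(dEmb, fw$caches$a, model@params, "a", spec))
  }
  list(loss = loss, acc = acc, grads = g)
}

.sliceBatch <- function(data, idx) {
  list(present = data$present[, , , idx, drop = FALSE],
       ancient = data$ancient[, , , idx, drop = FALSE],
       y = data$y[idx])
}

#' Class probabilities for encoded samples
#'
#' Deterministic forward pass (no dropout). Accepts a packed dataset (from
#' \code{\link{packTensors}}), a list of \code{\linkS4class{FeatureTensor}}
#' objects, or a single one.
#'
#' @param model a \code{\linkS4class{TemporalNet}}.
#' @param data encoded input(s).
#' @param silence \code{"none"} (default), or \code{"present"} /
#'   \code{"ancient"} to zero that branch's embedding before the dense head
#'   (structural ablation check; mode \code{"both"} only).
#' @return Matrix of class probabilities, one row per sample, columns
#'   N, D0.25-like, D0.5-like in the dataset's label order.
#' @export
predictProb <- function(model, data, silence = "none") {
  stopifnot(is(model, "TemporalNet"))
  if (is(data, "FeatureTensor")) data <- list(data)
  if (is.list(data) && !is.null(data$present)) packed <- data
  else packed <- packTensors(data)
  fw <- .netForward(model, packed, train = FALSE, silence = silence)
  t(fw$probs)
}

#' @describeIn predictProb S4 predict method; returns class probabilities.
#' @param object a \code{\linkS4class{TemporalNet}}.
#' @param newdata encoded input(s).
#' @param ... passed to \code{predictProb}.
#' @export
setMethod("predict", "TemporalNet", function(object, newdata, ...) {
  predictProb(object, newdata, ...)
})

#' Serialize / restore a model checkpoint
#'
#' The checkpoint embeds the spec, input shape, seed and parameters.
#' @param model a \code{\linkS4class{TemporalNet}}.
#' @param path checkpoint file path.
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(spec = model@spec, shape = model@shape, params = model@params,
               seed = model@seed, package = "tempoSel"), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  x <- readRDS(path)
  new("TemporalNet", spec = x$spec, shape = x$shape, params = x$params, seed = x$seed)
}
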