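#' Write temporal samples in ms-style text format
#'
#' One `//` block per sample with `segsites:` and `positions:` lines
#' (positions as fractions of the locus, 6 decimals) and one 0/1 row per
#' haplotype, all sampling blocks concatenated oldest first. Block
#' boundaries, label and provenance travel in `#`-comment header lines, so
#' vanilla ms parsers still read the haplotypes. A sample-metadata TSV
#' (replicate_id, block_index, age_years, n_haplotypes, label, seed,
#' attempts) is written alongside.
#'
#' @param samples list of \code{\linkS4class{TemporalSample}} objects.
#' @param path output file; metadata goes to \code{metaPath}.
#' @param metaPath metadata TSV path (default \code{<path>.meta.tsv}).
#' @return \code{path}, invisibly.
#' @export
writeMsLike <- function(samples, path, metaPath = paste0(path, ".meta.tsv")) {
  if (is(samples, "TemporalSample")) samples <- list(samples)
  con <- file(path, "w")
  on.exit(close(con))
  meta <- list()
  writeLines("tempoSel ms-like haplotype output", con)
  writeLines("", con)
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    writeLines(sprintf("// replicate %d", i), con)
    writeLines(sprintf("# label: %s", s@label), con)
    writeLines(sprintf("# locus_length: %.10g", s@locusLength), con)
    writeLines(sprintf("# blocks: %s",
                       paste(sprintf("%g:%d", s@ages,
                                     vapply(s@blocks, nrow, integer(1))),
                             collapse = ";")), con)
    writeLines(sprintf("# focal_index: %d",
                       ifelse(is.na(s@focalIndex), 0L, s@focalIndex)), con)
    writeLines(sprintf("# seed: %d attempts: %d",
                       ifelse(is.na(s@provenance$seed), 0L, as.integer(s@provenance$seed)),
                       as.integer(s@provenance$attempts)), con)
    writeLines(sprintf("segsites: %d", length(s@positions)), con)
    writeLines(paste("positions:",
                     paste(sprintf("%.6f", s@positions / s@locusLength), collapse = " ")),
               con)
    for (b in s@blocks)
      writeLines(apply(b, 1, paste, collapse = ""), con)
    writeLines("", con)
    for (bi in seq_along(s@blocks))
      meta[[length(meta) + 1]] <- data.frame(
        replicate_id = i, block_index = bi, age_years = s@ages[bi],
        n_haplotypes = nrow(s@blocks[[bi]]), label = s@label,
        seed = ifelse(is.na(s@provenance$seed), NA_integer_, s@provenance$seed),
        attempts = s@provenance$attempts)
  }
  write.table(do.call(rbind, meta), metaPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read temporal samples from ms-style text
#'
#' Inverse of \code{\link{writeMsLike}}: write-then-read reproduces the
#' samples bit-exactly (positions carry the 6-decimal precision of the
#' positions line). Row counts are cross-checked against the metadata TSV.
#'
#' @param path ms-style file written by \code{\link{writeMsLike}}.
#' @param metaPath metadata TSV path (default \code{<path>.meta.tsv}).
#' @return List of \code{\linkS4class{TemporalSample}} objects.
#' @export
readMsLike <- function(path, metaPath = paste0(path, ".meta.tsv")) {
  lines <- readLines(path)
  meta <- read.delim(metaPath, sep = "\t", stringsAsFactors = FALSE)
  starts <- grep("^//", lines)
  out <- vector("list", length(starts))
  header <- function(block, key, rep) {
    ln <- grep(paste0("^# ", key, ":"), block, value = TRUE)
    if (!length(ln)) stop("format error: replicate ", rep, " missing '# ", key, ":' header")
    sub(paste0("^# ", key, ":\\s*"), "", ln[1])
  }
  for (r in seq_along(starts)) {
    end <- if (r < length(starts)) starts[r + 1] - 1 else length(lines)
    block <- lines[starts[r]:end]
    label <- header(block, "label", r)
    L <- as.numeric(header(block, "locus_length", r))
    bspec <- strsplit(strsplit(header(block, "blocks", r), ";")[[1]], ":")
    ages <- vapply(bspec, function(x) as.numeric(x[1]), numeric(1))
    ns <- vapply(bspec, function(x) as.integer(x[2]), integer(1))
    focal <- as.integer(header(block, "focal_index", r))
    sa <- strsplit(header(block, "seed", r), "\\s+attempts:\\s*")[[1]]
    segLine <- grep("^segsites:", block, value = TRUE)
    if (!length(segLine)) stop("format error: replicate ", r, " missing segsites line")
    S <- as.integer(sub("^segsites:\\s*", "", segLine[1]))
    pos <- if (S > 0) {
      pl <- grep("^positions:", block, value = TRUE)
      if (!length(pl)) stop("format error: replicate ", r, " missing positions line")
      as.numeric(strsplit(sub("^positions:\\s*", "", pl[1]), "\\s+")[[1]]) * L
    } else numeric()
    if (length(pos) != S) stop("format error: replicate ", r, " positions/segsites mismatch")
    hapLines <- block[grepl("^[01]+$", block)]
    bad <- block[grepl("^[01]", block) & !grepl("^[01]+$", block)]
    if (length(bad)) stop("format error: replicate ", r, " contains non-0/1 haplotype characters")
    if (S > 0 && length(hapLines) != sum(ns))
      stop("format error: replicate ", r, " truncated: expected ", sum(ns),
           " haplotype rows, found ", length(hapLines))
    mrows <- meta[meta$replicate_id == r, ]
    if (nrow(mrows) != length(ns) || any(mrows$n_haplotypes != ns))
      stop("format error: replicate ", r, " row counts disagree with metadata")
    blocks <- vector("list", length(ns))
    off <- 0
    for (bi in seq_along(ns)) {
      if (S > 0) {
        rows <- hapLines[off + seq_len(ns[bi])]
        if (any(nchar(rows) != S))
          stop("format error: replicate ", r, " block ", bi, " row width != segsites")
        m <- matrix(as.integer(unlist(strsplit(rows, ""), use.names = FALSE)),
                    nrow = ns[bi], byrow = TRUE)
      } else m <- matrix(integer(), nrow = ns[bi], ncol = 0)
      blocks[[bi]] <- m
      off <- off + ns[bi]
    }
    seedVal <- as.integer(sa[1])
    out[[r]] <- new("TemporalSample", ages = ages, blocks = blocks,
                    positions = pos, locusLength = L,
                    focalIndex = if (focal == 0) NA_integer_ else focal,
                    label = label,
                    provenance = list(seed = if (seedVal == 0) NA_integer_ else seedVal,
                                      attempts = as.integer(sa[2])))
  }
  out
}
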