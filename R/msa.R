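# Per-marker multiple alignment (deterministic center-star, or an external
# aligner command), gap-fraction column trimming, and concatenation into
# the supermatrix.

#' Align one marker across strains
#'
#' The built-in aligner is a deterministic center-star progressive
#' alignment: the center is the sequence maximizing the summed pairwise
#' global alignment scores against all others (ties broken by input
#' order); every other sequence is aligned to the center (global,
#' BLOSUM62 with X scored 0, affine 11/1) and the pairwise alignments are
#' merged with the usual once-a-gap-always-a-gap rule. All-X placeholder
#' sequences participate like ordinary sequences and stay all \{X, -\}
#' after alignment.
#'
#' Alternatively `alignerCmd` runs an external aligner: a shell command
#' template containing `{input}` and `{output}` placeholders for FASTA
#' paths (e.g. `"mafft --quiet {input} > {output}"`).
#'
#' @param seqs named character vector or [Biostrings::AAStringSet] mapping
#'   strain id to the marker's amino-acid sequence (placeholders included).
#' @param markerId marker identifier stored on the result.
#' @param alignerCmd optional external command template; NULL = built-in.
#' @return a [MarkerAlignment-class].
#' @export
alignMarker <- function(seqs, markerId = "marker", alignerCmd = NULL) {
  if (is.character(seqs)) seqs <- AAStringSet(seqs)
  if (length(seqs) < 2L)
    stop("alignMarker needs at least 2 sequences (marker ", markerId, ")")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique strain names")
  aln <- if (is.null(alignerCmd)) centerStarAlign(seqs)
         else externalAlign(seqs, alignerCmd, markerId)
  new("MarkerAlignment", markerId = markerId, aln = aln)
}

centerStarAlign <- function(seqs) {
  n <- length(seqs)
  mat <- blosum62X()
  sumScore <- numeric(n)
  for (i in seq_len(n - 1L)) {
    sc <- pairwiseAlignment(seqs[(i + 1L):n], seqs[[i]], type = "global",
                            substitutionMatrix = mat,
                            gapOpening = 11, gapExtension = 1,
                            scoreOnly = TRUE)
    sumScore[i] <- sumScore[i] + sum(sc)
    sumScore[(i + 1L):n] <- sumScore[(i + 1L):n] + sc
  }
  c0 <- which.max(sumScore)  # first index on ties = input order
  others <- setdiff(seq_len(n), c0)
  Lc <- width(seqs)[c0]

  # ins[[k]][i]: residues of sequence k inserted before center residue i
  # (slot Lc+1 = after the last residue); alignedChar[[k]][i]: the char
  # aligned to center residue i ('-' if deleted in k).
  al <- pairwiseAlignment(seqs[others], seqs[[c0]], type = "global",
                          substitutionMatrix = mat,
                          gapOpening = 11, gapExtension = 1)
  # fast aligned views clip terminal columns where one side has a gap;
  # reattach the clipped overhangs so both strings span both sequences
  apAll <- as.character(pattern(al))
  asAll <- as.character(subject(al))
  ps <- start(pattern(al)); pe <- end(pattern(al))
  ss <- start(subject(al)); se <- end(subject(al))
  pFull <- as.character(seqs[others])
  sFull <- as.character(seqs[[c0]])
  for (ki in seq_along(others)) {
    lead <- trail <- c("", "")
    if (ps[ki] > 1L)
      lead <- c(substr(pFull[ki], 1L, ps[ki] - 1L),
                strrep("-", ps[ki] - 1L))
    else if (ss[ki] > 1L)
      lead <- c(strrep("-", ss[ki] - 1L),
                substr(sFull, 1L, ss[ki] - 1L))
    if (pe[ki] < nchar(pFull[ki]))
      trail <- c(substr(pFull[ki], pe[ki] + 1L, nchar(pFull[ki])),
                 strrep("-", nchar(pFull[ki]) - pe[ki]))
    else if (se[ki] < nchar(sFull))
      trail <- c(strrep("-", nchar(sFull) - se[ki]),
                 substr(sFull, se[ki] + 1L, nchar(sFull)))
    apAll[ki] <- paste0(lead[1], apAll[ki], trail[1])
    asAll[ki] <- paste0(lead[2], asAll[ki], trail[2])
  }
  insChunks <- list(); alChars <- list()
  for (ki in seq_along(others)) {
    k <- others[ki]
    as <- strsplit(asAll[ki], "")[[1]]
    ap <- strsplit(apAll[ki], "")[[1]]
    resIdx <- which(as != "-")
    stopifnot(length(resIdx) == Lc)
    chunks <- character(Lc + 1L)
    chars <- character(Lc)
    prev <- 0L
    for (i in seq_len(Lc)) {
      if (resIdx[i] - prev > 1L)
        chunks[i] <- paste(ap[(prev + 1L):(resIdx[i] - 1L)], collapse = "")
      chars[i] <- ap[resIdx[i]]
      prev <- resIdx[i]
    }
    if (prev < length(ap))
      chunks[Lc + 1L] <- paste(ap[(prev + 1L):length(ap)], collapse = "")
    insChunks[[as.character(k)]] <- chunks
    alChars[[as.character(k)]] <- chars
  }
  masterIns <- integer(Lc + 1L)
  for (k in names(insChunks))
    masterIns <- pmax(masterIns, nchar(insChunks[[k]]))

  centerChars <- strsplit(as.character(seqs[[c0]]), "")[[1]]
  buildRow <- function(chunks, chars) {
    out <- character(0)
    for (i in seq_len(Lc)) {
      ins <- chunks[i]
      pad <- strrep("-", masterIns[i] - nchar(ins))
      out <- c(out, ins, pad, chars[i])
    }
    c(out, chunks[Lc + 1L],
      strrep("-", masterIns[Lc + 1L] - nchar(chunks[Lc + 1L])))
  }
  rows <- vector("list", n)
  rows[[c0]] <- paste(buildRow(character(Lc + 1L), centerChars),
                      collapse = "")
  for (k in others)
    rows[[k]] <- paste(buildRow(insChunks[[as.character(k)]],
                                alChars[[as.character(k)]]), collapse = "")
  AAStringSet(setNames(unlist(rows), names(seqs)))
}

externalAlign <- function(seqs, cmdTemplate, markerId) {
  fin <- tempfile(fileext = ".faa"); fout <- tempfile(fileext = ".afa")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeXStringSet(seqs, fin)
  cmd <- gsub("{output}", fout, gsub("{input}", fin, cmdTemplate,
                                     fixed = TRUE), fixed = TRUE)
  status <- system(cmd)
  if (status != 0L)
    stop("external aligner failed (exit ", status, ") for marker ",
         markerId)
  out <- tryCatch(readAAStringSet(fout), error = function(e)
    stop("external aligner produced unreadable output for marker ",
         markerId))
  names(out) <- sub("\\s.*$", "", names(out))
  if (!setequal(names(out), names(seqs)) ||
      length(unique(width(out))) != 1L)
    stop("external aligner output malformed for marker ", markerId)
  out[names(seqs)]
}

#' Remove gap-rich columns from a marker alignment
#'
#' Columns whose gap fraction (counting '-' only; X counts as a residue so
#' that placeholder columns survive and keep their pairwise-deletion
#' semantics) strictly exceeds `maxGapFraction` are removed. Trimming is
#' idempotent and never reorders rows.
#'
#' @param aln a [MarkerAlignment-class].
#' @param maxGapFraction maximum tolerated per-column gap fraction (0-1).
#' @return the trimmed [MarkerAlignment-class].
#' @export
trimAlignment <- function(aln, maxGapFraction = 0.9) {
  m <- as.matrix(alignedSeqs(aln))
  gapFrac <- colMeans(m == "-")
  keep <- gapFrac <= maxGapFraction
  if (!any(keep))
    stop("trimming removed every column of marker ", markerId(aln),
         "; consider raising maxGapFraction")
  rows <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  new("MarkerAlignment", markerId = markerId(aln),
      aln = AAStringSet(setNames(rows, names(alignedSeqs(aln)))))
}

#' Concatenate marker alignments into a supermatrix
#'
#' @param alignments list of [MarkerAlignment-class] objects in panel
#'   order; each must contain exactly the strains in `strainOrder`.
#' @param strainOrder character vector fixing the row order.
#' @return a [SuperMatrix-class] whose partition map records each marker's
#'   column range (0-based half-open, cumulative widths).
#' @export
concatenateAlignments <- function(alignments, strainOrder) {
  stopifnot(length(alignments) >= 1L)
  widths <- integer(length(alignments))
  pieces <- vector("list", length(alignments))
  ids <- character(length(alignments))
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    missing <- setdiff(strainOrder, names(alignedSeqs(a)))
    extra <- setdiff(names(alignedSeqs(a)), strainOrder)
    if (length(missing) || length(extra))
      stop("marker ", markerId(a), ": strain set mismatch (",
           if (length(missing)) paste("missing:",
                                      paste(missing, collapse = ",")),
           if (length(extra)) paste(" unexpected:",
                                    paste(extra, collapse = ",")), ")")
    pieces[[i]] <- as.character(alignedSeqs(a))[strainOrder]
    widths[i] <- alignmentWidth(a)
    ids[i] <- markerId(a)
  }
  rows <- do.call(paste0, pieces)
  ends <- cumsum(widths)
  part <- data.frame(marker_id = ids, start = c(0L, head(ends, -1L)),
                     end = ends, stringsAsFactors = FALSE)
  new("SuperMatrix", aln = AAStringSet(setNames(rows, strainOrder)),
      partition = part)
}

#' Extract one marker's alignment back out of a supermatrix
#'
#' @param sm a [SuperMatrix-class].
#' @param markerId which marker block to slice out.
#' @return the [MarkerAlignment-class] occupying that column range.
#' @export
sliceMarker <- function(sm, markerId) {
  p <- partitionMap(sm)
  i <- match(markerId, p$marker_id)
  if (is.na(i)) stop("marker ", markerId, " not in partition map")
  rows <- subseq(alignedSeqs(sm), start = p$start[i] + 1L, end = p$end[i])
  new("MarkerAlignment", markerId = markerId, aln = rows)
}

#' Write / read a supermatrix as aligned FASTA plus partition TSV
#'
#' @param sm a [SuperMatrix-class].
#' @param fastaFile aligned FASTA path.
#' @param partitionFile TSV path (marker_id, start, end; 0-based half-open).
#' @return invisibly the paths ([writeSuperMatrix()]) or the rebuilt
#'   [SuperMatrix-class] ([readSuperMatrix()]).
#' @export
writeSuperMatrix <- function(sm, fastaFile, partitionFile) {
  writeXStringSet(alignedSeqs(sm), fastaFile)
  write.table(partitionMap(sm), partitionFile, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(c(fastaFile, partitionFile))
}

#' @rdname writeSuperMatrix
#' @export
readSuperMatrix <- function(fastaFile, partitionFile = NULL) {
  aln <- readAAStringSet(fastaFile)
  names(aln) <- sub("\\s.*$", "", names(aln))
  part <- if (!is.null(partitionFile))
    read.delim(partitionFile, stringsAsFactors = FALSE)
  else data.frame(marker_id = "all", start = 0L,
                  end = unique(width(aln)), stringsAsFactors = FALSE)
  new("SuperMatrix", aln = aln, partition = part)
}
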