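# Translated marker search: six-frame translation of every contig, stop-free
# segments, 4-mer candidate seeding, then Smith-Waterman (BLOSUM62 with the
# X row/column zeroed so placeholders and fuzzy codons are score-neutral).

b62xCache <- new.env(parent = emptyenv())

blosum62X <- function() {
  if (is.null(b62xCache$mat)) {
    e <- new.env()
    data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    m["X", ] <- 0L
    m[, "X"] <- 0L
    b62xCache$mat <- m
  }
  b62xCache$mat
}

#' Translate a nucleotide sequence in all six reading frames
#'
#' Frames +1,+2,+3 translate the forward strand at offsets 0,1,2; frames
#' -1,-2,-3 translate the reverse complement at the same offsets. Stop
#' codons are emitted as '*'; any codon containing N (or another ambiguity)
#' is emitted as X. Incomplete terminal codons are dropped, so frame k has
#' floor((len - offset)/3) residues.
#'
#' @param seq a nucleotide string or [Biostrings::DNAString].
#' @return named character vector of the six translations, in the order
#'   `+1, +2, +3, -1, -2, -3`. An empty or too-short sequence yields empty
#'   frames with a warning.
#' @examples
#' translateSixFrames("ATGGCC")[["+1"]]  # "MA"
#' @export
translateSixFrames <- function(seq) {
  dna <- if (is(seq, "DNAString")) seq else DNAString(as.character(seq))
  rc <- reverseComplement(dna)
  frames <- setNames(character(6), c("+1","+2","+3","-1","-2","-3"))
  if (length(dna) < 3L) {
    warning("sequence shorter than one codon; returning empty frames",
            call. = FALSE)
    return(frames)
  }
  # the fuzzy-codon path is much slower; only take it when ambiguity
  # letters are actually present
  fuzzy <- length(setdiff(uniqueLetters(DNAStringSet(list(dna))),
                          c("A","C","G","T"))) > 0L
  one <- function(s, off) {
    n <- length(s) - off
    n <- n - n %% 3L
    if (n < 3L) return("")
    piece <- subseq(s, start = off + 1L, width = n)
    if (fuzzy)
      as.character(translate(piece, if.fuzzy.codon = "X",
                             no.init.codon = TRUE))
    else as.character(translate(piece, no.init.codon = TRUE))
  }
  for (off in 0:2) {
    frames[[off + 1L]] <- one(dna, off)
    frames[[off + 4L]] <- one(rc, off)
  }
  frames
}

# Split a translated frame at stop codons into stop-free segments.
# Returns data.frame(segment, aa_offset) where aa_offset is the 0-based
# position of the segment start within the frame.
stopFreeSegments <- function(frameAA, minLen = 5L) {
  if (!nzchar(frameAA)) return(data.frame(segment = character(),
                                          aa_offset = integer()))
  parts <- strsplit(frameAA, "*", fixed = TRUE)[[1]]
  offs <- cumsum(c(0L, nchar(parts) + 1L))[seq_along(parts)]
  keep <- nchar(parts) >= minLen
  data.frame(segment = parts[keep], aa_offset = offs[keep],
             stringsAsFactors = FALSE)
}

aaKmers <- function(s, k = 4L) {
  n <- nchar(s)
  if (n < k) return(character())
  unique(substring(s, 1:(n - k + 1L), k:n))
}

#' Locate panel markers in a genome by six-frame translated search
#'
#' Each contig is translated in all six frames and split into stop-free
#' segments; segments sharing a length-4 amino-acid word with a marker are
#' locally aligned to it (BLOSUM62, X scored 0 against everything, affine
#' gap open 11 / extend 1). For each marker the single best-scoring hit
#' across all segments is reported, provided its score and reference
#' coverage pass the acceptance thresholds. Because alignments live inside
#' stop-free segments, a reported hit never spans a stop codon; a marker
#' interrupted by an internal stop yields its best single segment.
#'
#' @param genome a [GenomeRecord-class].
#' @param panel a [MarkerPanel-class].
#' @param minScore minimum alignment score (substitution-matrix units).
#' @param minCoverage minimum fraction of the reference marker length that
#'   must be covered by the alignment.
#' @param seedLength amino-acid word length used for candidate seeding.
#' @return a data.frame of marker hits (at most one row per marker) with
#'   columns strain_id, marker_id, aa_sequence, score, identity_pct,
#'   coverage_frac, contig_id, start, end (0-based half-open, forward
#'   strand), strand, frame, is_placeholder. Markers without a qualifying
#'   hit are absent; use [fillMissingMarkers()] to add all-X placeholders.
#'   Ties on score break by contig id, then start, then '+' strand.
#' @export
findMarkerHits <- function(genome, panel, minScore = 50,
                           minCoverage = 0.5, seedLength = 4L) {
  stopifnot(is(genome, "GenomeRecord"), is(panel, "MarkerPanel"))
  refs <- referenceSeqs(panel)
  mids <- names(refs)

  # seed index: amino-acid word -> marker ids
  seedEnv <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(refs)) {
    for (km in aaKmers(as.character(refs[[i]]), seedLength)) {
      seedEnv[[km]] <- c(seedEnv[[km]], i)
    }
  }

  # enumerate stop-free segments over all contigs and frames
  segs <- list()
  for (ci in seq_along(contigs(genome))) {
    cid <- names(contigs(genome))[ci]
    clen <- width(contigs(genome))[ci]
    fr <- translateSixFrames(contigs(genome)[[ci]])
    for (fi in seq_along(fr)) {
      fname <- names(fr)[fi]
      sf <- stopFreeSegments(fr[[fi]])
      if (!nrow(sf)) next
      sf$contig_id <- cid
      sf$contig_len <- clen
      sf$strand <- substr(fname, 1, 1)
      sf$frame <- as.integer(substr(fname, 2, 2)) - 1L
      segs[[length(segs) + 1L]] <- sf
    }
  }
  if (!length(segs)) return(emptyHitTable())
  segs <- do.call(rbind, segs)

  # candidate (segment, marker) pairs by shared seed words
  candidates <- vector("list", length(refs))
  for (si in seq_len(nrow(segs))) {
    kms <- aaKmers(segs$segment[si], seedLength)
    if (!length(kms)) next
    hitIdx <- unique(unlist(mget(kms, envir = seedEnv,
                                 ifnotfound = list(NULL))))
    for (mi in hitIdx)
      candidates[[mi]] <- c(candidates[[mi]], si)
  }

  mat <- blosum62X()
  rows <- list()
  for (mi in seq_along(refs)) {
    segIdx <- candidates[[mi]]
    if (is.null(segIdx)) next
    refLen <- width(refs)[mi]
    al <- pairwiseAlignment(AAStringSet(segs$segment[segIdx]), refs[[mi]],
                            type = "local", substitutionMatrix = mat,
                            gapOpening = 11, gapExtension = 1)
    sc <- score(al)
    covs <- (end(subject(al)) - start(subject(al)) + 1L) / refLen
    ok <- which(sc >= minScore & covs >= minCoverage)
    if (!length(ok)) next
    pids <- pid(al, type = "PID1")
    patStart <- start(pattern(al))
    patEnd <- end(pattern(al))
    cand <- lapply(ok, function(k) {
      si <- segIdx[k]
      segStartAA <- segs$aa_offset[si] + patStart[k] - 1L # 0-based in frame
      segEndAA <- segs$aa_offset[si] + patEnd[k]          # half-open
      L <- segs$contig_len[si]; f <- segs$frame[si]
      if (segs$strand[si] == "+") {
        ntStart <- f + 3L * segStartAA
        ntEnd <- f + 3L * segEndAA
      } else {
        ntStart <- L - (f + 3L * segEndAA)
        ntEnd <- L - (f + 3L * segStartAA)
      }
      aaSeq <- substr(segs$segment[si], patStart[k], patEnd[k])
      data.frame(strain_id = strainId(genome), marker_id = mids[mi],
                 aa_sequence = aaSeq, score = sc[k],
                 identity_pct = pids[k],
                 coverage_frac = covs[k],
                 contig_id = segs$contig_id[si],
                 start = ntStart, end = ntEnd,
                 strand = segs$strand[si], frame = f,
                 is_placeholder = FALSE, stringsAsFactors = FALSE)
    })
    cand <- do.call(rbind, cand)
    ord <- order(-cand$score, cand$contig_id, cand$start,
                 cand$strand != "+")
    rows[[length(rows) + 1L]] <- cand[ord[1L], , drop = FALSE]
  }
  if (!length(rows)) return(emptyHitTable())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

emptyHitTable <- function() {
  data.frame(strain_id = character(), marker_id = character(),
             aa_sequence = character(), score = numeric(),
             identity_pct = numeric(), coverage_frac = numeric(),
             contig_id = character(), start = integer(), end = integer(),
             strand = character(), frame = integer(),
             is_placeholder = logical(), stringsAsFactors = FALSE)
}

#' Complete a hit list with all-X placeholder proteins
#'
#' Missing-data handling for the supermatrix: every panel marker absent
#' from the hit list is replaced by a placeholder sequence consisting
#' solely of X, of the reference marker's length, so that it carries no
#' signal under pairwise deletion downstream.
#'
#' @param hits a hit data.frame from [findMarkerHits()] (one strain).
#' @param panel the [MarkerPanel-class].
#' @param strainId strain identifier stamped onto placeholder rows.
#' @return a hit data.frame with exactly one row per panel marker, in
#'   panel order; `is_placeholder` marks the padded rows.
#' @export
fillMissingMarkers <- function(hits, panel, strainId) {
  if (anyDuplicated(hits$marker_id))
    stop("duplicate marker_id in hit list for strain ", strainId,
         " (upstream bug)")
  refs <- referenceSeqs(panel)
  rows <- lapply(seq_along(refs), function(i) {
    mid <- names(refs)[i]
    j <- which(hits$marker_id == mid)
    if (length(j) == 1L) return(hits[j, , drop = FALSE])
    data.frame(strain_id = strainId, marker_id = mid,
               aa_sequence = strrep("X", width(refs)[i]),
               score = NA_real_, identity_pct = NA_real_,
               coverage_frac = NA_real_, contig_id = NA_character_,
               start = NA_integer_, end = NA_integer_,
               strand = NA_character_, frame = NA_integer_,
               is_placeholder = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write per-strain marker hits as TSV and protein FASTA
#'
#' @param hits a completed hit table (see [fillMissingMarkers()]).
#' @param tsvFile,faaFile output paths; either may be NULL to skip.
#'   Coordinates in the TSV are 1-based inclusive (human-readable report);
#'   the in-memory representation stays 0-based half-open.
#' @return invisibly, the paths written.
#' @export
writeMarkerHits <- function(hits, tsvFile = NULL, faaFile = NULL) {
  if (!is.null(tsvFile)) {
    rep <- hits
    rep$start <- rep$start + 1L  # 1-based inclusive for reports
    write.table(rep, tsvFile, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(faaFile)) {
    seqs <- AAStringSet(setNames(hits$aa_sequence, hits$marker_id))
    writeXStringSet(seqs, faaFile)
  }
  invisible(c(tsvFile, faaFile))
}
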