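# Overall genome relatedness indices: a fragment-based ANI estimator for
# desk-scale genome pairs, ingestion of precomputed ANI/dDDH tables, and
# the species-synonymy decision rule (ANI >= 95 screen, 96% species
# cut-off, dDDH 70% rule). dDDH is consumed, never computed.

#' Estimate average nucleotide identity between two genomes
#'
#' Fragment-based estimator: the query genome's contigs are cut into
#' non-overlapping windows of `fragLen` bp (the trailing partial window is
#' dropped); each fragment is placed on the subject genome by exact seed
#' words (both strands) and locally aligned to the candidate region.
#' Fragments are kept if their alignment identity is at least
#' `minFragIdentity` over at least `minFragAlnFrac` of the fragment
#' length; ANI is the mean identity of kept fragments. Symmetric mode
#' averages the two directions.
#'
#' This is a transparent stand-in for sketch-based whole-genome tools;
#' precomputed ANI values can always be supplied via [readOgriTable()]
#' instead.
#'
#' @param a,b [GenomeRecord-class] objects (query, subject).
#' @param fragLen fragment window length in bp.
#' @param minFragIdentity minimum fragment identity (fraction, 0-1).
#' @param minFragAlnFrac minimum aligned fraction of the fragment.
#' @param symmetric average a->b and b->a (default TRUE).
#' @param seedLength exact-match seed word length in bp.
#' @return one-row data.frame (an OGRI record): strain_a, strain_b,
#'   ani (percent or NA if no fragment aligned), aligned_fragment_count,
#'   dddh/dddh_ci_lo/dddh_ci_hi (NA; never computed), source = "computed".
#' @export
estimateAni <- function(a, b, fragLen = 1020L, minFragIdentity = 0.3,
                        minFragAlnFrac = 0.7, symmetric = TRUE,
                        seedLength = 16L) {
  stopifnot(is(a, "GenomeRecord"), is(b, "GenomeRecord"))
  fwd <- aniOneWay(a, b, fragLen, minFragIdentity, minFragAlnFrac,
                   seedLength)
  if (symmetric) {
    rev <- aniOneWay(b, a, fragLen, minFragIdentity, minFragAlnFrac,
                     seedLength)
    idents <- c(fwd$identities, rev$identities)
    count <- fwd$count + rev$count
  } else {
    idents <- fwd$identities
    count <- fwd$count
  }
  ani <- if (count > 0L) mean(idents) else {
    warning("no fragment of ", strainId(a), " aligned to ", strainId(b),
            "; pair not comparable", call. = FALSE)
    NA_real_
  }
  data.frame(strain_a = strainId(a), strain_b = strainId(b),
             ani = ani, aligned_fragment_count = count,
             dddh = NA_real_, dddh_ci_lo = NA_real_, dddh_ci_hi = NA_real_,
             source = "computed", stringsAsFactors = FALSE)
}

aniOneWay <- function(a, b, fragLen, minFragIdentity, minFragAlnFrac,
                      seedLength) {
  frags <- character()
  for (ci in seq_along(contigs(a))) {
    s <- contigs(a)[[ci]]
    nFull <- length(s) %/% fragLen
    if (nFull == 0L) next
    starts <- (seq_len(nFull) - 1L) * fragLen + 1L
    frags <- c(frags, vapply(starts, function(st)
      as.character(subseq(s, st, width = fragLen)), character(1)))
  }
  if (!length(frags)) return(list(identities = numeric(), count = 0L))

  subjFwd <- contigs(b)
  subjRev <- reverseComplement(subjFwd)
  # seed words at fixed offsets within each fragment
  nSeeds <- 8L
  offs <- unique(pmin(fragLen - seedLength + 1L,
                      floor(seq(1L, fragLen - seedLength + 1L,
                                length.out = nSeeds))))
  seedSeqs <- DNAStringSet(unlist(lapply(frags, function(f)
    substring(f, offs, offs + seedLength - 1L))))
  seedFrag <- rep(seq_along(frags), each = length(offs))
  seedOff <- rep(offs, times = length(frags))
  usable <- !grepl("N", as.character(seedSeqs))
  pd <- PDict(seedSeqs[usable])
  mapBack <- which(usable)

  pad <- 60L
  idents <- numeric(0)
  candidates <- vector("list", length(frags))
  for (strand in c("+", "-")) {
    subj <- if (strand == "+") subjFwd else subjRev
    for (ci in seq_along(subj)) {
      mm <- matchPDict(pd, subj[[ci]])
      cnt <- vapply(mm, length, integer(1))
      hit <- which(cnt > 0L)
      for (h in hit) {
        k <- mapBack[h]
        fi <- seedFrag[k]
        for (p in start(mm[[h]])) {
          st <- p - seedOff[k] + 1L
          candidates[[fi]] <- rbind(candidates[[fi]],
            data.frame(strand = strand, ci = ci, start = st,
                       stringsAsFactors = FALSE))
        }
      }
    }
  }
  subMat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                     mismatch = -3)
  count <- 0L
  for (fi in seq_along(frags)) {
    cand <- candidates[[fi]]
    if (is.null(cand)) next
    cand <- unique(cand)
    # cluster candidate placements that map to nearly the same window
    cand <- cand[order(cand$strand, cand$ci, cand$start), , drop = FALSE]
    keep <- c(TRUE, diff(cand$start) > fragLen / 2 |
                diff(as.integer(factor(cand$ci))) != 0 |
                cand$strand[-1] != cand$strand[-nrow(cand)])
    cand <- cand[keep, , drop = FALSE]
    best <- NULL
    for (r in seq_len(nrow(cand))) {
      subj <- if (cand$strand[r] == "+") subjFwd else subjRev
      s <- subj[[cand$ci[r]]]
      wst <- max(1L, cand$start[r] - pad)
      wen <- min(length(s), cand$start[r] + fragLen - 1L + pad)
      if (wen - wst + 1L < seedLength) next
      al <- pairwiseAlignment(DNAString(frags[fi]), subseq(s, wst, wen),
                              type = "local", substitutionMatrix = subMat,
                              gapOpening = 5, gapExtension = 2)
      if (is.null(best) || score(al) > best$score)
        best <- list(score = score(al), pid = pid(al, type = "PID1"),
                     alnFrac = (end(pattern(al)) - start(pattern(al)) +
                                  1L) / fragLen)
    }
    if (!is.null(best) && best$pid / 100 >= minFragIdentity &&
        best$alnFrac >= minFragAlnFrac) {
      idents <- c(idents, best$pid)
      count <- count + 1L
    }
  }
  list(identities = idents, count = count)
}

#' Read a precomputed OGRI table
#'
#' TSV columns: strain_a, strain_b, ani, and optionally dddh, dddh_ci_lo,
#' dddh_ci_hi. Values are percentages in [0, 100]; dDDH confidence
#' intervals must bracket the dDDH value.
#'
#' @param file TSV path.
#' @return data.frame of OGRI records with `source = "table"`.
#' @export
readOgriTable <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("strain_a", "strain_b", "ani") %in% names(df)))
    stop("OGRI table needs columns strain_a, strain_b, ani")
  for (col in c("dddh", "dddh_ci_lo", "dddh_ci_hi"))
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  key <- pairKey(df$strain_a, df$strain_b)
  if (anyDuplicated(key)) stop("duplicate strain pair in OGRI table")
  bad <- with(df, (!is.na(ani) & (ani < 0 | ani > 100)) |
                (!is.na(dddh) & (dddh < 0 | dddh > 100)))
  if (any(bad)) stop("ANI/dDDH values must lie in [0, 100]")
  ciBad <- with(df, !is.na(dddh) & !is.na(dddh_ci_lo) & !is.na(dddh_ci_hi) &
                  (dddh_ci_lo > dddh | dddh > dddh_ci_hi))
  if (any(ciBad)) stop("dDDH confidence interval must bracket the value")
  df$source <- "table"
  df
}

pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Default thresholds for the synonymy decision rule
#'
#' @param aniScreen ANI screening threshold (pairs below it are distinct).
#' @param aniSpecies ANI species cut-off.
#' @param dddh dDDH same-species threshold.
#' @return named numeric vector of thresholds (percent).
#' @export
synonymyThresholds <- function(aniScreen = 95, aniSpecies = 96,
                               dddh = 70) {
  c(ani_screen = aniScreen, ani_species = aniSpecies, dddh = dddh)
}

#' Classify one strain pair as synonym / distinct / needs_dddh / conflict
#'
#' Decision rule, applied in order: (1) ANI below the screen threshold ->
#' distinct; (2) ANI at or above the screen but no dDDH available ->
#' needs_dddh; (3) dDDH >= 70 and ANI above the species cut-off ->
#' synonym; (4) dDDH < 70 -> distinct; (5) dDDH >= 70 but ANI at or below
#' the species cut-off -> conflict (flagged for manual review; the rule
#' never resolves this silently). Every call carries an ordered rule
#' trace recording each comparison.
#'
#' @param record one OGRI record (row with ani, dddh columns).
#' @param thresholds output of [synonymyThresholds()].
#' @return one-row data.frame: strain_a, strain_b, ani, dddh, verdict,
#'   rule_trace (semicolon-separated comparisons).
#' @export
classifyPair <- function(record, thresholds = synonymyThresholds()) {
  ani <- record$ani
  dddh <- record$dddh
  if (is.na(ani)) stop("classifyPair requires a present ANI value")
  trace <- character()
  step <- function(name, value, cmp, outcome)
    sprintf("%s=%.4g %s -> %s", name, value, cmp, outcome)
  verdict <- NULL
  if (ani < thresholds[["ani_screen"]]) {
    trace <- c(trace, step("ani", ani,
                           paste0("<", thresholds[["ani_screen"]]),
                           "distinct"))
    verdict <- "distinct"
  } else {
    trace <- c(trace, step("ani", ani,
                           paste0(">=", thresholds[["ani_screen"]]),
                           "screened"))
    if (is.na(dddh)) {
      trace <- c(trace, "dddh=absent -> needs_dddh")
      verdict <- "needs_dddh"
    } else if (dddh >= thresholds[["dddh"]] &&
               ani > thresholds[["ani_species"]]) {
      trace <- c(trace,
                 step("dddh", dddh, paste0(">=", thresholds[["dddh"]]),
                      "same-species signal"),
                 step("ani", ani, paste0(">", thresholds[["ani_species"]]),
                      "synonym"))
      verdict <- "synonym"
    } else if (dddh < thresholds[["dddh"]]) {
      trace <- c(trace, step("dddh", dddh,
                             paste0("<", thresholds[["dddh"]]),
                             "distinct"))
      verdict <- "distinct"
    } else {
      trace <- c(trace,
                 step("dddh", dddh, paste0(">=", thresholds[["dddh"]]),
                      "same-species signal"),
                 step("ani", ani,
                      paste0("<=", thresholds[["ani_species"]]),
                      "conflict"))
      verdict <- "conflict"
    }
  }
  data.frame(strain_a = record$strain_a, strain_b = record$strain_b,
             ani = ani, dddh = dddh, verdict = verdict,
             rule_trace = paste(trace, collapse = "; "),
             stringsAsFactors = FALSE)
}

#' Screen pairs and produce a synonymy report
#'
#' Lists the pairs passing the ANI screen (>= `ani_screen`), classifies
#' each with [classifyPair()], orders them by descending ANI, and
#' summarises verdict counts.
#'
#' @param records data.frame of OGRI records ([readOgriTable()] or rows
#'   from [estimateAni()]).
#' @param thresholds output of [synonymyThresholds()].
#' @return list with elements `calls` (data.frame of screened pairs with
#'   verdicts, descending ANI), `counts` (named verdict counts),
#'   `screened` (number of screened pairs), and `thresholds`.
#' @export
synonymyReport <- function(records, thresholds = synonymyThresholds()) {
  if (!nrow(records))
    return(list(calls = data.frame(), counts = c(distinct = 0L,
                synonym = 0L, needs_dddh = 0L, conflict = 0L),
                screened = 0L, thresholds = thresholds))
  if (anyDuplicated(pairKey(records$strain_a, records$strain_b)))
    stop("duplicate strain pair in records")
  screened <- records[!is.na(records$ani) &
                        records$ani >= thresholds[["ani_screen"]], ,
                      drop = FALSE]
  calls <- do.call(rbind, lapply(seq_len(nrow(screened)), function(i)
    classifyPair(screened[i, , drop = FALSE], thresholds)))
  if (is.null(calls)) calls <- data.frame()
  else calls <- calls[order(-calls$ani, calls$strain_a), , drop = FALSE]
  counts <- c(distinct = 0L, synonym = 0L, needs_dddh = 0L, conflict = 0L)
  if (nrow(calls)) {
    tb <- table(calls$verdict)
    counts[names(tb)] <- as.integer(tb)
  }
  rownames(calls) <- NULL
  list(calls = calls, counts = counts, screened = nrow(screened),
       thresholds = thresholds)
}

#' Write a synonymy report as TSV with a threshold header
#'
#' @param report output of [synonymyReport()].
#' @param file output path.
#' @return invisibly, the path.
#' @export
writeSynonymyReport <- function(report, file) {
  con <- file(file, "w")
  on.exit(close(con))
  th <- report$thresholds
  writeLines(c(
    sprintf("# synonymy report: ani_screen=%g ani_species=%g dddh=%g",
            th[["ani_screen"]], th[["ani_species"]], th[["dddh"]]),
    sprintf("# screened_pairs=%d %s", report$screened,
            paste(sprintf("%s=%d", names(report$counts), report$counts),
                  collapse = " "))), con)
  if (nrow(report$calls))
    write.table(report$calls, con, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(file)
}
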