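# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately naive (per-column double loops, exhaustive
# enumeration) so they stay independent of the implementation paths they
# check.

# per-column brute-force identity under pairwise deletion
naivePairwiseIdentity <- function(a, b, missing = c("-", "X")) {
  va <- strsplit(toupper(a), "")[[1]]
  vb <- strsplit(toupper(b), "")[[1]]
  matches <- 0L; compared <- 0L
  for (i in seq_along(va)) {
    if (va[i] %in% missing || vb[i] %in% missing) next
    compared <- compared + 1L
    if (va[i] == vb[i]) matches <- matches + 1L
  }
  c(matches = matches, compared = compared)
}

naiveCpaaiMatrix <- function(rows, missing = c("-", "X")) {
  n <- length(rows)
  out <- matrix(100, n, n, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    mc <- naivePairwiseIdentity(rows[[i]], rows[[j]], missing)
    out[i, j] <- out[j, i] <- 100 * mc[["matches"]] / mc[["compared"]]
  }
  out
}

# brute-force monophyly: a leaf set is monophyletic iff it equals the tip
# set of some node (clade) of the rooted tree
bruteForceMonophyletic <- function(tree, leaves) {
  ntip <- ape::Ntip(tree)
  cladeSets <- c(as.list(tree$tip.label),
                 lapply((ntip + 1L):(ntip + tree$Nnode), function(nd)
                   ape::extract.clade(tree, nd)$tip.label))
  any(vapply(cladeSets, setequal, logical(1), y = leaves))
}

# sum-of-pairs score of a set of aligned rows: BLOSUM62 with X scored 0,
# gap-vs-residue -2, gap-vs-gap 0 (a simple linear-gap SP criterion)
sumOfPairsScore <- function(rows) {
  e <- new.env(); data("BLOSUM62", package = "Biostrings", envir = e)
  mat <- e$BLOSUM62; mat["X", ] <- 0; mat[, "X"] <- 0
  chars <- lapply(rows, function(r) strsplit(r, "")[[1]])
  L <- length(chars[[1]])
  total <- 0
  for (i in seq_along(chars)) for (j in seq_along(chars)) {
    if (j <= i) next
    for (p in seq_len(L)) {
      a <- chars[[i]][p]; b <- chars[[j]][p]
      total <- total +
        if (a == "-" && b == "-") 0
        else if (a == "-" || b == "-") -2
        else mat[a, b]
    }
  }
  total
}

rightPadAlignment <- function(seqs) {
  w <- max(nchar(seqs))
  vapply(seqs, function(s) paste0(s, strrep("-", w - nchar(s))),
         character(1))
}

# supermatrix straight from evolved (indel-free) marker sets
supermatrixFromMarkers <- function(leafMarkers, placeholders = NULL) {
  strains <- names(leafMarkers)
  mids <- names(leafMarkers[[1]])
  alns <- lapply(mids, function(mid) {
    seqs <- vapply(leafMarkers, `[[`, character(1), mid)
    if (!is.null(placeholders)) {
      for (s in names(placeholders))
        if (mid %in% placeholders[[s]])
          seqs[[s]] <- strrep("X", nchar(seqs[[s]]))
    }
    alignMarker(setNames(seqs, strains), markerId = mid)
  })
  concatenateAlignments(alns, strains)
}

fixtureOgriPath <- function() {
  system.file("extdata", "rhizobiaceae_type_strain_ogri.tsv",
              package = "cpaaiDelimit")
}
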