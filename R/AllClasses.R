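#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet AAString AAStringSet
#'   readDNAStringSet readAAStringSet readBStringSet writeXStringSet
#'   translate reverseComplement pairwiseAlignment pid nmatch
#'   alignedPattern alignedSubject pattern subject
#'   nucleotideSubstitutionMatrix
#'   subseq uniqueLetters GENETIC_CODE PDict matchPDict
#' @importFrom BiocGenerics start end width score
#' @importFrom stats runif rbinom setNames
#' @importFrom utils read.delim write.table head tail data
NULL

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

#' GenomeRecord: one strain's assembly plus taxonomic metadata
#'
#' Container for a (possibly multi-contig) nucleotide assembly of a single
#' strain, together with its current genus/species labels and nomenclatural
#' type flags. Contigs are restricted to the alphabet \{A,C,G,T,N\};
#' [readGenome()] maps any other IUPAC letter to N with a warning.
#'
#' @slot strainId unique strain identifier.
#' @slot contigs a [Biostrings::DNAStringSet] of contig sequences.
#' @slot genusLabel,speciesLabel current labels (may be empty strings).
#' @slot isTypeStrain,isTypeSpecies nomenclatural type flags.
#' @aliases GenomeRecord-class
#' @exportClass GenomeRecord
setClass("GenomeRecord",
  representation(strainId = "character", contigs = "DNAStringSet",
                 genusLabel = "character", speciesLabel = "character",
                 isTypeStrain = "logical", isTypeSpecies = "logical"))

setValidity("GenomeRecord", function(object) {
  msg <- character()
  if (length(object@strainId) != 1L || !nzchar(object@strainId))
    msg <- c(msg, "strainId must be a single non-empty string")
  if (length(object@contigs) == 0L || any(width(object@contigs) == 0L))
    msg <- c(msg, "contigs must be non-empty sequences")
  bad <- setdiff(uniqueLetters(object@contigs), c("A","C","G","T","N"))
  if (length(bad))
    msg <- c(msg, paste0("contigs contain letters outside {A,C,G,T,N}: ",
                         paste(bad, collapse = ",")))
  if (length(msg)) msg else TRUE
})

#' MarkerPanel: an ordered panel of reference marker proteins
#'
#' The panel order is fixed and defines the concatenation order of the
#' supermatrix. A panel of 170 Rhizobiaceae core proteins is the motivating
#' use case, but any protein panel is accepted.
#'
#' @slot sequences a named [Biostrings::AAStringSet]; names are marker ids.
#' @slot panelName free-text panel label.
#' @aliases MarkerPanel-class
#' @exportClass MarkerPanel
setClass("MarkerPanel",
  representation(sequences = "AAStringSet", panelName = "character"))

setValidity("MarkerPanel", function(object) {
  msg <- character()
  ids <- names(object@sequences)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    msg <- c(msg, "marker ids must be unique non-empty names")
  if (length(object@sequences) == 0L)
    msg <- c(msg, "panel must contain at least one marker")
  bad <- setdiff(uniqueLetters(object@sequences), AA20)
  if (length(bad))
    msg <- c(msg, paste0("reference markers must use the 20 amino-acid ",
                         "letters; found: ", paste(bad, collapse = ",")))
  if (length(msg)) msg else TRUE
})

#' MarkerAlignment: one marker aligned across strains
#'
#' @slot markerId marker identifier.
#' @slot aln a named [Biostrings::AAStringSet] of equal-width aligned rows
#'   ('-' gaps, possibly X); names are strain ids.
#' @aliases MarkerAlignment-class
#' @exportClass MarkerAlignment
setClass("MarkerAlignment",
  representation(markerId = "character", aln = "AAStringSet"))

setValidity("MarkerAlignment", function(object) {
  msg <- character()
  if (length(object@aln) == 0L) msg <- c(msg, "alignment has no rows")
  if (length(unique(width(object@aln))) > 1L)
    msg <- c(msg, "alignment rows must all have the same width")
  if (is.null(names(object@aln)) || anyDuplicated(names(object@aln)))
    msg <- c(msg, "every strain must appear exactly once")
  if (length(msg)) msg else TRUE
})

#' SuperMatrix: concatenated trimmed marker alignments
#'
#' The central alignment object: one aligned amino-acid row per strain plus
#' a partition map recording which column range each marker occupies
#' (0-based half-open, contiguous, in panel order).
#'
#' @slot aln named [Biostrings::AAStringSet], one equal-width row per strain.
#' @slot partition data.frame with columns marker_id, start, end.
#' @aliases SuperMatrix-class
#' @exportClass SuperMatrix
setClass("SuperMatrix",
  representation(aln = "AAStringSet", partition = "data.frame"))

setValidity("SuperMatrix", function(object) {
  msg <- character()
  w <- unique(width(object@aln))
  if (length(w) != 1L) return("rows must all have the same width")
  p <- object@partition
  if (!all(c("marker_id","start","end") %in% names(p)))
    msg <- c(msg, "partition needs columns marker_id, start, end")
  else {
    if (nrow(p) && (p$start[1] != 0L || p$end[nrow(p)] != w ||
        any(p$start[-1] != p$end[-nrow(p)])))
      msg <- c(msg, "partition ranges must be contiguous and cover [0, width)")
    if (anyDuplicated(p$marker_id)) msg <- c(msg, "duplicate marker in partition")
  }
  if (is.null(names(object@aln)) || anyDuplicated(names(object@aln)))
    msg <- c(msg, "strain ids must be unique row names")
  if (length(msg)) msg else TRUE
})

#' CpaaiMatrix: core-proteome average amino acid identity matrix
#'
#' Symmetric percent-identity matrix over strains computed from a
#' [SuperMatrix] under pairwise deletion, plus the per-pair count of
#' compared sites.
#'
#' @slot values symmetric numeric matrix of percent identity (0-100),
#'   diagonal 100, dimnames = strain ids.
#' @slot comparedSites symmetric integer matrix of compared-site counts.
#' @aliases CpaaiMatrix-class
#' @exportClass CpaaiMatrix
setClass("CpaaiMatrix",
  representation(values = "matrix", comparedSites = "matrix"))

setValidity("CpaaiMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!isTRUE(all.equal(v, t(v)))) msg <- c(msg, "values must be symmetric")
  if (any(v < 0 | v > 100)) msg <- c(msg, "values must lie in [0, 100]")
  if (any(abs(diag(v) - 100) > 1e-9)) msg <- c(msg, "diagonal must be 100")
  if (!identical(dim(v), dim(object@comparedSites)))
    msg <- c(msg, "values and comparedSites must have identical dimensions")
  if (is.null(rownames(v))) msg <- c(msg, "strain ids required as dimnames")
  if (length(msg)) msg else TRUE
})

#' GenusPartition: delimited genera with monophyly status
#'
#' Result of reconciling threshold clustering of a [CpaaiMatrix] with a
#' rooted phylogeny. Each cluster carries the threshold at which it was
#' formed, its monophyly status, and summary cpAAI evidence.
#'
#' @slot clusters data.frame with one row per cluster: cluster_id, members
#'   (comma-joined strain ids), n, threshold_used, is_monophyletic, status
#'   (resolved / raised_threshold / manual_review), min_within_cpaai,
#'   max_between_cpaai.
#' @slot strains data.frame mapping strain_id to cluster_id.
#' @aliases GenusPartition-class
#' @exportClass GenusPartition
setClass("GenusPartition",
  representation(clusters = "data.frame", strains = "data.frame"))

setValidity("GenusPartition", function(object) {
  cl <- object@clusters; st <- object@strains
  msg <- character()
  need <- c("cluster_id","members","n","threshold_used","is_monophyletic",
            "status")
  if (!all(need %in% names(cl)))
    msg <- c(msg, paste("clusters needs columns", paste(need, collapse=", ")))
  if (!all(c("strain_id","cluster_id") %in% names(st)))
    msg <- c(msg, "strains needs columns strain_id, cluster_id")
  else if (anyDuplicated(st$strain_id))
    msg <- c(msg, "clusters must partition the strain set (duplicate strain)")
  if (all(need %in% names(cl)) &&
      any(!cl$is_monophyletic & cl$status != "manual_review"))
    msg <- c(msg, "non-monophyletic clusters must have status manual_review")
  if (length(msg)) msg else TRUE
})
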