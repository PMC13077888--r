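#' Accessors for cpaaiDelimit classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object of one of the package's S4 classes.
#' @return the requested component (see individual methods).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("strainId", function(x) standardGeneric("strainId"))
#' @rdname accessors
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))
#' @rdname accessors
#' @export
setGeneric("genusLabel", function(x) standardGeneric("genusLabel"))
#' @rdname accessors
#' @export
setGeneric("speciesLabel", function(x) standardGeneric("speciesLabel"))
#' @rdname accessors
#' @export
setGeneric("isTypeStrain", function(x) standardGeneric("isTypeStrain"))
#' @rdname accessors
#' @export
setGeneric("isTypeSpecies", function(x) standardGeneric("isTypeSpecies"))
#' @rdname accessors
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))
#' @rdname accessors
#' @export
setGeneric("markerId", function(x) standardGeneric("markerId"))
#' @rdname accessors
#' @export
setGeneric("panelName", function(x) standardGeneric("panelName"))
#' @rdname accessors
#' @export
setGeneric("referenceSeqs", function(x) standardGeneric("referenceSeqs"))
#' @rdname accessors
#' @export
setGeneric("alignedSeqs", function(x) standardGeneric("alignedSeqs"))
#' @rdname accessors
#' @export
setGeneric("alignmentWidth", function(x) standardGeneric("alignmentWidth"))
#' @rdname accessors
#' @export
setGeneric("strainOrder", function(x) standardGeneric("strainOrder"))
#' @rdname accessors
#' @export
setGeneric("partitionMap", function(x) standardGeneric("partitionMap"))
#' @rdname accessors
#' @export
setGeneric("cpaaiValues", function(x) standardGeneric("cpaaiValues"))
#' @rdname accessors
#' @export
setGeneric("comparedSites", function(x) standardGeneric("comparedSites"))
#' @rdname accessors
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))
#' @rdname accessors
#' @export
setGeneric("strainClusters", function(x) standardGeneric("strainClusters"))

#' @rdname accessors
setMethod("strainId", "GenomeRecord", function(x) x@strainId)
#' @rdname accessors
setMethod("contigs", "GenomeRecord", function(x) x@contigs)
#' @rdname accessors
setMethod("genusLabel", "GenomeRecord", function(x) x@genusLabel)
#' @rdname accessors
setMethod("speciesLabel", "GenomeRecord", function(x) x@speciesLabel)
#' @rdname accessors
setMethod("isTypeStrain", "GenomeRecord", function(x) x@isTypeStrain)
#' @rdname accessors
setMethod("isTypeSpecies", "GenomeRecord", function(x) x@isTypeSpecies)

#' @rdname accessors
setMethod("markerIds", "MarkerPanel", function(x) names(x@sequences))
#' @rdname accessors
setMethod("panelName", "MarkerPanel", function(x) x@panelName)
#' @rdname accessors
setMethod("referenceSeqs", "MarkerPanel", function(x) x@sequences)

#' @rdname accessors
setMethod("markerId", "MarkerAlignment", function(x) x@markerId)
#' @rdname accessors
setMethod("alignedSeqs", "MarkerAlignment", function(x) x@aln)
#' @rdname accessors
setMethod("alignmentWidth", "MarkerAlignment",
          function(x) unique(width(x@aln)))
#' @rdname accessors
setMethod("strainOrder", "MarkerAlignment", function(x) names(x@aln))

#' @rdname accessors
setMethod("alignedSeqs", "SuperMatrix", function(x) x@aln)
#' @rdname accessors
setMethod("alignmentWidth", "SuperMatrix", function(x) unique(width(x@aln)))
#' @rdname accessors
setMethod("strainOrder", "SuperMatrix", function(x) names(x@aln))
#' @rdname accessors
setMethod("partitionMap", "SuperMatrix", function(x) x@partition)
#' @rdname accessors
setMethod("markerIds", "SuperMatrix", function(x) x@partition$marker_id)

#' @rdname accessors
setMethod("strainOrder", "CpaaiMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("cpaaiValues", "CpaaiMatrix", function(x) x@values)
#' @rdname accessors
setMethod("comparedSites", "CpaaiMatrix", function(x) x@comparedSites)

#' @rdname accessors
setMethod("clusterTable", "GenusPartition", function(x) x@clusters)
#' @rdname accessors
setMethod("strainClusters", "GenusPartition", function(x) x@strains)
#' @rdname accessors
setMethod("strainOrder", "GenusPartition", function(x) x@strains$strain_id)

setMethod("show", "GenomeRecord", function(object) {
  cat("GenomeRecord", object@strainId, "\n")
  cat(" ", length(object@contigs), "contig(s),",
      sum(width(object@contigs)), "bp total\n")
  lab <- trimws(paste(object@genusLabel, object@speciesLabel))
  if (nzchar(lab)) cat("  label:", lab,
      if (object@isTypeStrain) "[type strain]" else "",
      if (object@isTypeSpecies) "[type species]" else "", "\n")
})

setMethod("show", "MarkerPanel", function(object) {
  cat("MarkerPanel", object@panelName, "with", length(object@sequences),
      "markers (", sum(width(object@sequences)), "aa total )\n")
})

setMethod("show", "MarkerAlignment", function(object) {
  cat("MarkerAlignment", object@markerId, ":", length(object@aln),
      "strains x", unique(width(object@aln)), "columns\n")
})

setMethod("show", "SuperMatrix", function(object) {
  cat("SuperMatrix:", length(object@aln), "strains x",
      unique(width(object@aln)), "columns,",
      nrow(object@partition), "marker blocks\n")
})

setMethod("show", "CpaaiMatrix", function(object) {
  v <- object@values
  n <- nrow(v)
  off <- v[upper.tri(v)]
  cat("CpaaiMatrix:", n, "strains; off-diagonal cpAAI",
      if (length(off)) sprintf("%.2f-%.2f%%", min(off), max(off)) else "-",
      "\n")
})

setMethod("show", "GenusPartition", function(object) {
  cl <- object@clusters
  cat("GenusPartition:", nrow(cl), "clusters over",
      nrow(object@strains), "strains\n")
  cat("  status:", paste(sprintf("%s=%d", names(table(cl$status)),
                                 as.integer(table(cl$status))),
                         collapse = ", "), "\n")
})
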