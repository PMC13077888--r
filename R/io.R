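#' Construct a GenomeRecord
#'
#' @param strainId unique strain identifier.
#' @param contigs a [Biostrings::DNAStringSet], named character vector, or
#'   character vector of contig sequences.
#' @param genusLabel,speciesLabel current taxonomic labels ("" if none).
#' @param isTypeStrain,isTypeSpecies nomenclatural type flags.
#' @return a validated [GenomeRecord-class] object. Letters outside
#'   \{A,C,G,T,N\} are mapped to N with a warning.
#' @export
GenomeRecord <- function(strainId, contigs, genusLabel = "",
                         speciesLabel = "", isTypeStrain = FALSE,
                         isTypeSpecies = FALSE) {
  if (is.character(contigs)) {
    if (is.null(names(contigs)))
      names(contigs) <- paste0("contig", seq_along(contigs))
    contigs <- sanitizeNucleotides(contigs, strainId)
    contigs <- DNAStringSet(contigs)
  } else {
    contigs <- DNAStringSet(sanitizeNucleotides(as.character(contigs),
                                                strainId))
  }
  new("GenomeRecord", strainId = strainId, contigs = contigs,
      genusLabel = genusLabel, speciesLabel = speciesLabel,
      isTypeStrain = isTypeStrain, isTypeSpecies = isTypeSpecies)
}

sanitizeNucleotides <- function(x, strainId) {
  up <- toupper(x)
  cleaned <- gsub("[^ACGTN]", "N", up)
  changed <- sum(nchar(gsub("[ACGTN]", "", up)))
  if (changed > 0)
    warning(sprintf("%s: %d non-ACGTN letter(s) mapped to N",
                    strainId, changed), call. = FALSE)
  cleaned
}

#' Read a genome assembly from a nucleotide FASTA file
#'
#' Multi-record FASTA files are interpreted as multi-contig assemblies of a
#' single strain. Non-ACGTN letters are mapped to N with a warning.
#'
#' @param file path to a nucleotide FASTA file.
#' @param strainId strain id; defaults to the file name without extension.
#' @param metadata optional strain metadata data.frame as returned by
#'   [readStrainMetadata()]; labels and type flags are looked up by strain id.
#' @return a [GenomeRecord-class].
#' @export
readGenome <- function(file, strainId = NULL, metadata = NULL) {
  if (is.null(strainId))
    strainId <- sub("\\.(fa|fna|fasta)(\\.gz)?$", "", basename(file))
  raw <- readBStringSet(file)
  seqs <- as.character(raw)
  names(seqs) <- sub("\\s.*$", "", names(raw))
  genus <- species <- ""
  ts <- tsp <- FALSE
  if (!is.null(metadata)) {
    row <- metadata[metadata$strain_id == strainId, , drop = FALSE]
    if (nrow(row) == 1L) {
      genus <- row$genus; species <- row$species
      ts <- isTRUE(row$is_type_strain); tsp <- isTRUE(row$is_type_species)
    }
  }
  GenomeRecord(strainId, seqs, genusLabel = genus, speciesLabel = species,
               isTypeStrain = ts, isTypeSpecies = tsp)
}

#' Read a directory (or files) of genome FASTAs
#'
#' @param path a directory containing `.fa`/`.fna`/`.fasta` files, or a
#'   character vector of file paths.
#' @param metadata optional metadata data.frame (see [readStrainMetadata()]).
#' @return a named list of [GenomeRecord-class] objects.
#' @export
readGenomes <- function(path, metadata = NULL) {
  files <- if (length(path) == 1L && dir.exists(path))
    list.files(path, pattern = "\\.(fa|fna|fasta)(\\.gz)?$",
               full.names = TRUE)
  else path
  if (!length(files)) stop("no genome FASTA files found in ", path)
  gs <- lapply(sort(files), readGenome, metadata = metadata)
  names(gs) <- vapply(gs, strainId, character(1))
  if (anyDuplicated(names(gs))) stop("duplicate strain ids among genomes")
  gs
}

#' Construct or read a marker panel
#'
#' @param sequences a named [Biostrings::AAStringSet] or named character
#'   vector of reference marker proteins.
#' @param panelName free-text label for the panel.
#' @return a validated [MarkerPanel-class]; marker order is preserved and
#'   defines the supermatrix concatenation order.
#' @export
MarkerPanel <- function(sequences, panelName = "custom") {
  if (is.character(sequences)) sequences <- AAStringSet(sequences)
  new("MarkerPanel", sequences = sequences, panelName = panelName)
}

#' @param file path to a protein FASTA file (one record per marker).
#' @rdname MarkerPanel
#' @export
readMarkerPanel <- function(file, panelName = NULL) {
  if (is.null(panelName))
    panelName <- sub("\\.(fa|faa|fasta)(\\.gz)?$", "", basename(file))
  seqs <- readAAStringSet(file)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  MarkerPanel(seqs, panelName)
}

#' Read a strain metadata table
#'
#' Expected TSV columns: strain_id, genus, species, is_type_strain,
#' is_type_species (logicals as TRUE/FALSE or 1/0).
#'
#' @param file path to the TSV.
#' @return a data.frame with those five columns.
#' @export
readStrainMetadata <- function(file) {
  md <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("strain_id","genus","species","is_type_strain","is_type_species")
  if (!all(need %in% names(md)))
    stop("metadata must have columns ", paste(need, collapse = ", "))
  md$is_type_strain <- as.logical(md$is_type_strain)
  md$is_type_species <- as.logical(md$is_type_species)
  if (anyDuplicated(md$strain_id)) stop("duplicate strain_id in metadata")
  md
}
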