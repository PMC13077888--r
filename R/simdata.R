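# Synthetic data with known ground truth: ultrametric genus trees, marker
# proteins evolved by Poisson substitution with uniform replacement,
# genomes assembled by reverse translation with random placement, and
# site-wise genome mutation for ANI calibration.
#
# Under uniform replacement over the 20 amino-acid letters, two leaves at
# path length L and rate r have expected identity
#   exp(-r L) + (1 - exp(-r L)) / 20,
# which lets tests and simulations target a cpAAI value exactly. The
# package defaults (within-genus crown depth 0.044, between-genus depth
# 0.118, rate 1 per site per unit length) invert this formula to plant
# within-genus cpAAI of 92.0 and between-genus cpAAI of 80.0 percent.

#' Expected amino-acid identity at a given path length
#'
#' @param pathLength total tree path length between two leaves.
#' @param rate substitution rate per site per unit branch length.
#' @param alphabetSize number of states (20 for amino acids).
#' @return expected identity as a percentage.
#' @export
expectedIdentity <- function(pathLength, rate = 1,
                             alphabetSize = 20L) {
  p <- exp(-rate * pathLength)
  100 * (p + (1 - p) / alphabetSize)
}

#' Simulate an ultrametric tree with planted genus clades
#'
#' Leaves sit at height 0; each genus is a clade whose crown is at
#' `withinDepth`; all genus ancestors join at the root at `betweenDepth`.
#' Within each genus the join order and sub-crown join heights are
#' random. Every genus is monophyletic by construction and every
#' between-genus leaf pair is at path length `2 * betweenDepth`.
#'
#' @param nGenera number of genera (>= 1).
#' @param strainsPerGenus strains per genus (>= 1).
#' @param withinDepth genus crown height (> 0).
#' @param betweenDepth root height (> withinDepth).
#' @param seed RNG seed (sets the session RNG).
#' @return list with `tree` (rooted ultrametric `ape::phylo`, leaves
#'   "G<g>S<s>") and `genusAssignment` (named character vector
#'   strain -> genus "G<g>").
#' @export
simulateTree <- function(nGenera = 5L, strainsPerGenus = 4L,
                         withinDepth = 0.044, betweenDepth = 0.118,
                         seed = 1L) {
  if (nGenera < 1L || strainsPerGenus < 1L)
    stop("counts must be >= 1")
  if (withinDepth <= 0 || betweenDepth <= withinDepth)
    stop("need 0 < withinDepth < betweenDepth")
  set.seed(seed)
  genusNewick <- function(g) {
    labs <- sprintf("G%dS%d", g, seq_len(strainsPerGenus))
    if (strainsPerGenus == 1L)
      return(list(txt = labs, height = 0))
    nodes <- lapply(labs, function(l) list(txt = l, height = 0))
    k <- length(nodes)
    joins <- if (k > 2L) sort(runif(k - 2L, 0, withinDepth)) else numeric()
    joins <- c(joins, withinDepth)
    for (h in joins) {
      pick <- sort(sample.int(length(nodes), 2L))
      a <- nodes[[pick[1]]]; b <- nodes[[pick[2]]]
      merged <- list(txt = sprintf("(%s:%.8f,%s:%.8f)", a$txt,
                                   h - a$height, b$txt, h - b$height),
                     height = h)
      nodes[[pick[2]]] <- NULL
      nodes[[pick[1]]] <- merged
    }
    nodes[[1]]
  }
  parts <- vapply(seq_len(nGenera), function(g) {
    sub <- genusNewick(g)
    sprintf("%s:%.8f", sub$txt, betweenDepth - sub$height)
  }, character(1))
  txt <- paste0("(", paste(parts, collapse = ","), ");")
  tree <- ape::read.tree(text = txt)
  # resolve the root polytomy with zero-length edges so the tree is
  # binary-rooted; genus clades and leaf-to-leaf path lengths unchanged
  if (nGenera > 2L) tree <- ape::multi2di(tree, random = FALSE)
  leaves <- tree$tip.label
  assignment <- setNames(sub("S\\d+$", "", leaves), leaves)
  list(tree = tree, genusAssignment = assignment)
}

#' Evolve marker proteins down a tree
#'
#' Root sequences are i.i.d. uniform over the 20 amino-acid letters; along
#' each branch every site is hit by a Poisson substitution process at
#' `rate` per site per unit length, and a hit site is replaced by a
#' uniform draw from the full alphabet (so the identity decay follows
#' [expectedIdentity()]).
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param nMarkers panel size m.
#' @param markerLengths integer vector of marker lengths (recycled to m).
#' @param rate substitution rate per site per unit branch length.
#' @param seed RNG seed.
#' @return list with `panel` (a [MarkerPanel-class] built from the root
#'   sequences, marker ids "M001"...) and `leafMarkers` (named list:
#'   leaf -> named character vector of marker sequences).
#' @export
evolveMarkers <- function(tree, nMarkers = 170L, markerLengths = 250L,
                          rate = 1, seed = 1L) {
  if (nMarkers < 1L) stop("nMarkers must be >= 1")
  if (rate < 0) stop("rate must be >= 0")
  set.seed(seed)
  lens <- rep_len(as.integer(markerLengths), nMarkers)
  mids <- sprintf("M%03d", seq_len(nMarkers))
  totalLen <- sum(lens)
  rootSeq <- sample(AA20, totalLen, replace = TRUE)

  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  seqs <- vector("list", ntip + nnode)
  rootNode <- ntip + 1L
  seqs[[rootNode]] <- rootSeq
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    bl <- ord$edge.length[e]
    s <- seqs[[parent]]
    pHit <- 1 - exp(-rate * bl)
    hit <- which(runif(totalLen) < pHit)
    if (length(hit)) s[hit] <- sample(AA20, length(hit), replace = TRUE)
    seqs[[child]] <- s
  }
  breaks <- c(0L, cumsum(lens))
  splitMarkers <- function(s) {
    setNames(vapply(seq_len(nMarkers), function(i)
      paste(s[(breaks[i] + 1L):breaks[i + 1L]], collapse = ""),
      character(1)), mids)
  }
  leafMarkers <- setNames(lapply(seq_len(ntip), function(i)
    splitMarkers(seqs[[i]])), tree$tip.label)
  panel <- MarkerPanel(splitMarkers(rootSeq), panelName = "simulated")
  list(panel = panel, leafMarkers = leafMarkers)
}

codonTableCache <- new.env(parent = emptyenv())
codonsByAA <- function() {
  if (is.null(codonTableCache$tab)) {
    gc <- GENETIC_CODE
    codonTableCache$tab <- split(names(gc), gc)
  }
  codonTableCache$tab
}

#' Assemble synthetic genomes from marker protein sets
#'
#' Each retained marker is reverse-translated (uniform choice among
#' synonymous codons), placed on a random strand in random order,
#' separated by random intergenic spacers of i.i.d. bases. Dropped
#' markers (each marker independently with probability `dropout`) are
#' absent from the genome. The returned truth records every placement
#' (0-based half-open forward-strand coordinates) and every dropped
#' marker.
#'
#' @param leafMarkers named list strain -> named marker sequence vector
#'   (from [evolveMarkers()]).
#' @param spacerLenRange length-2 integer range of spacer lengths in bp.
#' @param dropout per-marker dropout probability q.
#' @param shuffle permute marker order within each genome.
#' @param seed RNG seed.
#' @return list with `genomes` (named list of [GenomeRecord-class], one
#'   contig each) and `truth` (list per strain: data.frame
#'   marker_locations with marker_id, contig, start, end, strand, and a
#'   character vector dropped).
#' @export
buildGenomes <- function(leafMarkers, spacerLenRange = c(200L, 400L),
                         dropout = 0, shuffle = TRUE, seed = 1L) {
  set.seed(seed)
  tab <- codonsByAA()
  revTranslate <- function(aa) {
    chars <- strsplit(aa, "")[[1]]
    paste(vapply(chars, function(a) {
      cods <- tab[[a]]
      cods[sample.int(length(cods), 1L)]
    }, character(1)), collapse = "")
  }
  genomes <- list()
  truth <- list()
  for (strain in names(leafMarkers)) {
    mk <- leafMarkers[[strain]]
    dropped <- names(mk)[runif(length(mk)) < dropout]
    kept <- setdiff(names(mk), dropped)
    ordKept <- if (shuffle) sample(kept) else kept
    spacer <- function() paste(sample(c("A","C","G","T"),
      sample(seq(spacerLenRange[1], spacerLenRange[2]), 1L),
      replace = TRUE), collapse = "")
    pieces <- character()
    locs <- list()
    pos <- 0L
    sp <- spacer(); pieces <- sp; pos <- nchar(sp)
    for (mid in ordKept) {
      cds <- revTranslate(mk[[mid]])
      strand <- sample(c("+", "-"), 1L)
      ins <- if (strand == "+") cds else
        as.character(reverseComplement(DNAString(cds)))
      locs[[mid]] <- data.frame(marker_id = mid, contig = "contig1",
                                start = pos, end = pos + nchar(ins),
                                strand = strand, stringsAsFactors = FALSE)
      pieces <- c(pieces, ins)
      pos <- pos + nchar(ins)
      sp <- spacer(); pieces <- c(pieces, sp); pos <- pos + nchar(sp)
    }
    seqStr <- paste(pieces, collapse = "")
    genomes[[strain]] <- GenomeRecord(strain,
                                      setNames(seqStr, "contig1"))
    locDf <- if (length(locs)) do.call(rbind, locs) else
      data.frame(marker_id = character(), contig = character(),
                 start = integer(), end = integer(), strand = character(),
                 stringsAsFactors = FALSE)
    rownames(locDf) <- NULL
    truth[[strain]] <- list(marker_locations = locDf, dropped = dropped)
  }
  list(genomes = genomes, truth = truth)
}

#' Mutate a genome site-wise (for ANI calibration)
#'
#' Every site is independently replaced, with probability `d`, by a
#' uniform draw from the three other bases, so expected nucleotide
#' identity to the original is exactly 1 - d.
#'
#' @param genome a [GenomeRecord-class].
#' @param d per-site substitution probability (0 <= d < 0.75).
#' @param seed RNG seed.
#' @param newId strain id for the mutated copy.
#' @return a mutated [GenomeRecord-class].
#' @export
mutateGenome <- function(genome, d, seed = 1L,
                         newId = paste0(strainId(genome), "_mut")) {
  if (d < 0 || d >= 0.75) stop("d must lie in [0, 0.75)")
  set.seed(seed)
  bases <- c("A","C","G","T")
  newContigs <- vapply(seq_along(contigs(genome)), function(ci) {
    chars <- strsplit(as.character(contigs(genome)[[ci]]), "")[[1]]
    hit <- which(runif(length(chars)) < d & chars %in% bases)
    if (length(hit))
      chars[hit] <- vapply(chars[hit], function(b)
        sample(setdiff(bases, b), 1L), character(1))
    paste(chars, collapse = "")
  }, character(1))
  names(newContigs) <- names(contigs(genome))
  GenomeRecord(newId, newContigs, genusLabel = genusLabel(genome),
               speciesLabel = speciesLabel(genome))
}

#' Generate a complete synthetic study bundle
#'
#' Convenience wrapper chaining [simulateTree()], [evolveMarkers()] and
#' [buildGenomes()] with one seed, and writing the bundle to disk if
#' `outDir` is given (genome FASTAs, panel FASTA, metadata TSV, true tree
#' newick, truth JSON).
#'
#' @param nGenera,strainsPerGenus,withinDepth,betweenDepth see
#'   [simulateTree()].
#' @param nMarkers,markerLengths,rate see [evolveMarkers()].
#' @param spacerLenRange,dropout,shuffle see [buildGenomes()].
#' @param seed master seed; stage seeds are derived from it.
#' @param outDir optional output directory.
#' @return list: tree, genusAssignment, panel, leafMarkers, genomes,
#'   truth, metadata (data.frame), seed.
#' @export
simulateDataset <- function(nGenera = 5L, strainsPerGenus = 4L,
                            withinDepth = 0.044, betweenDepth = 0.118,
                            nMarkers = 170L, markerLengths = 250L,
                            rate = 1, spacerLenRange = c(200L, 400L),
                            dropout = 0, shuffle = TRUE, seed = 1L,
                            outDir = NULL) {
  sim <- simulateTree(nGenera, strainsPerGenus, withinDepth,
                      betweenDepth, seed = seed)
  ev <- evolveMarkers(sim$tree, nMarkers, markerLengths, rate,
                      seed = seed + 1000L)
  bg <- buildGenomes(ev$leafMarkers, spacerLenRange, dropout, shuffle,
                     seed = seed + 2000L)
  metadata <- data.frame(
    strain_id = names(bg$genomes),
    genus = unname(sim$genusAssignment[names(bg$genomes)]),
    species = paste0("sp_", names(bg$genomes)),
    is_type_strain = TRUE,
    is_type_species = !duplicated(unname(
      sim$genusAssignment[names(bg$genomes)])),
    stringsAsFactors = FALSE)
  out <- list(tree = sim$tree, genusAssignment = sim$genusAssignment,
              panel = ev$panel, leafMarkers = ev$leafMarkers,
              genomes = bg$genomes, truth = bg$truth,
              metadata = metadata, seed = seed)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (s in names(bg$genomes))
      writeXStringSet(contigs(bg$genomes[[s]]),
                      file.path(outDir, paste0(s, ".fna")))
    writeXStringSet(referenceSeqs(ev$panel),
                    file.path(outDir, "panel.faa"))
    write.table(metadata, file.path(outDir, "metadata.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeTreeFile(sim$tree, file.path(outDir, "true_tree.nwk"))
    truthJson <- lapply(bg$truth, function(x)
      list(marker_locations = x$marker_locations, dropped = x$dropped))
    jsonlite::write_json(
      list(seed = seed,
           genus_assignment = as.list(sim$genusAssignment),
           truth = truthJson),
      file.path(outDir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}
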