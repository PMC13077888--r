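# Tree construction and interrogation: neighbor-joining on 100 - cpAAI,
# newick ingestion, outgroup rooting (clan-checked), and monophyly tests.
# Maximum-likelihood inference is deliberately not re-implemented: an
# externally built tree can be read with readTreeFile() and used by every
# downstream stage, which needs only topology and rooting.

#' Distance matrix for tree building
#'
#' @param cp a [CpaaiMatrix-class].
#' @return symmetric percent-difference matrix `100 - cpAAI` with zero
#'   diagonal, suitable for [njTree()].
#' @export
cpaaiDistance <- function(cp) {
  d <- 100 - cpaaiValues(cp)
  diag(d) <- 0
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (via [ape::nj()]); negative
#' branch lengths are clamped to zero with the total deficit reported as
#' a message. On additive distances the true tree (topology and branch
#' lengths) is recovered exactly.
#'
#' @param d symmetric numeric matrix with zero diagonal and non-negative
#'   entries (typically [cpaaiDistance()] output); n = 2 gives the single
#'   connecting edge split evenly across the two pendant branches.
#' @return an unrooted `ape::phylo` tree.
#' @export
njTree <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) stop("distance matrix needs strain ids")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distances must be non-negative")
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 strains")
  if (n == 2L) {
    txt <- sprintf("(%s:%g,%s:%g);", rownames(d)[1], d[1, 2] / 2,
                   rownames(d)[2], d[1, 2] / 2)
    return(ape::read.tree(text = txt))
  }
  t <- ape::nj(d)
  neg <- t$edge.length < 0
  if (any(neg)) {
    message(sprintf("njTree: clamped %d negative branch length(s); total deficit %.4g",
                    sum(neg), -sum(t$edge.length[neg])))
    t$edge.length[neg] <- 0
  }
  t
}

# All clans (one side of some edge) of a tree, as a list of leaf-name sets.
treeClans <- function(t) {
  labs <- t$tip.label
  pp <- ape::prop.part(t)
  clades <- lapply(pp, function(i) labs[i])
  clans <- c(clades, lapply(clades, function(s) setdiff(labs, s)),
             as.list(labs),
             lapply(labs, function(l) setdiff(labs, l)))
  unique(lapply(clans, sort))
}

#' Root a tree on the edge separating an outgroup
#'
#' Verifies that the outgroup is a clan (one side of some edge) of the
#' unrooted tree, then places the root at the midpoint of that edge.
#'
#' @param t an `ape::phylo` tree (rooted input is unrooted first).
#' @param outgroup character vector of leaf labels; must be a non-empty
#'   proper subset of the leaves and form a clan.
#' @return a rooted `ape::phylo` with the outgroup as one child of the
#'   root and the separating edge length split evenly.
#' @export
rootWithOutgroup <- function(t, outgroup) {
  labs <- t$tip.label
  if (!length(outgroup)) stop("outgroup must be non-empty")
  unknown <- setdiff(outgroup, labs)
  if (length(unknown))
    stop("outgroup leaves not in tree: ", paste(unknown, collapse = ", "))
  if (setequal(outgroup, labs))
    stop("outgroup must be a proper subset of the leaves")
  ut <- if (ape::is.rooted(t)) ape::unroot(t) else t
  og <- sort(unique(outgroup))
  if (!any(vapply(treeClans(ut), identical, logical(1), y = og)))
    stop("outgroup is not a clan of the tree: no edge induces the ",
         "bipartition {", paste(og, collapse = ","), "} | {",
         paste(setdiff(labs, og), collapse = ","), "}")
  # ensure the outgroup reads as a clade in the stored orientation
  anchor <- setdiff(labs, og)[1]
  ut <- ape::root(ut, outgroup = anchor, resolve.root = TRUE)
  ut <- ape::unroot(ut)
  rt <- ape::root(ut, outgroup = og, resolve.root = TRUE)
  # split the separating edge evenly across the two root children
  rootNode <- ape::Ntip(rt) + 1L
  childEdges <- which(rt$edge[, 1] == rootNode)
  if (length(childEdges) == 2L && !is.null(rt$edge.length)) {
    tot <- sum(rt$edge.length[childEdges])
    rt$edge.length[childEdges] <- tot / 2
  }
  rt
}

#' Test a leaf set for monophyly in a rooted tree
#'
#' @param t a rooted `ape::phylo`.
#' @param leaves non-empty character vector of leaf labels.
#' @return TRUE iff the set of leaves descending from the most recent
#'   common ancestor of `leaves` is exactly `leaves`. Singletons and the
#'   full leaf set are monophyletic by convention.
#' @export
isMonophyletic <- function(t, leaves) {
  if (!ape::is.rooted(t)) stop("isMonophyletic requires a rooted tree")
  labs <- t$tip.label
  if (!length(leaves)) stop("leaf set must be non-empty")
  unknown <- setdiff(leaves, labs)
  if (length(unknown))
    stop("unknown leaves: ", paste(unknown, collapse = ", "))
  leaves <- unique(leaves)
  if (length(leaves) == 1L || setequal(leaves, labs)) return(TRUE)
  mrca <- ape::getMRCA(t, leaves)
  under <- ape::extract.clade(t, mrca)$tip.label
  setequal(under, leaves)
}

#' Read / write trees in newick format
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()]; branch
#' lengths and node support labels round-trip.
#'
#' @param file newick file path.
#' @return [readTreeFile()]: an `ape::phylo`; [writeTreeFile()]: the path,
#'   invisibly.
#' @export
readTreeFile <- function(file) {
  t <- ape::read.tree(file)
  if (is.null(t)) stop("could not parse newick file ", file)
  t
}

#' @param t an `ape::phylo`.
#' @rdname readTreeFile
#' @export
writeTreeFile <- function(t, file) {
  ape::write.tree(t, file)
  invisible(file)
}

#' Plain-text sketch of a tree
#'
#' ASCII rendering of the topology for reports (no plotting device).
#'
#' @param t an `ape::phylo`.
#' @return character vector of lines.
#' @export
asciiTree <- function(t) {
  out <- character()
  recurse <- function(node, prefix, isLast) {
    ntip <- ape::Ntip(t)
    lab <- if (node <= ntip) t$tip.label[node] else "+"
    branch <- if (isLast) "`-- " else "|-- "
    out <<- c(out, paste0(prefix, branch, lab))
    kids <- t$edge[t$edge[, 1] == node, 2]
    childPrefix <- paste0(prefix, if (isLast) "    " else "|   ")
    for (i in seq_along(kids))
      recurse(kids[i], childPrefix, i == length(kids))
  }
  root <- ape::Ntip(t) + 1L
  out <- "root"
  kids <- t$edge[t$edge[, 1] == root, 2]
  for (i in seq_along(kids))
    recurse(kids[i], "", i == length(kids))
  out
}
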