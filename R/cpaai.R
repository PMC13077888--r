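# Core-proteome average amino acid identity: raw proportion of identical
# residues over the compared columns of the concatenated alignment, with
# pairwise deletion of missing data ('-' and X by default).

#' Pairwise identity between two aligned rows under pairwise deletion
#'
#' A column is compared iff neither row carries a missing character there;
#' by default the missing set is \{'-', 'X'\}, so that all-X placeholder
#' markers contribute no signal. Lowercase letters are normalized to
#' uppercase before comparison.
#'
#' @param rowA,rowB equal-length aligned strings.
#' @param missingChars characters treated as missing data.
#' @return named integer vector `c(matches, compared)`.
#' @examples
#' pairwiseIdentity("AC-DX", "ACEDD")  # 3 matches over 3 compared columns
#' @export
pairwiseIdentity <- function(rowA, rowB, missingChars = c("-", "X")) {
  a <- strsplit(toupper(rowA), "")[[1]]
  b <- strsplit(toupper(rowB), "")[[1]]
  if (length(a) != length(b))
    stop("aligned rows differ in length (", length(a), " vs ",
         length(b), ")")
  ok <- !(a %in% missingChars) & !(b %in% missingChars)
  c(matches = sum(a[ok] == b[ok]), compared = sum(ok))
}

#' Compute the cpAAI matrix from a supermatrix
#'
#' For every strain pair, cpAAI = 100 x matches / compared over the
#' columns where neither strain has missing data (pairwise deletion).
#' Equivalently 100 x (1 - p), where p is the proportion of differences
#' in the pairwise comparison of the concatenated alignment. The count of
#' compared sites is recorded per pair. Full precision is retained
#' internally; table writers round to 2 decimals.
#'
#' @param sm a [SuperMatrix-class] (>= 2 strains).
#' @param missingChars characters treated as missing data; default
#'   \{'-', 'X'\} so all-X gap proteins are neutral.
#' @return a [CpaaiMatrix-class].
#' @export
cpAAI <- function(sm, missingChars = c("-", "X")) {
  ids <- strainOrder(sm)
  n <- length(ids)
  if (n < 2L) stop("cpAAI needs at least 2 strains")
  m <- as.matrix(alignedSeqs(sm))
  m[] <- toupper(m)
  present <- !matrix(m %in% missingChars, nrow = n)
  vals <- matrix(100, n, n, dimnames = list(ids, ids))
  comp <- matrix(0L, n, n, dimnames = list(ids, ids))
  diag(comp) <- as.integer(rowSums(present))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- present[i, ] & present[j, ]
      compared <- sum(ok)
      if (compared == 0L)
        stop("no comparable sites between ", ids[i], " and ", ids[j],
             " (disjoint missing-data patterns)")
      matches <- sum(m[i, ok] == m[j, ok])
      vals[i, j] <- vals[j, i] <- 100 * matches / compared
      comp[i, j] <- comp[j, i] <- compared
    }
  }
  new("CpaaiMatrix", values = vals, comparedSites = comp)
}

#' Write a cpAAI matrix as square CSV and long TSV
#'
#' The square CSV has strain ids as header row/column and values rounded
#' to 2 decimals; the long TSV (a, b, cpaai, compared_sites) holds one row
#' per unordered pair.
#'
#' @param cp a [CpaaiMatrix-class].
#' @param csvFile,longFile output paths; either may be NULL to skip.
#' @return invisibly, the paths written.
#' @export
writeCpaai <- function(cp, csvFile = NULL, longFile = NULL) {
  v <- cpaaiValues(cp)
  if (!is.null(csvFile))
    write.csv(round(v, 2), csvFile, quote = FALSE)
  if (!is.null(longFile)) {
    ids <- strainOrder(cp)
    idx <- which(upper.tri(v), arr.ind = TRUE)
    long <- data.frame(a = ids[idx[, 1]], b = ids[idx[, 2]],
                       cpaai = round(v[idx], 2),
                       compared_sites = comparedSites(cp)[idx])
    long <- long[order(-long$cpaai, long$a, long$b), ]
    write.table(long, longFile, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(c(csvFile, longFile))
}

#' @param csvFile square CSV written by [writeCpaai()].
#' @rdname writeCpaai
#' @export
readCpaai <- function(csvFile) {
  df <- read.csv(csvFile, row.names = 1, check.names = FALSE)
  v <- as.matrix(df)
  v <- (v + t(v)) / 2  # guard against asymmetric rounding artefacts
  diag(v) <- 100
  new("CpaaiMatrix", values = v,
      comparedSites = matrix(NA_integer_, nrow(v), ncol(v),
                             dimnames = dimnames(v)))
}

#' @importFrom utils write.csv read.csv
NULL
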