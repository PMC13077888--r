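test_that("identical sequences align without gaps", {
  seqs <- c(a = "MKLVADEFGH", b = "MKLVADEFGH", c = "MKLVADEFGH")
  a <- alignMarker(seqs, "m")
  expect_identical(alignmentWidth(a), 10L)
  expect_identical(unname(as.character(alignedSeqs(a))), unname(seqs))
})

test_that("a 3-residue deletion produces exactly 3 gaps in the shorter row", {
  long <- "MKLVADEFGHIKWWNP"
  short <- paste0(substr(long, 1, 5), substr(long, 9, 16))
  a <- alignMarker(c(s1 = long, s2 = short), "m")
  rows <- as.character(alignedSeqs(a))
  expect_identical(nchar(rows[["s1"]]), nchar(rows[["s2"]]))
  expect_identical(lengths(gregexpr("-", rows[["s2"]]))[[1]], 3L)
  expect_false(grepl("-", rows[["s1"]]))
})

test_that("center-star beats naive right-padding on indel variants", {
  set.seed(7)
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  base <- paste(sample(aa, 60, TRUE), collapse = "")
  seqs <- vapply(1:5, function(i) {
    s <- strsplit(base, "")[[1]]
    if (i > 1) {
      cut <- sample(5:50, 1)
      s <- s[-(cut:(cut + sample(1:4, 1)))]
    }
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- paste0("s", 1:5)
  a <- alignMarker(seqs, "m")
  rows <- as.character(alignedSeqs(a))
  # round-trip: de-gapping recovers the inputs
  expect_identical(gsub("-", "", rows), seqs)
  expect_gte(sumOfPairsScore(rows),
             sumOfPairsScore(rightPadAlignment(seqs)))
})

test_that("placeholder rows stay all {X, -} after alignment", {
  seqs <- c(a = "MKLVADEFGH", b = "MKLVADWFGH", p = strrep("X", 10))
  rows <- as.character(alignedSeqs(alignMarker(seqs, "m")))
  expect_true(grepl("^[X-]+$", rows[["p"]]))
})

test_that("an external aligner can replace the built-in stage", {
  seqs <- c(a = "MKLVADEFGHIK", b = "MKLVDEFGHIK", c = "MKLVADEFGHIK")
  a <- alignMarker(seqs, "m", alignerCmd = "mafft --quiet {input} > {output}")
  rows <- as.character(alignedSeqs(a))
  expect_setequal(names(rows), names(seqs))
  expect_identical(gsub("-", "", toupper(rows))[names(seqs)],
                   seqs)
  expect_error(alignMarker(seqs, "m", alignerCmd = "false # {input} {output}"),
               "aligner")
})

test_that("gap-fraction trimming removes only gap-heavy columns", {
  noGap <- alignMarker(c(a = "MKLV", b = "MKLV"), "m")
  expect_identical(as.character(alignedSeqs(trimAlignment(noGap))),
                   as.character(alignedSeqs(noGap)))

  # 20 rows: column 1 has 19 gaps (0.95 > 0.9, removed), column 2 has 10
  # gaps (0.5, kept), remaining columns gapless
  rows <- c(paste0("M", "K", "LVAD"),
            vapply(2:20, function(i)
              paste0("-", if (i <= 11) "-" else "K", "LVAD"),
              character(1)))
  names(rows) <- paste0("s", 1:20)
  aln <- new("MarkerAlignment", markerId = "m",
             aln = Biostrings::AAStringSet(rows))
  tr <- trimAlignment(aln, maxGapFraction = 0.9)
  expect_identical(alignmentWidth(tr), 5L)
  expect_identical(substr(as.character(alignedSeqs(tr))[[1]], 1, 1), "K")
  # X is a residue for trimming purposes: an all-X column survives
  xcol <- new("MarkerAlignment", markerId = "x",
              aln = Biostrings::AAStringSet(c(a = "XMK", b = "XMK")))
  expect_identical(alignmentWidth(trimAlignment(xcol, 0.5)), 3L)
  # a column that is '-' in every row is removed at any threshold < 1
  gapcol <- new("MarkerAlignment", markerId = "g",
                aln = Biostrings::AAStringSet(c(a = "M-K", b = "M-K")))
  expect_identical(alignmentWidth(trimAlignment(gapcol, 0.99)), 2L)
  # trimming is idempotent
  expect_identical(as.character(alignedSeqs(trimAlignment(tr, 0.9))),
                   as.character(alignedSeqs(tr)))
  # refusing to delete the whole alignment
  allGap <- new("MarkerAlignment", markerId = "a",
                aln = Biostrings::AAStringSet(c(a = "--", b = "K-")))
  expect_error(trimAlignment(allGap, 0.4), "maxGapFraction")
})

test_that("concatenation builds cumulative partition maps and round-trips", {
  mk <- function(id, w) {
    set.seed(match(id, c("m1", "m2", "m3")) + 40)
    aa <- c("A","C","D","E","F","G","H","I","K","L")
    rows <- vapply(1:3, function(i)
      paste(sample(aa, w, TRUE), collapse = ""), character(1))
    new("MarkerAlignment", markerId = id,
        aln = Biostrings::AAStringSet(setNames(rows, c("sA","sB","sC"))))
  }
  alns <- list(mk("m1", 10), mk("m2", 7), mk("m3", 12))
  sm <- concatenateAlignments(alns, c("sA", "sB", "sC"))
  expect_identical(alignmentWidth(sm), 29L)
  pm <- partitionMap(sm)
  expect_identical(pm$marker_id, c("m1", "m2", "m3"))
  expect_identical(pm$start, c(0L, 10L, 17L))
  expect_identical(pm$end, c(10L, 17L, 29L))
  # slicing the supermatrix recovers each input alignment exactly
  for (a in alns)
    expect_identical(
      as.character(alignedSeqs(sliceMarker(sm, markerId(a)))),
      as.character(alignedSeqs(a)))
  # single alignment concatenates to itself
  sm1 <- concatenateAlignments(alns[1], c("sA", "sB", "sC"))
  expect_identical(as.character(alignedSeqs(sm1)),
                   as.character(alignedSeqs(alns[[1]])))
  # permuting strain order permutes rows only
  sm2 <- concatenateAlignments(alns, c("sC", "sA", "sB"))
  expect_identical(as.character(alignedSeqs(sm2))[c("sA","sB","sC")],
                   as.character(alignedSeqs(sm)))
  # a missing strain is an error naming marker and strain
  bad <- mk("m2", 7)
  bad@aln <- bad@aln[c("sA", "sB")]
  expect_error(concatenateAlignments(list(mk("m1", 10), bad),
                                     c("sA", "sB", "sC")), "m2.*sC")
})

test_that("supermatrix FASTA + partition files round-trip", {
  ds <- simulateDataset(nGenera = 2, strainsPerGenus = 2, nMarkers = 3,
                        markerLengths = 40, seed = 9)
  sm <- supermatrixFromMarkers(ds$leafMarkers)
  fa <- tempfile(fileext = ".faa"); pt <- tempfile(fileext = ".tsv")
  writeSuperMatrix(sm, fa, pt)
  sm2 <- readSuperMatrix(fa, pt)
  expect_identical(as.character(alignedSeqs(sm2)),
                   as.character(alignedSeqs(sm)))
  expect_equal(partitionMap(sm2), partitionMap(sm))
})
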