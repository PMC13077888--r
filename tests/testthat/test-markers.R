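test_that("six-frame translation follows the standard code", {
  fr <- translateSixFrames("ATGGCC")
  expect_identical(fr[["+1"]], "MA")
  expect_identical(translateSixFrames("GGCCAT")[["-1"]], "MA")
  expect_identical(translateSixFrames("ATGTAA")[["+1"]], "M*")
  # codons containing N are emitted as X, even when resolvable
  expect_identical(translateSixFrames("GGNATG")[["+1"]], "XM")
  # frame lengths are floor((len - offset) / 3)
  set.seed(5)
  s <- paste(sample(c("A","C","G","T"), 50, TRUE), collapse = "")
  fr <- translateSixFrames(s)
  for (off in 0:2) {
    expect_identical(nchar(fr[[off + 1L]]), (50L - off) %/% 3L)
    expect_identical(nchar(fr[[off + 4L]]), (50L - off) %/% 3L)
  }
  expect_warning(fr0 <- translateSixFrames("AT"), "empty")
  expect_true(all(fr0 == ""))
})

test_that("planted markers are recovered at their exact coordinates", {
  ds <- simulateDataset(nGenera = 2, strainsPerGenus = 2, nMarkers = 10,
                        markerLengths = 90, rate = 0, seed = 21)
  g <- ds$genomes[[1]]
  hits <- findMarkerHits(g, ds$panel)
  expect_identical(nrow(hits), 10L)
  expect_true(all(hits$identity_pct == 100))
  expect_true(all(hits$coverage_frac == 1))
  truth <- ds$truth[[strainId(g)]]$marker_locations
  m <- merge(hits, truth, by = "marker_id", suffixes = c("", ".t"))
  expect_identical(nrow(m), 10L)
  expect_identical(m$start, m$start.t)
  expect_identical(m$end, m$end.t)
  expect_identical(m$strand, m$strand.t)
  expect_true(any(m$strand == "-"))  # minus-strand placements exercised
  expect_false(any(grepl("*", hits$aa_sequence, fixed = TRUE)))
})

test_that("random genomes yield no marker hits", {
  panel <- evolveMarkers(simulateTree(2, 2, seed = 1)$tree,
                         nMarkers = 8, markerLengths = 110,
                         seed = 2)$panel
  for (seed in 1:5) {
    set.seed(seed)
    g <- GenomeRecord(paste0("rand", seed),
                      paste(sample(c("A","C","G","T"), 8000, TRUE),
                            collapse = ""))
    expect_identical(nrow(findMarkerHits(g, panel)), 0L)
  }
})

test_that("reverse-complementing contigs flips only strand and coordinates", {
  ds <- simulateDataset(nGenera = 2, strainsPerGenus = 2, nMarkers = 8,
                        markerLengths = 100, seed = 8)
  g <- ds$genomes[[1]]
  L <- sum(BiocGenerics::width(contigs(g)))
  rc <- GenomeRecord(strainId(g),
    setNames(as.character(Biostrings::reverseComplement(
      contigs(g)[[1]])), names(contigs(g))[1]))
  h1 <- findMarkerHits(g, ds$panel)
  h2 <- findMarkerHits(rc, ds$panel)
  h1 <- h1[order(h1$marker_id), ]; h2 <- h2[order(h2$marker_id), ]
  expect_identical(h1$marker_id, h2$marker_id)
  expect_identical(h1$aa_sequence, h2$aa_sequence)
  expect_equal(h1$score, h2$score)
  expect_equal(h1$identity_pct, h2$identity_pct)
  expect_true(all(h1$strand != h2$strand))
  expect_identical(h2$start, L - h1$end)
  expect_identical(h2$end, L - h1$start)
})

test_that("dropped markers are never reported and retained ones always are", {
  for (seed in 1:3) {
    ds <- simulateDataset(nGenera = 2, strainsPerGenus = 2, nMarkers = 12,
                          markerLengths = 90, dropout = 0.2, seed = seed)
    for (s in names(ds$genomes)) {
      hits <- findMarkerHits(ds$genomes[[s]], ds$panel)
      dropped <- ds$truth[[s]]$dropped
      kept <- setdiff(markerIds(ds$panel), dropped)
      expect_setequal(hits$marker_id, kept)
      full <- fillMissingMarkers(hits, ds$panel, s)
      # placeholder conservation: |hits| + |placeholders| = m
      expect_identical(nrow(full), 12L)
      expect_identical(sum(full$is_placeholder), length(dropped))
      expect_identical(full$marker_id, markerIds(ds$panel))
    }
  }
})

test_that("fillMissingMarkers pads with reference-length all-X rows", {
  ds <- simulateDataset(nGenera = 2, strainsPerGenus = 2, nMarkers = 5,
                        markerLengths = c(60, 70, 80, 90, 100), seed = 3)
  g <- ds$genomes[[1]]
  hits <- findMarkerHits(g, ds$panel)
  # complete set returned unchanged
  expect_identical(fillMissingMarkers(hits, ds$panel, strainId(g))$aa_sequence,
                   hits$aa_sequence)
  # drop two hits -> exactly two placeholders of the reference lengths
  part <- hits[-c(2, 4), ]
  full <- fillMissingMarkers(part, ds$panel, strainId(g))
  expect_identical(sum(full$is_placeholder), 2L)
  ph <- full[full$is_placeholder, ]
  refLens <- BiocGenerics::width(referenceSeqs(ds$panel))[c(2, 4)]
  expect_identical(nchar(ph$aa_sequence), refLens)
  expect_true(all(grepl("^X+$", ph$aa_sequence)))
  expect_true(all(is.na(ph$start)))
  # empty hit list -> all placeholders
  allPh <- fillMissingMarkers(hits[0, ], ds$panel, strainId(g))
  expect_true(all(allPh$is_placeholder))
  # duplicate marker ids are an upstream bug
  expect_error(fillMissingMarkers(rbind(hits, hits[1, ]), ds$panel,
                                  strainId(g)), "duplicate")
})

test_that("marker search is deterministic", {
  ds <- simulateDataset(nGenera = 2, strainsPerGenus = 2, nMarkers = 6,
                        markerLengths = 80, seed = 13)
  g <- ds$genomes[[2]]
  expect_identical(findMarkerHits(g, ds$panel), findMarkerHits(g, ds$panel))
})
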