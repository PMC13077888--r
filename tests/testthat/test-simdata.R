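test_that("simulated trees plant monophyletic genera at the right depths", {
  sim <- simulateTree(2, 2, withinDepth = 0.05, betweenDepth = 0.15,
                      seed = 1)
  expect_identical(ape::Ntip(sim$tree), 4L)
  for (g in c("G1", "G2"))
    expect_true(isMonophyletic(sim$tree,
      names(sim$genusAssignment)[sim$genusAssignment == g]))
  co <- ape::cophenetic.phylo(sim$tree)
  # between-genus pairs sit at 2 * betweenDepth exactly
  expect_equal(co["G1S1", "G2S1"], 0.30, tolerance = 1e-6)
  expect_lte(co["G1S1", "G1S2"], 0.10 + 1e-9)

  # identical seeds are byte-identical; different seeds differ
  expect_identical(ape::write.tree(simulateTree(3, 3, seed = 4)$tree),
                   ape::write.tree(simulateTree(3, 3, seed = 4)$tree))

  big <- simulateTree(5, 4, seed = 2)
  expect_identical(ape::Ntip(big$tree), 20L)
  for (g in paste0("G", 1:5))
    expect_true(isMonophyletic(big$tree,
      names(big$genusAssignment)[big$genusAssignment == g]))
  expect_error(simulateTree(2, 2, withinDepth = 0.2, betweenDepth = 0.1),
               "withinDepth")
})

test_that("marker evolution follows the uniform-replacement identity decay", {
  sim <- simulateTree(2, 1, withinDepth = 0.05, betweenDepth = 0.15,
                      seed = 2)
  # rate 0: all leaves identical, cpAAI = 100 everywhere
  ev0 <- evolveMarkers(sim$tree, nMarkers = 3, markerLengths = 60,
                       rate = 0, seed = 5)
  v0 <- cpaaiValues(cpAAI(supermatrixFromMarkers(ev0$leafMarkers)))
  expect_true(all(v0 == 100))

  # two leaves at path length 0.3, 10,000 sites: identity within 3
  # binomial standard errors of the closed form
  ev <- evolveMarkers(sim$tree, nMarkers = 10, markerLengths = 1000,
                      rate = 1, seed = 5)
  obs <- cpaaiValues(cpAAI(supermatrixFromMarkers(ev$leafMarkers)))[1, 2]
  expFrac <- expectedIdentity(0.3) / 100
  se <- sqrt(expFrac * (1 - expFrac) / 10000)
  expect_lt(abs(obs / 100 - expFrac), 3 * se)
})

test_that("dropout counts follow the binomial law", {
  sim <- simulateTree(5, 4, seed = 9)
  ev <- evolveMarkers(sim$tree, nMarkers = 170, markerLengths = 10,
                      rate = 1, seed = 9)
  bg <- buildGenomes(ev$leafMarkers, dropout = 0.02, seed = 9)
  nDropped <- sum(vapply(bg$truth, function(x) length(x$dropped),
                         integer(1)))
  # central 99% interval of Binomial(3400, 0.02)
  bounds <- qbinom(c(0.005, 0.995), 170 * 20, 0.02)
  expect_gte(nDropped, bounds[1])
  expect_lte(nDropped, bounds[2])
  # q = 0 keeps every marker; truth records every location
  bg0 <- buildGenomes(ev$leafMarkers, dropout = 0, seed = 9)
  expect_true(all(vapply(bg0$truth, function(x)
    nrow(x$marker_locations) == 170L, logical(1))))
})

test_that("genome assembly is deterministic and truth-consistent", {
  sim <- simulateTree(2, 2, seed = 3)
  ev <- evolveMarkers(sim$tree, nMarkers = 5, markerLengths = 50,
                      seed = 3)
  b1 <- buildGenomes(ev$leafMarkers, seed = 12)
  b2 <- buildGenomes(ev$leafMarkers, seed = 12)
  for (s in names(b1$genomes))
    expect_identical(as.character(contigs(b1$genomes[[s]])),
                     as.character(contigs(b2$genomes[[s]])))
  # the recorded location re-translates to the marker protein
  s <- names(b1$genomes)[1]
  loc <- b1$truth[[s]]$marker_locations[1, ]
  seg <- Biostrings::subseq(contigs(b1$genomes[[s]])[[loc$contig]],
                            loc$start + 1L, loc$end)
  if (loc$strand == "-") seg <- Biostrings::reverseComplement(seg)
  expect_identical(as.character(Biostrings::translate(seg,
                                                      no.init.codon = TRUE)),
                   unname(ev$leafMarkers[[s]][[loc$marker_id]]))
  # q = 1 gives pure spacer genomes
  bAll <- buildGenomes(ev$leafMarkers, dropout = 1, seed = 2)
  expect_true(all(vapply(bAll$truth, function(x)
    length(x$dropped) == 5L, logical(1))))
})

test_that("site-wise genome mutation hits the planted rate", {
  set.seed(6)
  g <- GenomeRecord("ref", paste(sample(c("A","C","G","T"), 50000, TRUE),
                                 collapse = ""))
  expect_identical(unname(as.character(contigs(mutateGenome(g, 0,
                                                            seed = 1)))),
                   unname(as.character(contigs(g))))
  mut <- mutateGenome(g, 0.05, seed = 2)
  a <- strsplit(as.character(contigs(g)[[1]]), "")[[1]]
  b <- strsplit(as.character(contigs(mut)[[1]]), "")[[1]]
  frac <- mean(a != b)
  se <- sqrt(0.05 * 0.95 / 50000)
  expect_lt(abs(frac - 0.05), 3 * se)
  expect_error(mutateGenome(g, 0.8), "0.75")
})

test_that("simulateDataset writes a complete bundle to disk", {
  outDir <- tempfile("bundle")
  ds <- simulateDataset(nGenera = 2, strainsPerGenus = 2, nMarkers = 3,
                        markerLengths = 40, seed = 5, outDir = outDir)
  expect_setequal(list.files(outDir),
                  c(paste0(names(ds$genomes), ".fna"), "panel.faa",
                    "metadata.tsv", "true_tree.nwk", "truth.json"))
  md <- readStrainMetadata(file.path(outDir, "metadata.tsv"))
  expect_setequal(md$strain_id, names(ds$genomes))
  expect_identical(sum(md$is_type_species), 2L)
  g <- readGenome(file.path(outDir, paste0(names(ds$genomes)[1], ".fna")),
                  metadata = md)
  expect_identical(as.character(contigs(g)),
                   as.character(contigs(ds$genomes[[1]])))
  truth <- jsonlite::read_json(file.path(outDir, "truth.json"))
  expect_identical(truth$seed, 5L)
})
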