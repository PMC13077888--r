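# End-to-end pipeline: marker extraction -> per-marker alignment ->
# trimming -> supermatrix -> cpAAI -> tree (built-in NJ or ingested) ->
# genus delimitation -> proposed actions, with a checksummed manifest so
# a rerun on identical inputs is verifiably identical.

#' Build a pipeline configuration
#'
#' @param genomes directory of genome FASTAs, vector of FASTA paths, or a
#'   named list of [GenomeRecord-class] objects.
#' @param panel marker panel FASTA path or a [MarkerPanel-class].
#' @param metadata metadata TSV path or data.frame
#'   (see [readStrainMetadata()]).
#' @param outDir output directory.
#' @param outgroup character vector of strain ids used to root the tree
#'   (required unless `treeFile` is given and already rooted).
#' @param tau,tauMax,step genus delimitation thresholds (percent).
#' @param aniScreen,aniSpecies,dddh synonymy thresholds (percent).
#' @param maxGapFraction alignment trimming threshold.
#' @param minScore,minCoverage marker search acceptance thresholds.
#' @param alignerCmd,trimmerCmd optional external command templates
#'   (`{input}`/`{output}` placeholders); NULL = built-in stages.
#' @param treeFile optional externally built newick tree to ingest in
#'   place of the built-in distance tree.
#' @param ogriTable optional OGRI TSV to drive a synonymy report.
#' @param seed seed recorded in the manifest (the default pipeline is
#'   fully deterministic; the seed matters only for external stages that
#'   accept one).
#' @return a validated config list of class `cpaaiPipelineConfig`.
#' @export
pipelineConfig <- function(genomes, panel, metadata = NULL,
                           outDir = "cpaai-out", outgroup = NULL,
                           tau = 86.5, tauMax = 89, step = 0.1,
                           aniScreen = 95, aniSpecies = 96, dddh = 70,
                           maxGapFraction = 0.9, minScore = 50,
                           minCoverage = 0.5, alignerCmd = NULL,
                           trimmerCmd = NULL, treeFile = NULL,
                           ogriTable = NULL, seed = 1L) {
  th <- c(tau = tau, tauMax = tauMax, step = step, aniScreen = aniScreen,
          aniSpecies = aniSpecies, dddh = dddh,
          maxGapFraction = maxGapFraction)
  if (any(th[c("tau","tauMax","aniScreen","aniSpecies","dddh")] < 0) ||
      any(th[c("tau","tauMax","aniScreen","aniSpecies","dddh")] > 100))
    stop("percent thresholds must lie in [0, 100]")
  if (tau > tauMax) stop("tau must not exceed tauMax")
  for (f in c(if (is.character(genomes)) genomes,
              if (is.character(panel)) panel,
              if (is.character(metadata)) metadata, treeFile, ogriTable))
    if (!is.null(f) && !file.exists(f)) stop("file not found: ", f)
  structure(list(genomes = genomes, panel = panel, metadata = metadata,
                 outDir = outDir, outgroup = outgroup, tau = tau,
                 tauMax = tauMax, step = step, aniScreen = aniScreen,
                 aniSpecies = aniSpecies, dddh = dddh,
                 maxGapFraction = maxGapFraction, minScore = minScore,
                 minCoverage = minCoverage, alignerCmd = alignerCmd,
                 trimmerCmd = trimmerCmd, treeFile = treeFile,
                 ogriTable = ogriTable, seed = seed),
            class = "cpaaiPipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipelineConfig()]; `overrides` (named
#' list, e.g. from `--override key=val`) take precedence.
#'
#' @param file YAML path.
#' @param overrides named list of overriding values.
#' @return a `cpaaiPipelineConfig`.
#' @export
readPipelineConfig <- function(file, overrides = list()) {
  cfg <- yaml::read_yaml(file)
  cfg[names(overrides)] <- overrides
  do.call(pipelineConfig, cfg)
}

stageMsg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full taxonomic-assignment pipeline
#'
#' Stages: load inputs; extract markers from every genome (placeholders
#' for missing markers); align each marker; trim; concatenate; compute
#' cpAAI; build the NJ tree from 100 - cpAAI (or ingest `treeFile`);
#' root with the configured outgroup; cluster at tau and reconcile with
#' monophyly; propose taxonomic actions; optionally run the synonymy
#' report on `ogriTable`. All outputs are written under `outDir` together
#' with `manifest.json` carrying the configuration echo and an md5
#' checksum of every output file. Any stage failure aborts with the stage
#' name in the error.
#'
#' @param config a `cpaaiPipelineConfig` from [pipelineConfig()].
#' @return invisibly, a list with the main in-memory results
#'   (hits, supermatrix, cpaai, tree, partition, actions, manifest path).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "cpaaiPipelineConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  emit <- function(path) { outputs <<- c(outputs, path); path }
  withStage <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
    stageMsg(stage, sprintf("done in %.1fs",
                            proc.time()[["elapsed"]] - t0))
    r
  }

  md <- withStage("load", {
    if (is.character(config$metadata)) readStrainMetadata(config$metadata)
    else config$metadata
  })
  genomes <- withStage("load", {
    g <- config$genomes
    if (is.character(g)) readGenomes(g, metadata = md) else g
  })
  panel <- withStage("load", {
    p <- config$panel
    if (is.character(p)) readMarkerPanel(p) else p
  })
  strains <- names(genomes)

  markerDir <- file.path(config$outDir, "markers")
  dir.create(markerDir, showWarnings = FALSE)
  hits <- withStage("markers", {
    lapply(genomes, function(g) {
      h <- findMarkerHits(g, panel, minScore = config$minScore,
                          minCoverage = config$minCoverage)
      h <- fillMissingMarkers(h, panel, strainId(g))
      writeMarkerHits(h,
        tsvFile = emit(file.path(markerDir,
                                 paste0(strainId(g), ".tsv"))),
        faaFile = emit(file.path(markerDir,
                                 paste0(strainId(g), ".faa"))))
      h
    })
  })

  sm <- withStage("supermatrix", {
    alignments <- lapply(markerIds(panel), function(mid) {
      seqs <- vapply(hits, function(h)
        h$aa_sequence[h$marker_id == mid], character(1))
      a <- alignMarker(setNames(seqs, strains), markerId = mid,
                       alignerCmd = config$alignerCmd)
      if (is.null(config$trimmerCmd))
        trimAlignment(a, maxGapFraction = config$maxGapFraction)
      else externalTrim(a, config$trimmerCmd)
    })
    sm <- concatenateAlignments(alignments, strains)
    writeSuperMatrix(sm, emit(file.path(config$outDir, "supermatrix.faa")),
                     emit(file.path(config$outDir, "partition.tsv")))
    sm
  })

  cp <- withStage("cpaai", {
    cp <- cpAAI(sm)
    writeCpaai(cp, emit(file.path(config$outDir, "cpaai.csv")),
               emit(file.path(config$outDir, "cpaai_long.tsv")))
    cp
  })

  tree <- withStage("tree", {
    t <- if (!is.null(config$treeFile)) readTreeFile(config$treeFile)
    else {
      if (length(strains) < 3L)
        stop("the distance-tree stage needs at least 3 genomes (got ",
             length(strains), "); supply more genomes or an external tree")
      njTree(cpaaiDistance(cp))
    }
    if (!is.null(config$outgroup))
      t <- rootWithOutgroup(t, config$outgroup)
    else if (!ape::is.rooted(t))
      stop("tree is unrooted and no outgroup was configured")
    writeTreeFile(t, emit(file.path(config$outDir, "tree.nwk")))
    t
  })

  gp <- withStage("delimit", {
    clusters <- clusterByCpaai(cp, config$tau)
    reconcileWithTree(clusters, tree, cp, tau = config$tau,
                      tauMax = config$tauMax, step = config$step)
  })
  actions <- withStage("actions", {
    a <- proposeActions(gp, md)
    writeDelimitation(gp, a,
      partitionFile = emit(file.path(config$outDir,
                                     "genus_partition.tsv")),
      actionsFile = emit(file.path(config$outDir, "actions.tsv")),
      reportFile = emit(file.path(config$outDir, "report.txt")),
      thresholds = list(tau = config$tau, tauMax = config$tauMax,
                        step = config$step))
    a
  })

  synonymy <- NULL
  if (!is.null(config$ogriTable)) {
    synonymy <- withStage("synonymy", {
      rep <- synonymyReport(readOgriTable(config$ogriTable),
                            synonymyThresholds(config$aniScreen,
                                               config$aniSpecies,
                                               config$dddh))
      writeSynonymyReport(rep, emit(file.path(config$outDir,
                                              "synonymy.tsv")))
      rep
    })
  }

  manifestPath <- file.path(config$outDir, "manifest.json")
  withStage("manifest", {
    sums <- tools::md5sum(outputs)
    manifest <- list(
      thresholds = list(tau = config$tau, tauMax = config$tauMax,
                        step = config$step, aniScreen = config$aniScreen,
                        aniSpecies = config$aniSpecies,
                        dddh = config$dddh,
                        maxGapFraction = config$maxGapFraction,
                        minScore = config$minScore,
                        minCoverage = config$minCoverage),
      seed = config$seed,
      n_genomes = length(genomes),
      n_markers = length(markerIds(panel)),
      external_stages = list(
        aligner = if (is.null(config$alignerCmd)) "builtin"
                  else config$alignerCmd,
        trimmer = if (is.null(config$trimmerCmd)) "builtin"
                  else config$trimmerCmd,
        tree = if (is.null(config$treeFile)) "builtin-nj"
               else config$treeFile),
      outputs = as.list(setNames(unname(sums),
                                 sub(paste0("^", config$outDir, "/?"), "",
                                     names(sums)))))
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  })

  invisible(list(hits = hits, supermatrix = sm, cpaai = cp, tree = tree,
                 partition = gp, actions = actions, synonymy = synonymy,
                 manifest = manifestPath, outputs = outputs))
}

externalTrim <- function(aln, cmdTemplate) {
  fin <- tempfile(fileext = ".afa"); fout <- tempfile(fileext = ".afa")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeXStringSet(alignedSeqs(aln), fin)
  cmd <- gsub("{output}", fout, gsub("{input}", fin, cmdTemplate,
                                     fixed = TRUE), fixed = TRUE)
  status <- system(cmd)
  if (status != 0L)
    stop("external trimmer failed (exit ", status, ") for marker ",
         markerId(aln))
  out <- readAAStringSet(fout)
  names(out) <- sub("\\s.*$", "", names(out))
  new("MarkerAlignment", markerId = markerId(aln),
      aln = out[names(alignedSeqs(aln))])
}
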