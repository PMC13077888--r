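# Genus delimitation: single-linkage threshold clustering of the cpAAI
# matrix, reconciliation with tree monophyly by local threshold raising,
# and proposed taxonomic actions (transfers, novel genera, merge and
# paraphyly flags).

#' Cluster strains by a cpAAI threshold
#'
#' Clusters are the connected components of the graph with an edge
#' between i and j iff cpAAI(i, j) >= tau (single linkage: threshold
#' clustering that is order-independent and matches the idea of a "clean
#' separation" at the threshold). Complete linkage is available for
#' sensitivity analysis.
#'
#' @param cp a [CpaaiMatrix-class] (or plain symmetric matrix with
#'   dimnames).
#' @param tau threshold in percent (the genus guideline is ~86.5).
#' @param linkage "single" (connected components, default) or "complete"
#'   (every within-cluster pair must reach tau; greedy merge, for
#'   sensitivity checks only).
#' @param members optional subset of strain ids to cluster.
#' @return list of character vectors (clusters), ordered by their
#'   smallest member strain id; members sorted within each cluster.
#' @export
clusterByCpaai <- function(cp, tau, linkage = c("single", "complete"),
                           members = NULL) {
  linkage <- match.arg(linkage)
  v <- if (is(cp, "CpaaiMatrix")) cpaaiValues(cp) else cp
  ids <- rownames(v)
  if (!is.null(members)) {
    v <- v[members, members, drop = FALSE]
    ids <- members
  }
  n <- length(ids)
  adj <- v >= tau
  diag(adj) <- TRUE
  if (linkage == "single") {
    comp <- integer(n)
    cur <- 0L
    for (s in seq_len(n)) {
      if (comp[s] != 0L) next
      cur <- cur + 1L
      queue <- s
      comp[s] <- cur
      while (length(queue)) {
        u <- queue[1]; queue <- queue[-1]
        nb <- which(adj[u, ] & comp == 0L)
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
    clusters <- unname(split(ids, comp))
  } else {
    # greedy agglomeration under complete linkage, deterministic order
    clusters <- as.list(ids)
    repeat {
      merged <- FALSE
      for (i in seq_along(clusters)) {
        for (j in seq_along(clusters)) {
          if (j <= i) next
          if (all(v[clusters[[i]], clusters[[j]]] >= tau)) {
            clusters[[i]] <- c(clusters[[i]], clusters[[j]])
            clusters[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
  }
  clusters <- lapply(clusters, sort)
  clusters[order(vapply(clusters, `[`, character(1), 1L))]
}

#' Reconcile threshold clusters with tree monophyly
#'
#' Monophyly is required of every delimited genus. Clusters that are
#' monophyletic in the rooted tree pass through with status `resolved`.
#' A non-monophyletic cluster is re-clustered among its own members at
#' successively higher thresholds tau + step, tau + 2*step, ... up to
#' `tauMax`; the first threshold at which every resulting sub-cluster is
#' monophyletic is adopted (status `raised_threshold`, threshold raising
#' is local to the cluster, never global). If no threshold up to `tauMax`
#' works, the cluster is kept intact with status `manual_review` — expert
#' judgment, not the tool, decides those cases.
#'
#' @param clusters output of [clusterByCpaai()] at the global tau.
#' @param t rooted `ape::phylo` covering all clustered strains.
#' @param cp the [CpaaiMatrix-class] used for clustering.
#' @param tau global threshold the clusters were built at (percent).
#' @param tauMax cap on local threshold raising (percent).
#' @param step threshold increment (percentage points).
#' @return a [GenusPartition-class]; cluster evidence columns record the
#'   minimum within-cluster cpAAI and the maximum cpAAI to any strain
#'   outside the cluster.
#' @export
reconcileWithTree <- function(clusters, t, cp, tau = 86.5, tauMax = 89,
                              step = 0.1) {
  if (!ape::is.rooted(t))
    stop("reconcileWithTree requires a rooted tree; root it first ",
         "(see rootWithOutgroup)")
  if (tau > tauMax) stop("tau must not exceed tauMax")
  allStrains <- unlist(clusters)
  unknown <- setdiff(allStrains, t$tip.label)
  if (length(unknown))
    stop("strains absent from tree: ", paste(unknown, collapse = ", "))
  out <- list()
  for (cl in clusters) {
    if (length(cl) == 1L || isMonophyletic(t, cl)) {
      out[[length(out) + 1L]] <- list(members = cl, threshold = tau,
                                      mono = TRUE, status = "resolved")
      next
    }
    taus <- seq(tau + step, tauMax, by = step)
    resolved <- FALSE
    for (tp in taus) {
      sub <- clusterByCpaai(cp, round(tp, 6), members = cl)
      if (all(vapply(sub, function(s)
            length(s) == 1L || isMonophyletic(t, s), logical(1)))) {
        for (s in sub)
          out[[length(out) + 1L]] <- list(members = s,
                                          threshold = round(tp, 6),
                                          mono = TRUE,
                                          status = "raised_threshold")
        resolved <- TRUE
        break
      }
    }
    if (!resolved)
      out[[length(out) + 1L]] <- list(members = cl, threshold = tau,
                                      mono = FALSE,
                                      status = "manual_review")
  }
  out <- out[order(vapply(out, function(x) x$members[1], character(1)))]
  v <- cpaaiValues(cp)
  clusterRows <- lapply(seq_along(out), function(i) {
    x <- out[[i]]
    within <- if (length(x$members) > 1L) {
      sub <- v[x$members, x$members]
      min(sub[upper.tri(sub)])
    } else 100
    outside <- setdiff(rownames(v), x$members)
    between <- if (length(outside)) max(v[x$members, outside]) else NA_real_
    data.frame(cluster_id = sprintf("C%03d", i),
               members = paste(x$members, collapse = ","),
               n = length(x$members), threshold_used = x$threshold,
               is_monophyletic = x$mono, status = x$status,
               min_within_cpaai = within, max_between_cpaai = between,
               stringsAsFactors = FALSE)
  })
  clustersDf <- do.call(rbind, clusterRows)
  strainsDf <- do.call(rbind, lapply(seq_along(out), function(i)
    data.frame(strain_id = out[[i]]$members,
               cluster_id = sprintf("C%03d", i),
               stringsAsFactors = FALSE)))
  new("GenusPartition", clusters = clustersDf, strains = strainsDf)
}

#' Propose taxonomic actions from a genus partition
#'
#' Per cluster: exactly one genus type species present -> the cluster
#' inherits that genus name and members labelled otherwise become
#' `transfer` actions; two or more type species -> `merge_flag` on every
#' genus involved; none -> `novel_genus` with a placeholder name
#' (NOVEL-1, ...; nomenclature is a human act, the tool only flags).
#' Additionally any named genus whose members span two or more clusters
#' receives a `paraphyly_flag`. Every non-trivial action's justification
#' cites the cluster's cpAAI evidence (minimum within, maximum between)
#' and its monophyly status in the rooted tree.
#'
#' @param gp a [GenusPartition-class].
#' @param metadata strain metadata data.frame (see
#'   [readStrainMetadata()]) covering every clustered strain.
#' @return data.frame of actions: kind (none / transfer / novel_genus /
#'   merge_flag / paraphyly_flag), subject, target, justification.
#' @export
proposeActions <- function(gp, metadata) {
  cl <- clusterTable(gp)
  st <- strainClusters(gp)
  missing <- setdiff(st$strain_id, metadata$strain_id)
  if (length(missing))
    stop("metadata missing for strains: ", paste(missing, collapse = ", "))
  md <- metadata[match(st$strain_id, metadata$strain_id), ]
  md$cluster_id <- st$cluster_id

  ts <- md[md$is_type_species, , drop = FALSE]
  dup <- ts$genus[duplicated(ts$genus) & nzchar(ts$genus)]
  if (length(dup))
    stop("duplicate type-species flag within genus: ",
         paste(unique(dup), collapse = ", "))

  actions <- list()
  addAction <- function(kind, subject, target, justification)
    actions[[length(actions) + 1L]] <<- data.frame(
      kind = kind, subject = subject, target = target,
      justification = justification, stringsAsFactors = FALSE)

  novelCounter <- 0L
  for (i in seq_len(nrow(cl))) {
    cid <- cl$cluster_id[i]
    mem <- md[md$cluster_id == cid, , drop = FALSE]
    evid <- sprintf(paste0("cluster %s: min within-cluster cpAAI %.2f%%, ",
                           "max cpAAI to other clusters %.2f%%; ",
                           "cluster %s in rooted tree (status %s)"),
                    cid, cl$min_within_cpaai[i], cl$max_between_cpaai[i],
                    if (cl$is_monophyletic[i]) "monophyletic"
                    else "NOT monophyletic", cl$status[i])
    tsHere <- mem[mem$is_type_species, , drop = FALSE]
    if (nrow(tsHere) == 1L) {
      g <- tsHere$genus
      strays <- mem[mem$genus != g, , drop = FALSE]
      if (nrow(strays)) {
        for (k in seq_len(nrow(strays)))
          addAction("transfer",
                    trimws(paste(strays$genus[k], strays$species[k])),
                    g,
                    sprintf("groups with the type species of %s (%s); %s",
                            g, tsHere$strain_id, evid))
      } else {
        addAction("none", g, g,
                  sprintf("cluster coincides with genus %s around its type species; %s",
                          g, evid))
      }
    } else if (nrow(tsHere) >= 2L) {
      for (g in sort(unique(tsHere$genus)))
        addAction("merge_flag", g, paste(sort(unique(tsHere$genus)),
                                         collapse = "+"),
                  sprintf("type species of %s fall in one cluster; %s",
                          paste(sort(unique(tsHere$genus)),
                                collapse = " and "), evid))
    } else {
      novelCounter <- novelCounter + 1L
      addAction("novel_genus",
                paste(trimws(paste(mem$genus, mem$species)),
                      collapse = "; "),
                sprintf("NOVEL-%d", novelCounter),
                sprintf("no genus type species in cluster; %s", evid))
    }
  }

  # paraphyly: a named genus split across clusters
  byGenus <- split(md$cluster_id, md$genus)
  byGenus <- byGenus[nzchar(names(byGenus))]
  for (g in sort(names(byGenus))) {
    cls <- unique(byGenus[[g]])
    if (length(cls) >= 2L) {
      evid <- paste(vapply(cls, function(cid) {
        i <- match(cid, cl$cluster_id)
        sprintf("%s (min within %.2f%%, %s)", cid, cl$min_within_cpaai[i],
                if (cl$is_monophyletic[i]) "monophyletic"
                else "not monophyletic")
      }, character(1)), collapse = "; ")
      addAction("paraphyly_flag", g, "",
                sprintf("members of %s span clusters %s in the rooted tree; %s",
                        g, paste(cls, collapse = ","), evid))
    }
  }
  out <- do.call(rbind, actions)
  if (is.null(out))
    out <- data.frame(kind = character(), subject = character(),
                      target = character(), justification = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write partition and action tables
#'
#' @param gp a [GenusPartition-class].
#' @param actions data.frame from [proposeActions()].
#' @param partitionFile,actionsFile,reportFile output paths (NULL skips).
#' @param thresholds named list/vector echoed in the report header.
#' @return invisibly, the paths written.
#' @export
writeDelimitation <- function(gp, actions = NULL, partitionFile = NULL,
                              actionsFile = NULL, reportFile = NULL,
                              thresholds = NULL) {
  cl <- clusterTable(gp)
  st <- strainClusters(gp)
  if (!is.null(partitionFile)) {
    tab <- merge(st, cl[, c("cluster_id", "threshold_used", "status")],
                 by = "cluster_id")[, c("strain_id", "cluster_id",
                                        "threshold_used", "status")]
    tab <- tab[order(tab$cluster_id, tab$strain_id), ]
    write.table(tab, partitionFile, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(actionsFile) && !is.null(actions))
    write.table(actions, actionsFile, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(reportFile)) {
    con <- file(reportFile, "w")
    on.exit(close(con))
    if (!is.null(thresholds))
      writeLines(sprintf("# thresholds: %s",
                         paste(sprintf("%s=%g", names(thresholds),
                                       unlist(thresholds)),
                               collapse = " ")), con)
    for (i in seq_len(nrow(cl))) {
      writeLines(sprintf(
        "cluster %s [%s, threshold %.2f%%, %s]: %s | min within cpAAI %.2f%%, max between %.2f%%",
        cl$cluster_id[i], cl$status[i], cl$threshold_used[i],
        if (cl$is_monophyletic[i]) "monophyletic" else "non-monophyletic",
        cl$members[i], cl$min_within_cpaai[i], cl$max_between_cpaai[i]),
        con)
    }
  }
  invisible(c(partitionFile, actionsFile, reportFile))
}
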