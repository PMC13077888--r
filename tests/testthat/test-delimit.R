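# hand-built block matrix: within-block `within`, between `between`
blockMatrix <- function(blocks, within = 92, between = 80) {
  ids <- unlist(blocks)
  v <- matrix(between, length(ids), length(ids),
              dimnames = list(ids, ids))
  for (b in blocks) v[b, b] <- within
  diag(v) <- 100
  v
}

asCpaai <- function(v) {
  new("CpaaiMatrix", values = v,
      comparedSites = matrix(1000L, nrow(v), ncol(v),
                             dimnames = dimnames(v)))
}

test_that("threshold clustering finds planted blocks", {
  v <- blockMatrix(list(c("A1","A2","A3"), c("B1","B2","B3")),
                   within = 90, between = 80)
  cl <- clusterByCpaai(asCpaai(v), 86.5)
  expect_identical(cl, list(c("A1","A2","A3"), c("B1","B2","B3")))
  # all above tau -> one cluster; all below -> singletons
  expect_length(clusterByCpaai(asCpaai(v), 70), 1L)
  expect_length(clusterByCpaai(asCpaai(v), 101), 6L)
  expect_length(clusterByCpaai(asCpaai(v), 0), 1L)
})

test_that("raising tau only ever refines the partition", {
  set.seed(3)
  for (rep in 1:5) {
    n <- 8
    v <- matrix(runif(n * n, 70, 100), n)
    v[lower.tri(v)] <- t(v)[lower.tri(v)]
    diag(v) <- 100
    dimnames(v) <- list(paste0("s", 1:n), paste0("s", 1:n))
    cp <- asCpaai(v)
    prev <- clusterByCpaai(cp, 75)
    for (tau in c(80, 85, 90, 95)) {
      cur <- clusterByCpaai(cp, tau)
      for (cl in cur) {
        container <- Filter(function(p) all(cl %in% p), prev)
        expect_length(container, 1L)
      }
      prev <- cur
    }
  }
})

test_that("monophyletic clusters pass through reconciliation untouched", {
  v <- blockMatrix(list(c("A1","A2"), c("B1","B2")))
  t <- rootWithOutgroup(ape::read.tree(text =
    "((A1:1,A2:1):2,(B1:1,B2:1):2);"), c("B1", "B2"))
  gp <- reconcileWithTree(clusterByCpaai(asCpaai(v), 86.5), t,
                          asCpaai(v))
  cl <- clusterTable(gp)
  expect_identical(nrow(cl), 2L)
  expect_true(all(cl$status == "resolved"))
  expect_true(all(cl$threshold_used == 86.5))
  expect_true(all(cl$is_monophyletic))
})

test_that("a cluster spanning two clades is split by local threshold raising", {
  # A and B merge at tau = 86.5 (cpAAI 87.5) but clade C sits between
  # them in the tree, so {A, B} is not monophyletic; re-clustering the
  # members at 87.6 separates two monophyletic blocks
  ids <- c("A1","A2","B1","B2","C1","C2")
  v <- blockMatrix(list(c("A1","A2"), c("B1","B2"), c("C1","C2")))
  v[c("A1","A2"), c("B1","B2")] <- 87.5
  v[c("B1","B2"), c("A1","A2")] <- 87.5
  t <- ape::read.tree(text =
    "(((A1:1,A2:1):2,((B1:1,B2:1):1,(C1:1,C2:1):1):1):1,O:4);")
  v <- rbind(cbind(v, O = 60), O = c(rep(60, 6), 100))
  rownames(v)[7] <- "O"
  cp <- asCpaai(v)
  clusters <- clusterByCpaai(cp, 86.5)
  expect_true(any(vapply(clusters, setequal, logical(1),
                         y = c("A1","A2","B1","B2"))))
  gp <- reconcileWithTree(clusters, t, cp, tau = 86.5, tauMax = 89,
                          step = 0.1)
  cl <- clusterTable(gp)
  raised <- cl[cl$status == "raised_threshold", ]
  expect_identical(nrow(raised), 2L)
  expect_setequal(strsplit(raised$members, ","), list(c("A1","A2"),
                                                      c("B1","B2")))
  expect_equal(raised$threshold_used, c(87.6, 87.6), tolerance = 1e-9)
  expect_true(all(raised$is_monophyletic))
  # untouched clusters stay resolved; the partition covers all strains
  expect_setequal(strainClusters(gp)$strain_id, rownames(v))
})

test_that("inseparable interleaved clades fall back to manual review", {
  # A1 and B1 stay linked at any threshold (cpAAI 95) yet can never be
  # monophyletic without C1
  v <- matrix(80, 4, 4, dimnames = list(c("A1","B1","C1","O"),
                                        c("A1","B1","C1","O")))
  v["A1","B1"] <- v["B1","A1"] <- 95
  v[, "O"] <- v["O", ] <- 60
  diag(v) <- 100
  t <- ape::read.tree(text = "(((A1:1,C1:1):1,B1:2):1,O:3);")
  cp <- asCpaai(v)
  gp <- reconcileWithTree(clusterByCpaai(cp, 86.5), t, cp,
                          tau = 86.5, tauMax = 89, step = 0.1)
  cl <- clusterTable(gp)
  mr <- cl[cl$status == "manual_review", ]
  expect_identical(nrow(mr), 1L)
  expect_identical(mr$members, "A1,B1")
  expect_false(mr$is_monophyletic)
  expect_equal(mr$threshold_used, 86.5)
  expect_error(reconcileWithTree(clusterByCpaai(cp, 86.5),
                                 ape::unroot(t), cp), "rooted")
})

test_that("proposed actions follow the type-species rules", {
  md <- data.frame(
    strain_id = c("A1","A2","H1","B1","B2","N1","N2","M1","M2"),
    genus = c("Ga","Ga","Gh","Gb","Gb","Gn","Gn","Gm","Gq"),
    species = c("a1","a2","h1","b1","b2","n1","n2","m1","q1"),
    is_type_strain = TRUE,
    is_type_species = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                        TRUE, TRUE),
    stringsAsFactors = FALSE)
  clusters <- data.frame(
    cluster_id = c("C001","C002","C003","C004"),
    members = c("A1,A2,H1", "B1,B2", "N1,N2", "M1,M2"),
    n = c(3L, 2L, 2L, 2L),
    threshold_used = 86.5, is_monophyletic = TRUE, status = "resolved",
    min_within_cpaai = 91, max_between_cpaai = 81,
    stringsAsFactors = FALSE)
  strains <- data.frame(
    strain_id = c("A1","A2","H1","B1","B2","N1","N2","M1","M2"),
    cluster_id = c("C001","C001","C001","C002","C002","C003","C003",
                   "C004","C004"),
    stringsAsFactors = FALSE)
  gp <- new("GenusPartition", clusters = clusters, strains = strains)
  acts <- proposeActions(gp, md)
  # the stray species joins the genus whose type species anchors C001
  tr <- acts[acts$kind == "transfer", ]
  expect_identical(tr$subject, "Gh h1")
  expect_identical(tr$target, "Ga")
  # a cluster coinciding with its genus gives a single 'none'
  expect_identical(acts$kind[acts$subject == "Gb"], "none")
  # no type species -> novel genus placeholder
  nv <- acts[acts$kind == "novel_genus", ]
  expect_identical(nrow(nv), 1L)
  expect_match(nv$target, "^NOVEL-1$")
  # two type species in one cluster -> merge flags for both genera
  mg <- acts[acts$kind == "merge_flag", ]
  expect_setequal(mg$subject, c("Gm", "Gq"))
  # every non-trivial action cites cpAAI evidence and a tree statement
  nontrivial <- acts[acts$kind != "none", ]
  expect_true(all(grepl("cpAAI", nontrivial$justification)))
  expect_true(all(grepl("monophyletic|tree", nontrivial$justification)))
})

test_that("a genus split across clusters is flagged as paraphyletic", {
  md <- data.frame(strain_id = c("X1","X2","Y1"),
                   genus = c("Gx","Gx","Gx"),
                   species = c("x1","x2","y1"),
                   is_type_strain = TRUE,
                   is_type_species = c(TRUE, FALSE, FALSE),
                   stringsAsFactors = FALSE)
  clusters <- data.frame(cluster_id = c("C001","C002"),
                         members = c("X1,X2", "Y1"), n = c(2L, 1L),
                         threshold_used = 86.5, is_monophyletic = TRUE,
                         status = "resolved", min_within_cpaai = 90,
                         max_between_cpaai = 80, stringsAsFactors = FALSE)
  strains <- data.frame(strain_id = c("X1","X2","Y1"),
                        cluster_id = c("C001","C001","C002"),
                        stringsAsFactors = FALSE)
  gp <- new("GenusPartition", clusters = clusters, strains = strains)
  acts <- proposeActions(gp, md)
  expect_true("paraphyly_flag" %in% acts$kind)
  expect_identical(acts$subject[acts$kind == "paraphyly_flag"], "Gx")
  # duplicate type-species flags within one genus are rejected
  md2 <- md; md2$is_type_species <- c(TRUE, TRUE, FALSE)
  expect_error(proposeActions(gp, md2), "duplicate type-species")
})
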