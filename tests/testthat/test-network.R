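toyAssoc <- function(r, n = 50) {
  # wrap a correlation grid as an AssociationMatrix with tiny p-values
  dimnames(r) <- list(sprintf("V%02d", seq_len(nrow(r))),
    sprintf("F%02d", seq_len(ncol(r))))
  p <- matrix(1e-6, nrow(r), ncol(r), dimnames = dimnames(r))
  new("AssociationMatrix", r = r, p = p, n = as.integer(n),
    flagged = character(0))
}

test_that("pearson associations match direct correlation and flag constants", {
  set.seed(31)
  X <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(NULL, c("V1", "V2", "V3")))
  M <- cbind(F1 = X[, 1], F2 = rnorm(20), F3 = rep(1, 20))
  a <- associationMatrix(X, M)
  expect_equal(a@r["V1", "F1"], 1)
  expect_lt(a@p["V1", "F1"], 1e-10)
  expect_equal(unname(a@r[, "F3"]), c(0, 0, 0))
  expect_equal(unname(a@p[, "F3"]), c(1, 1, 1))
  expect_true("F3" %in% a@flagged)
  # hand example: y = 2x gives r = 1, reversed gives r = -1
  x <- c(1, 2, 3, 4)
  h <- associationMatrix(cbind(V1 = x), cbind(F1 = 2 * x, F2 = rev(2 * x)))
  expect_equal(unname(h@r[1, ]), c(1, -1))
  expect_error(associationMatrix(X[1:3, ], M[1:3, ]), "at least 4")
})

test_that("spls-mode associations stay in [-1,1] and track strong pairs", {
  set.seed(32)
  X <- matrix(rnorm(60 * 6), 60, 6, dimnames = list(NULL,
    sprintf("V%02d", 1:6)))
  M <- matrix(rnorm(60 * 8), 60, 8, dimnames = list(NULL,
    sprintf("F%02d", 1:8)))
  M[, 1] <- X[, 1] + rnorm(60, 0, 0.3)
  s <- associationMatrix(X, M, mode = "spls")
  expect_true(all(abs(s@r) <= 1))
  expect_equal(which.max(abs(s@r)), which.max(abs(cor(X, M))))
  p <- associationMatrix(X, M)
  expect_gt(sign(s@r["V01", "F01"]) * sign(p@r["V01", "F01"]), 0)
})

test_that("the automatic cutoff is the weakest row-maximum correlation", {
  a <- toyAssoc(rbind(c(0.9, 0.2), c(0.4, 0.1)))
  expect_equal(selectCutoff(a), 0.4)
  expect_equal(selectCutoff(toyAssoc(matrix(0.6, 1, 1))), 0.6)
  # property: at the cutoff every voxel keeps an edge; above it some
  # voxel loses all
  set.seed(33)
  for (i in 1:5) {
    X <- matrix(rnorm(50 * 20), 50, 20,
      dimnames = list(NULL, sprintf("V%02d", 1:20)))
    M <- matrix(rnorm(50 * 30), 50, 30,
      dimnames = list(NULL, sprintf("F%02d", 1:30)))
    M[, 1:20] <- M[, 1:20] + 0.5 * X  # guarantee passing pairs
    a <- associationMatrix(X, M)
    cut <- selectCutoff(a)
    keep <- abs(a@r) >= cut & a@p < 0.05
    expect_true(all(rowSums(keep) >= 1))
    above <- abs(a@r) >= cut + 1e-9 & a@p < 0.05
    expect_true(any(rowSums(above) == 0))
  }
  # voxels with no pair passing alpha are reported
  weak <- toyAssoc(rbind(c(0.9, 0.2), c(0.05, 0.02)))
  weak@p[2, ] <- 0.9
  expect_warning(cut2 <- selectCutoff(weak), "no metabolite pair")
  expect_equal(cut2, 0.9)
})

test_that("network construction keeps exactly the thresholded pairs", {
  a <- toyAssoc(rbind(c(0.5, 0.1, 0.1), c(0.1, -0.5, 0.1)))
  net <- buildNetwork(a, 0.4)
  e <- networkEdges(net)
  expect_equal(nrow(e), 2)
  expect_setequal(e$metabolite, c("F01", "F02"))
  expect_false("F03" %in% e$metabolite)
  expect_equal(e$sign[e$metabolite == "F02"], -1L)
  # boundary: cutoff 1 with all |r| < 1 is an empty network
  expect_error(buildNetwork(a, 1.0), "empty network")
  expect_error(buildNetwork(a, 0), "configuration error")
  # edge count is non-increasing in the cutoff
  set.seed(34)
  r <- matrix(runif(60, -1, 1) * 0.9, 6, 10)
  aa <- toyAssoc(r)
  counts <- vapply(c(0.1, 0.3, 0.5, 0.7), function(ct)
    tryCatch(nrow(networkEdges(buildNetwork(aa, ct))),
      error = function(e) 0L), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("exhaustive community detection equals the brute-force oracle", {
  # two disconnected bicliques form exactly two communities
  r <- matrix(0, 2, 4, dimnames = list(c("V01", "V02"),
    sprintf("F%02d", 1:4)))
  r["V01", 1:2] <- 0.8
  r["V02", 3:4] <- 0.8
  net <- buildNetwork(toyAssoc(r), 0.5)
  cs <- detectCommunities(net)
  expect_equal(cs@method, "exhaustive")
  memb <- communityMembership(cs)
  expect_equal(length(unique(memb)), 2)
  expect_equal(memb[["V01"]], memb[["F01"]])
  expect_equal(memb[["V02"]], memb[["F03"]])

  # random small weighted bipartite graphs: Q equals exhaustive maximum
  set.seed(35)
  for (i in 1:8) {
    nv <- sample(2:3, 1); nf <- sample(3:5, 1)
    r <- matrix(round(runif(nv * nf), 2) *
      (runif(nv * nf) < 0.55), nv, nf)
    if (all(r == 0)) next
    dimnames(r) <- list(sprintf("V%02d", 1:nv), sprintf("F%02d", 1:nf))
    net <- tryCatch(buildNetwork(toyAssoc(r), 0.05),
      error = function(e) NULL)
    if (is.null(net) || nrow(networkEdges(net)) == 0) next
    cs <- detectCommunities(net)
    g <- igraph::graph_from_data_frame(
      data.frame(from = networkEdges(net)$voxel,
        to = networkEdges(net)$metabolite,
        weight = abs(networkEdges(net)$r)), directed = FALSE)
    expect_equal(modularityScore(cs), oracleMaxModularity(g),
      tolerance = 1e-12)
  }
})

test_that("louvain path is reproducible under a fixed seed", {
  set.seed(36)
  r <- matrix(runif(15 * 20) * (runif(15 * 20) < 0.2), 15, 20)
  r[1:5, 1:6] <- 0.9; r[6:10, 7:13] <- 0.9; r[11:15, 14:20] <- 0.9
  dimnames(r) <- list(sprintf("V%02d", 1:15), sprintf("F%02d", 1:20))
  net <- buildNetwork(toyAssoc(r), 0.1)
  a <- detectCommunities(net, seed = 4, exactMax = 0L)
  b <- detectCommunities(net, seed = 4, exactMax = 0L)
  expect_equal(a@method, "louvain")
  expect_identical(communityMembership(a), communityMembership(b))
  # the three planted blocks dominate the partition
  expect_gte(length(unique(communityMembership(a))), 3)
})

test_that("eigenvector centrality matches a power-iteration oracle", {
  # star: the hub is the most central node, leaves tie below it
  r <- matrix(0.8, 1, 5, dimnames = list("V01", sprintf("F%02d", 1:5)))
  net <- buildNetwork(toyAssoc(r), 0.5)
  ce <- nodeCentrality(net)
  expect_equal(ce[["V01"]], 1)
  expect_true(all(ce[sprintf("F%02d", 1:5)] < 1))
  expect_lt(diff(range(ce[sprintf("F%02d", 1:5)])), 1e-12)

  # complete bipartite, equal weights: within-side scores are equal
  r2 <- matrix(0.6, 2, 3, dimnames = list(c("V01", "V02"),
    sprintf("F%02d", 1:3)))
  ce2 <- nodeCentrality(buildNetwork(toyAssoc(r2), 0.5))
  expect_lt(diff(range(ce2[c("V01", "V02")])), 1e-12)
  expect_lt(diff(range(ce2[sprintf("F%02d", 1:3)])), 1e-12)

  # 4-node path with distinct weights vs independent power iteration
  r3 <- matrix(0, 2, 2, dimnames = list(c("V01", "V02"), c("F01", "F02")))
  r3["V01", "F01"] <- 0.9
  r3["V02", "F01"] <- 0.5
  r3["V02", "F02"] <- 0.3
  net3 <- buildNetwork(toyAssoc(r3), 0.1)
  ce3 <- nodeCentrality(net3)
  nodes <- c("V01", "V02", "F01", "F02")
  A <- matrix(0, 4, 4, dimnames = list(nodes, nodes))
  A["V01", "F01"] <- A["F01", "V01"] <- 0.9
  A["V02", "F01"] <- A["F01", "V02"] <- 0.5
  A["V02", "F02"] <- A["F02", "V02"] <- 0.3
  v <- oraclePowerIteration(A)
  expect_equal(unname(ce3[nodes]), unname(v / max(v)), tolerance = 1e-8)
})

test_that("cluster summaries count metabolites per membership mode", {
  # V01-F01, V01-F02, V02-F02: a shared metabolite F02
  r <- matrix(0, 2, 2, dimnames = list(c("V01", "V02"), c("F01", "F02")))
  r["V01", "F01"] <- 0.9
  r["V01", "F02"] <- 0.6
  r["V02", "F02"] <- 0.9
  net <- buildNetwork(toyAssoc(r), 0.5)
  memb <- setNames(c(1L, 2L, 1L, 2L), c("V01", "V02", "F01", "F02"))
  cs <- new("CommunitySet", membership = memb, modularity = 0,
    nodeType = setNames(c("voxel", "voxel", "metabolite", "metabolite"),
      names(memb)), method = "exhaustive")
  edge <- summarizeClusters(cs, net, "edge")
  expect_equal(edge$n_voxels, c(1, 1, 2))
  expect_equal(edge$n_metabolites, c(2, 1, 3))  # F02 counted twice
  part <- summarizeClusters(cs, net, "partition")
  expect_equal(part$n_metabolites, c(1, 1, 2))
  # edge-linked totals can exceed the number of distinct metabolites
  expect_gt(edge$n_metabolites[3], length(unique(net@edges$metabolite)))
  empty <- new("CommunitySet", membership = integer(0),
    modularity = NA_real_, nodeType = character(0), method = "exhaustive")
  expect_equal(nrow(summarizeClusters(empty, net)), 0)
})

test_that("community recovery on synthetic data matches planted blocks", {
  run <- smallRun()
  memb <- communityMembership(run$communities)
  truth <- run$sim$truth
  mask <- run$mask
  trueLab <- c()
  for (r in seq_along(truth$region_voxels)) {
    vox <- linearToVoxel(mask, truth$region_voxels[[r]])
    vox <- vox[!is.na(vox)]
    trueLab <- c(trueLab,
      setNames(rep(r, length(vox)), sprintf("V%05d", vox)),
      setNames(rep(r, length(truth$signal_features[[r]])),
        truth$signal_features[[r]]))
  }
  common <- intersect(names(memb), names(trueLab))
  expect_gte(adjustedRand(memb[common], trueLab[common]), 0.8)
})

test_that("in-package adjusted Rand agrees with the mclust oracle", {
  skip_if_not_installed("mclust")
  set.seed(37)
  for (i in 1:5) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjustedRand(a, b), mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjustedRand(1:10, 1:10), 1)
})

test_that("network export writes GraphML and an edge list", {
  run <- smallRun()
  dir <- withr::local_tempdir()
  exportNetwork(run$network, dir, run$communities, run$centrality)
  expect_true(file.exists(file.path(dir, "network.graphml")))
  e <- read.delim(file.path(dir, "edges.tsv"))
  expect_equal(nrow(e), nrow(networkEdges(run$network)))
  g <- igraph::read_graph(file.path(dir, "network.graphml"),
    format = "graphml")
  expect_equal(igraph::vcount(g),
    length(communityMembership(run$communities)))
})
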