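#' @importFrom igraph graph_from_data_frame cluster_louvain membership
#'   modularity E V components induced_subgraph vcount ecount
#'   as_adjacency_matrix write_graph vertex_attr
NULL

#' Pairwise voxel-metabolite associations
#'
#' Estimates the voxel x metabolite association matrix between the
#' selected voxels' gray matter and the clean metabolite intensities.
#' The default `"pearson"` mode computes Pearson correlations with
#' two-sided p-values from `t = r sqrt(n-2) / sqrt(1-r^2)`. The
#' `"spls"` mode reconstructs the association from a sparse-PLS-style
#' decomposition of the cross-correlation matrix (soft-thresholded
#' singular-vector pairs) rescaled to \[-1, 1\], with p-values from the
#' same t transform applied to the rescaled scores.
#'
#' Constant columns yield undefined correlations; these entries are set
#' to r = 0, p = 1 and the offending column names recorded in the
#' result's `flagged` slot.
#'
#' @param X subject x voxel matrix (selected voxels).
#' @param M subject x metabolite matrix (same subjects, same order).
#' @param mode `"pearson"` (default) or `"spls"`.
#' @param splsComponents,splsSparsity components and soft-threshold
#'   quantile for `"spls"` mode.
#' @return an [AssociationMatrix].
#' @export
associationMatrix <- function(X, M, mode = c("pearson", "spls"),
    splsComponents = 3, splsSparsity = 0.5) {
  mode <- match.arg(mode)
  n <- nrow(X)
  if (nrow(M) != n) stop("input error: X and M need identical subjects")
  if (n < 4) stop("input error: need at least 4 subjects")
  constX <- apply(X, 2, sd) < 1e-12
  constM <- apply(M, 2, sd) < 1e-12
  if (mode == "pearson") {
    r <- suppressWarnings(cor(X, M))
  } else {
    sx <- autoscale(X); sm <- autoscale(M)
    C <- crossprod(sx$X, sm$X) / (n - 1)
    C[constX, ] <- 0; C[, constM] <- 0
    rec <- matrix(0, ncol(X), ncol(M))
    soft <- function(v, lam) sign(v) * pmax(abs(v) - lam, 0)
    Cd <- C
    for (a in seq_len(splsComponents)) {
      sv <- svd(Cd, nu = 1, nv = 1)
      u <- sv$u[, 1]; v <- sv$v[, 1]
      for (it in 1:50) {
        uNew <- soft(Cd %*% v, quantile(abs(Cd %*% v), splsSparsity))
        if (sum(uNew^2) < 1e-12) uNew <- Cd %*% v
        uNew <- uNew / sqrt(sum(uNew^2))
        vNew <- soft(crossprod(Cd, uNew),
          quantile(abs(crossprod(Cd, uNew)), splsSparsity))
        if (sum(vNew^2) < 1e-12) vNew <- crossprod(Cd, uNew)
        vNew <- vNew / sqrt(sum(vNew^2))
        if (max(abs(vNew - v)) < 1e-8) { u <- uNew; v <- vNew; break }
        u <- uNew; v <- vNew
      }
      d <- drop(crossprod(u, Cd %*% v))
      rec <- rec + d * tcrossprod(u, v)
      Cd <- Cd - d * tcrossprod(u, v)
    }
    mx <- max(abs(rec))
    r <- if (mx > 1) rec / mx else rec
    dimnames(r) <- list(colnames(X), colnames(M))
  }
  r[constX, ] <- 0
  r[, constM] <- 0
  r[r > 1] <- 1
  r[r < -1] <- -1
  den <- 1 - r^2
  den[den < 1e-12] <- 1e-12
  tstat <- abs(r) * sqrt((n - 2) / den)
  p <- 2 * pt(tstat, df = n - 2, lower.tail = FALSE)
  p[constX, ] <- 1
  p[, constM] <- 1
  new("AssociationMatrix", r = r, p = p, n = as.integer(n),
    flagged = c(colnames(X)[constX], colnames(M)[constM]))
}

#' Automatic correlation cutoff selection
#'
#' Implements the rule used to set the network threshold: the cutoff is
#' the weakest correlation at which every voxel still correlates with
#' at least one metabolite, i.e. the minimum over voxels of the maximum
#' `|r|` among that voxel's pairs with `p < alpha`. At this cutoff every
#' voxel retains at least one edge; at any strictly larger cutoff at
#' least one voxel loses all of its edges.
#'
#' Voxels with no pair passing `alpha` are reported with a warning and
#' excluded from the minimum.
#'
#' @param assoc an [AssociationMatrix].
#' @param alpha p-value threshold (default 0.05).
#' @return numeric cutoff.
#' @export
selectCutoff <- function(assoc, alpha = 0.05) {
  a <- abs(assoc@r)
  a[assoc@p >= alpha] <- NA
  best <- apply(a, 1, function(x)
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  if (anyNA(best)) {
    warning(sum(is.na(best)),
      " voxel(s) have no metabolite pair with p < alpha; ",
      "cutoff computed over the remaining voxels")
    best <- best[!is.na(best)]
  }
  if (length(best) == 0) stop("no voxel has any pair passing alpha")
  min(best)
}

#' Build the thresholded bipartite voxel-metabolite network
#'
#' Retains exactly the pairs with `|r| >= cutoff` and `p < alpha` as
#' edges, with the edge sign carrying the correlation direction.
#' Metabolites (and voxels) without any retained edge are excluded from
#' the node set.
#'
#' @param assoc an [AssociationMatrix].
#' @param cutoff correlation threshold in (0, 1\]; see [selectCutoff()].
#' @param alpha p-value threshold (default 0.05).
#' @return a [BipartiteNetwork].
#' @export
buildNetwork <- function(assoc, cutoff, alpha = 0.05) {
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff > 1)
    stop("configuration error: cutoff must lie in (0, 1]")
  hit <- which(abs(assoc@r) >= cutoff & assoc@p < alpha, arr.ind = TRUE)
  if (nrow(hit) == 0)
    stop("empty network: no pair passes |r| >= ", cutoff,
      " with p < ", alpha)
  edges <- data.frame(
    voxel = rownames(assoc@r)[hit[, 1]],
    metabolite = colnames(assoc@r)[hit[, 2]],
    r = assoc@r[hit], p = assoc@p[hit],
    sign = ifelse(assoc@r[hit] >= 0, 1L, -1L))
  edges <- edges[order(edges$voxel, edges$metabolite), ]
  rownames(edges) <- NULL
  new("BipartiteNetwork", edges = edges, cutoff = cutoff, alpha = alpha)
}

networkGraph <- function(net) {
  e <- net@edges
  g <- graph_from_data_frame(
    data.frame(from = e$voxel, to = e$metabolite, weight = abs(e$r)),
    directed = FALSE,
    vertices = data.frame(
      name = c(unique(e$voxel), unique(e$metabolite)),
      type = rep(c("voxel", "metabolite"),
        c(length(unique(e$voxel)), length(unique(e$metabolite))))))
  g
}

# all set partitions of n items as restricted-growth rows
allPartitions <- function(n) {
  parts <- matrix(1L, 1, 1)
  maxg <- 1L
  for (i in seq_len(n - 1)) {
    reps <- maxg + 1L
    idx <- rep(seq_len(nrow(parts)), reps)
    newg <- unlist(lapply(reps, seq_len))
    parts <- cbind(parts[idx, , drop = FALSE], newg)
    maxg <- pmax(maxg[idx], newg)
  }
  parts
}

weightedModularity <- function(memb, ei, ej, w, k) {
  m2 <- sum(w) * 2
  inside <- sum(w[memb[ei] == memb[ej]]) * 2
  ktot <- tapply(k, memb, sum)
  inside / m2 - sum(ktot^2) / m2^2
}

#' Detect modularity communities in the bipartite network
#'
#' Partitions the network's nodes by maximizing |r|-weighted modularity.
#' For tiny networks (at most `exactMax` nodes) the optimum is found by
#' exhaustive search over all partitions with a deterministic canonical
#' tie-break; larger networks use the multilevel (Louvain) heuristic
#' from igraph, seeded for reproducibility.
#'
#' @param net a [BipartiteNetwork].
#' @param seed RNG seed for the heuristic path.
#' @param exactMax node-count bound for the exhaustive path (default
#'   10).
#' @return a [CommunitySet].
#' @export
detectCommunities <- function(net, seed = 1L, exactMax = 10L) {
  g <- networkGraph(net)
  nodes <- vertex_attr(g, "name")
  type <- setNames(vertex_attr(g, "type"), nodes)
  ei <- match(net@edges$voxel, nodes)
  ej <- match(net@edges$metabolite, nodes)
  w <- abs(net@edges$r)
  k <- numeric(length(nodes))
  for (t in seq_along(w)) {
    k[ei[t]] <- k[ei[t]] + w[t]
    k[ej[t]] <- k[ej[t]] + w[t]
  }
  if (vcount(g) <= exactMax) {
    parts <- allPartitions(vcount(g))
    qs <- apply(parts, 1, weightedModularity, ei = ei, ej = ej, w = w,
      k = k)
    best <- parts[which.max(qs), ]
    memb <- setNames(as.integer(best), nodes)
    q <- max(qs)
    method <- "exhaustive"
  } else {
    set.seed(seed)
    cl <- cluster_louvain(g, weights = E(g)$weight)
    memb <- setNames(as.integer(membership(cl)), nodes)
    q <- modularity(g, memb, weights = E(g)$weight)
    method <- "louvain"
  }
  # canonical renumbering by first appearance
  memb <- setNames(as.integer(factor(memb, levels = unique(memb))), nodes)
  new("CommunitySet", membership = memb, modularity = q,
    nodeType = type, method = method)
}

#' Eigenvector centrality of network nodes
#'
#' Principal-eigenvector scores of the |r|-weighted adjacency matrix,
#' computed per connected component and normalized so the most central
#' node of each component scores 1.
#'
#' @param net a [BipartiteNetwork].
#' @return named numeric vector over all network nodes.
#' @export
nodeCentrality <- function(net) {
  g <- networkGraph(net)
  comp <- components(g)
  out <- numeric(vcount(g))
  names(out) <- vertex_attr(g, "name")
  for (ci in seq_len(comp$no)) {
    idx <- which(comp$membership == ci)
    if (length(idx) == 1) { out[idx] <- 1; next }
    sub <- induced_subgraph(g, idx)
    A <- as.matrix(as_adjacency_matrix(sub, attr = "weight",
      sparse = FALSE))
    ev <- eigen(A, symmetric = TRUE)
    v <- ev$vectors[, 1]
    if (sum(v) < 0) v <- -v
    v <- pmax(v, 0)  # Perron vector is non-negative up to rounding
    out[match(vertex_attr(sub, "name"), names(out))] <- v / max(v)
  }
  out
}

#' Community summary table (voxel and metabolite counts)
#'
#' Per-community voxel and metabolite counts with a totals row. Under
#' the default `metaboliteMode = "edge"`, a metabolite is counted in
#' every community containing at least one of its voxel partners, so
#' the metabolite total can exceed the number of distinct metabolites
#' (a metabolite can link to several communities);
#' `"partition"` counts each metabolite only in its own community.
#'
#' @param communities a [CommunitySet].
#' @param net the [BipartiteNetwork] the communities were detected on.
#' @param metaboliteMode `"edge"` (default) or `"partition"`.
#' @return data.frame with columns cluster, n_voxels, n_metabolites;
#'   the last row is the total.
#' @export
summarizeClusters <- function(communities, net,
    metaboliteMode = c("edge", "partition")) {
  metaboliteMode <- match.arg(metaboliteMode)
  memb <- communities@membership
  type <- communities@nodeType
  if (length(memb) == 0)
    return(data.frame(cluster = character(0), n_voxels = integer(0),
      n_metabolites = integer(0)))
  ids <- sort(unique(memb))
  nv <- vapply(ids, function(ci)
    sum(memb == ci & type == "voxel"), integer(1))
  if (metaboliteMode == "partition") {
    nm <- vapply(ids, function(ci)
      sum(memb == ci & type == "metabolite"), integer(1))
  } else {
    e <- net@edges
    vc <- memb[e$voxel]
    nm <- vapply(ids, function(ci)
      length(unique(e$metabolite[vc == ci])), integer(1))
  }
  out <- data.frame(cluster = as.character(ids), n_voxels = nv,
    n_metabolites = nm)
  rbind(out, data.frame(cluster = "Total", n_voxels = sum(nv),
    n_metabolites = sum(nm)))
}

#' List the metabolite features of each community
#'
#' @param communities a [CommunitySet].
#' @param net the [BipartiteNetwork] used for detection.
#' @param metaboliteMode as in [summarizeClusters()].
#' @return named list: community id to character vector of metabolite
#'   feature ids.
#' @export
communityMetabolites <- function(communities, net,
    metaboliteMode = c("edge", "partition")) {
  metaboliteMode <- match.arg(metaboliteMode)
  memb <- communities@membership
  ids <- sort(unique(memb))
  if (metaboliteMode == "partition") {
    type <- communities@nodeType
    out <- lapply(ids, function(ci)
      names(memb)[memb == ci & type == "metabolite"])
  } else {
    e <- net@edges
    vc <- memb[e$voxel]
    out <- lapply(ids, function(ci) unique(e$metabolite[vc == ci]))
  }
  setNames(out, as.character(ids))
}

#' Export the network as GraphML and an edge-list table
#'
#' @param net a [BipartiteNetwork].
#' @param dir output directory.
#' @param communities,centrality optional [CommunitySet] / centrality
#'   vector written as node attributes.
#' @return `dir`, invisibly.
#' @export
exportNetwork <- function(net, dir, communities = NULL,
    centrality = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- networkGraph(net)
  nodes <- vertex_attr(g, "name")
  if (!is.null(communities))
    g <- igraph::set_vertex_attr(g, "community",
      value = unname(communities@membership[nodes]))
  if (!is.null(centrality))
    g <- igraph::set_vertex_attr(g, "centrality",
      value = unname(centrality[nodes]))
  write_graph(g, file.path(dir, "network.graphml"), format = "graphml")
  write.table(net@edges, file.path(dir, "edges.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)
  invisible(dir)
}
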