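# shared fixtures (built in code) and independent oracles

tinyConfig <- function(...) {
  syntheticConfig(n_mci = 8, n_control = 10, grid_dims = c(12, 12, 12),
    n_regions = 2, region_size = 10, n_features = 80,
    n_signal_features_per_region = 4, n_pathways = 5,
    planted_pathway_size = 6, n_background_compounds = 40, ...)
}

smallConfig <- function(...) {
  syntheticConfig(n_mci = 20, n_control = 25, grid_dims = c(16, 16, 16),
    n_regions = 2, region_size = 15, n_features = 200,
    n_signal_features_per_region = 6, n_pathways = 6,
    planted_pathway_size = 8, n_background_compounds = 60, ...)
}

.voxCache <- new.env(parent = emptyenv())
cachedFixture <- function(key, expr) {
  if (!exists(key, envir = .voxCache))
    assign(key, force(expr), envir = .voxCache)
  get(key, envir = .voxCache)
}

tinySim <- function() cachedFixture("tinySim", simulateStudy(tinyConfig()))
smallRun <- function() cachedFixture("smallRun",
  runPipeline(smallConfig(), seed = 7, nPerm = 50))
acceptRun <- function() cachedFixture("acceptRun",
  runPipeline(syntheticConfig(), seed = 1))

# build a RawFeatureTable from per-replicate matrices (features x samples)
makeRaw <- function(rep1, rep2, rep3, diagnosis = NULL, batch = NULL) {
  nf <- nrow(rep1); ns <- ncol(rep1)
  feats <- sprintf("F%03d", seq_len(nf))
  samps <- sprintf("S%03d", seq_len(ns))
  dimnames(rep1) <- dimnames(rep2) <- dimnames(rep3) <- list(feats, samps)
  if (is.null(diagnosis))
    diagnosis <- factor(rep_len(c("control", "MCI"), ns),
      levels = c("control", "MCI"))
  if (is.null(batch)) batch <- factor(rep(1, ns))
  rawFeatureTable(rep1, rep2, rep3, mz = runif(nf, 85, 1275),
    time = runif(nf, 20, 600),
    sampleData = data.frame(subject_id = samps, diagnosis = diagnosis,
      batch = batch))
}

# independent enumerator of all set partitions (recursive, unlike the
# package's iterative matrix construction)
oraclePartitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oraclePartitions(n - 1)) {
    for (g in seq_len(max(p) + 1L)) out[[length(out) + 1L]] <- c(p, g)
  }
  out
}

# exhaustive maximum weighted modularity via igraph's scorer
oracleMaxModularity <- function(g) {
  max(vapply(oraclePartitions(igraph::vcount(g)), function(p)
    igraph::modularity(g, p, weights = igraph::E(g)$weight), numeric(1)))
}

# plain power iteration for the principal eigenvector; a positive
# diagonal shift keeps it convergent on bipartite graphs (whose spectra
# are symmetric about zero) without changing the eigenvector
oraclePowerIteration <- function(A, iter = 5000, tol = 1e-13) {
  shift <- max(colSums(abs(A)))
  B <- A + diag(shift, nrow(A))
  v <- rep(1, nrow(A))
  for (i in seq_len(iter)) {
    v2 <- drop(B %*% v)
    v2 <- v2 / sqrt(sum(v2^2))
    if (max(abs(v2 - v)) < tol) return(v2)
    v <- v2
  }
  v
}

# independent quantile-normalization oracle: explicit rank-group means
oracleQuantileNorm <- function(L) {
  ref <- rowMeans(apply(L, 2, sort))
  out <- L
  for (j in seq_len(ncol(L))) {
    rk <- rank(L[, j], ties.method = "min")
    for (v in unique(L[, j])) {
      pos <- which(L[, j] == v)
      out[pos, j] <- mean(ref[rk[pos[1]] + seq_along(pos) - 1])
    }
  }
  out
}

# hypergeometric right tail by direct combinatorial summation
oracleHyperTail <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}
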