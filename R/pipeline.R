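stageReport <- function(name, params, counts, t0) {
  list(stage = name, params = params, counts = counts,
    runtime_s = round(as.numeric(Sys.time()) - t0, 2))
}

#' Run one pipeline stage
#'
#' Thin dispatcher over the stage functions, for running the pipeline
#' piecewise: `"simulate"`, `"preprocess"`, `"select-voxels"`,
#' `"integrate"`, `"annotate"`, `"enrich"`, `"replicate"`. `state` is
#' the accumulating result list ([runPipeline()] shows the stage
#' order); each call returns the state extended with the stage outputs
#' and a machine-readable stage report.
#'
#' @param name stage name.
#' @param state list of prior stage outputs (a fresh list for
#'   `"simulate"`).
#' @param config a [syntheticConfig()] (used by `"simulate"`).
#' @param seed master seed; stage seeds derive from it.
#' @param ... threshold overrides passed to the stage function.
#' @return the extended state list.
#' @export
runStage <- function(name, state = list(), config = syntheticConfig(),
    seed = 1L, ...) {
  stages <- c("simulate", "preprocess", "select-voxels", "integrate",
    "annotate", "enrich", "replicate")
  if (!name %in% stages)
    stop("usage error: unknown stage '", name, "'; stages are: ",
      paste(stages, collapse = ", "))
  t0 <- as.numeric(Sys.time())
  dots <- list(...)
  need <- function(field, from) {
    if (is.null(state[[field]]))
      stop("missing input: stage '", name, "' needs '", field,
        "' produced by stage '", from, "'")
    state[[field]]
  }
  if (name == "simulate") {
    cfg <- config
    cfg$seed <- as.integer(seed)
    state$sim <- simulateStudy(cfg)
    state$reports$simulate <- stageReport(name, list(seed = seed),
      list(subjects = nrow(state$sim$cohort),
        features = nrow(state$sim$raw)), t0)
  } else if (name == "preprocess") {
    sim <- need("sim", "simulate")
    state$clean <- do.call(preprocessFeatureTable, c(list(sim$raw), dots))
    state$reports$preprocess <- stageReport(name, qcLog(state$clean)$params,
      list(features_in = nrow(sim$raw),
        features_out = nrow(state$clean),
        samples_out = ncol(state$clean)), t0)
  } else if (name == "select-voxels") {
    sim <- need("sim", "simulate")
    clean <- need("clean", "preprocess")
    thr <- dots$gmThreshold %||% 0.3
    state$mask <- buildGMMask(sim$gm, thr)
    keep <- match(colnames(clean), subjectIds(sim$gm))
    gmSub <- new("GMVolumeSet",
      data = sim$gm@data[, , , keep, drop = FALSE], affine = sim$gm@affine)
    state$X <- extractVoxelMatrix(gmSub, state$mask)
    state$y <- colData(clean)$diagnosis
    plsSeed <- deriveSeed(seed, "plsda")
    state$plsda <- fitPlsdaCV(state$X, state$y,
      kFolds = dots$kFolds %||% 3,
      maxComponents = dots$maxComponents %||% 5, seed = plsSeed)
    vip <- plsdaVIP(state$plsda)
    state$selection <- selectVoxels(vip, state$X, state$y,
      vipMin = dots$vipMin %||% 2, pctMin = dots$pctMin %||% 2)
    state$reports$`select-voxels` <- stageReport(name,
      list(gm_threshold = thr, vip_min = dots$vipMin %||% 2,
        pct_min = dots$pctMin %||% 2, seed = plsSeed,
        n_components = state$plsda@nComponents),
      list(mask_voxels = nVoxels(state$mask),
        selected = length(selectedVoxels(state$selection)),
        artifact = length(artifactVoxels(state$selection))), t0)
  } else if (name == "integrate") {
    clean <- need("clean", "preprocess")
    sel <- need("selection", "select-voxels")
    if (length(selectedVoxels(sel)) == 0)
      stop("no voxels selected: nothing to integrate")
    state$M <- t(assay(clean, "log2"))
    state$Xsel <- state$X[, selectedVoxels(sel), drop = FALSE]
    state$assoc <- associationMatrix(state$Xsel, state$M,
      mode = dots$assocMode %||% "pearson")
    alpha <- dots$alpha %||% 0.05
    state$cutoff <- if (!is.null(dots$cutoff)) dots$cutoff else
      selectCutoff(state$assoc, alpha)
    state$network <- buildNetwork(state$assoc, state$cutoff, alpha)
    commSeed <- deriveSeed(seed, "communities")
    state$communities <- detectCommunities(state$network, seed = commSeed)
    state$centrality <- nodeCentrality(state$network)
    state$clusterSummary <- summarizeClusters(state$communities,
      state$network)
    state$reports$integrate <- stageReport(name,
      list(alpha = alpha, cutoff = state$cutoff, seed = commSeed,
        mode = dots$assocMode %||% "pearson"),
      list(edges = nrow(networkEdges(state$network)),
        communities = length(unique(communityMembership(
          state$communities))),
        modularity = modularityScore(state$communities)), t0)
  } else if (name == "annotate") {
    sim <- need("sim", "simulate")
    comm <- need("communities", "integrate")
    state$annotation <- annotateCommunities(comm, state$mask, sim$atlas,
      contigMin = dots$contigMin %||% 0.5,
      majorityMin = dots$majorityMin %||% 0.5)
    state$reports$annotate <- stageReport(name,
      list(contig_min = dots$contigMin %||% 0.5,
        majority_min = dots$majorityMin %||% 0.5),
      list(annotated = sum(state$annotation$verdict != "N/A"),
        na = sum(state$annotation$verdict == "N/A")), t0)
  } else if (name == "enrich") {
    sim <- need("sim", "simulate")
    clean <- need("clean", "preprocess")
    comm <- need("communities", "integrate")
    allMz <- setNames(featureMz(clean), rownames(clean))
    feats <- communityMetabolites(comm, state$network)
    enrSeed <- deriveSeed(seed, "enrichment")
    state$enrichment <- lapply(feats, function(f)
      enrichCluster(f, allMz, sim$db, tolPpm = dots$tolPpm %||% 10,
        nPerm = dots$nPerm %||% 100, seed = enrSeed))
    state$reports$enrich <- stageReport(name,
      list(tol_ppm = dots$tolPpm %||% 10, n_perm = dots$nPerm %||% 100,
        seed = enrSeed),
      list(communities = length(feats)), t0)
  } else if (name == "replicate") {
    clean <- need("clean", "preprocess")
    splitSeed <- deriveSeed(seed, "split")
    meta <- data.frame(subject_id = colnames(clean),
      diagnosis = colData(clean)$diagnosis)
    state$split <- stratifiedSplit(meta,
      trainFrac = dots$trainFrac %||% 0.67, seed = splitSeed)
    state$replication <- replicateNetwork(state$Xsel, state$M,
      state$split, state$cutoff, dots$alpha %||% 0.05)
    state$reports$replicate <- stageReport(name,
      list(train_frac = dots$trainFrac %||% 0.67, seed = splitSeed,
        cutoff = state$cutoff),
      list(pairs = nrow(state$replication$pairs)), t0)
  }
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full integration pipeline on a synthetic study
#'
#' Executes every stage in order — simulate, preprocess, select-voxels,
#' integrate, annotate, enrich, replicate — and appends ground-truth
#' recovery metrics: the Jaccard index between selected and planted
#' voxels, the adjusted Rand index between detected and planted
#' communities (over nodes with known membership), the rank and
#' permutation p of the planted pathway in its best community, and the
#' replication R-squared on all pairs versus planted-signal pairs.
#'
#' When the voxel-selection stage selects nothing (e.g. a null
#' configuration with `atrophy_effect = 0`) the pipeline stops after
#' selection and returns with `status = "no voxels selected"`.
#'
#' @param config a [syntheticConfig()].
#' @param seed master seed for all stochastic stages.
#' @param outDir optional directory; when given, fixtures, tables,
#'   network exports and the JSON report are written there.
#' @param ... stage threshold overrides (see [runStage()]): gmThreshold,
#'   vipMin, pctMin, alpha, cutoff, assocMode, contigMin, majorityMin,
#'   tolPpm, nPerm, trainFrac, kFolds, maxComponents, plus the
#'   preprocessing thresholds of [preprocessFeatureTable()].
#' @return list of class `voxMetabRun` with all stage outputs, stage
#'   reports and `recovery` metrics.
#' @examples
#' \donttest{
#' run <- runPipeline(syntheticConfig(), seed = 1)
#' run$recovery
#' }
#' @export
runPipeline <- function(config = syntheticConfig(), seed = config$seed,
    outDir = NULL, ...) {
  validateConfig(config)
  state <- runStage("simulate", list(), config, seed, ...)
  pre <- intersect(names(list(...)),
    c("cvMax", "rMin", "missMax", "groupRule", "imputeScope",
      "batchCorrect"))
  state <- do.call(runStage, c(list("preprocess", state, config, seed),
    list(...)[pre]))
  state <- runStage("select-voxels", state, config, seed, ...)
  if (length(selectedVoxels(state$selection)) == 0) {
    state$status <- "no voxels selected"
    class(state) <- "voxMetabRun"
    return(state)
  }
  state <- runStage("integrate", state, config, seed, ...)
  state <- runStage("annotate", state, config, seed, ...)
  state <- runStage("enrich", state, config, seed, ...)
  state <- runStage("replicate", state, config, seed, ...)
  state$status <- "ok"
  state$recovery <- recoveryMetrics(state)
  class(state) <- "voxMetabRun"
  if (!is.null(outDir)) writeRunOutputs(state, outDir)
  state
}

# ground-truth comparison of a completed run
recoveryMetrics <- function(state) {
  sim <- state$sim
  truth <- sim$truth
  mask <- state$mask
  plantedVox <- linearToVoxel(mask,
    sort(unlist(truth$region_voxels)))
  plantedVox <- plantedVox[!is.na(plantedVox)]
  jac <- jaccardIndex(selectedVoxels(state$selection), plantedVox)

  # planted community labels: region id for planted voxels and their
  # coupled features; ARI evaluated over nodes present in the network
  memb <- communityMembership(state$communities)
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
  ari <- if (length(common) >= 2)
    adjustedRand(memb[common], trueLab[common]) else NA_real_

  # planted pathway, judged in the community where its evidence is
  # strongest (smallest Fisher p): its rank there and permutation p
  planted <- truth$enriched_pathway_id
  bestRank <- NA_integer_; bestP <- NA_real_; bestFisher <- Inf
  for (er in state$enrichment) {
    tb <- enrichmentTable(er)
    if (nrow(tb) == 0 || !planted %in% tb$pathway_id) next
    fp <- tb$fisher_p[tb$pathway_id == planted]
    if (fp < bestFisher) {
      bestFisher <- fp
      bestRank <- match(planted, tb$pathway_id[order(tb$fisher_p)])
      bestP <- tb$permutation_p[tb$pathway_id == planted]
    }
  }

  repl <- state$replication
  r2All <- if (!is.null(repl$fit)) repl$fit$r_squared else NA_real_
  sigFeat <- unlist(truth$signal_features)
  sigPairs <- repl$pairs[repl$pairs$metabolite %in% sigFeat, ]
  r2Sig <- if (nrow(sigPairs) >= 3 && sd(sigPairs$r_train) > 1e-12)
    fitR2(sigPairs$r_train, sigPairs$r_valid)$r_squared else NA_real_

  list(voxel_jaccard = jac, community_ari = ari,
    planted_pathway_rank = bestRank,
    planted_pathway_perm_p = bestP,
    replication_r2_all = r2All, replication_r2_signal = r2Sig,
    n_signal_pairs = nrow(sigPairs))
}

writeRunOutputs <- function(state, outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  writeFixtures(state$sim, file.path(outDir, "fixtures"))
  writeNifti(unflattenVoxels(vipScores(state$selection), state$mask,
    fill = 0), file.path(outDir, "vip_map.nii.gz"))
  writeNifti(state$mask@mask + 0, file.path(outDir, "gm_mask.nii.gz"))
  sel <- state$selection
  co <- maskCoords(state$mask)
  selTab <- data.frame(voxel = seq_along(vipScores(sel)),
    x = co[, 1], y = co[, 2], z = co[, 3], vip = vipScores(sel),
    pct_diff = pctDiff(sel),
    bucket = ifelse(seq_along(vipScores(sel)) %in% selectedVoxels(sel),
      "selected",
      ifelse(seq_along(vipScores(sel)) %in% artifactVoxels(sel),
        "artifact", "none")))
  write.table(selTab, file.path(outDir, "voxel_selection.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  exportNetwork(state$network, outDir, state$communities,
    state$centrality)
  write.table(state$clusterSummary, file.path(outDir,
    "cluster_summary.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write.table(state$annotation, file.path(outDir, "annotation.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  enr <- do.call(rbind, lapply(names(state$enrichment), function(ci) {
    tb <- enrichmentTable(state$enrichment[[ci]])
    if (nrow(tb) == 0) return(NULL)
    cbind(cluster = ci, tb)
  }))
  if (!is.null(enr))
    write.table(enr, file.path(outDir, "enrichment.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
  write_json(list(status = state$status, reports = state$reports,
    recovery = state$recovery, split = state$split[c("train",
      "validation", "counts", "seed")]),
    file.path(outDir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}

#' @export
print.voxMetabRun <- function(x, ...) {
  cat("voxMetab pipeline run [", x$status, "]\n")
  if (!is.null(x$selection))
    cat("  selected voxels:", length(selectedVoxels(x$selection)), "\n")
  if (!is.null(x$cutoff))
    cat("  correlation cutoff:", signif(x$cutoff, 4), "\n")
  if (!is.null(x$communities))
    cat("  communities:",
      length(unique(communityMembership(x$communities))), "\n")
  if (!is.null(x$recovery)) {
    cat("  recovery: Jaccard =", signif(x$recovery$voxel_jaccard, 3),
      ", ARI =", signif(x$recovery$community_ari, 3),
      ", planted pathway rank =", x$recovery$planted_pathway_rank, "\n")
  }
  invisible(x)
}
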