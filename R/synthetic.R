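#' Configuration of the synthetic imaging-metabolomics study
#'
#' Builds and validates the parameter set controlling the synthetic
#' cohort, gray-matter volumes, LC-MS feature table, atlas and pathway
#' database. The defaults emulate the study conditions of a two-group
#' MCI/control cohort (60 cases, 85 controls) with planted atrophy
#' regions and a planted enriched pathway, at a desk-scale grid.
#'
#' @param n_mci,n_control subjects per diagnosis group.
#' @param grid_dims integer(3), voxel grid shape.
#' @param n_regions number of planted atrophy regions.
#' @param region_size approximate voxels per planted region (ellipsoidal
#'   blobs; the realized count varies slightly with discretization).
#' @param atrophy_effect fractional gray-matter reduction in cases inside
#'   planted regions, in \[0, 1); 0 plants no effect.
#' @param gm_noise_sd per-voxel Gaussian noise on GM probability.
#' @param region_noise_sd per-subject-per-region anatomical variability
#'   (shared by all voxels of a region), the variance component that
#'   makes regions distinguishable across subjects.
#' @param n_features LC-MS feature count.
#' @param n_signal_features_per_region features coupled to each region's
#'   mean gray matter.
#' @param coupling target |Pearson r| between a signal feature's
#'   log-intensity and its region's subject-mean GM, in \[0, 1); the
#'   per-feature coupling is jittered by U(0.75, 1.25) around this.
#' @param n_batches,batch_shift batch count and log2-intensity offset
#'   between consecutive batches.
#' @param replicate_cv within-triplicate coefficient of variation.
#' @param missing_rate_background per-replicate-cell missingness rate.
#' @param missing_mode `"random"` (missing at random) or `"censored"`
#'   (left-censored: low-intensity cells are more likely missing).
#' @param n_pathways pathway count (>= 2; one planted + decoys).
#' @param planted_pathway_size compounds in the planted pathway, all
#'   mapped to signal features.
#' @param n_background_compounds decoy compounds in the database.
#' @param seed master RNG seed; all sub-stage seeds derive from it.
#' @return A validated list of class `SyntheticConfig`.
#' @examples
#' cfg <- syntheticConfig(n_mci = 5, n_control = 5,
#'   grid_dims = c(12, 12, 12), n_regions = 2, region_size = 10,
#'   n_features = 50, n_signal_features_per_region = 4)
#' @export
syntheticConfig <- function(n_mci = 60, n_control = 85,
    grid_dims = c(30L, 30L, 30L), n_regions = 5, region_size = 40,
    atrophy_effect = 0.15, gm_noise_sd = 0.05, region_noise_sd = 0.08,
    n_features = 2000, n_signal_features_per_region = 10, coupling = 0.6,
    n_batches = 2, batch_shift = 0.5, replicate_cv = 0.2,
    missing_rate_background = 0.05, missing_mode = c("random", "censored"),
    n_pathways = 25, planted_pathway_size = 10,
    n_background_compounds = 300, seed = 1L) {
  cfg <- list(n_mci = as.integer(n_mci), n_control = as.integer(n_control),
    grid_dims = as.integer(grid_dims), n_regions = as.integer(n_regions),
    region_size = as.integer(region_size), atrophy_effect = atrophy_effect,
    gm_noise_sd = gm_noise_sd, region_noise_sd = region_noise_sd,
    n_features = as.integer(n_features),
    n_signal_features_per_region = as.integer(n_signal_features_per_region),
    coupling = coupling, n_batches = as.integer(n_batches),
    batch_shift = batch_shift, replicate_cv = replicate_cv,
    missing_rate_background = missing_rate_background,
    missing_mode = match.arg(missing_mode),
    n_pathways = as.integer(n_pathways),
    planted_pathway_size = as.integer(planted_pathway_size),
    n_background_compounds = as.integer(n_background_compounds),
    seed = as.integer(seed))
  validateConfig(cfg)
  class(cfg) <- "SyntheticConfig"
  cfg
}

validateConfig <- function(cfg) {
  counts <- c("n_mci", "n_control", "n_regions", "region_size",
    "n_features", "n_signal_features_per_region", "n_batches",
    "planted_pathway_size", "n_background_compounds")
  for (f in counts)
    if (is.na(cfg[[f]]) || cfg[[f]] < 1)
      stop("configuration error: '", f, "' must be a count >= 1")
  if (length(cfg$grid_dims) != 3 || any(cfg$grid_dims < 4))
    stop("configuration error: grid_dims must be 3 dimensions >= 4")
  if (cfg$atrophy_effect < 0 || cfg$atrophy_effect >= 1)
    stop("configuration error: atrophy_effect must lie in [0, 1)")
  if (cfg$coupling < 0 || cfg$coupling >= 1)
    stop("configuration error: coupling must lie in [0, 1)")
  if (cfg$missing_rate_background < 0 || cfg$missing_rate_background >= 1)
    stop("configuration error: missing_rate_background must lie in [0, 1)")
  if (cfg$n_pathways < 2)
    stop("configuration error: n_pathways must be >= 2 (planted + decoys)")
  n_sig <- cfg$n_regions * cfg$n_signal_features_per_region
  if (n_sig > cfg$n_features)
    stop("configuration error: signal features exceed n_features")
  if (cfg$planted_pathway_size > n_sig)
    stop("configuration error: planted_pathway_size exceeds mapped compounds")
  invisible(TRUE)
}

#' Simulate the subject metadata table
#'
#' Diagnosis, age, sex and batch per subject. Ages and sex proportions
#' follow the cohort characteristics typical of an MCI/control study
#' (cases slightly older and more often male); batches are assigned
#' round-robin within each diagnosis group so that every batch carries a
#' balanced case/control mix.
#'
#' @param config a [syntheticConfig()].
#' @return data.frame with subject_id, diagnosis (factor
#'   control/MCI), age, sex, batch.
#' @export
simulateCohort <- function(config) {
  validateConfig(config)
  set.seed(deriveSeed(config$seed, "cohort"))
  n <- config$n_control + config$n_mci
  diagnosis <- factor(rep(c("control", "MCI"),
    c(config$n_control, config$n_mci)), levels = c("control", "MCI"))
  age <- ifelse(diagnosis == "MCI", rnorm(n, 67.1, 9.2), rnorm(n, 62.7, 7.1))
  sex <- ifelse(runif(n) < ifelse(diagnosis == "MCI", 0.42, 0.29),
    "male", "female")
  batch <- integer(n)
  for (lev in levels(diagnosis)) {
    idx <- which(diagnosis == lev)
    batch[idx] <- rep_len(seq_len(config$n_batches), length(idx))
  }
  data.frame(subject_id = sprintf("S%03d", seq_len(n)),
    diagnosis = diagnosis, age = round(age, 1), sex = sex,
    batch = factor(batch))
}

# voxels of an axis-aligned ellipsoid (center ctr, semi-axes ax) as
# column-major linear indices into a grid of dims d
ellipsoidVoxels <- function(ctr, ax, d) {
  lo <- pmax(1, floor(ctr - ax)); hi <- pmin(d, ceiling(ctr + ax))
  g <- expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
  inside <- ((g$x - ctr[1]) / ax[1])^2 + ((g$y - ctr[2]) / ax[2])^2 +
    ((g$z - ctr[3]) / ax[3])^2 <= 1
  g <- g[inside, , drop = FALSE]
  sort(g$x + d[1] * (g$y - 1) + d[1] * d[2] * (g$z - 1))
}

#' Simulate per-subject gray-matter probability volumes
#'
#' Generates a brain-shaped region of high GM probability inside the
#' grid, plants `n_regions` disjoint ellipsoidal atrophy regions, and
#' draws one volume per subject. Case subjects have their planted-region
#' gray matter reduced by `atrophy_effect` (scaled by a per-subject,
#' per-region severity drawn from U(0.5, 1.5)); all subjects additionally
#' receive a per-region anatomical offset (`region_noise_sd`) and
#' per-voxel noise (`gm_noise_sd`). Values are clipped to \[0, 1\].
#'
#' @param config a [syntheticConfig()].
#' @param cohort output of [simulateCohort()].
#' @return list with `gm` (a [GMVolumeSet]), `atlas` (list: `labels`
#'   integer 3D array, `names` data.frame), and `truth` (list:
#'   `region_voxels` per-region column-major linear indices,
#'   `region_centers`).
#' @export
simulateGMVolumes <- function(config, cohort) {
  validateConfig(config)
  set.seed(deriveSeed(config$seed, "gm"))
  d <- config$grid_dims
  ctr <- (d + 1) / 2
  brainAx <- 0.45 * d
  nvox <- prod(d)
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  brainDist2 <- ((g$x - ctr[1]) / brainAx[1])^2 +
    ((g$y - ctr[2]) / brainAx[2])^2 + ((g$z - ctr[3]) / brainAx[3])^2
  inBrain <- brainDist2 <= 1

  baseline <- ifelse(inBrain, runif(nvox, 0.45, 0.65), 0.05)

  # plant disjoint ellipsoidal regions well inside the brain
  r0 <- (3 * config$region_size / (4 * pi))^(1 / 3)
  candidates <- which(brainDist2 <= 0.55^2)
  used <- integer(0)
  regions <- vector("list", config$n_regions)
  centers <- matrix(NA_real_, config$n_regions, 3)
  tries <- 0
  for (r in seq_len(config$n_regions)) {
    repeat {
      tries <- tries + 1
      if (tries > 200 * config$n_regions)
        stop("configuration error: planted regions do not fit in the grid")
      lin <- sample(candidates, 1)
      cc <- c((lin - 1) %% d[1] + 1,
        ((lin - 1) %/% d[1]) %% d[2] + 1,
        (lin - 1) %/% (d[1] * d[2]) + 1)
      ax <- r0 * sample(c(1.25, 1.0, 0.8))
      vox <- ellipsoidVoxels(cc, ax, d)
      if (length(vox) >= 1 && !any(vox %in% used) &&
          all(brainDist2[vox] <= 0.8^2)) {
        regions[[r]] <- vox
        centers[r, ] <- cc
        used <- c(used, vox)
        break
      }
    }
  }

  n <- nrow(cohort)
  flat <- matrix(0, nvox, n)
  isCase <- cohort$diagnosis == "MCI"
  for (s in seq_len(n)) {
    v <- baseline
    for (r in seq_len(config$n_regions)) {
      mult <- if (isCase[s])
        1 - config$atrophy_effect * runif(1, 0.5, 1.5) else 1
      v[regions[[r]]] <- v[regions[[r]]] * mult +
        rnorm(1, 0, config$region_noise_sd)
    }
    v <- v + rnorm(nvox, 0, config$gm_noise_sd)
    flat[, s] <- pmin(1, pmax(0, v))
  }
  arr <- array(flat, dim = c(d, n),
    dimnames = list(NULL, NULL, NULL, cohort$subject_id))
  gm <- new("GMVolumeSet", data = arr, affine = diag(4))

  labels <- array(0L, dim = d)
  for (r in seq_len(config$n_regions)) labels[regions[[r]]] <- r
  atlas <- list(labels = labels,
    names = data.frame(label = seq_len(config$n_regions),
      name = sprintf("region_%02d", seq_len(config$n_regions))))
  list(gm = gm, atlas = atlas,
    truth = list(region_voxels = regions, region_centers = centers))
}

#' Positive-mode adduct mass rules
#'
#' The three singly-charged positive adducts used for m/z annotation:
#' the molecular ion M\[1+\] (minus one electron mass), protonated
#' M+H\[1+\], and sodiated M+Na\[1+\].
#'
#' @return data.frame with `name` and `delta` (Da added to the neutral
#'   monoisotopic mass to obtain the observed m/z at charge +1).
#' @export
adductRules <- function() {
  data.frame(name = c("M[1+]", "M+H[1+]", "M+Na[1+]"),
    delta = c(-0.000549, 1.007276, 22.989218))
}

#' Simulate the raw LC-MS feature table
#'
#' Draws `n_features` m/z features over the instrument scan range
#' 85-1275 Da. Signal features (per planted region) take their m/z from
#' a known compound's monoisotopic mass plus an adduct delta (with at
#' most 2 ppm jitter) and have log2 intensities coupled to the region's
#' subject-mean gray matter at the configured |r|; background features
#' are uncoupled. Intensities are expanded to technical triplicates with
#' the configured CV, shifted per batch, and missingness is injected.
#'
#' @param config a [syntheticConfig()].
#' @param gm a [GMVolumeSet] from [simulateGMVolumes()].
#' @param truth the `truth` list from [simulateGMVolumes()].
#' @param cohort output of [simulateCohort()].
#' @return list with `raw` (a [RawFeatureTable]) and `truth` extended
#'   with `signal_features` (per-region feature ids),
#'   `feature_compound_map`, `compounds` (data.frame compound, mass) and
#'   per-feature realized coupling.
#' @export
simulateFeatureTable <- function(config, gm, truth, cohort) {
  validateConfig(config)
  set.seed(deriveSeed(config$seed, "features"))
  d <- dim(gm@data)
  n <- d[4]
  stopifnot(identical(dimnames(gm@data)[[4]], cohort$subject_id))
  flat <- gm@data
  dim(flat) <- c(prod(d[1:3]), n)

  R <- config$n_regions
  nsig <- config$n_signal_features_per_region
  regionMean <- vapply(truth$region_voxels,
    function(v) colMeans(flat[v, , drop = FALSE]), numeric(n))
  z <- scale(regionMean)  # n x R standardized region-mean GM

  nf <- config$n_features
  adducts <- adductRules()
  nSigTot <- R * nsig
  compounds <- data.frame(
    compound = sprintf("C%04d", seq_len(nSigTot + config$n_background_compounds)),
    mass = runif(nSigTot + config$n_background_compounds, 85, 900))

  featIds <- sprintf("F%04d", seq_len(nf))
  sigRows <- sort(sample(nf, nSigTot))
  sigRegion <- rep(seq_len(R), each = nsig)
  sigAdduct <- sample(nrow(adducts), nSigTot, replace = TRUE)
  theoretical <- compounds$mass[seq_len(nSigTot)] + adducts$delta[sigAdduct]

  mz <- runif(nf, 85, 1275)
  mz[sigRows] <- theoretical * (1 + runif(nSigTot, -2e-6, 2e-6))
  rt <- runif(nf, 20, 600)

  # log2 intensity model
  mu <- runif(nf, 14, 22)
  sigma <- 1.0
  rho <- numeric(nf)
  sgn <- rep(1, nf)
  rho[sigRows] <- pmin(0.95, config$coupling * runif(nSigTot, 0.75, 1.25))
  sgn[sigRows] <- sample(c(-1, 1), nSigTot, replace = TRUE)
  L <- matrix(rnorm(nf * n), nf, n)
  L <- mu + sigma * L
  for (i in seq_len(nSigTot)) {
    f <- sigRows[i]
    L[f, ] <- mu[f] + sigma * (rho[f] * sgn[f] * z[, sigRegion[i]] +
      sqrt(1 - rho[f]^2) * rnorm(n))
  }
  batchShift <- config$batch_shift *
    (as.integer(cohort$batch) - (config$n_batches + 1) / 2)
  L <- sweep(L, 2, batchShift, "+")

  base <- 2^L
  sigmaN <- sqrt(log1p(config$replicate_cv^2))
  reps <- lapply(1:3, function(k)
    base * exp(matrix(rnorm(nf * n, -sigmaN^2 / 2, sigmaN), nf, n)))

  rate <- config$missing_rate_background
  if (rate > 0) {
    if (config$missing_mode == "random") {
      for (k in 1:3)
        reps[[k]][matrix(runif(nf * n) < rate, nf, n)] <- NA
    } else {
      # left-censored: missingness concentrated in low-intensity cells
      pm <- t(apply(L, 1, function(x) 2 * rate * (1 - (rank(x) - 0.5) /
        length(x))))
      for (k in 1:3) reps[[k]][matrix(runif(nf * n), nf, n) < pm] <- NA
    }
  }
  for (k in 1:3)
    dimnames(reps[[k]]) <- list(featIds, cohort$subject_id)

  raw <- new("RawFeatureTable", SummarizedExperiment(
    assays = SimpleList(rep1 = reps[[1]], rep2 = reps[[2]],
      rep3 = reps[[3]]),
    rowData = DataFrame(mz = mz, time = rt, row.names = featIds),
    colData = DataFrame(cohort, row.names = cohort$subject_id)))

  map <- data.frame(feature = featIds[sigRows],
    compound = compounds$compound[seq_len(nSigTot)],
    adduct = adducts$name[sigAdduct],
    mass = compounds$mass[seq_len(nSigTot)],
    theoretical_mz = theoretical, region = sigRegion,
    coupling = rho[sigRows], sign = sgn[sigRows])
  truth$signal_features <- split(map$feature, map$region)
  truth$feature_compound_map <- map
  truth$compounds <- compounds
  list(raw = raw, truth = truth)
}

#' Simulate the compound/pathway reference database
#'
#' Builds a KEGG-like long-format compound table. The planted pathway
#' contains exactly `planted_pathway_size` compounds, all of which are
#' mapped to signal features of the first planted region(s); decoy
#' pathways draw from the remaining (signal and background) compounds so
#' that every compound belongs to at least one pathway.
#'
#' @param config a [syntheticConfig()].
#' @param truth truth list from [simulateFeatureTable()].
#' @return list with `db` (data.frame: compound, mass, pathway_id,
#'   pathway_name) and `truth` extended with `enriched_pathway_id`.
#' @export
simulatePathwayDB <- function(config, truth) {
  validateConfig(config)
  set.seed(deriveSeed(config$seed, "pathways"))
  map <- truth$feature_compound_map
  if (is.null(map)) stop("truth must carry feature_compound_map")
  if (config$planted_pathway_size > nrow(truth$compounds))
    stop("configuration error: planted_pathway_size exceeds compound count")
  planted <- map$compound[order(map$region)][seq_len(config$planted_pathway_size)]
  rest <- setdiff(truth$compounds$compound, planted)

  ids <- sprintf("P%02d", seq_len(config$n_pathways))
  nms <- sprintf("pathway_%02d", seq_len(config$n_pathways))
  rows <- data.frame(compound = planted, pathway_id = ids[1],
    pathway_name = nms[1])
  # decoys: every remaining compound joins 1-3 random decoy pathways
  nDecoy <- config$n_pathways - 1
  for (cmp in rest) {
    k <- sample(1:min(3, nDecoy), 1)
    for (p in sample(seq_len(nDecoy), k) + 1)
      rows <- rbind(rows, data.frame(compound = cmp, pathway_id = ids[p],
        pathway_name = nms[p]))
  }
  db <- merge(rows, truth$compounds, by = "compound", sort = FALSE)
  db <- db[order(db$pathway_id, db$compound),
    c("compound", "mass", "pathway_id", "pathway_name")]
  rownames(db) <- NULL
  truth$enriched_pathway_id <- ids[1]
  list(db = db, truth = truth)
}

#' Simulate a complete synthetic study
#'
#' Runs the cohort, gray-matter, feature-table and pathway-database
#' generators in order under seeds derived from `config$seed`, returning
#' every input the integration pipeline needs together with the ground
#' truth. Identical configurations yield identical studies.
#'
#' @param config a [syntheticConfig()].
#' @return list of class `voxMetabSim` with elements config, cohort,
#'   gm, atlas, raw, db, truth.
#' @examples
#' sim <- simulateStudy(syntheticConfig(n_mci = 6, n_control = 8,
#'   grid_dims = c(12, 12, 12), n_regions = 2, region_size = 10,
#'   n_features = 60, n_signal_features_per_region = 4,
#'   n_pathways = 4, planted_pathway_size = 6,
#'   n_background_compounds = 40))
#' sim$raw
#' @export
simulateStudy <- function(config = syntheticConfig()) {
  validateConfig(config)
  cohort <- simulateCohort(config)
  vols <- simulateGMVolumes(config, cohort)
  feats <- simulateFeatureTable(config, vols$gm, vols$truth, cohort)
  pw <- simulatePathwayDB(config, feats$truth)
  out <- list(config = config, cohort = cohort, gm = vols$gm,
    atlas = vols$atlas, raw = feats$raw, db = pw$db, truth = pw$truth)
  class(out) <- "voxMetabSim"
  out
}
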