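#' @importFrom RNifti writeNifti readNifti
#' @importFrom jsonlite write_json read_json
#' @importFrom yaml write_yaml read_yaml
NULL

fmtNum <- function(x) format(x, digits = 15, trim = TRUE, scientific = FALSE)

#' Write a synthetic study to disk as standard formats
#'
#' Serializes a [simulateStudy()] result: gray-matter volumes as a 4D
#' NIfTI, the atlas as NIfTI plus a label-name table, the raw feature
#' table as tab-delimited text (`mz`, `time`, then
#' `<sample>_rep1..rep3`), subject metadata and the compound/pathway
#' database as tab-delimited text, the configuration as YAML, and a JSON
#' ground-truth manifest recording the seed and a config hash.
#'
#' @param sim a `voxMetabSim` from [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeFixtures <- function(sim, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("I/O error: cannot create '", dir, "'")
  writeNifti(sim$gm@data, file.path(dir, "gm_volumes.nii.gz"),
    datatype = "double")
  writeNifti(sim$atlas$labels, file.path(dir, "atlas.nii.gz"),
    datatype = "int16")
  write.table(sim$atlas$names, file.path(dir, "atlas_labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  reps <- lapply(c("rep1", "rep2", "rep3"), function(a) assay(sim$raw, a))
  samples <- colnames(sim$raw)
  tab <- data.frame(mz = fmtNum(featureMz(sim$raw)),
    time = fmtNum(featureRT(sim$raw)), check.names = FALSE)
  for (s in seq_along(samples)) for (k in 1:3)
    tab[[paste0(samples[s], "_rep", k)]] <- fmtNum(reps[[k]][, s])
  write.table(tab, file.path(dir, "feature_table.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)

  write.table(sim$cohort, file.path(dir, "metadata.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)
  db <- sim$db
  db$mass <- fmtNum(db$mass)
  write.table(db, file.path(dir, "compound_db.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)

  cfg <- sim$config
  write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  manifest <- list(seed = cfg$seed, config_hash = configHash(unclass(cfg)),
    subjects = sim$cohort$subject_id,
    region_voxels = lapply(sim$truth$region_voxels, as.integer),
    signal_features = sim$truth$signal_features,
    feature_compound_map = sim$truth$feature_compound_map,
    enriched_pathway_id = sim$truth$enriched_pathway_id)
  write_json(manifest, file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a fixture set written by [writeFixtures()]
#'
#' @param dir directory written by [writeFixtures()].
#' @return list with the same shape as a [simulateStudy()] result
#'   (config, cohort, gm, atlas, raw, db, truth).
#' @export
readFixtures <- function(dir) {
  cfg <- read_yaml(file.path(dir, "config.yaml"))
  cfg$grid_dims <- as.integer(cfg$grid_dims)
  class(cfg) <- "SyntheticConfig"
  cohort <- read.delim(file.path(dir, "metadata.tsv"))
  cohort$diagnosis <- factor(cohort$diagnosis, levels = c("control", "MCI"))
  cohort$batch <- factor(cohort$batch)

  img <- readNifti(file.path(dir, "gm_volumes.nii.gz"))
  arr <- array(as.vector(img), dim = dim(img))
  dimnames(arr) <- list(NULL, NULL, NULL, cohort$subject_id)
  gm <- new("GMVolumeSet", data = arr, affine = diag(4))
  aimg <- readNifti(file.path(dir, "atlas.nii.gz"))
  labels <- array(as.integer(aimg), dim = dim(aimg))
  atlas <- list(labels = labels,
    names = read.delim(file.path(dir, "atlas_labels.tsv")))

  tab <- read.delim(file.path(dir, "feature_table.tsv"),
    check.names = FALSE)
  samples <- cohort$subject_id
  featIds <- sprintf("F%04d", seq_len(nrow(tab)))
  reps <- lapply(1:3, function(k) {
    m <- as.matrix(tab[, paste0(samples, "_rep", k), drop = FALSE])
    dimnames(m) <- list(featIds, samples)
    m
  })
  raw <- new("RawFeatureTable", SummarizedExperiment(
    assays = SimpleList(rep1 = reps[[1]], rep2 = reps[[2]],
      rep3 = reps[[3]]),
    rowData = DataFrame(mz = tab$mz, time = tab$time,
      row.names = featIds),
    colData = DataFrame(cohort, row.names = samples)))

  db <- read.delim(file.path(dir, "compound_db.tsv"))
  man <- read_json(file.path(dir, "ground_truth.json"),
    simplifyVector = TRUE)
  truth <- list(region_voxels = lapply(man$region_voxels, as.integer),
    signal_features = man$signal_features,
    feature_compound_map = man$feature_compound_map,
    enriched_pathway_id = man$enriched_pathway_id)
  out <- list(config = cfg, cohort = cohort, gm = gm, atlas = atlas,
    raw = raw, db = db, truth = truth)
  class(out) <- "voxMetabSim"
  out
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys are [syntheticConfig()] fields plus any
#' of the pipeline thresholds accepted by [runPipeline()]; unknown keys
#' are rejected so typos fail loudly.
#'
#' @param path YAML file path.
#' @return list with `synthetic` (a validated `SyntheticConfig`) and
#'   `pipeline` (named list of threshold overrides).
#' @export
readPipelineConfig <- function(path) {
  y <- read_yaml(path)
  synNames <- names(formals(syntheticConfig))
  pipeNames <- c("gmThreshold", "vipMin", "pctMin", "alpha", "cutoff",
    "assocMode", "contigMin", "majorityMin", "tolPpm", "nPerm",
    "trainFrac", "kFolds", "maxComponents", "cvMax", "rMin", "missMax",
    "groupRule", "imputeScope", "batchCorrect")
  unknown <- setdiff(names(y), c(synNames, pipeNames))
  if (length(unknown) > 0)
    stop("configuration error: unknown field(s): ",
      paste(unknown, collapse = ", "))
  syn <- y[intersect(names(y), synNames)]
  if (!is.null(syn$grid_dims)) syn$grid_dims <- as.integer(syn$grid_dims)
  list(synthetic = do.call(syntheticConfig, syn),
    pipeline = y[intersect(names(y), pipeNames)])
}
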