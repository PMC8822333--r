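test_that("cohort generation honors group sizes, balance and determinism", {
  cfg <- syntheticConfig(n_mci = 60, n_control = 85)
  cohort <- simulateCohort(cfg)
  expect_equal(nrow(cohort), 145)
  expect_equal(sum(cohort$diagnosis == "MCI"), 60)
  expect_equal(sum(cohort$diagnosis == "control"), 85)
  expect_true(all(c("subject_id", "diagnosis", "age", "sex", "batch") %in%
    colnames(cohort)))
  # batches balanced within each diagnosis group (round-robin)
  tab <- table(cohort$diagnosis, cohort$batch)
  expect_true(all(abs(tab[, 1] - tab[, 2]) <= 1))
  expect_identical(cohort, simulateCohort(cfg))
})

test_that("invalid configurations are rejected", {
  expect_error(syntheticConfig(n_mci = 0), "count >= 1")
  expect_error(syntheticConfig(atrophy_effect = 1), "atrophy_effect")
  expect_error(syntheticConfig(coupling = 1), "coupling")
  expect_error(syntheticConfig(n_pathways = 1), "n_pathways")
  expect_error(
    syntheticConfig(planted_pathway_size = 50,
      n_signal_features_per_region = 4, n_regions = 2),
    "planted_pathway_size")
  # regions that cannot fit in the grid
  cfg <- syntheticConfig(n_mci = 3, n_control = 3,
    grid_dims = c(6, 6, 6), n_regions = 8, region_size = 60)
  expect_error(simulateGMVolumes(cfg, simulateCohort(cfg)),
    "do not fit")
})

test_that("planted regions are disjoint, in-mask and 26-connected", {
  sim <- tinySim()
  vox <- sim$truth$region_voxels
  expect_equal(length(vox), 2)
  expect_length(intersect(vox[[1]], vox[[2]]), 0)
  mask <- buildGMMask(sim$gm)
  for (v in vox) {
    ids <- linearToVoxel(mask, v)
    expect_false(anyNA(ids))
    cc <- connectedComponents(ids, mask)
    expect_equal(length(cc$sizes), 1)
  }
})

test_that("atrophy effect hits the generating mean; null effect vanishes", {
  cfg <- syntheticConfig(n_mci = 100, n_control = 100,
    grid_dims = c(16, 16, 16), n_regions = 2, region_size = 15,
    atrophy_effect = 0.1, gm_noise_sd = 0.01, region_noise_sd = 0.01,
    n_features = 20, n_signal_features_per_region = 2, n_pathways = 3,
    planted_pathway_size = 4, n_background_compounds = 20)
  cohort <- simulateCohort(cfg)
  vols <- simulateGMVolumes(cfg, cohort)
  flat <- vols$gm@data
  dim(flat) <- c(prod(cfg$grid_dims), nrow(cohort))
  planted <- unlist(vols$truth$region_voxels)
  isCase <- cohort$diagnosis == "MCI"
  ratio <- mean(flat[planted, isCase]) / mean(flat[planted, !isCase])
  expect_lt(abs(ratio - 0.9), 0.02)

  cfg0 <- syntheticConfig(n_mci = 100, n_control = 100,
    grid_dims = c(16, 16, 16), n_regions = 2, region_size = 15,
    atrophy_effect = 0, gm_noise_sd = 0.01, region_noise_sd = 0.01,
    n_features = 20, n_signal_features_per_region = 2, n_pathways = 3,
    planted_pathway_size = 4, n_background_compounds = 20)
  vols0 <- simulateGMVolumes(cfg0, simulateCohort(cfg0))
  flat0 <- vols0$gm@data
  dim(flat0) <- c(prod(cfg0$grid_dims), nrow(cohort))
  planted0 <- unlist(vols0$truth$region_voxels)
  diff0 <- mean(flat0[planted0, isCase]) - mean(flat0[planted0, !isCase])
  expect_lt(abs(diff0), 0.01)
})

test_that("signal features couple to region-mean GM at the target |r|", {
  cfg <- syntheticConfig(n_mci = 60, n_control = 85,
    grid_dims = c(16, 16, 16), n_regions = 2, region_size = 15,
    coupling = 0.6, n_features = 300,
    n_signal_features_per_region = 10, n_pathways = 5,
    planted_pathway_size = 10, n_background_compounds = 60)
  cohort <- simulateCohort(cfg)
  vols <- simulateGMVolumes(cfg, cohort)
  feats <- simulateFeatureTable(cfg, vols$gm, vols$truth, cohort)
  med <- summarizeReplicates(feats$raw)
  flat <- vols$gm@data
  dim(flat) <- c(prod(cfg$grid_dims), nrow(cohort))
  map <- feats$truth$feature_compound_map
  rs <- vapply(seq_len(nrow(map)), function(i) {
    rm <- colMeans(flat[vols$truth$region_voxels[[map$region[i]]], ])
    abs(cor(log2(med[map$feature[i], ]), rm, use = "complete.obs"))
  }, numeric(1))
  expect_lt(abs(median(rs) - 0.6), 0.1)

  # null coupling: signal features indistinguishable from background
  cfg0 <- syntheticConfig(n_mci = 30, n_control = 30,
    grid_dims = c(14, 14, 14), n_regions = 2, region_size = 12,
    coupling = 0, n_features = 200, n_signal_features_per_region = 10,
    n_pathways = 4, planted_pathway_size = 8,
    n_background_compounds = 40)
  cohort0 <- simulateCohort(cfg0)
  vols0 <- simulateGMVolumes(cfg0, cohort0)
  feats0 <- simulateFeatureTable(cfg0, vols0$gm, vols0$truth, cohort0)
  med0 <- summarizeReplicates(feats0$raw)
  flat0 <- vols0$gm@data
  dim(flat0) <- c(prod(cfg0$grid_dims), nrow(cohort0))
  map0 <- feats0$truth$feature_compound_map
  rm1 <- colMeans(flat0[vols0$truth$region_voxels[[1]], ])
  rsSig <- vapply(map0$feature[map0$region == 1], function(f)
    abs(cor(log2(med0[f, ]), rm1, use = "complete.obs")), numeric(1))
  bg <- setdiff(rownames(med0), map0$feature)[1:50]
  rsBg <- vapply(bg, function(f)
    abs(cor(log2(med0[f, ]), rm1, use = "complete.obs")), numeric(1))
  expect_gt(suppressWarnings(wilcox.test(rsSig, rsBg)$p.value), 0.01)
})

test_that("signal feature m/z derive from compound mass plus adduct delta", {
  sim <- tinySim()
  map <- sim$truth$feature_compound_map
  ad <- adductRules()
  mz <- setNames(featureMz(sim$raw), rownames(sim$raw))
  for (i in seq_len(nrow(map))) {
    theo <- map$mass[i] + ad$delta[match(map$adduct[i], ad$name)]
    expect_lt(abs(mz[map$feature[i]] - theo) / theo * 1e6, 2.0001)
  }
})

test_that("pathway database plants exactly one fully mapped pathway", {
  sim <- tinySim()
  db <- sim$db
  planted <- db$compound[db$pathway_id == sim$truth$enriched_pathway_id]
  expect_length(planted, sim$config$planted_pathway_size)
  expect_true(all(planted %in% sim$truth$feature_compound_map$compound))
  expect_true(all(db$mass > 0))
  # every mapped compound belongs to at least one pathway
  expect_true(all(sim$truth$feature_compound_map$compound %in% db$compound))
})

test_that("same configuration and seed reproduce the study byte-for-byte", {
  a <- simulateStudy(tinyConfig())
  b <- simulateStudy(tinyConfig())
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$gm@data, b$gm@data)
  expect_identical(assay(a$raw, "rep2"), assay(b$raw, "rep2"))
  expect_identical(a$db, b$db)
})

test_that("fixture sets round-trip through disk losslessly", {
  sim <- tinySim()
  dir <- withr::local_tempdir()
  writeFixtures(sim, dir)
  expect_true(all(file.exists(file.path(dir, c("gm_volumes.nii.gz",
    "atlas.nii.gz", "feature_table.tsv", "metadata.tsv",
    "compound_db.tsv", "ground_truth.json", "config.yaml")))))
  back <- readFixtures(dir)
  expect_equal(back$gm@data, sim$gm@data, tolerance = 1e-12,
    ignore_attr = FALSE)
  expect_equal(assay(back$raw, "rep1"), assay(sim$raw, "rep1"),
    tolerance = 1e-9)
  expect_equal(featureMz(back$raw), featureMz(sim$raw), tolerance = 1e-12)
  expect_identical(back$cohort$diagnosis, sim$cohort$diagnosis)
  expect_identical(back$atlas$labels, sim$atlas$labels)
  expect_identical(sort(back$db$compound), sort(sim$db$compound))
  man <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(man$seed, sim$config$seed)
  expect_match(man$config_hash, "^[0-9a-f]{8}$")
  expect_identical(back$truth$enriched_pathway_id,
    sim$truth$enriched_pathway_id)
})
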