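repArrays <- function(raw)
  lapply(c("rep1", "rep2", "rep3"), function(a) assay(raw, a))

# per-(feature,sample) replicate count, mean and sd across the triplicate
repStats <- function(raw) {
  r <- repArrays(raw)
  k <- (!is.na(r[[1]])) + (!is.na(r[[2]])) + (!is.na(r[[3]]))
  s <- rowSums(array(unlist(lapply(r, function(m) ifelse(is.na(m), 0, m))),
    dim = c(dim(r[[1]]), 3)), dims = 2)
  s2 <- rowSums(array(unlist(lapply(r, function(m)
    ifelse(is.na(m), 0, m^2))), dim = c(dim(r[[1]]), 3)), dims = 2)
  m <- ifelse(k > 0, s / k, NA)
  v <- ifelse(k > 1, pmax(0, (s2 - k * m^2) / (k - 1)), NA)
  list(k = k, mean = m, sd = sqrt(v))
}

initQc <- function(raw) {
  qc <- metadata(raw)$qc
  if (is.null(qc))
    qc <- list(features = data.frame(feature = rownames(raw),
      mz = featureMz(raw), time = featureRT(raw), status = "kept",
      n_imputed = 0L), dropped_samples = character(0), params = list())
  qc
}

#' Drop features with high within-triplicate CV
#'
#' Removes m/z features whose median (across samples) coefficient of
#' variation within technical replicates is at or above `cvMax`
#' (default 0.75, i.e. 75%). The CV uses the sample standard deviation
#' (n-1); the median is taken over samples with at least two non-missing
#' replicates, and features with no such sample are also dropped.
#'
#' @param raw a [RawFeatureTable].
#' @param cvMax CV threshold; features with median CV `>= cvMax` are
#'   removed.
#' @return The filtered [RawFeatureTable]; removals are recorded in the
#'   QC log (status `dropped_cv`).
#' @export
filterReplicateCV <- function(raw, cvMax = 0.75) {
  if (!is.numeric(cvMax) || length(cvMax) != 1 || cvMax <= 0 ||
      !is.finite(cvMax))
    stop("configuration error: cvMax must be a positive number")
  st <- repStats(raw)
  cv <- ifelse(st$k >= 2 & st$mean > 0, st$sd / st$mean,
    ifelse(st$k >= 2 & st$mean == 0, 0, NA))
  medcv <- apply(cv, 1, median, na.rm = TRUE)
  drop <- is.na(medcv) | medcv >= cvMax
  qc <- initQc(raw)
  qc$features$status[match(rownames(raw)[drop], qc$features$feature)] <-
    "dropped_cv"
  qc$params$cv_max <- cvMax
  out <- raw[!drop, ]
  metadata(out)$qc <- qc
  out
}

#' Drop samples with poorly correlated technical replicates
#'
#' For every sample, computes the three pairwise Pearson correlations
#' among its replicate intensity vectors (across features, on
#' pairwise-complete observations) and drops the sample when the minimum
#' pairwise correlation is below `rMin` (or cannot be computed).
#'
#' @param raw a [RawFeatureTable] with at least 3 features.
#' @param rMin minimum pairwise replicate correlation (default 0.7).
#' @return The filtered [RawFeatureTable]; dropped sample ids are
#'   recorded in the QC log.
#' @export
filterSampleReplicateCorr <- function(raw, rMin = 0.7) {
  if (nrow(raw) < 3)
    stop("degenerate input: need at least 3 features to correlate replicates")
  r <- repArrays(raw)
  minr <- vapply(seq_len(ncol(raw)), function(j) {
    v <- cbind(r[[1]][, j], r[[2]][, j], r[[3]][, j])
    cc <- suppressWarnings(cor(v, use = "pairwise.complete.obs"))
    min(cc[upper.tri(cc)], na.rm = FALSE)
  }, numeric(1))
  keep <- !is.na(minr) & minr >= rMin
  qc <- initQc(raw)
  qc$dropped_samples <- c(qc$dropped_samples, colnames(raw)[!keep])
  qc$params$replicate_r_min <- rMin
  out <- raw[, keep]
  metadata(out)$qc <- qc
  out
}

#' Median-summarize technical triplicates
#'
#' Collapses the three replicate assays to one value per feature and
#' sample: the median of the non-missing replicates when at least two
#' are present, otherwise missing.
#'
#' @param raw a [RawFeatureTable].
#' @return numeric matrix (features x samples) with `NA` where fewer
#'   than two replicates were observed.
#' @export
summarizeReplicates <- function(raw) {
  r <- repArrays(raw)
  k <- (!is.na(r[[1]])) + (!is.na(r[[2]])) + (!is.na(r[[3]]))
  s <- rowSums(array(unlist(lapply(r, function(m) ifelse(is.na(m), 0, m))),
    dim = c(dim(r[[1]]), 3)), dims = 2)
  mx <- pmax(r[[1]], r[[2]], r[[3]], na.rm = TRUE)
  mn <- pmin(r[[1]], r[[2]], r[[3]], na.rm = TRUE)
  med <- ifelse(k == 3, s - mx - mn, ifelse(k == 2, s / 2, NA))
  dimnames(med) <- dimnames(r[[1]])
  med
}

#' Filter by group-wise missingness and impute with half the minimum
#'
#' A feature is retained when its missing fraction is below `missMax`
#' in at least one diagnosis group (`groupRule = "either"`, the
#' default; `"both"` requires it in both groups). Missing cells of
#' retained features are set to half the feature's minimum observed
#' intensity (`imputeScope = "feature"`) or half the global minimum
#' (`"global"`).
#'
#' @param mat feature x sample intensity matrix with `NA` for missing.
#' @param diagnosis factor of diagnosis labels aligned with columns.
#' @param missMax missingness threshold (default 0.20).
#' @param groupRule,imputeScope see Description.
#' @return list with `mat` (imputed, no `NA`), `kept`/`dropped` feature
#'   names and `n_imputed` per retained feature.
#' @export
filterImputeMissing <- function(mat, diagnosis, missMax = 0.20,
    groupRule = c("either", "both"),
    imputeScope = c("feature", "global")) {
  groupRule <- match.arg(groupRule)
  imputeScope <- match.arg(imputeScope)
  diagnosis <- droplevels(as.factor(diagnosis))
  if (nlevels(diagnosis) < 2 || any(table(diagnosis) == 0))
    stop("degenerate input: both diagnosis groups must be non-empty")
  fracs <- vapply(levels(diagnosis), function(g)
    rowMeans(is.na(mat[, diagnosis == g, drop = FALSE])), numeric(nrow(mat)))
  keep <- if (groupRule == "either") apply(fracs < missMax, 1, any)
    else apply(fracs < missMax, 1, all)
  kept <- mat[keep, , drop = FALSE]
  nImp <- rowSums(is.na(kept))
  if (any(nImp > 0)) {
    fill <- if (imputeScope == "feature")
      apply(kept, 1, min, na.rm = TRUE) / 2
    else rep(min(kept, na.rm = TRUE) / 2, nrow(kept))
    idx <- which(is.na(kept), arr.ind = TRUE)
    kept[idx] <- fill[idx[, 1]]
  }
  list(mat = kept, kept = rownames(mat)[keep],
    dropped = rownames(mat)[!keep], n_imputed = nImp)
}

quantileNormalizeMatrix <- function(L) {
  ref <- rowMeans(apply(L, 2, sort))
  out <- L
  for (j in seq_len(ncol(L))) {
    o <- order(L[, j])
    grp <- cumsum(c(TRUE, diff(L[o, j]) != 0))
    out[o, j] <- ave(ref, grp)  # ties share the mean of their ranks' refs
  }
  out
}

#' Log2-transform and quantile-normalize an intensity matrix
#'
#' Applies log2 and then quantile normalization across samples: each
#' sample's order statistics are replaced by the across-sample mean of
#' order statistics; tied values receive the mean of the tied ranks'
#' reference values. After normalization every column has identical
#' sorted values, and re-applying the operation is a no-op.
#'
#' @param mat feature x sample matrix of positive intensities (no
#'   missing values; run [filterImputeMissing()] first).
#' @param logTransform set `FALSE` if `mat` is already on the log2
#'   scale.
#' @return matrix of log2 quantile-normalized intensities.
#' @export
log2QuantileNormalize <- function(mat, logTransform = TRUE) {
  if (anyNA(mat))
    stop("numeric-domain error: matrix must have no missing values")
  if (logTransform) {
    if (any(mat <= 0))
      stop("numeric-domain error: intensities must be positive for log2")
    mat <- log2(mat)
  }
  quantileNormalizeMatrix(mat)
}

#' Run the full LC-MS preprocessing cascade
#'
#' Applies, in order: the replicate-CV feature filter, the
#' replicate-correlation sample filter, median summarization of
#' triplicates, empirical-Bayes batch correction on the log2 scale
#' (skipped when there is a single batch), group-wise missingness
#' filtering with half-minimum imputation, and log2 + quantile
#' normalization. Feature counts only decrease and every removal is
#' accounted for in the QC log.
#'
#' @param raw a [RawFeatureTable] whose `colData` carries `diagnosis`
#'   and `batch`.
#' @param cvMax,rMin,missMax,groupRule,imputeScope stage thresholds; see
#'   the stage functions.
#' @param batchCorrect set `FALSE` to skip batch correction.
#' @return a [CleanFeatureTable]; `qcLog()` returns the per-feature
#'   status, imputation counts and dropped samples.
#' @examples
#' sim <- simulateStudy(syntheticConfig(n_mci = 6, n_control = 8,
#'   grid_dims = c(12, 12, 12), n_regions = 2, region_size = 10,
#'   n_features = 60, n_signal_features_per_region = 4,
#'   n_pathways = 4, planted_pathway_size = 6,
#'   n_background_compounds = 40))
#' clean <- preprocessFeatureTable(sim$raw)
#' clean
#' @export
preprocessFeatureTable <- function(raw, cvMax = 0.75, rMin = 0.7,
    missMax = 0.20, groupRule = c("either", "both"),
    imputeScope = c("feature", "global"), batchCorrect = TRUE) {
  groupRule <- match.arg(groupRule)
  imputeScope <- match.arg(imputeScope)
  a <- filterReplicateCV(raw, cvMax)
  b <- filterSampleReplicateCorr(a, rMin)
  if (ncol(b) == 0) stop("degenerate input: all samples failed replicate QC")
  m <- summarizeReplicates(b)

  batch <- droplevels(as.factor(colData(b)$batch))
  if (batchCorrect && nlevels(batch) > 1)
    m <- 2^combatCorrect(log2(m), batch)

  diagnosis <- colData(b)$diagnosis
  fi <- filterImputeMissing(m, diagnosis, missMax, groupRule, imputeScope)
  norm <- log2QuantileNormalize(fi$mat)

  qc <- metadata(b)$qc
  qc$features$status[qc$features$feature %in% fi$dropped] <-
    "dropped_missing"
  qc$features$n_imputed[match(names(fi$n_imputed), qc$features$feature)] <-
    as.integer(fi$n_imputed)
  qc$params <- c(qc$params, list(miss_max = missMax,
    group_rule = groupRule, impute_scope = imputeScope,
    batch_correct = batchCorrect && nlevels(batch) > 1))

  keep <- rownames(b) %in% rownames(norm)
  out <- new("CleanFeatureTable", SummarizedExperiment(
    assays = SimpleList(log2 = norm),
    rowData = rowData(b)[keep, , drop = FALSE],
    colData = colData(b)))
  metadata(out)$qc <- qc
  out
}
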