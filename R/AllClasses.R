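#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData
#' @importFrom S4Vectors metadata metadata<- DataFrame SimpleList
NULL

#' Raw LC-MS feature table with technical replicates
#'
#' Container for an untargeted LC-MS feature table before preprocessing:
#' features (rows, identified by m/z and retention time) by samples
#' (columns), each measured in technical triplicate. Extends
#' [SummarizedExperiment::SummarizedExperiment] with three assays
#' (`rep1`, `rep2`, `rep3`) holding non-negative intensities with `NA`
#' for missing signals. `rowData` must carry `mz` (Da) and `time`
#' (seconds); `colData` must carry `diagnosis` and `batch`.
#'
#' @seealso [rawFeatureTable()] to construct one,
#'   [preprocessFeatureTable()] for the cleaning cascade.
#' @export
setClass("RawFeatureTable", contains = "SummarizedExperiment")

setValidity("RawFeatureTable", function(object) {
  msg <- NULL
  if (!identical(assayNames(object), c("rep1", "rep2", "rep3")))
    msg <- c(msg, "assays must be exactly 'rep1', 'rep2', 'rep3'")
  if (!all(c("mz", "time") %in% colnames(rowData(object))))
    msg <- c(msg, "rowData must contain 'mz' and 'time'")
  if (!all(c("diagnosis", "batch") %in% colnames(colData(object))))
    msg <- c(msg, "colData must contain 'diagnosis' and 'batch'")
  for (a in assayNames(object)) {
    v <- assay(object, a)
    if (any(v < 0, na.rm = TRUE)) {
      msg <- c(msg, "intensities must be non-negative")
      break
    }
  }
  if (nrow(object) > 0) {
    mz <- rowData(object)$mz
    if (any(!is.finite(mz)) || any(mz <= 0))
      msg <- c(msg, "mz must be positive and finite")
    if (any(rowData(object)$time < 0))
      msg <- c(msg, "retention times must be >= 0")
  }
  if (is.null(msg)) TRUE else msg
})

#' Preprocessed LC-MS feature table
#'
#' The output of the preprocessing cascade: a single `log2` assay of
#' quantile-normalized intensities with no missing cells. The per-feature
#' QC log (drop reasons, imputation counts) and the list of samples
#' dropped by the replicate-correlation filter live in
#' `metadata(x)$qc` (see [qcLog()]).
#'
#' @export
setClass("CleanFeatureTable", contains = "SummarizedExperiment")

setValidity("CleanFeatureTable", function(object) {
  msg <- NULL
  if (!identical(assayNames(object), "log2"))
    msg <- c(msg, "assay must be exactly 'log2'")
  else if (anyNA(assay(object, "log2")))
    msg <- c(msg, "log2 assay must not contain missing values")
  if (!"diagnosis" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain 'diagnosis'")
  if (is.null(msg)) TRUE else msg
})

#' Per-subject gray-matter probability volumes
#'
#' Holds one 3D gray-matter probability map per subject on a shared grid
#' with a shared voxel-to-world affine. Values are probabilities in
#' \[0, 1\].
#'
#' @slot data 4D numeric array, `x * y * z * subject`; the 4th dimension
#'   is named by subject id.
#' @slot affine 4x4 voxel-to-world transform shared by all subjects.
#' @export
setClass("GMVolumeSet",
  representation(data = "array", affine = "matrix"))

setValidity("GMVolumeSet", function(object) {
  msg <- NULL
  if (length(dim(object@data)) != 4)
    msg <- c(msg, "data must be a 4D array (x, y, z, subject)")
  if (!identical(dim(object@affine), c(4L, 4L)))
    msg <- c(msg, "affine must be 4x4")
  rng <- range(object@data, na.rm = TRUE)
  if (rng[1] < -1e-8 || rng[2] > 1 + 1e-8)
    msg <- c(msg, "gray-matter probabilities must lie in [0, 1]")
  if (is.null(dimnames(object@data)[[4]]))
    msg <- c(msg, "4th dimension must be named by subject id")
  if (is.null(msg)) TRUE else msg
})

#' Binary gray-matter mask with a 3D/1D index bijection
#'
#' A boolean 3D mask plus the bijection between in-mask 3D coordinates
#' and 1D voxel ids used for all statistical analyses. Voxel id `j`
#' corresponds to row `j` of `coords` and to linear array index
#' `linear[j]` (column-major order).
#'
#' @slot mask logical 3D array.
#' @slot coords integer matrix (voxels x 3) of in-mask i/j/k coordinates.
#' @slot linear integer vector of column-major linear indices, one per
#'   voxel id, strictly increasing.
#' @export
setClass("GMMask",
  representation(mask = "array", coords = "matrix", linear = "integer"))

setValidity("GMMask", function(object) {
  msg <- NULL
  if (!is.logical(object@mask) || length(dim(object@mask)) != 3)
    msg <- c(msg, "mask must be a logical 3D array")
  n <- sum(object@mask)
  if (nrow(object@coords) != n || length(object@linear) != n)
    msg <- c(msg, "coords/linear must enumerate exactly the TRUE voxels")
  if (n > 1 && any(diff(object@linear) <= 0))
    msg <- c(msg, "linear indices must be strictly increasing")
  if (is.null(msg)) TRUE else msg
})

#' Cross-validated PLS-DA model
#'
#' A NIPALS partial least squares discriminant analysis model fit on
#' autoscaled predictors with the class coded +/-1, together with the
#' cross-validation curve used to pick the number of components.
#'
#' @slot weights p x A matrix of unit-norm X-weights.
#' @slot xLoadings p x A matrix of X-loadings.
#' @slot scores n x A matrix of X-scores (orthogonal across components).
#' @slot yLoadings length-A numeric of y-loadings.
#' @slot nComponents integer, the selected component count.
#' @slot cvCurve data.frame with `ncomp` and mean CV `balanced_accuracy`.
#' @slot center,scale per-column centering/scaling applied to X.
#' @slot yMean numeric, mean of the +/-1 coded response.
#' @slot threshold numeric, decision threshold on the fitted response.
#' @slot yLevels character(2): (control level, case level).
#' @export
setClass("PlsdaModel",
  representation(weights = "matrix", xLoadings = "matrix",
    scores = "matrix", yLoadings = "numeric", nComponents = "integer",
    cvCurve = "data.frame", center = "numeric", scale = "numeric",
    yMean = "numeric", threshold = "numeric", yLevels = "character"))

#' Voxel selection by VIP and percent mean difference
#'
#' Per-voxel VIP scores and percent gray-matter difference
#' (control minus case, relative to control), with the ids passing the
#' joint threshold split by direction: `selected` (lower gray matter in
#' cases — the biologically retained direction) and `artifact` (higher
#' gray matter in cases, excluded from integration).
#'
#' @slot vip,pctDiff per-voxel numeric vectors (length = mask voxels).
#' @slot selected,artifact,flagged integer voxel ids; `flagged` holds
#'   voxels excluded for a zero control mean.
#' @slot params list of thresholds used.
#' @export
setClass("VoxelSelection",
  representation(vip = "numeric", pctDiff = "numeric",
    selected = "integer", artifact = "integer", flagged = "integer",
    params = "list"))

setValidity("VoxelSelection", function(object) {
  if (length(intersect(object@selected, object@artifact)) > 0)
    "selected and artifact voxel sets must be disjoint" else TRUE
})

#' Voxel-by-metabolite association matrix
#'
#' Pairwise associations between selected voxels (rows) and clean
#' metabolite features (columns): correlation-scale values in \[-1, 1\]
#' with two-sided p-values and the sample count used.
#'
#' @slot r,p numeric matrices (voxels x metabolites).
#' @slot n integer, subjects used.
#' @slot flagged character, columns/rows with zero variance (r set to 0).
#' @export
setClass("AssociationMatrix",
  representation(r = "matrix", p = "matrix", n = "integer",
    flagged = "character"))

setValidity("AssociationMatrix", function(object) {
  msg <- NULL
  if (!identical(dim(object@r), dim(object@p)))
    msg <- c(msg, "r and p must have identical dimensions")
  if (any(abs(object@r) > 1 + 1e-8, na.rm = TRUE))
    msg <- c(msg, "|r| must be <= 1")
  if (any(object@p < 0 | object@p > 1, na.rm = TRUE))
    msg <- c(msg, "p must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' Thresholded bipartite voxel-metabolite network
#'
#' Edges are exactly the voxel-metabolite pairs with `|r| >= cutoff` and
#' `p < alpha`; the node set contains only endpoints of retained edges
#' (isolated voxels/metabolites are excluded). There are never
#' voxel-voxel or metabolite-metabolite edges.
#'
#' @slot edges data.frame with columns voxel, metabolite, r, p, sign.
#' @slot cutoff,alpha the thresholds used.
#' @export
setClass("BipartiteNetwork",
  representation(edges = "data.frame", cutoff = "numeric",
    alpha = "numeric"))

setValidity("BipartiteNetwork", function(object) {
  msg <- NULL
  need <- c("voxel", "metabolite", "r", "p", "sign")
  if (!all(need %in% colnames(object@edges)))
    msg <- c(msg, "edges must have voxel, metabolite, r, p, sign")
  else if (nrow(object@edges) > 0) {
    if (any(abs(object@edges$r) < object@cutoff - 1e-12))
      msg <- c(msg, "all edges must satisfy |r| >= cutoff")
    if (any(object@edges$p >= object@alpha))
      msg <- c(msg, "all edges must satisfy p < alpha")
  }
  if (is.null(msg)) TRUE else msg
})

#' Modularity communities of a bipartite network
#'
#' A hard partition of the network's nodes into communities maximizing
#' weighted modularity, with the achieved modularity score and node
#' types.
#'
#' @slot membership named integer vector (community id per node).
#' @slot modularity numeric modularity Q of the partition.
#' @slot nodeType named character: "voxel" or "metabolite" per node.
#' @slot method character, "exhaustive" or "louvain".
#' @export
setClass("CommunitySet",
  representation(membership = "integer", modularity = "numeric",
    nodeType = "character", method = "character"))

setValidity("CommunitySet", function(object) {
  if (!identical(names(object@membership), names(object@nodeType)))
    "membership and nodeType must be named identically" else TRUE
})

#' Pathway enrichment result for one voxel-metabolite community
#'
#' Per-pathway overlap counts, right-tail Fisher/hypergeometric p and
#' permutation-based empirical p. `status` is `"ok"` or
#' `"no pathway mapping"` when none of the community's features
#' annotated to a compound.
#'
#' @slot table data.frame: pathway_id, pathway_name, k, K, n, N,
#'   fisher_p, permutation_p.
#' @slot status character.
#' @slot nSignificant,nReference compound counts behind n and N.
#' @export
setClass("EnrichmentResult",
  representation(table = "data.frame", status = "character",
    nSignificant = "integer", nReference = "integer"))

setValidity("EnrichmentResult", function(object) {
  tb <- object@table
  msg <- NULL
  if (nrow(tb) > 0) {
    if (any(tb$k > pmin(tb$K, tb$n)))
      msg <- c(msg, "overlap k must be <= min(K, n)")
    if (any(tb$fisher_p < 0 | tb$fisher_p > 1))
      msg <- c(msg, "fisher_p must lie in [0, 1]")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a RawFeatureTable from replicate matrices
#'
#' @param rep1,rep2,rep3 feature x sample intensity matrices (NA =
#'   missing), identical dimnames.
#' @param mz,time per-feature m/z (Da) and retention time (s).
#' @param sampleData data.frame with at least `diagnosis` and `batch`,
#'   one row per sample.
#' @return a [RawFeatureTable].
#' @export
rawFeatureTable <- function(rep1, rep2, rep3, mz, time, sampleData) {
  new("RawFeatureTable", SummarizedExperiment(
    assays = SimpleList(rep1 = rep1, rep2 = rep2, rep3 = rep3),
    rowData = DataFrame(mz = mz, time = time,
      row.names = rownames(rep1)),
    colData = DataFrame(sampleData, row.names = colnames(rep1))))
}
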