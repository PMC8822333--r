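#' Accessors for voxMetab containers
#'
#' Small accessor functions for the S4 containers; prefer these over
#' direct slot access.
#'
#' @param x a voxMetab object.
#' @return The requested component; see the individual class pages.
#' @name accessors
NULL

#' Per-feature and per-sample QC log of the preprocessing cascade
#'
#' @param x a [CleanFeatureTable] (or any SummarizedExperiment carrying a
#'   `qc` entry in its metadata).
#' @return A list with `features` (data.frame: feature, mz, time, status,
#'   n_imputed) and `dropped_samples` (character).
#' @export
setMethod("qcLog", "SummarizedExperiment", function(x) metadata(x)$qc)

#' @rdname accessors
#' @export
setMethod("featureMz", "SummarizedExperiment",
  function(x) rowData(x)$mz)

#' @rdname accessors
#' @export
setMethod("featureRT", "SummarizedExperiment",
  function(x) rowData(x)$time)

#' @rdname accessors
#' @export
setMethod("subjectIds", "GMVolumeSet",
  function(x) dimnames(x@data)[[4]])

#' @rdname accessors
#' @export
setMethod("nVoxels", "GMMask", function(x) length(x@linear))

#' @rdname accessors
#' @export
setMethod("maskCoords", "GMMask", function(x) x@coords)

#' @rdname accessors
#' @export
setMethod("selectedVoxels", "VoxelSelection", function(x) x@selected)

#' @rdname accessors
#' @export
setMethod("artifactVoxels", "VoxelSelection", function(x) x@artifact)

#' @rdname accessors
#' @export
setMethod("vipScores", "VoxelSelection", function(x) x@vip)

#' @rdname accessors
#' @export
setMethod("pctDiff", "VoxelSelection", function(x) x@pctDiff)

#' @rdname accessors
#' @export
setMethod("networkEdges", "BipartiteNetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("communityMembership", "CommunitySet",
  function(x) x@membership)

#' @rdname accessors
#' @export
setMethod("modularityScore", "CommunitySet", function(x) x@modularity)

#' @rdname accessors
#' @export
setMethod("enrichmentTable", "EnrichmentResult", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("enrichmentStatus", "EnrichmentResult", function(x) x@status)

setMethod("show", "GMVolumeSet", function(object) {
  d <- dim(object@data)
  cat("GMVolumeSet:", d[4], "subjects on a", paste(d[1:3], collapse = " x "),
    "grid\n")
  cat("  GM probability range:",
    paste(signif(range(object@data), 3), collapse = " .. "), "\n")
})

setMethod("show", "GMMask", function(object) {
  cat("GMMask:", nVoxels(object), "of", length(object@mask),
    "voxels in mask (", paste(dim(object@mask), collapse = " x "),
    "grid )\n")
})

setMethod("show", "PlsdaModel", function(object) {
  cat("PlsdaModel:", object@nComponents, "component(s),",
    nrow(object@weights), "predictors\n")
  cat("  CV balanced accuracy at selected size:",
    signif(object@cvCurve$balanced_accuracy[object@nComponents], 4), "\n")
})

setMethod("show", "VoxelSelection", function(object) {
  cat("VoxelSelection:", length(object@selected), "selected,",
    length(object@artifact), "artifact-direction voxels of",
    length(object@vip), "tested\n")
})

setMethod("show", "AssociationMatrix", function(object) {
  cat("AssociationMatrix:", nrow(object@r), "voxels x", ncol(object@r),
    "metabolites, n =", object@n, "\n")
})

setMethod("show", "BipartiteNetwork", function(object) {
  cat("BipartiteNetwork:", nrow(object@edges), "edges between",
    length(unique(object@edges$voxel)), "voxels and",
    length(unique(object@edges$metabolite)), "metabolites\n")
  cat("  |r| >=", signif(object@cutoff, 4), ", p <", object@alpha, "\n")
})

setMethod("show", "CommunitySet", function(object) {
  cat("CommunitySet:", length(unique(object@membership)),
    "communities over", length(object@membership), "nodes (Q =",
    signif(object@modularity, 4), ",", object@method, ")\n")
})

setMethod("show", "EnrichmentResult", function(object) {
  cat("EnrichmentResult [", object@status, "]:", nrow(object@table),
    "pathways tested, n =", object@nSignificant, "of N =",
    object@nReference, "compounds significant\n")
})
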