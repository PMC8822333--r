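#' @rdname qcLog
#' @export
setGeneric("qcLog", function(x) standardGeneric("qcLog"))

#' @rdname accessors
#' @export
setGeneric("featureMz", function(x) standardGeneric("featureMz"))

#' @rdname accessors
#' @export
setGeneric("featureRT", function(x) standardGeneric("featureRT"))

#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname accessors
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))

#' @rdname accessors
#' @export
setGeneric("maskCoords", function(x) standardGeneric("maskCoords"))

#' @rdname accessors
#' @export
setGeneric("selectedVoxels", function(x) standardGeneric("selectedVoxels"))

#' @rdname accessors
#' @export
setGeneric("artifactVoxels", function(x) standardGeneric("artifactVoxels"))

#' @rdname accessors
#' @export
setGeneric("vipScores", function(x) standardGeneric("vipScores"))

#' @rdname accessors
#' @export
setGeneric("pctDiff", function(x) standardGeneric("pctDiff"))

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname accessors
#' @export
setGeneric("communityMembership",
  function(x) standardGeneric("communityMembership"))

#' @rdname accessors
#' @export
setGeneric("modularityScore", function(x) standardGeneric("modularityScore"))

#' @rdname accessors
#' @export
setGeneric("enrichmentTable", function(x) standardGeneric("enrichmentTable"))

#' @rdname accessors
#' @export
setGeneric("enrichmentStatus",
  function(x) standardGeneric("enrichmentStatus"))
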