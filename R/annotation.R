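neighborOffsets <- function(connectivity) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  if (connectivity == 6)
    g <- g[abs(g$dx) + abs(g$dy) + abs(g$dz) == 1, ]
  as.matrix(g)
}

#' Connected components of a voxel set in 3D
#'
#' Partitions a set of mask voxels into spatially connected components
#' under 26-connectivity (voxels sharing a face, edge or corner are
#' neighbors; `connectivity = 6` restricts to faces).
#'
#' @param voxelIds integer mask voxel ids.
#' @param mask a [GMMask].
#' @param connectivity 26 (default) or 6.
#' @return list with `sizes` (component sizes, descending) and
#'   `membership` (component id per input voxel, aligned with
#'   `voxelIds`).
#' @export
connectedComponents <- function(voxelIds, mask, connectivity = 26) {
  stopifnot(connectivity %in% c(6, 26))
  if (length(voxelIds) == 0)
    return(list(sizes = integer(0), membership = integer(0)))
  d <- dim(mask@mask)
  lin <- mask@linear[voxelIds]
  co <- mask@coords[voxelIds, , drop = FALSE]
  off <- neighborOffsets(connectivity)
  # linear-index offsets; boundary wraps are screened with coordinates
  linOff <- off[, 1] + d[1] * off[, 2] + d[1] * d[2] * off[, 3]
  pos <- seq_along(lin)
  edges <- NULL
  for (k in seq_len(nrow(off))) {
    nb <- match(lin + linOff[k], lin)
    ok <- !is.na(nb) &
      abs(co[nb, 1] - co[, 1]) <= 1 &
      abs(co[nb, 2] - co[, 2]) <= 1 &
      abs(co[nb, 3] - co[, 3]) <= 1
    if (any(ok, na.rm = TRUE))
      edges <- rbind(edges, cbind(pos[ok], nb[ok]))
  }
  g <- igraph::graph_from_edgelist(
    rbind(cbind(pos, pos), edges), directed = FALSE)
  comp <- components(g)
  memb <- comp$membership[pos]
  memb <- as.integer(factor(memb, levels = unique(memb)))
  sizes <- sort(tabulate(memb), decreasing = TRUE)
  list(sizes = sizes, membership = memb)
}

#' Annotate a voxel community with a brain region or N/A
#'
#' Maps a community's voxels back to 3D space and judges whether they
#' form a contiguous, atlas-consistent region: the verdict is the
#' majority atlas region name when (a) the largest connected component
#' holds at least `contigMin` of the voxels and (b) the majority region
#' covers at least `majorityMin` of them; otherwise `"N/A"`. Background
#' (label 0) voxels count toward the denominator but can never be the
#' majority region.
#'
#' @param voxelIds integer mask voxel ids of one community.
#' @param mask a [GMMask].
#' @param atlas list with `labels` (integer 3D array on the mask grid)
#'   and `names` (data.frame label/name), e.g. from [simulateStudy()].
#' @param contigMin,majorityMin fraction thresholds (defaults 0.5).
#' @param connectivity 26 (default) or 6.
#' @return one-row data.frame: n_voxels, largest_connected_fraction,
#'   majority_label, majority_fraction, verdict.
#' @export
annotateCluster <- function(voxelIds, mask, atlas, contigMin = 0.5,
    majorityMin = 0.5, connectivity = 26) {
  if (!identical(dim(atlas$labels), dim(mask@mask)))
    stop("input error: atlas grid does not match the mask")
  n <- length(voxelIds)
  if (n == 0)
    return(data.frame(n_voxels = 0L, largest_connected_fraction = NA,
      majority_label = NA_integer_, majority_fraction = NA,
      verdict = "N/A"))
  cc <- connectedComponents(voxelIds, mask, connectivity)
  contig <- cc$sizes[1] / n
  labs <- atlas$labels[mask@linear[voxelIds]]
  fg <- labs[labs != 0]
  if (length(fg) == 0) {
    majLab <- NA_integer_; majFrac <- 0
  } else {
    tab <- sort(table(fg), decreasing = TRUE)
    majLab <- as.integer(names(tab)[1])
    majFrac <- tab[[1]] / n
  }
  ok <- contig >= contigMin && majFrac >= majorityMin && !is.na(majLab)
  verdict <- if (ok)
    atlas$names$name[match(majLab, atlas$names$label)] else "N/A"
  data.frame(n_voxels = as.integer(n),
    largest_connected_fraction = contig,
    majority_label = majLab, majority_fraction = unname(majFrac),
    verdict = verdict)
}

#' Annotate every community of a network
#'
#' @param communities a [CommunitySet].
#' @param mask,atlas,contigMin,majorityMin,connectivity see
#'   [annotateCluster()].
#' @return data.frame with one row per community (column `cluster`
#'   first).
#' @export
annotateCommunities <- function(communities, mask, atlas,
    contigMin = 0.5, majorityMin = 0.5, connectivity = 26) {
  memb <- communities@membership
  type <- communities@nodeType
  ids <- sort(unique(memb))
  rows <- lapply(ids, function(ci) {
    vox <- names(memb)[memb == ci & type == "voxel"]
    cbind(data.frame(cluster = ci),
      annotateCluster(as.integer(sub("^V", "", vox)), mask, atlas,
        contigMin, majorityMin, connectivity))
  })
  do.call(rbind, rows)
}
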