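#' Build the binary gray-matter mask
#'
#' A voxel enters the mask when its across-subject mean gray-matter
#' probability is at least `threshold` (default 0.3, i.e. voxels with
#' less than 30% probability of being gray matter are removed; the
#' boundary value is included). The mask carries the bijection between
#' 3D coordinates and 1D voxel ids used by all downstream statistics.
#'
#' @param gm a [GMVolumeSet].
#' @param threshold probability threshold in \[0, 1\].
#' @return a [GMMask].
#' @export
buildGMMask <- function(gm, threshold = 0.3) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    stop("configuration error: threshold must lie in [0, 1]")
  d <- dim(gm@data)
  if (d[4] < 1) stop("need at least one subject")
  flat <- gm@data
  dim(flat) <- c(prod(d[1:3]), d[4])
  meanGM <- rowMeans(flat)
  mask <- array(meanGM >= threshold, dim = d[1:3])
  linear <- which(mask)
  coords <- which(mask, arr.ind = TRUE)
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  new("GMMask", mask = mask, coords = coords,
    linear = as.integer(linear))
}

#' Map voxel ids to 3D coordinates and back
#'
#' `voxelToCoord()` returns the i/j/k coordinates of mask voxel ids;
#' `coordToVoxel()` inverts it (`NA` for coordinates outside the mask).
#' `linearToVoxel()` converts column-major linear indices of the 3D grid
#' (e.g. planted-region ground truth) to mask voxel ids.
#'
#' @param mask a [GMMask].
#' @param ids integer voxel ids (1-based positions in the mask's flat
#'   order).
#' @param coords integer matrix with columns x, y, z.
#' @param linear column-major linear indices into the full 3D grid.
#' @return coordinates matrix, voxel ids, or voxel ids respectively.
#' @export
voxelToCoord <- function(mask, ids) mask@coords[ids, , drop = FALSE]

#' @rdname voxelToCoord
#' @export
coordToVoxel <- function(mask, coords) {
  d <- dim(mask@mask)
  lin <- coords[, 1] + d[1] * (coords[, 2] - 1) +
    d[1] * d[2] * (coords[, 3] - 1)
  match(lin, mask@linear)
}

#' @rdname voxelToCoord
#' @export
linearToVoxel <- function(mask, linear) match(linear, mask@linear)

#' Extract the subject-by-voxel analysis matrix
#'
#' Flattens the masked gray-matter probabilities to the 2D table used
#' for voxel-wise statistics: one row per subject, one column per mask
#' voxel (in mask flat order, named `V<id>`).
#'
#' @param gm a [GMVolumeSet].
#' @param mask a [GMMask] built on the same grid.
#' @return numeric matrix, subjects x voxels.
#' @export
extractVoxelMatrix <- function(gm, mask) {
  d <- dim(gm@data)
  if (!identical(d[1:3], dim(mask@mask)))
    stop("input error: mask grid does not match the volumes")
  flat <- gm@data
  dim(flat) <- c(prod(d[1:3]), d[4])
  X <- t(flat[mask@linear, , drop = FALSE])
  dimnames(X) <- list(dimnames(gm@data)[[4]],
    sprintf("V%05d", seq_len(nVoxels(mask))))
  X
}

#' Write a per-voxel statistic back to 3D image space
#'
#' The inverse of the flattening transform: places a per-voxel vector
#' (e.g. VIP scores) back at its 3D coordinates, with `fill` elsewhere.
#'
#' @param values numeric vector, one value per mask voxel.
#' @param mask a [GMMask].
#' @param fill value outside the mask (default `NA`).
#' @return 3D numeric array.
#' @export
unflattenVoxels <- function(values, mask, fill = NA_real_) {
  stopifnot(length(values) == nVoxels(mask))
  arr <- array(fill, dim = dim(mask@mask))
  arr[mask@linear] <- values
  arr
}
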