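#' Bounding box of a planning image
#'
#' The box spans the outer corners of all voxels: from the origin minus half
#' a voxel to the far voxel centre plus half a voxel, per axis. The z extent
#' uses the actual slice positions, so non-unit slice gaps are honoured.
#'
#' @param series an [ImageSeries-class] with at least 2 slices.
#' @return A [BoundingBox-class].
#' @export
computeBoundingBox <- function(series) {
  validObject(series)
  d <- dim(series@voxels)
  if (d[3] < 2) stop("degenerate extent: need at least 2 slices")
  sp <- series@spacing
  o <- series@origin
  zmin <- series@slicePositions[1] - sp[3] / 2
  zmax <- series@slicePositions[d[3]] + sp[3] / 2
  BoundingBox(
    c(o[1] - sp[1] / 2, o[2] - sp[2] / 2, zmin),
    c(o[1] + (d[1] - 1) * sp[1] + sp[1] / 2,
      o[2] + (d[2] - 1) * sp[2] + sp[2] / 2, zmax))
}

# continuous grid coordinates of a point set for a box/grid pair:
# voxel centers sit at integers 0..n-1 per axis
.toGridCoords <- function(xy, box, gridShape, axes = 1:2) {
  span <- box@maxCorner - box@minCorner
  sz <- span[axes] / gridShape[axes]
  sweep(sweep(xy, 2, box@minCorner[axes]), 2, sz, "/") - 0.5
}

.gridVoxelSize <- function(box, gridShape)
  (box@maxCorner - box@minCorner) / gridShape

#' Rasterize a structure's contours onto a fixed occupancy grid
#'
#' Voxel (i, j, k) is set iff its centre lies inside (or exactly on the
#' boundary of) a filled contour polygon assigned to z-slab k. Polygons are
#' filled with the even-odd rule, so annular contours keep their holes;
#' multiple contours in one slab are OR-combined. Contours (or parts)
#' outside the box are clipped silently; contours with fewer than 3 points
#' are skipped with a warning.
#'
#' @param record a [StructureRecord-class].
#' @param box the planning-image [BoundingBox-class] from
#'   [computeBoundingBox()].
#' @param gridShape integer(3) target grid, default `c(96, 96, 48)`.
#' @return A [BinaryVolume-class] of shape `gridShape`.
#' @export
rasterizeStructure <- function(record, box, gridShape = c(96L, 96L, 48L)) {
  gridShape <- as.integer(gridShape)
  if (any(gridShape < 1)) stop("gridShape must be >= 1 per axis")
  vol <- array(0L, dim = gridShape)
  sz <- .gridVoxelSize(box, gridShape)[3]
  bySlab <- vector("list", gridShape[3])
  for (ct in record@contours) {
    if (nrow(ct$points) < 3) {
      warning("skipping contour with fewer than 3 points in '",
              record@givenName, "'")
      next
    }
    k <- floor((ct$z - box@minCorner[3]) / sz) + 1
    if (k < 1 || k > gridShape[3]) next  # outside the image: clipped
    bySlab[[k]] <- c(bySlab[[k]],
                     list(.toGridCoords(ct$points, box, gridShape)))
  }
  for (k in seq_len(gridShape[3])) {
    if (is.null(bySlab[[k]])) next
    vol[, , k] <- .fillPolygonsGrid(bySlab[[k]], gridShape[1], gridShape[2])
  }
  new("BinaryVolume", bits = vol, box = box)
}

#' Extract bony anatomy as a binary volume
#'
#' Samples the CT (nearest neighbour) at each target-grid voxel centre and
#' thresholds: strictly greater than `thresholdHU` becomes 1 (so exactly
#' 1300 HU stays 0). Dense cortical bone sits well above 1300 HU, which is
#' the default cut.
#'
#' @param series an [ImageSeries-class].
#' @param box the [BoundingBox-class] the grid spans.
#' @param gridShape integer(3), default `c(96, 96, 48)`.
#' @param thresholdHU finite HU threshold, default 1300.
#' @return A [BinaryVolume-class].
#' @export
extractBonyAnatomy <- function(series, box, gridShape = c(96L, 96L, 48L),
                               thresholdHU = 1300) {
  if (!is.finite(thresholdHU)) stop("thresholdHU must be finite")
  gridShape <- as.integer(gridShape)
  d <- dim(series@voxels)
  sz <- .gridVoxelSize(box, gridShape)
  centers <- lapply(1:3, function(a)
    box@minCorner[a] + (seq_len(gridShape[a]) - 0.5) * sz[a])
  # nearest neighbour; exact half-way ties go to the higher index in x/y
  # and the lower slice in z (first minimum)
  ix <- pmin(pmax(floor((centers[[1]] - series@origin[1]) /
                          series@spacing[1] + 0.5) + 1, 1), d[1])
  iy <- pmin(pmax(floor((centers[[2]] - series@origin[2]) /
                          series@spacing[2] + 0.5) + 1, 1), d[2])
  iz <- vapply(centers[[3]], function(z)
    which.min(abs(series@slicePositions - z)), integer(1))
  sampled <- series@voxels[ix, iy, iz, drop = FALSE]
  new("BinaryVolume", bits = array(as.integer(sampled > thresholdHU),
                                   dim = gridShape), box = box)
}

#' Flatten / unflatten a binary volume
#'
#' The flattening order is fixed and documented: x fastest, then y, then z
#' (slice-major, k slowest). The default 96 x 96 x 48 grid yields a vector
#' of length 442,368. `unflattenVolume()` inverts it exactly.
#'
#' @param volume a [BinaryVolume-class].
#' @return Integer 0/1 vector of length `prod(dim)`.
#' @export
flattenVolume <- function(volume) {
  as.integer(volume@bits)
}

#' @rdname flattenVolume
#' @param values flat 0/1 vector.
#' @param gridShape integer(3) target shape; `prod(gridShape)` must equal
#'   `length(values)`.
#' @param box the [BoundingBox-class] the grid spans.
#' @export
unflattenVolume <- function(values, gridShape, box) {
  gridShape <- as.integer(gridShape)
  if (length(values) != prod(gridShape))
    stop("length mismatch: expected ", prod(gridShape), " values")
  new("BinaryVolume", bits = array(as.integer(values), dim = gridShape),
      box = box)
}

#' Concatenate structure and bony-anatomy feature vectors
#'
#' Structure occupancy first, bone second; the result has twice the length
#' (884,736 at the default grid).
#'
#' @param structureVec,boneVec equal-length flat 0/1 vectors.
#' @return Concatenated vector.
#' @export
concatStructureAndBone <- function(structureVec, boneVec) {
  if (length(structureVec) != length(boneVec))
    stop("length mismatch between structure and bone vectors")
  c(structureVec, boneVec)
}
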