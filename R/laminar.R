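#' Assign voxels to six partially overlapping cortical-depth bins
#'
#' Voxels are assigned by interval membership to six equidistant depth
#' bins centred at 0.1, 0.26, 0.42, 0.58, 0.74 and 0.9 of cortical depth
#' (0 = white-matter boundary, 1 = pial surface): voxel `v` belongs to bin
#' `k` iff `|depth_v - centre_k| <= binHalfwidth`. With the default
#' half-width 0.1, adjacent bins overlap by 0.04 depth units (so
#' neighbouring bins partly share voxels) and the bins jointly cover the
#' whole [0, 1] depth range.
#'
#' @param voxelDepths per-voxel depth fraction in [0, 1].
#' @param binHalfwidth half-width of each bin in depth units.
#' @return A [DepthAssignment-class].
#' @examples
#' a <- assignDepthBins(c(0.10, 0.18, 0.5))
#' binMembers(a, 1)  # voxels 1 and 2
#' @export
assignDepthBins <- function(voxelDepths, binHalfwidth = 0.1) {
  bad <- which(voxelDepths < 0 | voxelDepths > 1 | !is.finite(voxelDepths))
  if (length(bad))
    stop("voxel depths outside [0, 1] at indices: ",
         paste(utils::head(bad, 10), collapse = ", "))
  stopifnot(binHalfwidth > 0)
  membership <- lapply(.LAYER_CENTRES, function(ctr)
    which(abs(voxelDepths - ctr) <= binHalfwidth + 1e-12))
  new("DepthAssignment", binCentres = .LAYER_CENTRES,
      halfwidth = binHalfwidth, membership = membership,
      depths = as.numeric(voxelDepths))
}

#' Restrict a depth assignment to a voxel subset
#'
#' Intersects every bin with a set of voxel indices (e.g. an ROI or an
#' intensity mask) and optionally reindexes members relative to the
#' subset, which is the indexing a [BetaMatrix-class] restricted to those
#' voxels uses.
#'
#' @param assignment a [DepthAssignment-class].
#' @param voxels integer voxel indices to keep.
#' @param reindex logical; if TRUE (default) members are renumbered to
#'   positions within `voxels`.
#' @return A [DepthAssignment-class] over the subset.
#' @export
subsetDepthBins <- function(assignment, voxels, reindex = TRUE) {
  membership <- lapply(assignment@membership, function(m) {
    kept <- intersect(m, voxels)
    if (reindex) match(kept, voxels) else kept
  })
  new("DepthAssignment", binCentres = assignment@binCentres,
      halfwidth = assignment@halfwidth, membership = membership,
      depths = assignment@depths[voxels])
}
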