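#' Back-project classifier weights into visual space
#'
#' Translates per-voxel classifier influence into a visual-field image by
#' pRF-weighted averaging: each pixel's value is
#' `y_i = sum_j(w_ij * x_j) / sum_j(w_ij)`, where `x_j` is voxel j's
#' classifier weight and `w_ij` is voxel j's unnormalised Gaussian pRF
#' evaluated at pixel i, truncated to zero beyond two standard deviations
#' of its centre (Euclidean distance in degrees, boundary-inclusive at
#' exactly 2 sigma). Pixels with zero summed pRF weight (no coverage) are
#' defined as 0, preventing arbitrary inflation where coverage is
#' negligible.
#'
#' @param weights a [WeightMap-class] (voxel influences `x_j`).
#' @param models per-voxel pRF fits (as from [fitPrfGrid()]); rows must
#'   cover the weight map's voxel indices.
#' @param grid the [VisualFieldGrid-class] to project onto.
#' @return A [ProjectionMap-class].
#' @export
backprojectWeights <- function(weights, models, grid) {
  stopifnot(is(weights, "WeightMap"), is(grid, "VisualFieldGrid"))
  vox <- weights@voxels
  if (any(vox < 1 | vox > nrow(models)))
    stop("weight map and pRF models index different voxel sets")
  m <- models[vox, , drop = FALSE]
  px <- pixelCentres(grid)
  d2 <- outer(px[, 1], m$x, "-")^2 + outer(px[, 2], m$y, "-")^2
  W <- exp(-d2 / (2 * rep(m$sigma^2, each = nrow(px))))
  W[d2 > rep((2 * m$sigma)^2, each = nrow(px))] <- 0   # truncate > 2 sigma
  coverage <- rowSums(W)
  y <- as.numeric(W %*% weights@weights)
  y <- ifelse(coverage > 0, y / coverage, 0)
  n <- grid@nPixels
  new("ProjectionMap", grid = grid,
      values = matrix(y, n, n),
      coverage = matrix(coverage, n, n))
}
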