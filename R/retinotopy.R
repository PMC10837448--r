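#' Fourier phase mapping of a retinotopic run
#'
#' Applies a Fourier transform to each voxel's time series and extracts
#' amplitude and phase at the stimulation frequency, plus an F-ratio: the
#' squared amplitude at the stimulation frequency divided by the mean of
#' the squared amplitudes at all other nonzero frequencies. Baseline
#' volumes at the start and end of the run can be excluded so the analysed
#' window contains a whole number of stimulation cycles.
#'
#' @param run voxel x time matrix (one mapping run).
#' @param stimulationPeriodS duration of one stimulation cycle (s),
#'   e.g. 64.
#' @param trS repetition time (s).
#' @param nBaselineVols number of baseline volumes to drop at each end of
#'   the run (e.g. 6 for a 12-s baseline at TR = 2 s).
#' @return data.frame with one row per voxel: `amplitude` (in the units of
#'   the data; a pure sinusoid of amplitude A returns A), `phase`
#'   (radians, in (-pi, pi]) and `fRatio`.
#' @export
fourierPhaseMap <- function(run, stimulationPeriodS, trS,
                            nBaselineVols = 0L) {
  if (is.vector(run)) run <- matrix(run, nrow = 1)
  n0 <- ncol(run)
  if (nBaselineVols > 0)
    run <- run[, (nBaselineVols + 1L):(n0 - nBaselineVols), drop = FALSE]
  n <- ncol(run)
  k <- n * trS / stimulationPeriodS        # cycles in the analysed window
  if (abs(k - round(k)) > 1e-8 || round(k) < 2)
    stop("stimulation frequency not representable: the analysed window ",
         "must contain an integer number (>= 2) of stimulation cycles")
  k <- round(k)
  X <- t(apply(run, 1, fft))               # voxels x n complex
  if (n == 1L) X <- matrix(X, nrow = nrow(run))
  pow <- Mod(X)^2
  nyq <- floor(n / 2)
  others <- setdiff(seq_len(nyq), k)
  num <- pow[, k + 1L]
  den <- rowMeans(pow[, others + 1L, drop = FALSE])
  fRatio <- ifelse(num == 0, 0, ifelse(den == 0, Inf, num / den))
  # reference the phase back to the start of the full run, so excluding
  # baseline volumes does not shift the reported phase
  shift <- 2 * pi * nBaselineVols * trS / stimulationPeriodS
  ph <- Arg(X[, k + 1L]) - shift
  ph <- ph - 2 * pi * ceiling((ph - pi) / (2 * pi))  # wrap to (-pi, pi]
  data.frame(amplitude = 2 * Mod(X[, k + 1L]) / n,
             phase = ph,
             fRatio = fRatio)
}

#' Build a pRF candidate grid
#'
#' Candidate isotropic Gaussian pRF models over the mapped visual field:
#' a fixed number of sizes (standard deviations), and for each size a
#' square lattice of candidate centres spaced one standard deviation
#' apart, all within the field extent.
#'
#' @param halfExtent field half-extent (deg); candidate centres satisfy
#'   `|x| <= halfExtent`, `|y| <= halfExtent`.
#' @param nSigma number of sizes (default 24).
#' @param sigmaRange range of sizes (deg); sizes are log-spaced.
#' @return List of class `PRFGrid` with `sigmaLevels` and a `candidates`
#'   data.frame (`x`, `y`, `sigma`), sorted by sigma, then x, then y, so
#'   that ties in fit quality resolve to the smallest size and then the
#'   lexicographically smallest centre.
#' @export
makePrfGrid <- function(halfExtent, nSigma = 24,
                        sigmaRange = c(0.2, 4.8)) {
  stopifnot(halfExtent > 0, nSigma >= 1, all(sigmaRange > 0))
  sigmaLevels <- exp(seq(log(sigmaRange[1]), log(sigmaRange[2]),
                         length.out = nSigma))
  cand <- lapply(sigmaLevels, function(s) {
    kmax <- floor(halfExtent / s)
    ax <- (-kmax:kmax) * s
    g <- expand.grid(y = ax, x = ax)[, c("x", "y")]
    g <- g[g$x^2 + g$y^2 <= halfExtent^2 + 1e-9, ]   # stimulated disc
    g <- g[order(g$x, g$y), ]
    data.frame(x = g$x, y = g$y, sigma = s)
  })
  structure(list(sigmaLevels = sigmaLevels,
                 halfExtent = halfExtent,
                 candidates = do.call(rbind, cand)),
            class = "PRFGrid")
}

#' Predict a voxel time course from a pRF model and a stimulus aperture
#'
#' The neural drive at each frame is the sum over grid pixels of the
#' aperture occupancy times an isotropic Gaussian centred on the pRF;
#' the drive is then convolved with the two-gamma HRF sampled at the
#' aperture's TR.
#'
#' @param model list or one-row data.frame with `x`, `y`, `sigma`.
#' @param aperture a [StimulusAperture-class].
#' @param hrf an [hrfParams()] list.
#' @return Numeric prediction, one value per aperture frame (unitless).
#' @export
predictPrfTimecourse <- function(model, aperture, hrf = hrfParams()) {
  E <- aperture@grid@halfExtent
  if (abs(model$x) > E || abs(model$y) > E)
    stop("pRF centre lies outside the grid extent")
  px <- pixelCentres(aperture@grid)
  g <- exp(-((px[, 1] - model$x)^2 + (px[, 2] - model$y)^2) /
             (2 * model$sigma^2))
  drive <- as.numeric(g %*% apertureFrames(aperture))
  kern <- twoGammaHrf(hrf, trS = aperture@trS)
  convolve(drive, rev(kern), type = "open")[seq_along(drive)]
}

# HRF-convolved predictions for every grid candidate, concatenated across
# apertures: candidates x total frames.
.prfPredictions <- function(grid, apertures, hrf = hrfParams()) {
  cand <- grid$candidates
  blocks <- lapply(apertures, function(ap) {
    px <- pixelCentres(ap@grid)
    kern <- twoGammaHrf(hrf, trS = ap@trS)
    lk <- length(kern)
    P <- matrix(0, nrow(cand), ncol(apertureFrames(ap)))
    for (s in unique(cand$sigma)) {
      rows <- which(cand$sigma == s)
      G <- exp(-(outer(cand$x[rows], px[, 1], "-")^2 +
                   outer(cand$y[rows], px[, 2], "-")^2) / (2 * s^2))
      D <- G %*% apertureFrames(ap)         # candidates x frames
      padded <- rbind(matrix(0, lk - 1L, length(rows)), t(D))
      conv <- stats::filter(padded, kern, method = "convolution",
                            sides = 1)
      P[rows, ] <- t(conv[lk:nrow(padded), , drop = FALSE])
    }
    P
  })
  do.call(cbind, blocks)
}

#' Fit pRF models by exhaustive grid search
#'
#' Scores every candidate model by the squared Pearson correlation (r2)
#' between its HRF-convolved predicted time course and the observed time
#' course, concatenated across the supplied mapping runs (wedge and ring),
#' and returns the best candidate per voxel. Amplitude and offset are
#' implicitly free because the score is correlation-based. Ties are broken
#' by the smallest size, then the lexicographically smallest centre.
#' All-constant voxels get a sentinel model with r2 = 0.
#'
#' @param voxTs voxel x time matrix (or single time course), columns
#'   concatenated in the same order as `apertures`.
#' @param apertures list of [StimulusAperture-class] objects (e.g. wedge
#'   and ring) whose total frame count matches `ncol(voxTs)`.
#' @param grid a [makePrfGrid()] grid.
#' @param hrf an [hrfParams()] list.
#' @return data.frame with one row per voxel: `x`, `y`, `sigma`, `r2`.
#' @export
fitPrfGrid <- function(voxTs, apertures, grid, hrf = hrfParams()) {
  if (is.vector(voxTs)) voxTs <- matrix(voxTs, nrow = 1)
  stopifnot(inherits(grid, "PRFGrid"))
  totFrames <- sum(vapply(apertures, nFrames, 1L))
  if (ncol(voxTs) != totFrames)
    stop("voxTs columns must match the total aperture frame count")
  P <- .prfPredictions(grid, apertures, hrf)
  Pz <- .rowStandardise(P)
  Xz <- .rowStandardise(voxTs)
  r2 <- (tcrossprod(Pz, Xz) / (totFrames - 1))^2  # candidates x voxels
  best <- apply(r2, 2, which.max)
  flat <- rowSums(Xz^2) == 0
  out <- grid$candidates[best, c("x", "y", "sigma")]
  out$r2 <- r2[cbind(best, seq_len(ncol(r2)))]
  if (any(flat)) {
    out$x[flat] <- 0; out$y[flat] <- 0
    out$sigma[flat] <- grid$sigmaLevels[1]
    out$r2[flat] <- 0
  }
  rownames(out) <- NULL
  out
}

# Centre and scale rows to unit variance; zero-variance rows become zero.
.rowStandardise <- function(M) {
  M <- M - rowMeans(M)
  s <- sqrt(rowSums(M^2) / (ncol(M) - 1))
  s[s == 0] <- Inf
  M / s
}

#' Visual-field region constructors
#'
#' Geometric target regions over the visual field used for ROI definition:
#' a disc, a semicircle (a disc clipped by a half-plane), or a union of
#' regions. Coordinates and radii are in degrees; `normalAngle` is the
#' direction (radians) of the half-plane normal pointing into the kept
#' side, and `edgeOffset` its signed distance from the origin along that
#' normal.
#'
#' @param radius disc radius (deg), > 0.
#' @param centre disc centre, `c(x, y)` in degrees.
#' @param normalAngle direction of the half-plane normal (radians).
#' @param edgeOffset signed distance of the straight edge from the origin.
#' @param ... regions to combine in [unionRegion()].
#' @return A region description list of class `VisualFieldRegion`.
#' @export
discRegion <- function(radius, centre = c(0, 0)) {
  if (radius <= 0) stop("region must have positive area")
  structure(list(type = "disc", radius = radius, centre = centre),
            class = "VisualFieldRegion")
}

#' @rdname discRegion
#' @export
semicircleRegion <- function(radius, centre = c(0, 0), normalAngle = 0,
                             edgeOffset = 0) {
  if (radius <= 0 || edgeOffset >= radius)
    stop("region must have positive area")
  structure(list(type = "semicircle", radius = radius, centre = centre,
                 normalAngle = normalAngle, edgeOffset = edgeOffset),
            class = "VisualFieldRegion")
}

#' @rdname discRegion
#' @export
unionRegion <- function(...) {
  parts <- list(...)
  if (!length(parts)) stop("region must have positive area")
  stopifnot(all(vapply(parts, inherits, TRUE, "VisualFieldRegion")))
  structure(list(type = "union", parts = parts),
            class = "VisualFieldRegion")
}

# TRUE where the closed disc of radius `spread` around (x, y) lies fully
# inside the region (boundary-inclusive). For unions, containment within a
# single component is required (conservative for overlapping components).
.discContained <- function(x, y, spread, region) {
  switch(region$type,
         disc = sqrt((x - region$centre[1])^2 +
                       (y - region$centre[2])^2) + spread <=
           region$radius + 1e-12,
         semicircle = {
           u <- c(cos(region$normalAngle), sin(region$normalAngle))
           inDisc <- sqrt((x - region$centre[1])^2 +
                            (y - region$centre[2])^2) + spread <=
             region$radius + 1e-12
           inHalf <- (x * u[1] + y * u[2]) - region$edgeOffset >=
             spread - 1e-12
           inDisc & inHalf
         },
         union = {
           hit <- rep(FALSE, length(x))
           for (p in region$parts)
             hit <- hit | .discContained(x, y, spread, p)
           hit
         },
         stop("unknown region type"))
}

#' Define an ROI from fitted pRF models
#'
#' A voxel joins the ROI if its fit quality exceeds the r2 threshold and
#' the disc of one standard deviation around its fitted pRF centre lies
#' entirely within the target region. If a stacked-column map is supplied,
#' all voxels belonging to a passing voxel's cortical column are added and
#' flagged as completed, so every cortical depth is represented without a
#' bias towards the superficial voxels that dominate above-threshold fits.
#'
#' @param models per-voxel pRF fits as returned by [fitPrfGrid()].
#' @param region a [discRegion()], [semicircleRegion()] or
#'   [unionRegion()].
#' @param r2Threshold include voxels with `r2 > r2Threshold` (e.g. 0.2, or
#'   0.1 for small target regions).
#' @param stackedColumns optional integer vector mapping each voxel to a
#'   cortical-column id for depth completion.
#' @param name ROI label.
#' @return An [ROI-class].
#' @export
defineRoi <- function(models, region, r2Threshold = 0.2,
                      stackedColumns = NULL, name = "roi") {
  stopifnot(inherits(region, "VisualFieldRegion"))
  pass <- models$r2 > r2Threshold &
    .discContained(models$x, models$y, models$sigma, region)
  voxels <- which(pass)
  completed <- rep(FALSE, length(voxels))
  if (!is.null(stackedColumns)) {
    stopifnot(length(stackedColumns) == nrow(models))
    cols <- unique(stackedColumns[voxels])
    added <- setdiff(which(stackedColumns %in% cols), voxels)
    voxels <- c(voxels, added)
    completed <- c(completed, rep(TRUE, length(added)))
    ord <- order(voxels)
    voxels <- voxels[ord]
    completed <- completed[ord]
  }
  new("ROI", name = name, region = unclass(region),
      voxels = as.integer(voxels), completed = completed,
      r2Threshold = r2Threshold)
}
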