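#' @import methods
#' @importFrom stats convolve dgamma fft p.adjust predict quantile rnorm
#'   runif sd
NULL

#' VisualFieldGrid: a square pixel grid over the visual field
#'
#' A square grid of pixels centred on fixation, used to rasterise stimulus
#' apertures and population receptive fields (pRFs). Coordinates are in
#' degrees of visual angle; pixel positions are the centres of the grid
#' cells.
#'
#' @slot halfExtent numeric(1), degrees of visual angle from fixation to the
#'   grid edge.
#' @slot nPixels integer(1), number of pixels per side (>= 8).
#' @export
setClass("VisualFieldGrid",
         representation(halfExtent = "numeric", nPixels = "integer"))

setValidity("VisualFieldGrid", function(object) {
  msg <- NULL
  if (length(object@halfExtent) != 1L || !is.finite(object@halfExtent) ||
      object@halfExtent <= 0)
    msg <- c(msg, "halfExtent must be a single positive number (degrees)")
  if (length(object@nPixels) != 1L || object@nPixels < 8L)
    msg <- c(msg, "nPixels must be a single integer >= 8")
  if (is.null(msg)) TRUE else msg
})

#' Construct a visual-field grid
#'
#' @param halfExtent degrees of visual angle from fixation to the grid edge.
#' @param nPixels pixels per side (>= 8).
#' @return A [VisualFieldGrid-class] object.
#' @examples
#' g <- VisualFieldGrid(6.2, 32)
#' head(pixelCentres(g))
#' @export
VisualFieldGrid <- function(halfExtent, nPixels) {
  new("VisualFieldGrid", halfExtent = as.numeric(halfExtent),
      nPixels = as.integer(nPixels))
}

#' @describeIn VisualFieldGrid pixel centre coordinates as an (nPixels^2 x 2)
#'   matrix with columns `x`, `y` (degrees), row-major over y then x.
#' @param grid a `VisualFieldGrid`.
#' @export
pixelCentres <- function(grid) {
  stopifnot(is(grid, "VisualFieldGrid"))
  step <- 2 * grid@halfExtent / grid@nPixels
  ax <- -grid@halfExtent + step * (seq_len(grid@nPixels) - 0.5)
  cbind(x = rep(ax, times = grid@nPixels),
        y = rep(ax, each = grid@nPixels))
}

#' @describeIn VisualFieldGrid spacing between adjacent pixel centres
#'   (degrees).
#' @export
pixelSpacing <- function(grid) 2 * grid@halfExtent / grid@nPixels

setMethod("show", "VisualFieldGrid", function(object) {
  cat("VisualFieldGrid:", object@nPixels, "x", object@nPixels,
      "pixels over [", -object@halfExtent, ",", object@halfExtent,
      "] deg\n")
})

#' StimulusAperture: per-volume binary stimulus occupancy
#'
#' Binary occupancy of a visual stimulus over the pixels of a
#' [VisualFieldGrid-class], one column per acquired volume (frame).
#'
#' @slot grid the underlying `VisualFieldGrid`.
#' @slot frames numeric matrix (nPixels^2 x nFrames) with values in \{0, 1\}.
#' @slot trS numeric(1), volume repetition time in seconds.
#' @slot kind one of `"wedge"`, `"ring"`, `"task_block"`.
#' @export
setClass("StimulusAperture",
         representation(grid = "VisualFieldGrid", frames = "matrix",
                        trS = "numeric", kind = "character"))

setValidity("StimulusAperture", function(object) {
  msg <- NULL
  if (!all(object@frames %in% c(0, 1)))
    msg <- c(msg, "frame values must be 0 or 1")
  if (nrow(object@frames) != object@grid@nPixels^2)
    msg <- c(msg, "frames must have one row per grid pixel")
  if (!object@kind %in% c("wedge", "ring", "task_block"))
    msg <- c(msg, "kind must be 'wedge', 'ring' or 'task_block'")
  if (object@trS <= 0) msg <- c(msg, "trS must be positive")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn StimulusAperture the frame matrix (pixels x frames).
#' @param aperture a `StimulusAperture`.
#' @export
apertureFrames <- function(aperture) aperture@frames

#' @describeIn StimulusAperture number of frames (volumes).
#' @export
nFrames <- function(aperture) ncol(aperture@frames)

setMethod("show", "StimulusAperture", function(object) {
  cat("StimulusAperture (", object@kind, "): ", ncol(object@frames),
      " frames, TR = ", object@trS, " s, grid ", object@grid@nPixels,
      "^2 px\n", sep = "")
})

#' TrialDesign: block onsets for the five-condition task
#'
#' One row per 8-s task block with its run, condition, colour, onset and
#' duration. Within every run each of the five conditions appears six
#' times, three per colour.
#'
#' @slot events data.frame with columns `run`, `condition`, `colour`,
#'   `onset` (s), `duration` (s).
#' @slot nRuns integer(1).
#' @export
setClass("TrialDesign",
         representation(events = "data.frame", nRuns = "integer"))

.TASK_CONDITIONS <- c("perception", "imagery", "illusory", "amodal", "mock")
.TASK_COLOURS <- c("red", "green")

setValidity("TrialDesign", function(object) {
  ev <- object@events
  msg <- NULL
  need <- c("run", "condition", "colour", "onset", "duration")
  if (!all(need %in% names(ev)))
    return(paste("events must have columns", paste(need, collapse = ", ")))
  if (!all(ev$duration == 8))
    msg <- c(msg, "all task blocks must last 8 s")
  if (!all(ev$condition %in% .TASK_CONDITIONS))
    msg <- c(msg, "unknown condition label")
  if (!all(ev$colour %in% .TASK_COLOURS))
    msg <- c(msg, "colour must be 'red' or 'green'")
  for (r in unique(ev$run)) {
    tab <- table(ev$condition[ev$run == r], ev$colour[ev$run == r])
    if (!all(tab == 3L))
      msg <- c(msg, sprintf("run %s: condition x colour cells must all be 3", r))
    ons <- sort(ev$onset[ev$run == r])
    gaps <- diff(ons) - 8
    if (length(gaps) && (min(gaps) < 7 - 1e-9 || max(gaps) > 8 + 1e-9))
      msg <- c(msg, sprintf("run %s: inter-block gaps must lie in [7, 8] s", r))
  }
  if (is.null(msg)) TRUE else msg
})

#' @describeIn TrialDesign the event table.
#' @param design a `TrialDesign`.
#' @export
designEvents <- function(design) design@events

#' @describeIn TrialDesign number of runs.
#' @export
nRuns <- function(design) design@nRuns

setMethod("show", "TrialDesign", function(object) {
  cat("TrialDesign:", nrow(object@events), "blocks over", object@nRuns,
      "runs (5 conditions x 2 colours x 3 repeats per run)\n")
})

#' LaminarSubject: a simulated laminar fMRI subject
#'
#' Container for one synthetic subject: task runs, retinotopic mapping runs
#' (wedge and ring), the trial design, and per-voxel ground truth (pRF
#' parameters, cortical depth, baseline, amplitude gain, pattern weights).
#'
#' @slot taskRuns list of voxel x time matrices (one per run).
#' @slot retinotopyRuns list with elements `wedge` and `ring`
#'   (voxel x time matrices), possibly empty.
#' @slot design a [TrialDesign-class].
#' @slot truth data.frame of per-voxel ground truth: `prfX`, `prfY`,
#'   `prfSigma` (deg), `depth` (0 = white-matter boundary, 1 = pial
#'   surface), `column` (stacked-column id), `baseline`, `gain`.
#' @slot patternWeights numeric array voxel x condition x colour of signed
#'   response amplitudes.
#' @slot grid the [VisualFieldGrid-class] used for the retinotopy stimuli.
#' @slot trS repetition time (s).
#' @slot seed integer seed the subject was generated from.
#' @slot config the generator configuration list.
#' @export
setClass("LaminarSubject",
         representation(taskRuns = "list", retinotopyRuns = "list",
                        design = "TrialDesign", truth = "data.frame",
                        patternWeights = "array", grid = "VisualFieldGrid",
                        trS = "numeric", seed = "integer", config = "list"))

setValidity("LaminarSubject", function(object) {
  msg <- NULL
  nv <- nrow(object@truth)
  for (m in c(object@taskRuns, object@retinotopyRuns))
    if (nrow(m) != nv)
      msg <- c(msg, "all runs must share the subject's voxel set")
  if (any(object@truth$depth < 0 | object@truth$depth > 1))
    msg <- c(msg, "voxel depths must lie in [0, 1]")
  if (any(object@truth$prfSigma <= 0))
    msg <- c(msg, "pRF sigma must be positive")
  if (any(object@truth$gain <= 0))
    msg <- c(msg, "amplitude gain must be positive")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn LaminarSubject number of voxels.
#' @param subject a `LaminarSubject`.
#' @export
nVoxels <- function(subject) nrow(subject@truth)

#' @describeIn LaminarSubject list of task-run voxel x time matrices.
#' @export
taskRuns <- function(subject) subject@taskRuns

#' @describeIn LaminarSubject list of retinotopy voxel x time matrices.
#' @export
retinotopyRuns <- function(subject) subject@retinotopyRuns

#' @describeIn LaminarSubject per-voxel ground-truth table.
#' @export
subjectTruth <- function(subject) subject@truth

#' @describeIn LaminarSubject the subject's `TrialDesign`.
#' @export
subjectDesign <- function(subject) subject@design

setMethod("show", "LaminarSubject", function(object) {
  cat("LaminarSubject:", nVoxels(object), "voxels,",
      length(object@taskRuns), "task runs,",
      length(object@retinotopyRuns), "retinotopy runs, TR =",
      object@trS, "s, seed =", object@seed, "\n")
})

#' BetaMatrix: trial-wise GLM response estimates
#'
#' Trial x voxel beta estimates from the per-trial GLM, together with the
#' (run, condition, colour) label of every trial. This is the decoding
#' substrate.
#'
#' @slot values numeric matrix, trials x voxels.
#' @slot labels data.frame with columns `run`, `condition`, `colour`,
#'   `onset`, rows aligned with `values`.
#' @export
setClass("BetaMatrix",
         representation(values = "matrix", labels = "data.frame"))

setValidity("BetaMatrix", function(object) {
  msg <- NULL
  if (nrow(object@values) != nrow(object@labels))
    msg <- c(msg, "one label row per trial required")
  if (!all(c("run", "condition", "colour") %in% names(object@labels)))
    msg <- c(msg, "labels need columns run, condition, colour")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "beta values must be finite")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn BetaMatrix the trial x voxel value matrix.
#' @param betas a `BetaMatrix`.
#' @export
betaValues <- function(betas) betas@values

#' @describeIn BetaMatrix the trial label table.
#' @export
betaLabels <- function(betas) betas@labels

setMethod("show", "BetaMatrix", function(object) {
  cat("BetaMatrix:", nrow(object@values), "trials x", ncol(object@values),
      "voxels (", length(unique(object@labels$run)), "runs )\n")
})

#' DepthAssignment: voxel membership in cortical-depth bins
#'
#' Membership of voxels in six equidistant, partially overlapping
#' cortical-depth bins centred at 0.1, 0.26, 0.42, 0.58, 0.74 and 0.9
#' (0 = white-matter boundary, 1 = pial surface). A voxel belongs to every
#' bin whose centre is within `halfwidth` of its depth, so adjacent bins
#' partly share voxels.
#'
#' @slot binCentres the six bin-centre depths.
#' @slot halfwidth half-width of each bin in depth units.
#' @slot membership list of integer vectors, voxel indices per bin.
#' @slot depths the per-voxel depth fractions the assignment was built from.
#' @export
setClass("DepthAssignment",
         representation(binCentres = "numeric", halfwidth = "numeric",
                        membership = "list", depths = "numeric"))

setValidity("DepthAssignment", function(object) {
  msg <- NULL
  if (length(object@binCentres) != 6L)
    msg <- c(msg, "exactly 6 depth bins required")
  if (length(object@membership) != length(object@binCentres))
    msg <- c(msg, "one membership set per bin required")
  if (any(abs(diff(object@binCentres) - 0.16) > 1e-9))
    msg <- c(msg, "consecutive bin centres must differ by 0.16")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn DepthAssignment voxel indices belonging to bin `k`.
#' @param assignment a `DepthAssignment`.
#' @param k bin index in 1..6 (1 = deepest).
#' @export
binMembers <- function(assignment, k) assignment@membership[[k]]

#' @describeIn DepthAssignment the six bin-centre depths.
#' @export
binCentres <- function(assignment) assignment@binCentres

setMethod("show", "DepthAssignment", function(object) {
  cat("DepthAssignment: 6 bins at",
      paste(object@binCentres, collapse = ", "),
      "+/-", object@halfwidth, "; sizes",
      paste(lengths(object@membership), collapse = ", "), "\n")
})

#' ROI: voxels whose pRFs fall within a visual-field region
#'
#' A region of interest defined by the rule that a voxel's fitted pRF,
#' taken with a spread of one standard deviation, must fall entirely within
#' a target region of the visual field, with fit quality r2 above a
#' threshold. Voxels added by stacked-column completion (all depths of a
#' passing voxel's cortical column) are flagged.
#'
#' @slot name character label.
#' @slot region the geometric region description (see [discRegion()]).
#' @slot voxels integer indices of member voxels.
#' @slot completed logical flag per member voxel: TRUE if included by
#'   column completion rather than by its own pRF.
#' @slot r2Threshold the r2 threshold used.
#' @export
setClass("ROI",
         representation(name = "character", region = "list",
                        voxels = "integer", completed = "logical",
                        r2Threshold = "numeric"))

setValidity("ROI", function(object) {
  if (length(object@voxels) != length(object@completed))
    "one completion flag per member voxel required" else TRUE
})

#' @describeIn ROI member voxel indices.
#' @param roi an `ROI`.
#' @export
roiVoxels <- function(roi) roi@voxels

setMethod("show", "ROI", function(object) {
  cat("ROI '", object@name, "': ", length(object@voxels), " voxels (",
      sum(object@completed), " column-completed), r2 > ",
      object@r2Threshold, "\n", sep = "")
})

#' ProjectionMap: classifier influence back-projected into visual space
#'
#' Pixel-wise influence values over a [VisualFieldGrid-class], obtained by
#' pRF-weighted averaging of classifier voxel weights. Pixels with zero
#' pRF coverage carry the value 0 by definition.
#'
#' @slot grid the `VisualFieldGrid`.
#' @slot values numeric matrix (nPixels x nPixels) of influence values;
#'   `values[ix, iy]` sits at the pixel centre with the ix-th x and iy-th
#'   y coordinate of [pixelCentres()].
#' @slot coverage numeric matrix of summed (truncated) pRF weights per
#'   pixel.
#' @export
setClass("ProjectionMap",
         representation(grid = "VisualFieldGrid", values = "matrix",
                        coverage = "matrix"))

setValidity("ProjectionMap", function(object) {
  msg <- NULL
  if (!all(dim(object@values) == object@grid@nPixels) ||
      !all(dim(object@coverage) == object@grid@nPixels))
    msg <- c(msg, "values and coverage must be nPixels x nPixels")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "projection values must be finite")
  if (any(object@values[object@coverage == 0] != 0))
    msg <- c(msg, "uncovered pixels must carry value 0")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn ProjectionMap the influence-value matrix.
#' @param map a `ProjectionMap`.
#' @export
projectionValues <- function(map) map@values

#' @describeIn ProjectionMap the per-pixel summed pRF weights.
#' @export
projectionCoverage <- function(map) map@coverage

setMethod("show", "ProjectionMap", function(object) {
  cov <- mean(object@coverage > 0)
  cat("ProjectionMap:", object@grid@nPixels, "x", object@grid@nPixels,
      "pixels,", sprintf("%.0f%%", 100 * cov), "covered\n")
})

#' WeightMap: linear classifier weights over a depth bin's voxels
#'
#' Primal weight vector of a linear support-vector classifier (averaged
#' across cross-validation folds), with the sign convention that positive
#' weights are evidence for the first-named class.
#'
#' @slot voxels integer indices the weights refer to.
#' @slot weights numeric weight per voxel.
#' @slot bias numeric(1) bias term.
#' @slot classes character(2): first entry is the positive class.
#' @export
setClass("WeightMap",
         representation(voxels = "integer", weights = "numeric",
                        bias = "numeric", classes = "character"))

setValidity("WeightMap", function(object) {
  msg <- NULL
  if (length(object@voxels) != length(object@weights))
    msg <- c(msg, "one weight per voxel required")
  if (!all(is.finite(object@weights)) || !is.finite(object@bias))
    msg <- c(msg, "weights and bias must be finite")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "WeightMap", function(object) {
  cat("WeightMap:", length(object@weights), "voxels; positive class =",
      object@classes[1], "\n")
})
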