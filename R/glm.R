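#' Canonical two-gamma HRF parameters
#'
#' Defaults follow the common canonical parameterisation: response peak at
#' 5 s, undershoot peak at 15 s, positive-to-negative peak-amplitude ratio
#' 6, no onset delay, no derivatives.
#'
#' @param timeToPeakS time of the positive response peak (s).
#' @param timeToUndershootS time of the undershoot peak (s).
#' @param posNegRatio ratio of positive peak amplitude to undershoot
#'   magnitude.
#' @param onsetDelayS delay before the response begins (s).
#' @return A named list of class `HRFParams`.
#' @export
hrfParams <- function(timeToPeakS = 5, timeToUndershootS = 15,
                      posNegRatio = 6, onsetDelayS = 0) {
  stopifnot(timeToPeakS >= 0, timeToUndershootS >= 0, posNegRatio > 0,
            onsetDelayS >= 0)
  structure(list(timeToPeakS = timeToPeakS,
                 timeToUndershootS = timeToUndershootS,
                 posNegRatio = posNegRatio,
                 onsetDelayS = onsetDelayS),
            class = "HRFParams")
}

#' Sample the two-gamma haemodynamic response kernel
#'
#' Difference of two gamma density shapes. Unit-rate gamma densities are
#' used, with shapes chosen so the density modes sit exactly at the stated
#' peak and undershoot times; each lobe is scaled to peak amplitude 1 and
#' 1/posNegRatio respectively before subtraction, and the resulting kernel
#' is normalised to peak 1.
#'
#' @param params an [hrfParams()] list.
#' @param trS sampling interval (s).
#' @param durationS kernel length (s); must cover the undershoot peak.
#' @return Numeric vector sampled at `t = 0, trS, 2*trS, ...` up to
#'   `durationS`.
#' @examples
#' h <- twoGammaHrf(hrfParams(), trS = 0.1)
#' (which.max(h) - 1) * 0.1   # peak at 5 s
#' @export
twoGammaHrf <- function(params = hrfParams(), trS, durationS = 32) {
  stopifnot(inherits(params, "HRFParams"), trS > 0)
  if (durationS < params$timeToUndershootS)
    stop("durationS must be at least timeToUndershootS")
  t <- seq(0, durationS, by = trS) - params$onsetDelayS
  shapePos <- params$timeToPeakS + 1       # mode of gamma(a, rate 1) = a - 1
  shapeNeg <- params$timeToUndershootS + 1
  pos <- dgamma(t, shape = shapePos, rate = 1) /
    dgamma(params$timeToPeakS, shape = shapePos, rate = 1)
  neg <- dgamma(t, shape = shapeNeg, rate = 1) /
    dgamma(params$timeToUndershootS, shape = shapeNeg, rate = 1)
  pos[t < 0] <- 0
  neg[t < 0] <- 0
  if (is.finite(params$posNegRatio)) {
    h <- pos - neg / params$posNegRatio
  } else {
    h <- pos
  }
  h / max(h)
}

# Convolve per-event boxcars with the HRF on a fine time grid and sample at
# volume onsets. Returns an nVols x nEvents matrix.
.convolveEvents <- function(onsets, durations, nVols, trS, params, dt = 0.1) {
  kern <- twoGammaHrf(params, trS = dt)
  nFine <- ceiling(nVols * trS / dt)
  out <- matrix(0, nVols, length(onsets))
  volIdx <- round((seq_len(nVols) - 1) * trS / dt) + 1L
  for (j in seq_along(onsets)) {
    box <- numeric(nFine)
    i0 <- floor(onsets[j] / dt) + 1L
    i1 <- min(nFine, ceiling((onsets[j] + durations[j]) / dt))
    box[i0:i1] <- 1
    conv <- convolve(box, rev(kern), type = "open")[seq_len(nFine)] * dt
    out[, j] <- conv[volIdx]
  }
  out
}

#' Build a GLM design matrix for one task run
#'
#' Boxcar regressors time-locked to block onsets, convolved with the
#' two-gamma HRF and sampled at the volume times. With `perTrial = TRUE`
#' each block gets its own column (the substrate for trial-wise beta
#' estimation); with `perTrial = FALSE` blocks are pooled into one column
#' per condition x colour (10 columns for the five-condition task).
#' Nuisance events (e.g. end-of-run target/surround mapping blocks) are
#' regressed out as additional columns. A constant term is appended last.
#'
#' @param design a [TrialDesign-class] (its events are filtered to `run`).
#' @param run which run to build the matrix for.
#' @param nVols number of volumes in the run.
#' @param trS repetition time (s).
#' @param hrf an [hrfParams()] list.
#' @param perTrial logical; one column per block (TRUE) or per
#'   condition x colour (FALSE).
#' @param nuisanceEvents optional data.frame with columns `onset`,
#'   `duration`, `name` of extra events to regress out.
#' @return List with `X` (nVols x p design matrix with column names),
#'   `labels` (per-trial label table when `perTrial = TRUE`, else NULL).
#' @export
buildDesignMatrix <- function(design, run, nVols, trS = 2,
                              hrf = hrfParams(), perTrial = TRUE,
                              nuisanceEvents = NULL) {
  ev <- designEvents(design)
  ev <- ev[ev$run == run, , drop = FALSE]
  ev <- ev[order(ev$onset), , drop = FALSE]
  if (nrow(ev) && max(ev$onset + ev$duration) > nVols * trS)
    stop("all events must end before the run ends")
  labels <- NULL
  if (perTrial) {
    if (nrow(ev)) {
      X <- .convolveEvents(ev$onset, ev$duration, nVols, trS, hrf)
      colnames(X) <- sprintf("trial%03d", seq_len(nrow(ev)))
      labels <- data.frame(run = ev$run, condition = ev$condition,
                           colour = ev$colour, onset = ev$onset,
                           stringsAsFactors = FALSE)
    } else X <- matrix(0, nVols, 0)
  } else {
    cells <- expand.grid(colour = .TASK_COLOURS, condition = .TASK_CONDITIONS,
                         stringsAsFactors = FALSE)[, 2:1]
    X <- matrix(0, nVols, 0)
    nm <- character(0)
    for (i in seq_len(nrow(cells))) {
      sel <- ev$condition == cells$condition[i] & ev$colour == cells$colour[i]
      if (!any(sel)) next
      sub <- ev[sel, , drop = FALSE]
      ord <- order(sub$onset)
      if (any(diff(sub$onset[ord]) < sub$duration[ord][-nrow(sub)]))
        stop("overlapping events within one design column")
      cols <- .convolveEvents(sub$onset, sub$duration, nVols, trS, hrf)
      X <- cbind(X, rowSums(cols))
      nm <- c(nm, paste(cells$condition[i], cells$colour[i], sep = "_"))
    }
    colnames(X) <- nm
  }
  if (!is.null(nuisanceEvents) && nrow(nuisanceEvents)) {
    if (max(nuisanceEvents$onset + nuisanceEvents$duration) > nVols * trS)
      stop("all events must end before the run ends")
    N <- .convolveEvents(nuisanceEvents$onset, nuisanceEvents$duration,
                         nVols, trS, hrf)
    colnames(N) <- nuisanceEvents$name
    X <- cbind(X, N)
  }
  X <- cbind(X, `(Intercept)` = 1)
  list(X = X, labels = labels)
}

#' Estimate trial-wise betas by ordinary least squares
#'
#' Fits the per-trial design matrix to every voxel's time course in one run
#' and returns the beta estimates for the trial columns, ordered by block
#' onset.
#'
#' @param runTs voxel x time matrix for one run.
#' @param designMatrix output of [buildDesignMatrix()] with
#'   `perTrial = TRUE`.
#' @return List with `values` (trials x voxels beta matrix) and `labels`
#'   (the per-trial label table).
#' @export
estimateTrialBetas <- function(runTs, designMatrix) {
  X <- designMatrix$X
  if (ncol(runTs) != nrow(X))
    stop("run length does not match the design matrix")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qrX, t(runTs))          # p x voxels
  trialCols <- grep("^trial", colnames(X))
  if (!length(trialCols))
    stop("designMatrix must be built with perTrial = TRUE")
  list(values = coefs[trialCols, , drop = FALSE],
       labels = designMatrix$labels)
}

#' Remove voxels with low raw signal intensity
#'
#' Voxels whose raw mean BOLD intensity across all task volumes falls below
#' the threshold are excluded from further analysis. The boundary is
#' retained: a voxel at exactly the threshold passes.
#'
#' @param runTsList list of voxel x time matrices (task runs).
#' @param threshold raw intensity cutoff (default 100).
#' @return Logical mask, TRUE for voxels to keep.
#' @export
filterLowIntensityVoxels <- function(runTsList, threshold = 100) {
  grand <- rowMeans(do.call(cbind, runTsList))
  grand >= threshold
}

#' Mean response amplitude per cortical-depth bin
#'
#' Averages each voxel's mean response over the selected trials, then
#' averages those voxel means within every depth bin. Used to characterise
#' the superficial amplitude bias (gradient-echo BOLD grows toward the pial
#' surface) and to contrast amplitude with decodability across depth.
#'
#' @param betas a [BetaMatrix-class].
#' @param assignment a [DepthAssignment-class] over the same voxels.
#' @param conditions conditions to include (default all).
#' @param colours colours to include (default both).
#' @return data.frame with one row per bin: `bin`, `depth`, `mean`, `sd`
#'   (dispersion across member voxels) and `nVoxels`.
#' @export
depthAmplitudeProfile <- function(betas, assignment,
                                  conditions = NULL, colours = NULL) {
  lab <- betaLabels(betas)
  sel <- rep(TRUE, nrow(lab))
  if (!is.null(conditions)) sel <- sel & lab$condition %in% conditions
  if (!is.null(colours)) sel <- sel & lab$colour %in% colours
  if (!any(sel)) stop("no trials match the condition selector")
  voxMean <- colMeans(betaValues(betas)[sel, , drop = FALSE])
  out <- lapply(seq_along(assignment@binCentres), function(k) {
    idx <- binMembers(assignment, k)
    if (!length(idx))
      stop("depth bin ", k, " is empty")
    data.frame(bin = k, depth = assignment@binCentres[k],
               mean = mean(voxMean[idx]), sd = sd(voxMean[idx]),
               nVoxels = length(idx))
  })
  do.call(rbind, out)
}
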