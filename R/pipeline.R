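#' Estimate a subject's trial-wise beta matrix
#'
#' Runs the full first-level route from raw task runs to the decoding
#' substrate: voxels below the raw-intensity threshold are removed, then
#' per-run per-trial GLMs (two-gamma HRF regressors plus intercept)
#' estimate one beta per block and voxel; runs are stacked into one
#' [BetaMatrix-class].
#'
#' @param subject a [LaminarSubject-class].
#' @param hrf an [hrfParams()] list.
#' @param intensityThreshold raw-intensity cutoff (see
#'   [filterLowIntensityVoxels()]); `NULL` skips the filter.
#' @return List: `betas` (a `BetaMatrix` over the retained voxels) and
#'   `voxels` (indices of retained voxels in the subject's voxel set).
#' @export
computeTrialBetas <- function(subject, hrf = hrfParams(),
                              intensityThreshold = 100) {
  runs <- taskRuns(subject)
  keep <- if (is.null(intensityThreshold)) rep(TRUE, nVoxels(subject))
  else filterLowIntensityVoxels(runs, intensityThreshold)
  if (!any(keep)) stop("no voxels survive the intensity filter")
  vals <- list()
  labs <- list()
  for (r in seq_along(runs)) {
    dm <- buildDesignMatrix(subjectDesign(subject), run = r,
                            nVols = ncol(runs[[r]]), trS = subject@trS,
                            hrf = hrf, perTrial = TRUE)
    est <- estimateTrialBetas(runs[[r]][keep, , drop = FALSE], dm)
    vals[[r]] <- est$values
    labs[[r]] <- est$labels
  }
  list(betas = new("BetaMatrix", values = do.call(rbind, vals),
                   labels = do.call(rbind, labs)),
       voxels = which(keep))
}

#' Depth-resolved leave-one-run-out decoding for one subject
#'
#' Decodes stimulus colour within each requested condition separately for
#' every cortical-depth bin of the assignment, using the linear C-SVM
#' with leave-one-run-out cross-validation.
#'
#' @param betas a [BetaMatrix-class].
#' @param assignment a [DepthAssignment-class] whose members index the
#'   beta matrix columns (see [subsetDepthBins()]).
#' @param conditions conditions to decode (default: all five).
#' @param config a [decoderConfig()].
#' @return Tidy data.frame, one row per (condition, bin, fold):
#'   `condition`, `bin`, `depth`, `nVoxels`, `run`, `accuracy`.
#' @export
decodeDepthProfile <- function(betas, assignment,
                               conditions = .TASK_CONDITIONS,
                               config = decoderConfig()) {
  rows <- list()
  for (cond in conditions) {
    for (k in seq_along(binCentres(assignment))) {
      vox <- binMembers(assignment, k)
      if (!length(vox)) next
      entry <- decodeLoro(betas, cond, vox, config)
      rows[[length(rows) + 1L]] <-
        data.frame(condition = cond, bin = k,
                   depth = binCentres(assignment)[k],
                   nVoxels = length(vox),
                   run = entry$folds$run,
                   accuracy = entry$folds$accuracy)
    }
  }
  do.call(rbind, rows)
}

#' Full per-subject depth decoding pipeline
#'
#' Convenience wrapper: intensity filter, trial-beta GLM, depth-bin
#' assignment restricted to the retained voxels, and per-depth
#' leave-one-run-out colour decoding.
#'
#' @param subject a [LaminarSubject-class].
#' @param conditions conditions to decode.
#' @param binHalfwidth depth-bin half-width (see [assignDepthBins()]).
#' @param config a [decoderConfig()].
#' @param intensityThreshold raw-intensity cutoff, `NULL` to skip.
#' @return As [decodeDepthProfile()], with fold accuracies per condition
#'   and depth bin.
#' @export
decodeSubject <- function(subject, conditions = .TASK_CONDITIONS,
                          binHalfwidth = 0.1, config = decoderConfig(),
                          intensityThreshold = 100) {
  tb <- computeTrialBetas(subject, intensityThreshold = intensityThreshold)
  full <- assignDepthBins(subjectTruth(subject)$depth, binHalfwidth)
  assignment <- subsetDepthBins(full, tb$voxels)
  decodeDepthProfile(tb$betas, assignment, conditions, config)
}

#' Group-level bootstrap + FDR inference over depth profiles
#'
#' First-level inference for depth-resolved decoding: for every
#' (condition, depth bin) cell, the across-subject mean accuracy is
#' tested one-sided against chance by bootstrapping of the mean, and the
#' resulting p values are FDR-adjusted over the whole comparison family
#' (all bins x conditions supplied, e.g. 30 comparisons for five
#' conditions and six bins in one ROI).
#'
#' @param accTable data.frame with columns `subject`, `condition`, `bin`,
#'   `depth`, `accuracy` (one row per subject x condition x bin; average
#'   fold accuracies first).
#' @param chance chance level.
#' @param nBoot bootstrap resamples per cell.
#' @param seed integer seed.
#' @param alpha significance level applied to the adjusted p values.
#' @return data.frame with one row per (condition, bin): mean accuracy,
#'   `pRaw`, `pAdj`, 90% CI bounds and `significant`.
#' @export
groupDepthInference <- function(accTable, chance = 0.5, nBoot = 10000,
                                seed = NULL, alpha = 0.05) {
  need <- c("subject", "condition", "bin", "accuracy")
  stopifnot(all(need %in% names(accTable)))
  cells <- unique(accTable[, c("condition", "bin", "depth")])
  cells <- cells[order(cells$condition, cells$bin), ]
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- accTable$condition == cells$condition[i] &
      accTable$bin == cells$bin[i]
    acc <- accTable$accuracy[sel]
    bt <- bootstrapMeanTest(acc, chance = chance, nBoot = nBoot,
                            seed = if (is.null(seed)) NULL else
                              subSeed(seed, i))
    cbind(cells[i, , drop = FALSE], bt)
  })
  out <- do.call(rbind, out)
  out$pAdj <- fdrAdjust(out$pRaw)
  out$significant <- out$pAdj < alpha
  rownames(out) <- NULL
  out
}

#' Per-subject mean accuracies from a fold-level decoding table
#'
#' Averages fold accuracies within subject, condition and depth bin —
#' the unit entering group-level inference.
#'
#' @param foldTable data.frame with columns `subject`, `condition`,
#'   `bin`, `depth`, `accuracy` at fold level.
#' @return data.frame with the same columns, one row per
#'   subject x condition x bin.
#' @export
summariseFolds <- function(foldTable) {
  agg <- stats::aggregate(accuracy ~ subject + condition + bin + depth,
                          data = foldTable, FUN = mean)
  agg[order(agg$subject, agg$condition, agg$bin), ]
}
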