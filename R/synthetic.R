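#' Build a retinotopic mapping stimulus aperture
#'
#' Rasterises the classic phase-encoded mapping stimuli on a
#' [VisualFieldGrid-class] at TR resolution: a 22.5-degree wedge rotating
#' anti-clockwise about fixation in 12 cycles of 64 s (396 volumes at
#' TR = 2 s), or a ring expanding from the centre to the grid edge in 8
#' cycles of 64 s (268 volumes). Both have a 12-s all-zero baseline before
#' and after stimulation.
#'
#' @param kind `"wedge"` or `"ring"`.
#' @param grid a [VisualFieldGrid-class].
#' @param trS repetition time (s), default 2.
#' @param ringWidthFrac ring thickness as a fraction of the grid
#'   half-extent (default 0.25).
#' @return A [StimulusAperture-class].
#' @examples
#' ap <- makeRetinotopyStimulus("wedge", VisualFieldGrid(6.2, 16))
#' nFrames(ap)   # 396
#' @export
makeRetinotopyStimulus <- function(kind, grid, trS = 2,
                                   ringWidthFrac = 0.25) {
  if (!kind %in% c("wedge", "ring"))
    stop("unknown stimulus kind: ", kind)
  stopifnot(is(grid, "VisualFieldGrid"))
  cycleS <- 64
  baselineS <- 12
  nCycles <- if (kind == "wedge") 12L else 8L
  fpc <- as.integer(cycleS / trS)
  nBase <- as.integer(baselineS / trS)
  px <- pixelCentres(grid)
  ecc <- sqrt(px[, 1]^2 + px[, 2]^2)
  ang <- atan2(px[, 2], px[, 1])
  inField <- ecc <= grid@halfExtent & ecc > 0
  cycle <- matrix(0, nrow(px), fpc)
  for (f in seq_len(fpc)) {
    if (kind == "wedge") {
      centre <- 2 * pi * (f - 1) / fpc       # anti-clockwise rotation
      d <- abs(((ang - centre + pi) %% (2 * pi)) - pi)
      cycle[, f] <- as.numeric(inField & d <= (22.5 / 2) * pi / 180)
    } else {
      inner <- grid@halfExtent * (f - 1) / fpc
      outer <- inner + grid@halfExtent * ringWidthFrac
      cycle[, f] <- as.numeric(inField & ecc > inner & ecc <= outer)
    }
  }
  blank <- matrix(0, nrow(px), nBase)
  frames <- cbind(blank, cycle[, rep(seq_len(fpc), nCycles)], blank)
  new("StimulusAperture", grid = grid, frames = frames, trS = trS,
      kind = kind)
}

#' Generate a randomised balanced task design
#'
#' Builds the five-condition block design: per run, 30 blocks of 8 s (each
#' condition six times, three red and three green) in randomised order,
#' separated by inter-stimulus intervals drawn uniformly from 7-8 s and
#' rounded to the design-matrix time resolution.
#'
#' @param nRuns number of runs (>= 2, so leave-one-run-out CV is possible).
#' @param seed integer seed; the same seed reproduces the same design.
#' @param isiResolution rounding step for the jittered ISI (s).
#' @param leadInS time before the first block (s).
#' @return A [TrialDesign-class].
#' @export
makeTaskDesign <- function(nRuns, seed, isiResolution = 0.5, leadInS = 12) {
  if (nRuns < 2) stop("nRuns must be >= 2 (leave-one-run-out needs >= 2 folds)")
  cells <- expand.grid(condition = .TASK_CONDITIONS, colour = .TASK_COLOURS,
                       stringsAsFactors = FALSE)
  withSeed(seed, {
    runs <- lapply(seq_len(nRuns), function(r) {
      idx <- sample(rep(seq_len(nrow(cells)), each = 3L))
      isi <- round(runif(length(idx) - 1, 7, 8) / isiResolution) *
        isiResolution
      onsets <- leadInS + cumsum(c(0, isi + 8))
      data.frame(run = r, condition = cells$condition[idx],
                 colour = cells$colour[idx], onset = onsets, duration = 8,
                 stringsAsFactors = FALSE)
    })
    new("TrialDesign", events = do.call(rbind, runs),
        nRuns = as.integer(nRuns))
  })
}

#' Generator settings for a synthetic laminar subject
#'
#' Defaults emulate the study design this package targets: 6 task runs of
#' 272 volumes at TR = 2 s with the balanced five-condition block design;
#' wedge (396 volumes) and ring (268 volumes) mapping runs; voxels
#' organised in cortical columns of six depths sharing one pRF; colour
#' encoded as an antisymmetric multivoxel pattern injected only within a
#' condition-specific depth band (imagery deep, illusory/amodal
#' superficial, under the convention depth 0 = white-matter boundary and
#' 1 = pial surface); and a linear superficial amplitude gain emulating the
#' gradient-echo draining-vein bias.
#'
#' @param nColumns number of cortical columns (6 voxels each).
#' @param depthJitter half-range of the uniform jitter around the six
#'   canonical depths when placing a column's voxels.
#' @param grid [VisualFieldGrid-class] for the retinotopy stimuli.
#' @param prfEccMax maximal pRF centre eccentricity (deg).
#' @param sigmaRange range of pRF sizes (deg); sizes are log-uniform.
#' @param effectSize named vector of colour-pattern amplitudes (fraction
#'   of baseline) per condition.
#' @param depthBand named list of `c(lo, hi)` depth bands in which each
#'   condition's colour pattern lives.
#' @param visualDrive condition-unspecific stimulus response amplitude
#'   (fraction of baseline) shared by all blocks; gives every visually
#'   responsive voxel a positive response so amplitude profiles across
#'   depth are meaningful.
#' @param baseline raw baseline intensity (arbitrary BOLD units).
#' @param gainSlope slope of the amplitude gain `1 + gainSlope * depth`
#'   (superficial bias; >= 0).
#' @param noiseSd i.i.d. Gaussian noise sd per volume (raw units) at unit
#'   gain; the per-voxel noise sd is `noiseSd * gain`, since the vascular
#'   amplification toward the pial surface scales signal fluctuations
#'   together with the signal (so contrast-to-noise is depth-flat and
#'   amplitude carries no information by itself).
#' @param nRuns,trS,taskVols task-run geometry.
#' @param retinotopy logical; also simulate the wedge/ring runs.
#' @param retinotopyAmp response amplitude (fraction of baseline) of the
#'   pRF-driven mapping signal.
#' @return Configuration list of class `SubjectConfig`.
#' @export
subjectConfig <- function(nColumns = 24,
                          depthJitter = 0.08,
                          grid = VisualFieldGrid(6.2, 32),
                          prfEccMax = 5,
                          sigmaRange = c(0.5, 2),
                          effectSize = c(perception = 0.003,
                                         imagery = 0.002,
                                         illusory = 0.002,
                                         amodal = 0.0012,
                                         mock = 0.0025),
                          depthBand = list(perception = c(0, 1),
                                           imagery = c(0, 0.3),
                                           illusory = c(0.7, 1),
                                           amodal = c(0.7, 1),
                                           mock = c(0, 1)),
                          visualDrive = 0.02,
                          baseline = 500,
                          gainSlope = 0.5,
                          noiseSd = 40,
                          nRuns = 6, trS = 2, taskVols = 272,
                          retinotopy = TRUE,
                          retinotopyAmp = 0.06) {
  stopifnot(all(effectSize >= 0), noiseSd > 0, gainSlope >= 0,
            all(.TASK_CONDITIONS %in% names(effectSize)),
            all(.TASK_CONDITIONS %in% names(depthBand)))
  structure(as.list(environment()), class = "SubjectConfig")
}

.LAYER_CENTRES <- c(0.1, 0.26, 0.42, 0.58, 0.74, 0.9)

#' Simulate a laminar fMRI subject with known ground truth
#'
#' Generates task runs, optional retinotopic mapping runs, the trial
#' design and full per-voxel ground truth under a seeded configuration.
#' Every voxel's task time course is
#' `baseline * gain * (1 + sum over blocks of (visualDrive + w) * boxcar)`
#' convolved with the two-gamma HRF, plus i.i.d. Gaussian noise, where the
#' colour-pattern weight `w` for a (condition, colour) is antisymmetric in
#' colour (`+w` red, `-w` green), drawn once per subject from a seeded
#' standard normal scaled by the condition's effect size, and nonzero only
#' for voxels whose depth lies in that condition's target band. Voxels are
#' stacked in columns: the six depths of a column share one pRF centre
#' (hypercolumn assumption) but receive independent noise. Retinotopy time
#' courses are each voxel's true Gaussian pRF overlapped with the wedge and
#' ring aperture frames, HRF-convolved.
#'
#' @param config a [subjectConfig()] list.
#' @param seed integer seed; identical config + seed reproduce the subject
#'   bit-for-bit.
#' @return A [LaminarSubject-class].
#' @export
simulateSubject <- function(config = subjectConfig(), seed) {
  stopifnot(inherits(config, "SubjectConfig"))
  design <- makeTaskDesign(config$nRuns, subSeed(seed, 1L))

  truth <- withSeed(subSeed(seed, 2L), {
    nc <- config$nColumns
    r <- config$prfEccMax * sqrt(runif(nc))
    th <- runif(nc, 0, 2 * pi)
    sig <- exp(runif(nc, log(config$sigmaRange[1]),
                     log(config$sigmaRange[2])))
    perCol <- lapply(seq_len(nc), function(j) {
      d <- pmin(1, pmax(0, .LAYER_CENTRES +
                          runif(6, -config$depthJitter, config$depthJitter)))
      data.frame(prfX = r[j] * cos(th[j]), prfY = r[j] * sin(th[j]),
                 prfSigma = sig[j], depth = d, column = j)
    })
    do.call(rbind, perCol)
  })
  truth$baseline <- config$baseline
  truth$gain <- 1 + config$gainSlope * truth$depth
  nv <- nrow(truth)

  patternWeights <- withSeed(subSeed(seed, 3L), {
    w <- array(0, dim = c(nv, length(.TASK_CONDITIONS), 2L),
               dimnames = list(NULL, .TASK_CONDITIONS, .TASK_COLOURS))
    for (cond in .TASK_CONDITIONS) {
      es <- config$effectSize[[cond]]
      band <- config$depthBand[[cond]]
      inBand <- truth$depth >= band[1] & truth$depth <= band[2]
      if (es > 0) {
        if (!any(inBand))
          stop("condition '", cond, "' has nonzero effect but an empty ",
               "target depth band")
        z <- rnorm(sum(inBand))
        w[inBand, cond, "red"] <- es * z
        w[inBand, cond, "green"] <- -es * z
      }
    }
    w
  })

  taskRuns <- lapply(seq_len(config$nRuns), function(r) {
    dm <- buildDesignMatrix(design, run = r, nVols = config$taskVols,
                            trS = config$trS, perTrial = TRUE)
    lab <- dm$labels
    R <- dm$X[, grep("^trial", colnames(dm$X)), drop = FALSE]
    W <- vapply(seq_len(nrow(lab)), function(j) {
      config$visualDrive +
        patternWeights[, lab$condition[j], lab$colour[j]]
    }, numeric(nv))                         # voxels x trials
    signal <- tcrossprod(W, R)              # voxels x vols
    ts <- truth$baseline * truth$gain * (1 + signal)
    # the gain amplifies fluctuations along with the signal (vascular
    # amplification), keeping contrast-to-noise flat across depth
    ts + truth$gain * withSeed(subSeed(seed, 10L + r),
                               matrix(rnorm(length(ts), 0, config$noiseSd),
                                      nrow = nv))
  })

  retino <- list()
  if (config$retinotopy) {
    px <- pixelCentres(config$grid)
    G <- exp(-(outer(truth$prfX, px[, 1], "-")^2 +
                 outer(truth$prfY, px[, 2], "-")^2) /
               (2 * truth$prfSigma^2))      # voxels x pixels
    for (kind in c("wedge", "ring")) {
      ap <- makeRetinotopyStimulus(kind, config$grid, trS = config$trS)
      drive <- G %*% apertureFrames(ap)     # voxels x frames
      peak <- apply(drive, 1, max)
      peak[peak == 0] <- 1
      drive <- drive / peak
      kern <- twoGammaHrf(trS = config$trS)
      conv <- t(apply(drive, 1, function(d)
        convolve(d, rev(kern), type = "open")[seq_along(d)]))
      ts <- truth$baseline * truth$gain * (1 + config$retinotopyAmp * conv)
      off <- if (kind == "wedge") 20L else 21L
      retino[[kind]] <- ts + truth$gain *
        withSeed(subSeed(seed, off),
                 matrix(rnorm(length(ts), 0, config$noiseSd), nrow = nv))
    }
  }

  new("LaminarSubject", taskRuns = taskRuns, retinotopyRuns = retino,
      design = design, truth = truth, patternWeights = patternWeights,
      grid = config$grid, trS = config$trS, seed = as.integer(seed),
      config = unclass(config))
}

#' Simulate a binocular-rivalry imagery pre-test
#'
#' Generates one participant's rivalry trial table: on every non-catch
#' trial a colour cue is imagined, then a brief rivalry display is shown
#' and the dominant colour reported. Among non-mixed responses the cued
#' colour dominates with probability `truePriming`; a fixed fraction of
#' trials are catch trials (physically mixed displays).
#'
#' @param nTrials number of trials.
#' @param truePriming probability that a non-mixed response matches the
#'   cue.
#' @param catchFraction fraction of catch trials (allocated exactly:
#'   `round(nTrials * catchFraction)` trials, at seeded random positions).
#' @param mixedRate probability of a "mixed" response on non-catch trials.
#' @param seed integer seed.
#' @param catchAccuracy probability that a catch trial is (correctly)
#'   reported as mixed.
#' @return data.frame with columns `trial`, `cue`, `response`,
#'   `vividness`, `isCatch`.
#' @export
simulateRivalryTrials <- function(nTrials, truePriming, catchFraction = 0.1,
                                  mixedRate = 0.1, seed,
                                  catchAccuracy = 0.9) {
  stopifnot(truePriming >= 0, truePriming <= 1,
            catchFraction >= 0, catchFraction <= 1,
            mixedRate >= 0, mixedRate <= 1)
  withSeed(seed, {
    nCatch <- round(nTrials * catchFraction)
    isCatch <- rep(FALSE, nTrials)
    if (nCatch > 0) isCatch[sample(nTrials, nCatch)] <- TRUE
    cue <- sample(.TASK_COLOURS, nTrials, replace = TRUE)
    response <- character(nTrials)
    for (i in seq_len(nTrials)) {
      if (isCatch[i]) {
        response[i] <- if (runif(1) < catchAccuracy) "mixed" else
          sample(.TASK_COLOURS, 1)
      } else if (runif(1) < mixedRate) {
        response[i] <- "mixed"
      } else {
        response[i] <- if (runif(1) < truePriming) cue[i] else
          setdiff(.TASK_COLOURS, cue[i])
      }
    }
    data.frame(trial = seq_len(nTrials), cue = cue, response = response,
               vividness = sample(1:4, nTrials, replace = TRUE),
               isCatch = isCatch, stringsAsFactors = FALSE)
  })
}
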