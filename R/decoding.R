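#' Decoder configuration
#'
#' Settings of the soft-margin linear support-vector classifier used for
#' all decoding analyses: C-classification with cost 1, linear kernel,
#' termination tolerance 0.001, and equal class costs (no class
#' weighting).
#'
#' @param cost soft-margin cost parameter C (> 0).
#' @param tolerance termination tolerance of the optimiser.
#' @return A list of class `DecoderConfig`.
#' @export
decoderConfig <- function(cost = 1, tolerance = 0.001) {
  stopifnot(cost > 0, tolerance > 0)
  structure(list(cost = cost, kernel = "linear", tolerance = tolerance),
            class = "DecoderConfig")
}

#' Rescale beta values to [-1, 1]
#'
#' Affine per-voxel rescaling of trial betas onto [-1, 1]. The scaling
#' parameters (per-voxel min and max) are learned on the training rows
#' only and applied to all rows, so held-out trials can map slightly
#' outside [-1, 1]; no clipping is applied.
#'
#' @param values trial x voxel matrix, or a [BetaMatrix-class].
#' @param trainRows row indices on which to fit the scaling (default: all
#'   rows).
#' @return Rescaled object of the same type as the input.
#' @export
rescaleBetas <- function(values, trainRows = NULL) {
  if (is(values, "BetaMatrix")) {
    out <- values
    out@values <- rescaleBetas(betaValues(values), trainRows)
    return(out)
  }
  if (is.null(trainRows)) trainRows <- seq_len(nrow(values))
  lo <- apply(values[trainRows, , drop = FALSE], 2, min)
  hi <- apply(values[trainRows, , drop = FALSE], 2, max)
  if (any(hi == lo))
    stop("cannot rescale: constant values within the scaling scope")
  sweep(sweep(values, 2, (lo + hi) / 2), 2, (hi - lo) / 2, "/")
}

# Fit the linear C-SVM and return primal weights with the convention that
# positive decision values are evidence for levels(y)[1].
.fitSvm <- function(X, y, config) {
  model <- e1071::svm(X, y, type = "C-classification", kernel = "linear",
                      cost = config$cost, tolerance = config$tolerance,
                      scale = FALSE)
  w <- as.numeric(crossprod(model$coefs, model$SV))
  b <- -model$rho
  # libsvm orders classes by appearance in the training data; align signs
  # with the factor-level convention.
  pred <- predict(model, X[1, , drop = FALSE], decision.values = TRUE)
  firstNamed <- strsplit(colnames(attr(pred, "decision.values")),
                         "/")[[1]][1]
  if (firstNamed != levels(y)[1]) {
    w <- -w
    b <- -b
  }
  list(model = model, w = w, b = b, classes = levels(y))
}

.predictSvm <- function(fit, X) {
  d <- as.numeric(X %*% fit$w + fit$b)
  ifelse(d >= 0, fit$classes[1], fit$classes[2])
}

# Leave-one-run-out worker: X trials x voxels (unscaled), y factor,
# runs per trial. Scaling is fitted on each fold's training rows only.
.loroDecode <- function(X, y, runs, config, keepModels = FALSE) {
  foldRuns <- sort(unique(runs))
  if (length(foldRuns) < 2) stop("leave-one-run-out needs >= 2 runs")
  folds <- data.frame(run = foldRuns, accuracy = NA_real_,
                      nTest = NA_integer_)
  models <- vector("list", length(foldRuns))
  for (i in seq_along(foldRuns)) {
    testSel <- runs == foldRuns[i]
    yTr <- y[!testSel]
    if (length(unique(yTr)) < 2)
      stop("a class is missing from the training fold for run ",
           foldRuns[i])
    Xs <- rescaleBetas(X, trainRows = which(!testSel))
    fit <- .fitSvm(Xs[!testSel, , drop = FALSE], droplevels(yTr), config)
    pred <- .predictSvm(fit, Xs[testSel, , drop = FALSE])
    folds$accuracy[i] <- mean(pred == as.character(y[testSel]))
    folds$nTest[i] <- sum(testSel)
    if (keepModels) models[[i]] <- fit
  }
  structure(list(folds = folds, meanAccuracy = mean(folds$accuracy),
                 classes = levels(y), nVoxels = ncol(X),
                 models = if (keepModels) models),
            class = "DecodingEntry")
}

#' @export
print.DecodingEntry <- function(x, ...) {
  cat("DecodingEntry [", paste(x$classes, collapse = " vs "), "]: mean",
      sprintf("%.3f", x$meanAccuracy), "over", nrow(x$folds), "folds,",
      x$nVoxels, "voxels\n")
  invisible(x)
}

#' Decode stimulus colour within one condition, leave-one-run-out
#'
#' Red-vs-green classification of a condition's trial betas restricted to
#' one depth bin's voxels, with leave-one-run-out cross-validation: for
#' every fold the classifier is trained on all other runs' trials (with
#' [-1, 1] rescaling fitted on the training trials) and accuracy is the
#' fraction of held-out trials labelled correctly. The reported accuracy
#' is the arithmetic mean over folds.
#'
#' @param betas a [BetaMatrix-class] (unscaled).
#' @param condition the condition whose red/green trials are decoded.
#' @param voxels voxel (column) indices to use, e.g. one depth bin's
#'   members.
#' @param config a [decoderConfig()].
#' @param keepModels keep the per-fold primal weights (needed for
#'   [extractWeightMap()]).
#' @return A `DecodingEntry`: per-fold accuracies, their mean, class
#'   labels and voxel count.
#' @export
decodeLoro <- function(betas, condition, voxels = NULL,
                       config = decoderConfig(), keepModels = FALSE) {
  lab <- betaLabels(betas)
  sel <- lab$condition == condition
  if (!any(sel)) stop("no trials for condition '", condition, "'")
  X <- betaValues(betas)[sel, , drop = FALSE]
  if (!is.null(voxels)) X <- X[, voxels, drop = FALSE]
  y <- factor(lab$colour[sel], levels = .TASK_COLOURS)
  out <- .loroDecode(X, y, lab$run[sel], config, keepModels)
  out$condition <- condition
  out$voxels <- voxels %||% seq_len(ncol(betaValues(betas)))
  out
}

#' Decode one condition against another, leave-one-run-out
#'
#' Binary classification of condition A versus condition B restricted to
#' trials of one colour (run separately for red and for green as a
#' reliability check), with leave-one-run-out cross-validation. Used for
#' contrasts such as illusory perception versus the mock version of the
#' illusion.
#'
#' @param betas a [BetaMatrix-class].
#' @param conditionA,conditionB the two conditions to discriminate
#'   (A is the positive class).
#' @param colour which colour's trials to use (`"red"` or `"green"`).
#' @param voxels voxel indices to use.
#' @param config a [decoderConfig()].
#' @param keepModels keep per-fold weights.
#' @return A `DecodingEntry`.
#' @export
decodeConditionPair <- function(betas, conditionA, conditionB, colour,
                                voxels = NULL, config = decoderConfig(),
                                keepModels = FALSE) {
  stopifnot(colour %in% .TASK_COLOURS)
  lab <- betaLabels(betas)
  sel <- lab$condition %in% c(conditionA, conditionB) &
    lab$colour == colour
  if (!any(sel)) stop("no matching trials")
  X <- betaValues(betas)[sel, , drop = FALSE]
  if (!is.null(voxels)) X <- X[, voxels, drop = FALSE]
  y <- factor(lab$condition[sel], levels = c(conditionA, conditionB))
  out <- .loroDecode(X, y, lab$run[sel], config, keepModels)
  out$colour <- colour
  out$voxels <- voxels %||% seq_len(ncol(betaValues(betas)))
  out
}

#' Cross-classification between conditions
#'
#' Trains the red-vs-green classifier on all runs of one condition and
#' tests it on all runs of another, asking whether the two conditions
#' share a colour code. Because train and test sets are disjoint by
#' construction there is no fold structure; rescaling is fitted on the
#' training condition's trials and applied to the test condition's. If
#' the same condition is passed twice the call is redirected to
#' leave-one-run-out decoding ([decodeLoro()]).
#'
#' @param betas a [BetaMatrix-class].
#' @param trainCondition,testCondition conditions to train and test on.
#' @param voxels voxel indices to use.
#' @param config a [decoderConfig()].
#' @return A `DecodingEntry` with a single accuracy and the recorded
#'   train -> test direction (or a leave-one-run-out entry if both
#'   conditions coincide).
#' @export
crossClassify <- function(betas, trainCondition, testCondition,
                          voxels = NULL, config = decoderConfig()) {
  if (trainCondition == testCondition) {
    message("train and test conditions coincide; ",
            "running leave-one-run-out decoding instead")
    return(decodeLoro(betas, trainCondition, voxels, config))
  }
  lab <- betaLabels(betas)
  selTr <- lab$condition == trainCondition
  selTe <- lab$condition == testCondition
  if (!any(selTr) || !any(selTe)) stop("no matching trials")
  if (length(unique(lab$colour[selTr])) < 2 ||
      length(unique(lab$colour[selTe])) < 2)
    stop("both colours must be present in train and test conditions")
  V <- betaValues(betas)
  if (!is.null(voxels)) V <- V[, voxels, drop = FALSE]
  Vs <- rescaleBetas(V, trainRows = which(selTr))
  y <- factor(lab$colour, levels = .TASK_COLOURS)
  fit <- .fitSvm(Vs[selTr, , drop = FALSE], droplevels(y[selTr]), config)
  pred <- .predictSvm(fit, Vs[selTe, , drop = FALSE])
  acc <- mean(pred == as.character(y[selTe]))
  structure(list(folds = data.frame(run = NA, accuracy = acc,
                                    nTest = sum(selTe)),
                 meanAccuracy = acc, classes = levels(y),
                 nVoxels = ncol(V),
                 direction = paste(trainCondition, "->", testCondition),
                 models = list(fit)),
            class = "DecodingEntry")
}

#' Extract the fold-averaged primal weight map
#'
#' Averages the linear classifier's primal weight vector across
#' cross-validation folds. Positive weights are evidence for the
#' first-named class.
#'
#' @param entry a `DecodingEntry` produced with `keepModels = TRUE` (or a
#'   [crossClassify()] entry).
#' @param voxels voxel indices the weights refer to (defaults to the
#'   entry's).
#' @return A [WeightMap-class].
#' @export
extractWeightMap <- function(entry, voxels = NULL) {
  stopifnot(inherits(entry, "DecodingEntry"))
  if (is.null(entry$models) || !length(entry$models) ||
      is.null(entry$models[[1]]))
    stop("entry carries no models; rerun with keepModels = TRUE")
  W <- vapply(entry$models, `[[`, numeric(entry$nVoxels), "w")
  b <- mean(vapply(entry$models, `[[`, numeric(1), "b"))
  voxels <- voxels %||% entry$voxels %||% seq_len(entry$nVoxels)
  new("WeightMap", voxels = as.integer(voxels),
      weights = rowMeans(matrix(W, nrow = entry$nVoxels)), bias = b,
      classes = entry$classes)
}
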