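#' One-sided bootstrap test of the mean accuracy against chance
#'
#' Resamples the per-subject accuracies with replacement and tests the
#' mean against chance level (0.5): the one-sided p value is
#' `(1 + #resampled means <= chance) / (nBoot + 1)` (the add-one form
#' avoids p = 0), and the 90% confidence interval is the empirical 5th
#' and 95th percentile of the resampled means (matching the one-sided
#' alpha = 0.05 test).
#'
#' @param accuracies per-subject mean accuracies (>= 2 subjects).
#' @param chance chance level (default 0.5).
#' @param nBoot number of bootstrap resamples (default 10000).
#' @param seed integer seed for the resampling.
#' @return One-row data.frame: `meanAccuracy`, `pRaw`, `ci90Lower`,
#'   `ci90Upper`, `nBoot`, `chance`, `nSubjects`.
#' @export
bootstrapMeanTest <- function(accuracies, chance = 0.5, nBoot = 10000,
                              seed = NULL) {
  n <- length(accuracies)
  if (n < 2) stop("bootstrap test needs >= 2 subjects")
  boots <- withSeed(seed, {
    idx <- matrix(sample.int(n, n * nBoot, replace = TRUE), nrow = nBoot)
    rowMeans(matrix(accuracies[idx], nrow = nBoot))
  })
  ci <- unname(quantile(boots, c(0.05, 0.95), type = 7))
  data.frame(meanAccuracy = mean(accuracies),
             pRaw = (1 + sum(boots <= chance)) / (nBoot + 1),
             ci90Lower = ci[1], ci90Upper = ci[2],
             nBoot = nBoot, chance = chance, nSubjects = n)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p values with monotonicity enforcement, capped at 1.
#' An empty input is returned unchanged.
#'
#' @param pValues vector of raw p values in (0, 1].
#' @return Adjusted p values, same length and order as the input.
#' @export
fdrAdjust <- function(pValues) {
  if (!length(pValues)) return(pValues)
  stopifnot(all(pValues > 0 & pValues <= 1))
  p.adjust(pValues, method = "BH")
}

# Build the numeric coding used by the depth LMM: centred +/- 0.5
# contrasts so main effects are interpretable at the mean of the other
# factors.
.codeHalf <- function(f, levels) {
  ifelse(as.character(f) == levels[2], 0.5, -0.5)
}

.lmmTerm <- function(sm, ci, term) {
  i <- match(term, rownames(sm))
  data.frame(term = term, estimate = sm[i, "Value"],
             ciLower = ci[i, 1], ciUpper = ci[i, 2],
             t = sm[i, "t-value"], df = sm[i, "DF"],
             p = sm[i, "p-value"], stringsAsFactors = FALSE)
}

# Shared REML fit with fallback to a simplified random structure when the
# full random-effects fit fails or is degenerate.
.fitLmm <- function(data, fixedForm, randFull, randSimple) {
  ctrl <- nlme::lmeControl(opt = "nlminb", maxIter = 200, msMaxIter = 200,
                           returnObject = FALSE)
  fit <- tryCatch(
    nlme::lme(fixedForm, data = data, random = randFull,
              method = "REML", control = ctrl),
    error = function(e) NULL)
  degenerate <- is.null(fit)
  if (degenerate)
    fit <- nlme::lme(fixedForm, data = data, random = randSimple,
                     method = "REML",
                     control = nlme::lmeControl(opt = "nlminb",
                                                returnObject = TRUE))
  list(fit = fit, degenerate = degenerate)
}

#' Second-level depth-parameterised linear mixed model
#'
#' Fits decoding accuracy as a linear function of continuous cortical
#' depth, experiment and stimulus condition, with all their interactions
#' as fixed effects, and per-subject random intercept, depth slope and
#' condition-by-depth slope; estimated by REML. Parameterising across
#' depth avoids one test per depth bin (the number of bins is an
#' arbitrary sampling choice). Condition and experiment enter as centred
#' +/- 0.5 contrasts; depth is the continuous bin-centre value in [0, 1].
#' If the full random-effects fit fails to converge it is refit with
#' random intercept + depth only and flagged as degenerate.
#'
#' @param table data.frame with columns `subject`, `experiment`,
#'   `condition` (two levels, e.g. imagery/illusory), `depth` (continuous,
#'   e.g. 0.1 ... 0.9) and `accuracy`.
#' @return List of class `LmmFit`: `fixed` (term table with estimate, 95%
#'   CI, t, df, p), `degenerate` flag, `method`, and the underlying `nlme`
#'   fit object.
#' @export
fitDepthLmm <- function(table) {
  need <- c("subject", "condition", "depth", "accuracy")
  stopifnot(all(need %in% names(table)))
  condLev <- sort(unique(as.character(table$condition)))
  if (length(condLev) != 2) stop("exactly two conditions required")
  if (length(unique(table$depth)) < 2) stop(">= 2 depths required")
  d <- data.frame(subject = factor(table$subject),
                  depth = as.numeric(table$depth),
                  cond = .codeHalf(table$condition, condLev),
                  accuracy = as.numeric(table$accuracy))
  d$condDepth <- d$cond * d$depth
  expLev <- if ("experiment" %in% names(table))
    sort(unique(as.character(table$experiment))) else "exp1"
  if (length(expLev) > 2) stop("at most two experiments supported")
  withExp <- length(expLev) == 2
  if (withExp) {
    d$exper <- .codeHalf(table$experiment, expLev)
    fixedForm <- accuracy ~ depth * cond * exper
  } else {
    fixedForm <- accuracy ~ depth * cond
  }
  res <- .fitLmm(d, fixedForm,
                 randFull = ~ 1 + depth + condDepth | subject,
                 randSimple = ~ 1 + depth | subject)
  sm <- summary(res$fit)$tTable
  se <- sm[, "Std.Error"]
  tcrit <- stats::qt(0.975, sm[, "DF"])
  ci <- cbind(sm[, "Value"] - tcrit * se, sm[, "Value"] + tcrit * se)
  terms <- rownames(sm)
  fixed <- do.call(rbind, lapply(terms, function(tm) .lmmTerm(sm, ci, tm)))
  # human-readable term names
  ren <- c("(Intercept)" = "intercept", "depth" = "depth",
           "cond" = "condition", "exper" = "experiment",
           "depth:cond" = "condition:depth",
           "depth:exper" = "experiment:depth",
           "cond:exper" = "experiment:condition",
           "depth:cond:exper" = "experiment:condition:depth")
  fixed$term <- ifelse(fixed$term %in% names(ren), ren[fixed$term],
                       fixed$term)
  structure(list(fixed = fixed, degenerate = res$degenerate,
                 method = "REML", conditionLevels = condLev,
                 experimentLevels = expLev, model = res$fit),
            class = "LmmFit")
}

#' @export
print.LmmFit <- function(x, ...) {
  cat("Linear mixed model (REML", if (x$degenerate)
    ", simplified random structure", ")\n", sep = "")
  print(x$fixed, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Check that voxel counts carry no cortical-depth trend
#'
#' Quality-control gate for the depth-resolved decoding analyses: a mixed
#' model of per-bin voxel counts on depth, ROI and their interaction
#' (random per-subject intercept, depth, ROI and depth:ROI) should show no
#' significant depth effect; a significant trend triggers a warning, since
#' depth differences in voxel numbers could masquerade as laminar
#' decoding effects.
#'
#' @param counts data.frame with columns `subject`, `roi`, `depth`
#'   (continuous bin centre) and `count`.
#' @param alpha significance level for the warning gate.
#' @return An `LmmFit` (see [fitDepthLmm()]) of counts on depth; the term
#'   table contains the depth effect and, with two ROIs, the ROI and
#'   depth:ROI terms.
#' @export
checkDepthVoxelBalance <- function(counts, alpha = 0.05) {
  need <- c("subject", "depth", "count")
  stopifnot(all(need %in% names(counts)))
  if (length(unique(counts$depth)) < 2) stop(">= 2 depths required")
  d <- data.frame(subject = factor(counts$subject),
                  depth = as.numeric(counts$depth),
                  count = as.numeric(counts$count))
  roiLev <- if ("roi" %in% names(counts))
    sort(unique(as.character(counts$roi))) else "roi"
  if (length(roiLev) > 2) stop("at most two ROIs supported")
  if (length(roiLev) == 2) {
    d$roi <- .codeHalf(counts$roi, roiLev)
    d$roiDepth <- d$roi * d$depth
    res <- .fitLmm(d, count ~ depth + roi + roi:depth,
                   randFull = ~ 1 + depth + roi + roiDepth | subject,
                   randSimple = ~ 1 + depth | subject)
  } else {
    res <- .fitLmm(d, count ~ depth,
                   randFull = ~ 1 + depth | subject,
                   randSimple = ~ 1 | subject)
  }
  sm <- summary(res$fit)$tTable
  se <- sm[, "Std.Error"]
  tcrit <- stats::qt(0.975, sm[, "DF"])
  ci <- cbind(sm[, "Value"] - tcrit * se, sm[, "Value"] + tcrit * se)
  fixed <- do.call(rbind, lapply(rownames(sm),
                                 function(tm) .lmmTerm(sm, ci, tm)))
  depthP <- fixed$p[fixed$term == "depth"]
  if (length(depthP) && depthP < alpha)
    warning("voxel counts show a significant depth trend (p = ",
            signif(depthP, 3), "); laminar comparisons may be confounded")
  structure(list(fixed = fixed, degenerate = res$degenerate,
                 method = "REML", roiLevels = roiLev, model = res$fit),
            class = "LmmFit")
}
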