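#' Score binocular-rivalry imagery strength (%primed)
#'
#' Individual imagery strength is the bias with which the imagined colour
#' gains perceptual dominance during subsequent binocular rivalry:
#' `strength = nPrimed / (n - nMock - nMixed)`, where `n` is the total
#' number of trials, `nMock` the number of catch trials, `nMixed` the
#' number of non-catch trials with a "mixed" report, and `nPrimed` the
#' number of non-catch trials whose report matched the cued colour.
#' Catch and mixed trials are never counted as primed. The catch-trial
#' failure rate (non-"mixed" reports on catch trials, an indicator of
#' decision bias) is reported but no exclusion rule is applied.
#'
#' @param trials data.frame as produced by [simulateRivalryTrials()] (or
#'   read from a TSV) with columns `cue`, `response`, `isCatch`.
#' @return List of class `ImageryScore`: `strength`, `passesThreshold`
#'   (at 0.60), the counts `n`, `nPrimed`, `nMock`, `nMixed`, and
#'   `catchFailureRate`.
#' @export
scoreImageryStrength <- function(trials) {
  stopifnot(all(c("cue", "response", "isCatch") %in% names(trials)))
  n <- nrow(trials)
  nMock <- sum(trials$isCatch)
  nMixed <- sum(!trials$isCatch & trials$response == "mixed")
  nPrimed <- sum(!trials$isCatch & trials$response == trials$cue)
  denom <- n - nMock - nMixed
  if (denom <= 0) stop("no scorable trials: denominator is zero")
  strength <- nPrimed / denom
  catchFail <- if (nMock > 0)
    sum(trials$isCatch & trials$response != "mixed") / nMock else NA_real_
  structure(list(strength = strength,
                 passesThreshold = strength >= 0.60,
                 n = n, nPrimed = nPrimed, nMock = nMock, nMixed = nMixed,
                 catchFailureRate = catchFail),
            class = "ImageryScore")
}

#' @export
print.ImageryScore <- function(x, ...) {
  cat(sprintf("Imagery strength (%%primed): %.3f (%d/%d scorable trials)%s\n",
              x$strength, x$nPrimed, x$n - x$nMock - x$nMixed,
              if (x$passesThreshold) " - passes 60% threshold" else ""))
  invisible(x)
}

#' Select participants by the a priori imagery-strength threshold
#'
#' Returns the indices of participants whose priming score lies at or
#' above the threshold (default 60%).
#'
#' @param scores list of `ImageryScore` objects, or a numeric vector of
#'   strengths.
#' @param threshold selection threshold on the strength fraction.
#' @return Integer indices of the selected participants.
#' @export
selectParticipants <- function(scores, threshold = 0.60) {
  strengths <- if (is.numeric(scores)) scores else
    vapply(scores, `[[`, numeric(1), "strength")
  which(strengths >= threshold)
}
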