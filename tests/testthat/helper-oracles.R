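# Independent oracles used to cross-check the package implementations.

# Benjamini-Hochberg step-up, written directly from the definition:
# adj_(i) = min_{j >= i} min(1, m/j * p_(j)) on the sorted p values.
bhStepUp <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, m / seq_len(m) * ps)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Linear soft-margin C-SVM solved as the dual quadratic programme with a
# generic QP solver (kernlab::ipop); independent of libsvm.
qpSvmOracle <- function(X, yFactor, C = 1) {
  y <- ifelse(yFactor == levels(yFactor)[1], 1, -1)
  n <- nrow(X)
  H <- (y %*% t(y)) * (X %*% t(X)) + diag(1e-10, n)
  sol <- kernlab::ipop(c = matrix(-1, n), H = H, A = t(y), b = 0,
                       l = rep(0, n), u = rep(C, n), r = 0,
                       sigf = 9, maxiter = 100)
  a <- kernlab::primal(sol)
  w <- as.numeric(t(X) %*% (a * y))
  free <- which(a > 1e-6 * C & a < C * (1 - 1e-6))
  if (!length(free)) free <- which(a > 1e-6 * C)
  b <- mean(y[free] - X[free, , drop = FALSE] %*% w)
  list(w = w, b = b, predict = function(Xn)
    ifelse(as.numeric(Xn %*% w + b) >= 0,
           levels(yFactor)[1], levels(yFactor)[2]))
}

# Naive O(pixels x voxels) double loop over the pRF-weighted average.
bruteForceProjection <- function(weights, models, grid) {
  px <- pixelCentres(grid)
  m <- models[weights@voxels, , drop = FALSE]
  vals <- numeric(nrow(px))
  cov <- numeric(nrow(px))
  for (i in seq_len(nrow(px))) {
    num <- 0
    den <- 0
    for (j in seq_len(nrow(m))) {
      d2 <- (px[i, 1] - m$x[j])^2 + (px[i, 2] - m$y[j])^2
      if (d2 <= (2 * m$sigma[j])^2) {
        w <- exp(-d2 / (2 * m$sigma[j]^2))
        num <- num + w * weights@weights[j]
        den <- den + w
      }
    }
    cov[i] <- den
    vals[i] <- if (den > 0) num / den else 0
  }
  n <- grid@nPixels
  list(values = matrix(vals, n, n), coverage = matrix(cov, n, n))
}

# Exhaustive scoring of every grid candidate with cor(), one at a time.
bruteForcePrfFit <- function(voxTs, apertures, grid, hrf = hrfParams()) {
  preds <- lapply(apertures, function(ap)
    vapply(seq_len(nrow(grid$candidates)), function(i)
      predictPrfTimecourse(grid$candidates[i, ], ap, hrf),
      numeric(nFrames(ap))))
  P <- do.call(rbind, preds)                 # frames x candidates
  r2 <- apply(P, 2, function(p)
    if (sd(p) == 0 || sd(voxTs) == 0) 0 else cor(p, voxTs)^2)
  best <- which.max(r2)                      # candidates sorted for ties
  cbind(grid$candidates[best, ], r2 = r2[best])
}
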