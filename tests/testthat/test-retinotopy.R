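test_that("Fourier phase mapping recovers sinusoid parameters", {
  t <- (0:395) * 2
  x <- 3 * cos(2 * pi * t / 64 + 0.9)
  pm <- fourierPhaseMap(x, stimulationPeriodS = 64, trS = 2,
                        nBaselineVols = 6)
  expect_equal(pm$phase, 0.9, tolerance = 1e-6)
  expect_equal(pm$amplitude, 3, tolerance = 1e-6)
  expect_gt(pm$fRatio, 1e3)
  # constant series: zero amplitude and F-ratio, no crash
  pc <- fourierPhaseMap(rep(5, 384), 64, 2)
  expect_equal(pc$amplitude, 0)
  expect_equal(pc$fRatio, 0)
  expect_error(fourierPhaseMap(rnorm(100), 64, 2), "not representable")
})

test_that("white-noise F-ratios are centred on one", {
  set.seed(11)
  fr <- fourierPhaseMap(matrix(rnorm(4000 * 384), 4000), 64, 2)$fRatio
  # periodogram ordinates are exchangeable under white noise, so the
  # ratio of one to the mean of the rest has expectation ~ 1
  expect_equal(mean(fr), 1, tolerance = 0.06)
})

test_that("pRF predictions behave as impulse responses of the HRF", {
  g <- VisualFieldGrid(4, 16)
  px <- pixelCentres(g)
  mkAp <- function(frames) new("StimulusAperture", grid = g,
                               frames = frames, trS = 2, kind = "task_block")
  # aperture far from the pRF: flat zero prediction
  far <- matrix(0, nrow(px), 20)
  far[which.min((px[, 1] - 3.5)^2 + (px[, 2] - 3.5)^2), ] <- 1
  p0 <- predictPrfTimecourse(list(x = -3, y = -3, sigma = 0.2), mkAp(far))
  expect_equal(max(abs(p0)), 0, tolerance = 1e-10)
  # full-field constant aperture: ramps to a plateau
  p1 <- predictPrfTimecourse(list(x = 0, y = 0, sigma = 1),
                             mkAp(matrix(1, nrow(px), 30)))
  expect_true(all(diff(p1[1:5]) > 0))
  expect_equal(p1[25], p1[30], tolerance = 1e-6 * abs(p1[30]))
  # single-frame point stimulus at the centre: scaled copy of the kernel
  imp <- matrix(0, nrow(px), 20)
  imp[which.min(px[, 1]^2 + px[, 2]^2), 1] <- 1
  p2 <- predictPrfTimecourse(list(x = px[1, 1], y = px[1, 2], sigma = 0.5),
                             mkAp(imp))
  kern <- twoGammaHrf(trS = 2)
  kern <- c(kern, rep(0, 20 - length(kern)))
  expect_equal(p2 / max(p2), kern, tolerance = 1e-9)
  expect_error(predictPrfTimecourse(list(x = 9, y = 0, sigma = 1),
                                    mkAp(far)), "outside")
})

test_that("grid fitting self-recovers candidates and matches brute force", {
  g <- VisualFieldGrid(3, 16)
  aps <- list(makeRetinotopyStimulus("wedge", g),
              makeRetinotopyStimulus("ring", g))
  grid <- makePrfGrid(3, nSigma = 6, sigmaRange = c(0.5, 2.4))
  P <- laminardecode:::.prfPredictions(grid, aps)
  set.seed(3)
  pick <- sample(nrow(grid$candidates), 25)
  fit <- fitPrfGrid(P[pick, ], aps, grid)
  expect_equal(fit$x, grid$candidates$x[pick])
  expect_equal(fit$y, grid$candidates$y[pick])
  expect_equal(fit$sigma, grid$candidates$sigma[pick])
  expect_true(all(abs(fit$r2 - 1) < 1e-9))
  # off-grid pRFs: winner must equal exhaustive single-candidate scoring
  for (mod in list(list(x = 0.37, y = -1.21, sigma = 0.8),
                   list(x = -2.05, y = 0.44, sigma = 1.7))) {
    ts <- unlist(lapply(aps, function(ap)
      predictPrfTimecourse(mod, ap)))
    got <- fitPrfGrid(ts, aps, grid)
    want <- bruteForcePrfFit(ts, aps, grid)
    expect_equal(got$x, want$x)
    expect_equal(got$y, want$y)
    expect_equal(got$sigma, want$sigma)
    expect_equal(got$r2, want$r2, tolerance = 1e-8)
  }
})

test_that("fit score is invariant to affine rescaling of the time course", {
  g <- VisualFieldGrid(3, 16)
  aps <- list(makeRetinotopyStimulus("wedge", g),
              makeRetinotopyStimulus("ring", g))
  grid <- makePrfGrid(3, nSigma = 5, sigmaRange = c(0.5, 2))
  mod <- list(x = 1.1, y = 0.6, sigma = 0.9)
  ts <- unlist(lapply(aps, function(ap) predictPrfTimecourse(mod, ap)))
  set.seed(4)
  ts <- ts + rnorm(length(ts), 0, sd(ts))
  f1 <- fitPrfGrid(ts, aps, grid)
  f2 <- fitPrfGrid(250 + 40 * ts, aps, grid)
  expect_equal(f1, f2)
  # all-constant voxel yields the r2 = 0 sentinel, not an error
  f3 <- fitPrfGrid(rep(7, length(ts)), aps, grid)
  expect_equal(f3$r2, 0)
})

test_that("pure-noise voxels rarely exceed the r2 = 0.2 threshold", {
  g <- VisualFieldGrid(3, 12)
  aps <- list(makeRetinotopyStimulus("wedge", g),
              makeRetinotopyStimulus("ring", g))
  grid <- makePrfGrid(3, nSigma = 6, sigmaRange = c(0.5, 2.4))
  set.seed(5)
  noise <- matrix(rnorm(500 * 664), 500)
  fit <- fitPrfGrid(noise, aps, grid)
  expect_gte(mean(fit$r2 < 0.2), 0.99)
})

test_that("ROI membership follows the 1-sigma containment rule", {
  models <- data.frame(
    x = c(0, 0, 1.5, 0), y = c(0, 0, 0, 0),
    sigma = c(1, 1, 1, 2.5), r2 = c(0.5, 0.15, 0.5, 0.5))
  disc <- discRegion(2.1)
  roi <- defineRoi(models, disc, r2Threshold = 0.2)
  # voxel 1: centred, sigma 1 disc inside radius 2.1 -> in
  # voxel 2: below threshold -> out; voxel 3: 1.5 + 1 > 2.1 -> out
  # voxel 4: sigma disc crosses the boundary -> out
  expect_equal(roiVoxels(roi), 1L)
  roi10 <- defineRoi(models, disc, r2Threshold = 0.1)
  expect_equal(roiVoxels(roi10), c(1L, 2L))
  expect_error(discRegion(0), "positive area")
})

test_that("lowering the r2 threshold never removes ROI voxels", {
  set.seed(6)
  models <- data.frame(x = runif(200, -2, 2), y = runif(200, -2, 2),
                       sigma = runif(200, 0.3, 1.5),
                       r2 = runif(200))
  reg <- discRegion(2.5)
  prev <- integer(0)
  for (th in c(0.4, 0.3, 0.2, 0.1, 0.05)) {
    cur <- roiVoxels(defineRoi(models, reg, th))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("stacked-column completion adds flagged depth mates", {
  models <- data.frame(x = c(0, 5, 0), y = 0, sigma = c(0.5, 0.5, 0.5),
                       r2 = c(0.9, 0.9, 0.05))
  cols <- c(1L, 2L, 1L)   # voxels 1 and 3 share a column
  roi <- defineRoi(models, discRegion(2.1), 0.2, stackedColumns = cols)
  expect_equal(roiVoxels(roi), c(1L, 3L))
  expect_equal(roi@completed, c(FALSE, TRUE))
})

test_that("semicircle containment honours the straight edge", {
  semi <- semicircleRegion(3, normalAngle = 0, edgeOffset = 0)
  models <- data.frame(x = c(1.5, 1.5, 0.3), y = 0,
                       sigma = c(1, 1.6, 0.5), r2 = 0.9)
  roi <- defineRoi(models, semi, 0.2)
  # voxel 1 fits; voxel 2's disc leaks over the arc; voxel 3's disc
  # crosses the straight edge (0.3 - 0.5 < 0)
  expect_equal(roiVoxels(roi), 1L)
})
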