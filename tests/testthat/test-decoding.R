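test_that("beta rescaling maps the training scope onto [-1, 1]", {
  v <- matrix(c(2, 4, 6), 3, 1)
  expect_equal(rescaleBetas(v), matrix(c(-1, 0, 1), 3, 1))
  spanned <- matrix(c(-1, 0.2, 1), 3, 1)
  expect_equal(rescaleBetas(spanned), spanned)
  # parameters fitted on training rows only: test values may leave [-1, 1]
  v2 <- matrix(c(0, 10, 12), 3, 1)
  expect_equal(rescaleBetas(v2, trainRows = 1:2)[3, 1], 1.4)
  expect_error(rescaleBetas(matrix(1, 3, 1)), "constant")
})

test_that("separable antisymmetric patterns decode perfectly, chance under permutation", {
  set.seed(21)
  b <- patternBetas(list(imagery = rnorm(10)), nRuns = 4, noise = 0.01)
  res <- decodeLoro(b, "imagery")
  expect_equal(res$meanAccuracy, 1.0)
  expect_equal(nrow(res$folds), 4L)
  expect_equal(res$meanAccuracy, mean(res$folds$accuracy))
  # permuting colour labels within runs is a label-exchangeable null
  set.seed(22)
  accs <- replicate(300, {
    bp <- b
    lab <- betaLabels(bp)
    for (r in unique(lab$run)) {
      idx <- which(lab$run == r)
      lab$colour[idx] <- sample(lab$colour[idx])
    }
    bp@labels <- lab
    decodeLoro(bp, "imagery")$meanAccuracy
  })
  expect_equal(mean(accs), 0.5, tolerance = 0.02)
})

test_that("class-missing training folds and unknown conditions are rejected", {
  set.seed(23)
  b <- patternBetas(list(imagery = rnorm(6)), nRuns = 2, noise = 0.01)
  lab <- betaLabels(b)
  lab$colour[lab$run == 1] <- "red"        # run 2 training fold loses green
  b@labels <- lab
  expect_error(decodeLoro(b, "imagery"), "missing from the training fold")
  expect_error(decodeLoro(b, "perception"), "no trials")
})

test_that("the SVM solution matches a generic QP oracle, also under voxel duplication", {
  skip_if_not_installed("kernlab")
  set.seed(24)
  X <- matrix(rnorm(16 * 4), 16)
  y <- factor(rep(c("red", "green"), 8), levels = c("red", "green"))
  X[y == "red", ] <- X[y == "red", ] + 3   # wide margin: no bounded SVs
  cfg <- decoderConfig()
  fit <- laminardecode:::.fitSvm(X, y, cfg)
  orc <- qpSvmOracle(X, y, C = cfg$cost)
  expect_equal(fit$w, orc$w, tolerance = 1e-3)
  probe <- matrix(rnorm(40 * 4), 40)
  expect_equal(laminardecode:::.predictSvm(fit, probe), orc$predict(probe))
  # duplicating every voxel: identical predictions, and the duplicated
  # weights sum to the original voxel's weight
  Xd <- cbind(X, X)
  fitD <- laminardecode:::.fitSvm(Xd, y, cfg)
  orcD <- qpSvmOracle(Xd, y, C = cfg$cost)
  expect_equal(fitD$w, orcD$w, tolerance = 1e-3)
  expect_equal(fitD$w[1:4] + fitD$w[5:8], fit$w, tolerance = 1e-3)
  expect_equal(laminardecode:::.predictSvm(fitD, cbind(probe, probe)),
               laminardecode:::.predictSvm(fit, probe))
})

test_that("accuracies are invariant to positive per-bin amplitude scaling", {
  set.seed(25)
  b <- patternBetas(list(imagery = rnorm(12)), nRuns = 4, noise = 0.5)
  a1 <- decodeLoro(b, "imagery")$meanAccuracy
  bScaled <- b
  bScaled@values <- b@values * 37.5
  expect_equal(decodeLoro(bScaled, "imagery")$meanAccuracy, a1)
})

test_that("cross-classification reduces to train accuracy for shared patterns", {
  set.seed(26)
  v <- rnorm(10)
  b <- patternBetas(list(illusory = v, perception = v),
                    nRuns = 4, noise = 1.0)
  # make the test condition's trials literal copies of the train trials
  lab <- betaLabels(b)
  trainRows <- which(lab$condition == "illusory")
  testRows <- which(lab$condition == "perception")
  b@values[testRows, ] <- b@values[trainRows, ]
  cc <- crossClassify(b, "illusory", "perception")
  # train-set accuracy computed directly from the same fitted model
  Vs <- rescaleBetas(betaValues(b), trainRows = trainRows)
  fit <- laminardecode:::.fitSvm(
    Vs[trainRows, ], factor(lab$colour[trainRows],
                            levels = c("red", "green")), decoderConfig())
  trainAcc <- mean(laminardecode:::.predictSvm(fit, Vs[trainRows, ]) ==
                     lab$colour[trainRows])
  expect_equal(cc$meanAccuracy, trainAcc)
  expect_equal(cc$direction, "illusory -> perception")
  # colour inversion in the test set flips the accuracy
  bFlip <- b
  labF <- betaLabels(bFlip)
  labF$colour[testRows] <- ifelse(labF$colour[testRows] == "red",
                                  "green", "red")
  bFlip@labels <- labF
  ccF <- crossClassify(bFlip, "illusory", "perception")
  expect_equal(ccF$meanAccuracy, 1 - trainAcc)
})

test_that("orthogonal test patterns yield chance cross-classification", {
  set.seed(27)
  accs <- replicate(120, {
    v <- rnorm(12)
    u <- rnorm(12)
    u <- u - sum(u * v) / sum(v * v) * v    # orthogonal to the train code
    b <- patternBetas(list(imagery = v, illusory = u), nRuns = 3,
                      noise = 0.3, seed = sample.int(1e6, 1))
    crossClassify(b, "imagery", "illusory")$meanAccuracy
  })
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})

test_that("same-condition cross-classification redirects to leave-one-run-out", {
  set.seed(28)
  b <- patternBetas(list(imagery = rnorm(8)), nRuns = 3, noise = 0.2)
  expect_message(cc <- crossClassify(b, "imagery", "imagery"),
                 "leave-one-run-out")
  expect_equal(cc$meanAccuracy, decodeLoro(b, "imagery")$meanAccuracy)
})

test_that("condition-pair decoding finds signal only at the injected depths", {
  es <- 0.01
  cfg <- fastConfig(nColumns = 16, nRuns = 6,
                    effectSize = c(perception = 0, imagery = 0,
                                   illusory = es, amodal = 0, mock = 0))
  s <- simulateSubject(cfg, seed = 31)
  tb <- computeTrialBetas(s)
  a <- subsetDepthBins(assignDepthBins(subjectTruth(s)$depth), tb$voxels)
  accs <- vapply(1:6, function(k) {
    mean(c(decodeConditionPair(tb$betas, "illusory", "mock", "red",
                               binMembers(a, k))$meanAccuracy,
           decodeConditionPair(tb$betas, "illusory", "mock", "green",
                               binMembers(a, k))$meanAccuracy))
  }, numeric(1))
  expect_gt(mean(accs[5:6]), mean(accs[1:2]) + 0.2)
  expect_gt(mean(accs[5:6]), 0.7)
  # identical generating patterns: chance discrimination
  cfg0 <- fastConfig(nColumns = 16, nRuns = 6,
                     effectSize = c(perception = 0, imagery = 0,
                                    illusory = 0, amodal = 0, mock = 0))
  s0 <- simulateSubject(cfg0, seed = 31)
  tb0 <- computeTrialBetas(s0)
  acc0 <- decodeConditionPair(tb0$betas, "illusory", "mock", "red",
                              NULL)$meanAccuracy
  expect_lt(abs(acc0 - 0.5), 0.25)
})

test_that("weight maps carry the informative voxels with consistent signs", {
  set.seed(29)
  v <- c(5, rep(0, 9))                     # single informative voxel
  b <- patternBetas(list(imagery = v), nRuns = 4, noise = 0.3)
  entry <- decodeLoro(b, "imagery", keepModels = TRUE)
  wm <- extractWeightMap(entry)
  expect_equal(which.max(abs(wm@weights)), 1L)
  expect_equal(wm@classes[1], "red")
  expect_gt(wm@weights[1], 0)              # red carries +v on voxel 1
  # swapping class labels flips every weight
  bSwap <- b
  lab <- betaLabels(bSwap)
  lab$colour <- ifelse(lab$colour == "red", "green", "red")
  bSwap@labels <- lab
  wmS <- extractWeightMap(decodeLoro(bSwap, "imagery", keepModels = TRUE))
  expect_equal(wmS@weights, -wm@weights, tolerance = 1e-6)
  expect_error(extractWeightMap(decodeLoro(b, "imagery")), "keepModels")
})
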