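test_that("bootstrap p values are exact in the degenerate cases", {
  b1 <- bootstrapMeanTest(rep(1, 16), nBoot = 10000, seed = 1)
  expect_equal(b1$pRaw, 1 / 10001)
  expect_equal(c(b1$ci90Lower, b1$ci90Upper), c(1, 1))
  b2 <- bootstrapMeanTest(rep(0.5, 16), nBoot = 10000, seed = 1)
  expect_equal(b2$pRaw, 1)
  expect_error(bootstrapMeanTest(0.7), ">= 2")
})

test_that("bootstrap p agrees with a high-replicate oracle and ignores order", {
  acc <- rep(c(0.55, 0.60, 0.65), times = 16)[1:16]
  p1 <- bootstrapMeanTest(acc, nBoot = 10000, seed = 5)$pRaw
  expect_equal(bootstrapMeanTest(rev(acc), nBoot = 10000, seed = 5)$pRaw,
               p1)
  # weaker evidence: mean 0.52, sd such that p is non-extreme
  accW <- c(0.55, 0.45, 0.60, 0.40, 0.58, 0.52, 0.47, 0.62,
            0.50, 0.56, 0.44, 0.61, 0.49, 0.55, 0.48, 0.50)
  pPkg <- bootstrapMeanTest(accW, nBoot = 10000, seed = 6)$pRaw
  # independent large-sample oracle of the same resampling scheme
  set.seed(99)
  n <- length(accW)
  oracle <- mean(replicate(2e5,
    mean(accW[sample.int(n, n, replace = TRUE)])) <= 0.5)
  expect_equal(pPkg, oracle, tolerance = 0.01)
  # seeded determinism
  expect_identical(bootstrapMeanTest(accW, nBoot = 2000, seed = 7),
                   bootstrapMeanTest(accW, nBoot = 2000, seed = 7))
})

test_that("FDR adjustment equals the step-up definition", {
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdrAdjust(0.03), 0.03)
  expect_equal(fdrAdjust(rep(0.2, 5)), rep(0.2, 5))
  expect_identical(fdrAdjust(numeric(0)), numeric(0))
  set.seed(8)
  for (i in 1:200) {
    p <- runif(sample(1:60, 1))
    expect_equal(fdrAdjust(p), bhStepUp(p))
  }
})

test_that("the depth LMM recovers exact linear structure", {
  tab <- expand.grid(subject = 1:10,
                     condition = c("imagery", "illusory"),
                     depth = c(0.1, 0.26, 0.42, 0.58, 0.74, 0.9))
  condC <- ifelse(tab$condition == "imagery", 0.5, -0.5)
  tab$accuracy <- 0.5 + 0.1 * tab$depth - 0.04 * condC +
    0.3 * condC * tab$depth
  fit <- suppressWarnings(fitDepthLmm(tab))
  est <- setNames(fit$fixed$estimate, fit$fixed$term)
  expect_equal(unname(est["condition:depth"]), 0.3, tolerance = 1e-6)
  expect_equal(unname(est["depth"]), 0.1, tolerance = 1e-6)
  expect_equal(unname(est["condition"]), -0.04, tolerance = 1e-6)
  expect_true(all(fit$fixed$ciLower <= fit$fixed$estimate &
                    fit$fixed$estimate <= fit$fixed$ciUpper))
  # relabelling the conditions flips the interaction exactly
  tabSwap <- tab
  tabSwap$condition <- ifelse(tab$condition == "imagery",
                              "illusory", "imagery")
  fitS <- suppressWarnings(fitDepthLmm(tabSwap))
  estS <- setNames(fitS$fixed$estimate, fitS$fixed$term)
  expect_equal(unname(estS["condition:depth"]), -0.3, tolerance = 1e-6)
  expect_error(fitDepthLmm(tab[tab$condition == "imagery", ]),
               "two conditions")
})

test_that("the LMM handles two experiments and reports all interactions", {
  set.seed(12)
  tab <- expand.grid(subject = 1:12,
                     condition = c("imagery", "illusory"),
                     experiment = c("exp1", "exp2"),
                     depth = c(0.1, 0.42, 0.74, 0.9))
  tab$subject <- paste(tab$experiment, tab$subject)
  tab$accuracy <- 0.55 + 0.2 * tab$depth +
    rnorm(nrow(tab), 0, 0.05)
  fit <- suppressWarnings(fitDepthLmm(tab))
  expect_setequal(fit$fixed$term,
                  c("intercept", "depth", "condition", "experiment",
                    "condition:depth", "experiment:depth",
                    "experiment:condition", "experiment:condition:depth"))
  expect_true(all(fit$fixed$df > 0))
})

test_that("interaction type-I error is controlled under the null", {
  set.seed(13)
  pvals <- replicate(200, {
    tab <- expand.grid(subject = 1:12,
                       condition = c("imagery", "illusory"),
                       depth = c(0.1, 0.26, 0.42, 0.58, 0.74, 0.9))
    b0 <- rnorm(12, 0.55, 0.04)
    bd <- rnorm(12, 0, 0.05)
    tab$accuracy <- b0[tab$subject] + bd[tab$subject] * tab$depth +
      rnorm(nrow(tab), 0, 0.07)
    fit <- suppressWarnings(fitDepthLmm(tab))
    fit$fixed$p[fit$fixed$term == "condition:depth"]
  })
  expect_gt(mean(pvals < 0.05), 0.015)
  expect_lt(mean(pvals < 0.05), 0.10)
})

test_that("voxel-balance checks flag depth trends and recover exact slopes", {
  # equal counts everywhere: depth effect indistinguishable from zero
  flat <- expand.grid(subject = 1:8, depth = c(0.1, 0.26, 0.42, 0.58,
                                               0.74, 0.9))
  flat$count <- 120
  f <- suppressWarnings(checkDepthVoxelBalance(flat))
  expect_equal(f$fixed$estimate[f$fixed$term == "depth"], 0,
               tolerance = 1e-8)
  # counts rising by exactly +10 per bin: slope 10 / 0.16 per depth unit
  rising <- flat
  rising$count <- 100 + 10 * (match(rising$depth, sort(unique(rising$depth))) - 1)
  w <- capture_warnings(fr <- checkDepthVoxelBalance(rising))
  expect_true(any(grepl("depth trend", w)))
  expect_equal(fr$fixed$estimate[fr$fixed$term == "depth"], 10 / 0.16,
               tolerance = 1e-6)
  # two-ROI table reports the interaction
  two <- rbind(cbind(flat, roi = "fovea"), cbind(flat, roi = "periphery"))
  two$count <- two$count + rnorm(nrow(two), 0, 5)
  f2 <- suppressWarnings(checkDepthVoxelBalance(two))
  expect_true("depth:roi" %in% f2$fixed$term ||
                "roi:depth" %in% f2$fixed$term)
})

test_that("default synthetic subjects show no systematic depth trend in counts", {
  set.seed(14)
  ok <- replicate(30, {
    depths <- subjectTruth(simulateSubject(fastConfig(),
                                           seed = sample.int(1e6, 1)))$depth
    a <- assignDepthBins(depths)
    lengths(a@membership)
  })
  # per-bin counts across subjects: no monotone drift toward either surface
  slope <- apply(ok, 2, function(cnt)
    coef(lm(cnt ~ seq_along(cnt)))[2])
  expect_lt(abs(mean(slope)), 1)
})
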