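test_that("balanced REML matches the closed-form ANOVA estimator", {
  set.seed(201)
  n <- 150; W <- 4
  y <- matrix(rnorm(n, 2, 1), n, W) + matrix(rnorm(n * W, 0, sqrt(0.5)), n, W)
  r <- gaussianRates(y)
  fit <- fitRandomIntercept(r, "D", covariates = character(0))
  vs <- varianceShares(fit)
  oracle <- anovaComponents(y)
  expect_equal(vs$sigma2_between, unname(oracle["s2b"]), tolerance = 1e-6)
  expect_equal(vs$sigma2_within, unname(oracle["s2w"]), tolerance = 1e-6)
})

test_that("independent residuals give a near-zero between component", {
  set.seed(202)
  n <- 2000; W <- 2
  y <- matrix(rnorm(n * W, 1.5, 1), n, W)
  fit <- fitRandomIntercept(gaussianRates(y), "D", covariates = character(0))
  vs <- varianceShares(fit)
  expect_lt(vs$sigma2_between,
            1e-6 * (vs$sigma2_between + vs$sigma2_within) + 0.01)
  expect_gt(vs$within_share, 0.99)
})

test_that("variance shares follow their definition", {
  set.seed(203)
  n <- 400; W <- 4
  y <- matrix(rnorm(n, 0, 1), n, W) + matrix(rnorm(n * W, 0, 1), n, W)
  fit <- fitRandomIntercept(gaussianRates(y), "D", covariates = character(0))
  vs <- varianceShares(fit)
  expect_equal(vs$between_share + vs$within_share, 1, tolerance = 1e-12)
  expect_equal(vs$between_share,
               vs$sigma2_between / (vs$sigma2_between + vs$sigma2_within))
  # equal components -> shares near (0.5, 0.5)
  expect_lt(abs(vs$between_share - 0.5), 0.1)
})

test_that("participants with fewer than minObs diaries are dropped", {
  r <- rbind(gaussianRates(matrix(rnorm(40), 10, 4)),
             rateTable("lonely", "R1", K = 1L, D = 3))
  fit <- fitRandomIntercept(r, "D", covariates = character(0))
  expect_equal(fit$nParticipants, 10)
})

test_that("rank-deficient designs fail naming the aliased column", {
  set.seed(204)
  r <- gaussianRates(matrix(rnorm(200), 50, 4))
  # sex is constant male in the fixture: its dummy column is aliased
  expect_error(fitRandomIntercept(r, "D", covariates = c("sex", "wave")),
               "sexfemale")
})

test_that("the location covariate is refused for the L response", {
  r <- gaussianRates(matrix(rnorm(80), 20, 4))
  r$L <- r$K
  expect_error(fitRandomIntercept(r, "L",
                                  covariates = c("wave", "location_category")),
               "location")
})

test_that("percentage contribution is 100 at the comparator and matches hand calculation", {
  set.seed(205)
  n <- 300; W <- 2
  # single binary covariate: wave effect beta on the log1p scale
  beta <- 0.4
  b <- rnorm(n, 0, 0.3)
  y <- cbind(2 + b + rnorm(n, 0, 0.4), 2 + beta + b + rnorm(n, 0, 0.4))
  fit <- fitRandomIntercept(gaussianRates(y), "D", covariates = "wave")
  expect_equal(percentageContribution(fit, comparatorProfile()), 100)

  co <- lme4::fixef(fit$fit)
  hand <- 100 * expm1(co[1] + co["waveR2"]) / expm1(co[1])
  expect_equal(percentageContribution(fit, list(wave = "R2")),
               unname(hand), tolerance = 1e-9)
  # and the recovered effect is near the truth
  expect_lt(abs(unname(co["waveR2"]) - beta), 0.1)
})

test_that("contributions rise monotonically with location count when coupling is positive", {
  cfg <- syntheticConfig(nHouseholds = 500, locationCoupling = 0.25,
                         dropoutPerWave = 0, initialParticipation = 1)
  r <- deriveRates(generatePanel(config = cfg, seed = 31))
  fit <- fitRandomIntercept(r, "K")
  ct <- contributionTable(fit)
  lc <- ct[ct$covariate == "location_category", ]
  lc <- lc[match(c(as.character(1:5), "6+"), lc$level), ]
  expect_true(all(diff(lc$percentage) > 0))
})

test_that("accumulation: constant identical series give zero CV equal to the null", {
  r <- balancedRates(matrix(5L, 40, 4))
  acc <- accumulationAnalysis(r, "K", nullReps = 20, seed = 3)
  expect_equal(acc$observed_cv, rep(0, 4))
  expect_equal(acc$null_mean, rep(0, 4))
})

test_that("accumulation horizon 1 equals the plain between-participant CV", {
  set.seed(207)
  Kmat <- matrix(rpois(200, 10), 50, 4)
  r <- balancedRates(Kmat)
  acc <- accumulationAnalysis(r, "K", nullReps = 10, seed = 1)
  expect_equal(acc$observed_cv[1], sd(Kmat[, 1]) / mean(Kmat[, 1]))
  expect_error(accumulationAnalysis(r[1:4, ], "K"), "fewer than 2")
})

test_that("permutation nulls preserve each wave's marginal distribution", {
  set.seed(208)
  m <- matrix(rpois(120, 8), 30, 4)
  mp <- diarycontacts:::.permuteColumns(m)
  for (j in 1:4) expect_equal(sort(mp[, j]), sort(m[, j]))
})

test_that("quantile consistency is 100% for a single quantile", {
  set.seed(209)
  r <- balancedRates(matrix(rpois(160, 9), 40, 4))
  qc <- quantileConsistency(r, "K", nQuantiles = 1, nullReps = 10, seed = 2)
  expect_equal(qc$observed, 100)
  expect_equal(qc$null_mean, 100)
})
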