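test_that("contacts drawn exactly proportional to the census give all-ones", {
  cen <- defaultCensus()
  # two participants per participant age group, each reporting contact
  # counts exactly proportional to census (x1000)
  counts <- matrix(rep(cen$proportion * 1000, 8), nrow = 8, byrow = TRUE)
  ages <- rep(c(10, 30, 50, 70), each = 2)
  panel <- countsPanel(counts, ages, cen)
  mm <- mixingRatioMatrix(panel, cen, "R1")
  expect_equal(unname(mixingRatios(mm)),
               matrix(1, 4, 5), tolerance = 1e-9)
})

test_that("two-group hand-worked example gives cells 1.5 and 0.5", {
  cen <- data.frame(age_group = c("20-39", "40-64"),
                    proportion = c(0.5, 0.5), stringsAsFactors = FALSE)
  # group-A participants (ages 20-39) report 3 within-group and 1 cross
  counts <- matrix(c(3, 1,
                     1, 3), nrow = 2, byrow = TRUE)
  panel <- countsPanel(counts, ages = c(30, 50), cen)
  mm <- mixingRatioMatrix(panel, cen, "R1",
                          participantBreaks = c(20, 40, Inf),
                          participantLabels = c("A", "B"))
  r <- mixingRatios(mm)
  expect_equal(r["A", "20-39"], (3 / 4) / 0.5) # 1.5
  expect_equal(r["A", "40-64"], 0.5)
  expect_equal(r["B", "40-64"], 1.5)
})

test_that("observed shares reconstruct to a distribution and scaling is irrelevant", {
  set.seed(21)
  cen <- defaultCensus()
  counts <- matrix(rpois(8 * 5, 20) + 1, nrow = 8)
  ages <- rep(c(10, 30, 50, 70), each = 2)
  panel <- countsPanel(counts, ages, cen)
  mm <- mixingRatios(mixingRatioMatrix(panel, cen, "R1"))
  # row-wise: sum_b cell(a,b) * census(b) = 1
  recon <- mm %*% cen$proportion
  expect_equal(unname(recon[, 1]), rep(1, 4), tolerance = 1e-9)

  # uniform scaling of every participant's counts leaves the matrix unchanged
  panel5 <- countsPanel(counts * 5, ages, cen)
  mm5 <- mixingRatios(mixingRatioMatrix(panel5, cen, "R1"))
  expect_equal(mm5, mm, tolerance = 1e-9)
})

test_that("participants aged 2-4 are excluded from the matrix", {
  cen <- defaultCensus()
  counts <- matrix(rep(cen$proportion * 1000, 5), nrow = 5, byrow = TRUE)
  # one under-5 participant whose contacts would break proportionality
  counts[5, ] <- c(1000, 0, 0, 0, 0)
  panel <- countsPanel(counts, ages = c(10, 30, 50, 70, 3), cen)
  mm <- mixingRatios(mixingRatioMatrix(panel, cen, "R1"))
  expect_equal(unname(mm), matrix(1, 4, 5), tolerance = 1e-9)
})

test_that("bootstrap keeps the plug-in point estimate and is seed-deterministic", {
  set.seed(31)
  cen <- defaultCensus()
  counts <- matrix(rpois(20 * 5, 15), nrow = 20)
  ages <- rep(c(10, 30, 50, 70), 5)
  panel <- countsPanel(counts, ages, cen)
  point <- mixingRatioMatrix(panel, cen, "R1")
  bs1 <- bootstrapMixing(panel, cen, "R1", nBoot = 100, seed = 7)
  bs2 <- bootstrapMixing(panel, cen, "R1", nBoot = 100, seed = 7)
  expect_equal(mixingRatios(bs1), mixingRatios(point))
  expect_identical(mixingCI(bs1), mixingCI(bs2))
  ci <- mixingCI(bs1)
  expect_true(all(ci$low <= mixingRatios(bs1) + 1e-12, na.rm = TRUE))
  expect_true(all(mixingRatios(bs1) <= ci$high + 1e-12, na.rm = TRUE))
  expect_error(bootstrapMixing(panel, cen, "R1", nBoot = 1), "nBoot")
})

test_that("a single-participant group has a degenerate CI at its point estimate", {
  cen <- defaultCensus()
  counts <- matrix(c(10, 10, 10, 10, 10,
                     5, 5, 5, 5, 5), nrow = 2, byrow = TRUE)
  panel <- countsPanel(counts, ages = c(10, 30), cen) # one per group
  bs <- bootstrapMixing(panel, cen, "R1", nBoot = 50, seed = 1)
  ci <- mixingCI(bs)
  r <- mixingRatios(bs)
  expect_equal(ci$low["5-19", ], r["5-19", ], tolerance = 1e-12)
  expect_equal(ci$high["5-19", ], r["5-19", ], tolerance = 1e-12)
})

test_that("bootstrap intervals tighten as the sample grows", {
  cen <- defaultCensus()
  width <- sapply(c(100, 1000), function(n) {
    cfg <- syntheticConfig(nHouseholds = n, meanHouseholdSize = 1,
                           nWaves = 1, dropoutPerWave = 0,
                           initialParticipation = 1)
    panel <- generatePanel(config = cfg, seed = 19)
    bs <- bootstrapMixing(panel, cen, "R1", nBoot = 200, seed = 2)
    ci <- mixingCI(bs)
    mean(ci$high - ci$low, na.rm = TRUE)
  })
  expect_lt(width[2], width[1])
})

test_that("dominant eigenvalues: closed forms, oracle, Perron bounds, errors", {
  # one group: eigenvalue is the contact rate itself
  expect_equal(dominantEigenvalue(matrix(3.7)), 3.7)
  # symmetric 2x2 closed form
  expect_equal(dominantEigenvalue(matrix(c(2, 1, 1, 2), 2)), 3)

  set.seed(41)
  for (i in 1:20) {
    m <- matrix(runif(16, 0, 5), 4)
    ev <- dominantEigenvalue(m)
    # independent oracle: power iteration
    v <- rep(1, 4)
    for (it in 1:500) v <- as.vector(m %*% v) / sqrt(sum((m %*% v)^2))
    lam <- as.numeric(t(v) %*% m %*% v / sum(v^2))
    expect_equal(ev, lam, tolerance = 1e-6)
    # Perron bounds: min and max row sum bracket the eigenvalue
    expect_gte(ev, min(rowSums(m)) - 1e-10)
    expect_lte(ev, max(rowSums(m)) + 1e-10)
  }

  expect_error(dominantEigenvalue(matrix(1:6, 2)), "square")
  expect_error(dominantEigenvalue(matrix(c(1, -1, 0, 1), 2)), "non-negative")
})

test_that("waves are ranked by decreasing growth factor", {
  ms <- list(R1 = matrix(c(2, 1, 1, 2), 2),  # eigenvalue 3
             R2 = matrix(c(4, 0, 0, 1), 2),  # eigenvalue 4
             R3 = matrix(c(1, 0, 0, 1), 2))  # eigenvalue 1
  gr <- ngmGrowthRank(ms)
  expect_equal(gr$wave, c("R2", "R1", "R3"))
  expect_equal(gr$rank, 1:3)
  expect_equal(gr$eigenvalue, c(4, 3, 1))
  # susceptibility profile scales rows before the eigenvalue
  gr2 <- ngmGrowthRank(ms, susceptibility = c(0.5, 0.5))
  expect_equal(gr2$eigenvalue[gr2$wave == "R2"], 2)
})

test_that("contact rate matrices collapse to the common age grouping", {
  cfg <- syntheticConfig(nHouseholds = 400, nWaves = 1, dropoutPerWave = 0,
                         initialParticipation = 1)
  panel <- generatePanel(config = cfg, seed = 23)
  crm <- contactRateMatrix(panel, "R1")
  expect_equal(dim(crm), c(4, 4))
  expect_equal(rownames(crm), colnames(crm))
  expect_true(all(crm >= 0))
  # per-capita rates: group totals divided by group sizes; spot-check 65+
  r <- deriveRates(panel)
  e <- events(panel)
  old <- r$participant_id[r$age_years >= 65]
  eo <- e[e$participant_id %in% old & e$contact_age_group == "65+", ]
  expect_equal(unname(crm["65+", "65+"]), sum(eo$group_size) / length(old))
})
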