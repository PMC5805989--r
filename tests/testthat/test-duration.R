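test_that("degenerate zero-width categories recover the uncensored MLE", {
  # exact durations 10, 30, 50 min (mean 30) -> rate 1/30
  cats <- durationCategories(lower = c(10, 30, 50), upper = c(10, 30, 50))
  fit <- fitCensoredExponential(c(1, 1, 1), cats)
  expect_equal(durationRate(fit), 1 / 30, tolerance = 1e-7)
})

test_that("the EM estimate equals the numeric MLE on random instances", {
  set.seed(101)
  cats <- durationCategories()
  for (i in 1:25) {
    counts <- rmultinom(1, 200 + rpois(1, 300),
                        prob = runif(5, 0.05, 1))[, 1]
    if (sum(counts[1:4]) == 0) next
    fit <- fitCensoredExponential(counts, cats)
    oracle <- numericMLE(counts, cats)
    expect_equal(durationRate(fit), oracle, tolerance = 1e-6)
    # log-likelihood trace is non-decreasing
    expect_true(all(diff(fit@logLikTrace) >=
                      -1e-8 * (1 + abs(fit@logLik))))
  }
})

test_that("the rate is recovered from a large simulated sample", {
  set.seed(102)
  cats <- durationCategories()
  tdur <- rexp(1e5, 0.02)
  counts <- table(cut(tdur, c(cats$lower, Inf), right = FALSE))
  fit <- fitCensoredExponential(as.integer(counts), cats)
  expect_equal(durationRate(fit), 0.02, tolerance = 0.02)
})

test_that("non-identifiable inputs are rejected", {
  cats1 <- durationCategories(lower = 0, upper = Inf)
  expect_error(fitCensoredExponential(100, cats1), "not identifiable")
  cats2 <- durationCategories(breaks = c(0, 60, Inf))
  expect_error(fitCensoredExponential(c(0, 50), cats2), "open tail")
  expect_error(fitCensoredExponential(c(0, 0), cats2), "no observations")
  expect_error(fitCensoredExponential(c(1, 2, 3), durationCategories()),
               "does not match")
})

test_that("imputation respects interval bounds and point categories exactly", {
  tt <- toyTables()
  # event 1 in category 3 ([15,60)), event 2 in category 2 ([5,15))
  panel <- diaryPanel(tt$participants, tt$diaries, tt$events)
  cats <- durationCategories()
  model <- fitCensoredExponential(c(5, 10, 20, 10, 2), cats)
  imp <- imputeDurations(panel, model, nReplicates = 50, seed = 4)
  expect_true(all(imp@draws[1, ] >= 15 & imp@draws[1, ] < 60))
  expect_true(all(imp@draws[2, ] >= 5 & imp@draws[2, ] < 15))

  # point interval [10,10] imputes exactly 10
  catsP <- durationCategories(lower = c(0, 10), upper = c(5, 10))
  ev <- tt$events
  ev$duration_category <- c(2L, 2L)
  panelP <- diaryPanel(tt$participants, tt$diaries, ev)
  modelP <- fitCensoredExponential(c(3, 2), catsP)
  impP <- imputeDurations(panelP, modelP, catsP, nReplicates = 10, seed = 1)
  expect_true(all(impP@draws == 10))
})

test_that("truncated draws match the closed-form truncated mean", {
  set.seed(103)
  r <- 0.02
  x <- diarycontacts:::.rtruncexp(1e5, r, rep(5, 1e5), rep(15, 1e5))
  m_closed <- diarycontacts:::.truncExpMean(r, 5, 15)
  expect_true(all(x >= 5 & x < 15))
  expect_equal(mean(x), m_closed, tolerance = 0.005)
})

test_that("group events contribute one duration and totals are exact for points", {
  tt <- toyTables()
  # one group of 9 and one individual event, both with exact durations
  ev <- tt$events
  ev$group_size <- c(9L, 1L)
  ev$duration_category <- c(1L, 2L)
  cats <- durationCategories(lower = c(30, 90), upper = c(30, 90))
  panel <- diaryPanel(tt$participants, tt$diaries, ev)
  model <- fitCensoredExponential(c(1, 1), cats)
  imp <- imputeDurations(panel, model, cats, nReplicates = 5, seed = 2)
  td <- totalDuration(imp)
  # 30 + 90 minutes = 2 hours, regardless of the group size of 9
  expect_equal(td$D, 2.0)
  expect_equal(td$D_low, 2.0)

  # no-event diary: D = 0 in every replicate
  panel0 <- diaryPanel(tt$participants, tt$diaries, ev[0, ])
  imp0 <- imputeDurations(panel0, model, cats, nReplicates = 5, seed = 2)
  expect_true(all(imp0@diaryTotals == 0))
  r0 <- addDurations(deriveRates(panel0), imp0)
  expect_equal(r0$D, 0)
})

test_that("unknown duration categories are drawn untruncated and flagged", {
  tt <- toyTables()
  ev <- tt$events
  ev$duration_category <- c(NA_integer_, 2L)
  panel <- diaryPanel(tt$participants, tt$diaries, ev)
  model <- fitCensoredExponential(c(5, 10, 20, 10, 2), durationCategories())
  imp <- imputeDurations(panel, model, nReplicates = 20, seed = 9)
  expect_true(imp@events$flagged[1])
  expect_false(imp@events$flagged[2])
  expect_true(all(imp@draws[1, ] >= 0))
})

test_that("replicate spread of totals shrinks as categories narrow", {
  tt <- toyTables()
  spreadFor <- function(breaks) {
    cats <- durationCategories(breaks)
    ev <- tt$events
    tdur <- c(42, 12)
    ev$duration_category <- findInterval(tdur, cats$lower)
    panel <- diaryPanel(tt$participants, tt$diaries, ev)
    model <- new("DurationModel", rate = 1 / 45, logLik = 0,
                 nIterations = 1L, converged = TRUE, categories = cats,
                 logLikTrace = 0)
    imp <- imputeDurations(panel, model, cats, nReplicates = 100, seed = 5)
    sd(imp@diaryTotals[1, ])
  }
  coarse <- spreadFor(c(0, 5, 15, 60, 240, Inf))
  fine <- spreadFor(c(seq(0, 240, by = 2), Inf))
  expect_lt(fine, coarse / 5)
})
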