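test_that("meanOfParticipantMeans weights participants, not diaries", {
  r <- rateTable(participant_id = c("A", "A", "B"),
                 wave = c("R1", "R2", "R1"), K = c(2L, 4L, 6L))
  expect_equal(meanOfParticipantMeans(r, "K"), 4.5) # (3 + 6) / 2

  # one diary each: reduces to the plain mean
  r1 <- rateTable(participant_id = c("A", "B", "C"), wave = "R1",
                  K = c(1L, 5L, 9L))
  expect_equal(meanOfParticipantMeans(r1, "K"), 5)

  # duplicating a participant's full diary set (same values again) does not
  # move the estimate: participants are weighted, not diaries
  rdup <- rbind(r, r[r$participant_id == "A", ])
  expect_equal(meanOfParticipantMeans(rdup, "K"), 4.5)

  expect_error(meanOfParticipantMeans(r[0, ], "K"), "no non-missing")
})

test_that("wave homogeneity chi-square matches hand calculation and edge cases", {
  # identical binned counts -> statistic 0, p = 1
  r <- rateTable(participant_id = sprintf("p%02d", 1:40),
                 wave = rep(c("R1", "R2"), each = 20),
                 K = rep(c(rep(0L, 10), rep(5L, 10)), 2))
  ht0 <- waveHomogeneityTest(r, "K", breaks = c(0, 1, Inf), minExpected = 1)
  expect_equal(ht0$statistic, 0)
  expect_equal(ht0$p.value, 1)

  # printed 2x2 table {10,20; 20,10}: Pearson statistic 20/3, no correction
  r2 <- rateTable(participant_id = sprintf("p%02d", 1:60),
                  wave = rep(c("R1", "R2"), c(30, 30)),
                  K = c(rep(0L, 10), rep(5L, 20), rep(0L, 20), rep(5L, 10)))
  ht <- waveHomogeneityTest(r2, "K", breaks = c(0, 1, Inf), minExpected = 1)
  expect_equal(ht$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(ht$df, 1)

  expect_error(waveHomogeneityTest(r[r$wave == "R1", ], "K"), "two waves")
})

test_that("a wave effect on duration only is detected for D and not K", {
  set.seed(77)
  n <- 300
  pid <- sprintf("p%03d", seq_len(n))
  K <- rpois(2 * n, 10)
  D1 <- rlnorm(n, log(8), 0.4)
  D2 <- rlnorm(n, log(13), 0.4) # strong duration shift in wave 2
  r <- rateTable(participant_id = rep(pid, 2),
                 wave = rep(c("R1", "R2"), each = n), K = K,
                 D = c(D1, D2))
  htK <- waveHomogeneityTest(r, "K")
  htD <- waveHomogeneityTest(r, "D", breaks = c(0, 2^(0:6), Inf))
  expect_lt(htD$p.value, 0.001)
  expect_gt(htK$p.value, 0.001)
})

test_that("between-wave correlation handles perfect, perfect-negative and null cases", {
  r <- rateTable(participant_id = rep(sprintf("p%d", 1:4), each = 2),
                 wave = rep(c("R1", "R2"), 4),
                 K = as.integer(c(1, 1, 5, 5, 2, 2, 4, 4)))
  expect_equal(betweenWaveCorrelation(r, "K")$estimate, 1)

  ranti <- rateTable(participant_id = rep(sprintf("p%d", 1:4), each = 2),
                     wave = rep(c("R1", "R2"), 4),
                     K = as.integer(c(1, 5, 5, 1, 2, 4, 4, 2)))
  expect_equal(betweenWaveCorrelation(ranti, "K")$estimate, -1)

  set.seed(5)
  n <- 500
  rnull <- rateTable(participant_id = rep(sprintf("p%03d", 1:n), each = 2),
                     wave = rep(c("R1", "R2"), n),
                     K = rpois(2 * n, 10))
  bw <- betweenWaveCorrelation(rnull, "K")
  expect_lt(abs(bw$estimate), 2 / sqrt(n))
  expect_equal(bw$n, n)

  expect_error(betweenWaveCorrelation(r[1:2, ], "K"), "fewer than 3")
})

test_that("participant CV: exact values, scale invariance, shared volatility", {
  r <- rateTable(participant_id = rep(c("A", "B"), c(3, 2)),
                 wave = c("R1", "R2", "R3", "R1", "R2"),
                 K = as.integer(c(3, 3, 3, 2, 4)))
  cv <- participantCV(r, "K")$cv
  expect_equal(cv$cv_K[cv$participant_id == "A"], 0)
  expect_equal(cv$cv_K[cv$participant_id == "B"], sqrt(2) / 3,
               tolerance = 1e-12)

  # scale invariance: multiplying one participant's series by c > 0
  r2 <- r
  r2$K[r2$participant_id == "B"] <- r2$K[r2$participant_id == "B"] * 7L
  cv2 <- participantCV(r2, "K")$cv
  expect_equal(cv2$cv_K, cv$cv_K, tolerance = 1e-12)

  # shared per-participant volatility factor induces positive CV correlation
  set.seed(11)
  n <- 200
  vol <- runif(n, 0.05, 0.6)
  mk <- function(v) pmax(0, rnorm(4, 20, 20 * v))
  Ks <- t(vapply(vol, mk, numeric(4)))
  Ds <- t(vapply(vol, mk, numeric(4)))
  rr <- rateTable(participant_id = rep(sprintf("p%03d", 1:n), each = 4),
                  wave = rep(sprintf("R%d", 1:4), n),
                  K = as.integer(round(as.vector(t(Ks)))),
                  D = as.vector(t(Ds)))
  cors <- participantCV(rr, c("K", "D"))$correlations
  expect_gt(cors["K", "D"], 0)
})

test_that("typical-day filtering reports the right proportion", {
  r <- rateTable(participant_id = sprintf("p%d", 1:4), wave = "R1",
                 K = 1L, typical_day = c("typical", "typical", "typical",
                                         "non_typical"))
  tf <- typicalDayFilter(r)
  expect_equal(tf$proportion, 0.75)
  expect_equal(nrow(tf$rates), 3)

  r$typical_day <- "typical"
  expect_equal(typicalDayFilter(r)$proportion, 1.0)
})
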