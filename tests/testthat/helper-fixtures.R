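# Fixture builders shared across test files. Everything is constructed in
# code; no fixture files on disk.

# One participant, one diary, two events (group of 5 at location A, single
# contact at location B).
toyTables <- function() {
  list(
    participants = data.frame(
      participant_id = "p1", household_id = "h1", age_years = 34,
      sex = "female", household_size = 2, stringsAsFactors = FALSE),
    diaries = data.frame(
      participant_id = "p1", wave = "R1", reporting_day = "2012-05-07",
      typical_day = "typical", stringsAsFactors = FALSE),
    events = data.frame(
      participant_id = "p1", wave = "R1", event_id = c("e1", "e2"),
      group_size = c(5L, 1L), contact_age_group = c("20-39", "40-64"),
      setting = c("work", "other"), duration_category = c(3L, 2L),
      touch = c(FALSE, TRUE), location_label = c("A", "B"),
      frequency = c(1L, 2L), stringsAsFactors = FALSE)
  )
}

toyPanel <- function() {
  tt <- toyTables()
  diaryPanel(tt$participants, tt$diaries, tt$events)
}

# A hand-assembled panel with nP participants in one wave, each reporting the
# given per-contact-age-group counts (a matrix nP x length(groups)), all as
# individual events. Ages place participant i in participantGroups[i].
countsPanel <- function(counts, ages, census,
                        wave = "R1") {
  nP <- nrow(counts)
  pid <- sprintf("p%03d", seq_len(nP))
  participants <- data.frame(
    participant_id = pid, household_id = pid, age_years = ages,
    sex = "male", household_size = 1, stringsAsFactors = FALSE)
  diaries <- data.frame(
    participant_id = pid, wave = wave, reporting_day = "2012-05-07",
    typical_day = "typical", stringsAsFactors = FALSE)
  ev <- list()
  for (i in seq_len(nP)) for (j in seq_len(ncol(counts))) {
    k <- counts[i, j]
    if (k > 0)
      ev[[length(ev) + 1L]] <- data.frame(
        participant_id = pid[i], wave = wave,
        event_id = sprintf("%s_g%d", pid[i], j),
        group_size = as.integer(k),
        contact_age_group = census$age_group[j], setting = "other",
        duration_category = 2L, touch = FALSE,
        location_label = "loc1", frequency = 1L, stringsAsFactors = FALSE)
  }
  events <- if (length(ev)) do.call(rbind, ev) else toyTables()$events[0, ]
  diaryPanel(participants, diaries, events)
}

# Rate table built directly (bypassing panels) for summary/longitudinal
# operations that only consume rates.
rateTable <- function(participant_id, wave, K,
                      D = NA_real_, L = 1L,
                      weekday = "Mon", typical_day = "typical",
                      age_years = 50, sex = "male", household_size = 1) {
  data.frame(participant_id = participant_id, wave = wave, K = K, L = L,
             K_home = 0L, K_schoolwork = 0L, K_other = K, D = D,
             weekday = weekday, typical_day = typical_day,
             age_years = age_years, sex = sex,
             household_size = household_size, stringsAsFactors = FALSE)
}

# Balanced longitudinal rates: n participants x W waves with response y
# supplied on the log1p scale is not needed; K values given directly.
balancedRates <- function(Kmat, ...) {
  n <- nrow(Kmat); W <- ncol(Kmat)
  rateTable(
    participant_id = rep(sprintf("p%04d", seq_len(n)), each = W),
    wave = rep(sprintf("R%d", seq_len(W)), n),
    K = as.vector(t(Kmat)), ...)
}

# Balanced rates carrying a continuous Gaussian response through D, so that
# log1p(D) reproduces the supplied y matrix exactly.
gaussianRates <- function(ymat) {
  n <- nrow(ymat); W <- ncol(ymat)
  rateTable(participant_id = rep(sprintf("p%04d", seq_len(n)), each = W),
            wave = rep(sprintf("R%d", seq_len(W)), n),
            K = 1L, D = as.vector(t(expm1(ymat))))
}

# Independent oracle for the censored-exponential MLE: direct numerical
# maximisation of the censored log-likelihood.
numericMLE <- function(counts, cats) {
  ll <- function(r) diarycontacts:::.censExpLogLik(r, counts, cats$lower,
                                                   cats$upper)
  optimize(ll, interval = c(1e-6, 2), maximum = TRUE, tol = 1e-12)$maximum
}

# Closed-form one-way ANOVA (method of moments) variance components for a
# balanced design: the independent oracle for REML in the balanced case.
anovaComponents <- function(ymat) {
  n <- nrow(ymat); m <- ncol(ymat)
  gm <- rowMeans(ymat)
  msw <- sum((ymat - gm)^2) / (n * (m - 1))
  msb <- m * sum((gm - mean(ymat))^2) / (n - 1)
  c(s2b = max(0, (msb - msw) / m), s2w = msw)
}
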