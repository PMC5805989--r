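#' Mean of participants' means
#'
#' Overall average of a per-diary rate that accounts for repeated
#' observations per participant: each participant's diaries are first
#' averaged, then the participant means are averaged with equal weight. A
#' participant with four diaries therefore counts no more than one with a
#' single diary.
#'
#' @param rates a rate table from [deriveRates()].
#' @param variable column to average ("K", "D" or "L").
#' @return a single number.
#' @export
meanOfParticipantMeans <- function(rates, variable = "K") {
  if (!variable %in% names(rates)) .stopf("no column '%s' in rates", variable)
  x <- rates[[variable]]
  keep <- !is.na(x)
  if (!any(keep)) .stopf("no non-missing observations of %s", variable)
  pm <- tapply(x[keep], rates$participant_id[keep], mean)
  mean(pm)
}

#' Chi-square test of distributional homogeneity across waves
#'
#' Pearson chi-square test (no continuity correction) on the wave-by-bin
#' contingency table of per-diary values of a rate. Default binning is
#' integer bins for counts pooled upward so every expected cell count is at
#' least minExpected; explicit breaks may be supplied (for durations,
#' log-spaced breaks are conventional). The binning actually used is
#' returned alongside the statistic, since the p-value is only interpretable
#' together with it.
#'
#' @param rates rate table.
#' @param variable column to test.
#' @param breaks optional numeric cut points (passed to [cut()], right-open);
#'   default bins each integer value then pools sparse tail bins.
#' @param minExpected minimum expected count per cell; sparser adjacent tail
#'   bins are pooled until satisfied.
#' @return list with statistic, df, p.value, binning (the break vector used)
#'   and the contingency table.
#' @export
waveHomogeneityTest <- function(rates, variable = "K", breaks = NULL,
                                minExpected = 5) {
  x <- rates[[variable]]
  w <- as.character(rates$wave)
  keep <- !is.na(x)
  x <- x[keep]; w <- w[keep]
  waves <- sort(unique(w))
  if (length(waves) < 2) .stopf("need at least two waves")
  for (wv in waves) if (!sum(w == wv)) .stopf("wave %s has no diaries", wv)

  if (is.null(breaks)) breaks <- c(sort(unique(floor(x))), Inf)
  bin <- cut(x, breaks = breaks, right = FALSE, include.lowest = TRUE)
  tab <- table(w, bin)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]

  ## pool tail bins (rightmost first) until all expected counts clear the bar
  expectedOK <- function(tb) {
    e <- outer(rowSums(tb), colSums(tb)) / sum(tb)
    all(e >= minExpected)
  }
  while (ncol(tab) > 2 && !expectedOK(tab)) {
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    j <- max(which(apply(e < minExpected, 2, any)))
    jj <- if (j == ncol(tab)) j - 1L else j + 1L
    merged <- tab[, min(j, jj)] + tab[, max(j, jj)]
    keep_cols <- setdiff(seq_len(ncol(tab)), max(j, jj))
    lab <- paste(colnames(tab)[min(j, jj)], colnames(tab)[max(j, jj)],
                 sep = "+")
    tab <- tab[, keep_cols, drop = FALSE]
    tab[, min(j, jj)] <- merged
    colnames(tab)[min(j, jj)] <- lab
  }

  if (ncol(tab) < 2)
    return(list(statistic = 0, df = 0L, p.value = 1, binning = breaks,
                table = tab))
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = unname(ht$p.value), binning = breaks, table = tab)
}

#' Correlation of a rate between two waves
#'
#' Pearson correlation (default) of per-diary values over the participants
#' observed in both waves, with a Fisher-z 95\% confidence interval.
#'
#' @param rates rate table.
#' @param variable column to correlate.
#' @param wavePair character vector of two wave labels.
#' @param method "pearson" (Fisher-z CI) or "spearman" (no CI).
#' @return list with estimate, conf.int (Pearson only), n, and waves.
#' @export
betweenWaveCorrelation <- function(rates, variable = "K",
                                   wavePair = c("R1", "R2"),
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(wavePair) == 2)
  a <- rates[rates$wave == wavePair[1], c("participant_id", variable)]
  b <- rates[rates$wave == wavePair[2], c("participant_id", variable)]
  m <- merge(a, b, by = "participant_id")
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3)
    .stopf("fewer than 3 participants observed in both %s and %s",
           wavePair[1], wavePair[2])
  x <- m[[2]]; y <- m[[3]]
  if (method == "pearson") {
    ct <- suppressWarnings(stats::cor.test(x, y, method = "pearson"))
    list(estimate = unname(ct$estimate),
         conf.int = as.numeric(ct$conf.int), n = nrow(m), waves = wavePair)
  } else {
    list(estimate = suppressWarnings(stats::cor(x, y, method = "spearman")),
         conf.int = NULL, n = nrow(m), waves = wavePair)
  }
}

#' Per-participant coefficients of variation and their cross-rate correlation
#'
#' For each participant with at least two diaries, the coefficient of
#' variation (sample sd / mean) of each requested rate across their diaries;
#' participants whose mean is zero have an undefined CV and are excluded for
#' that rate. Also returns the pairwise Pearson correlations between the CVs
#' of different rates over participants with both defined.
#'
#' @param rates rate table.
#' @param variables columns to summarise.
#' @return list with cv (data.frame participant_id + one CV column per rate)
#'   and correlations (matrix).
#' @export
participantCV <- function(rates, variables = c("K", "D", "L")) {
  variables <- intersect(variables, names(rates))
  ids <- sort(unique(rates$participant_id))
  out <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  for (v in variables) {
    x <- rates[[v]]
    cvs <- tapply(seq_along(x), rates$participant_id, function(i) {
      xi <- x[i][!is.na(x[i])]
      if (length(xi) < 2) return(NA_real_)
      .cv(xi)
    })
    out[[paste0("cv_", v)]] <- as.numeric(cvs[ids])
  }
  cols <- paste0("cv_", variables)
  cm <- matrix(NA_real_, length(variables), length(variables),
               dimnames = list(variables, variables))
  for (i in seq_along(variables)) for (j in seq_along(variables)) {
    ok <- stats::complete.cases(out[, cols[c(i, j)]])
    if (sum(ok) >= 3)
      cm[i, j] <- stats::cor(out[ok, cols[i]], out[ok, cols[j]])
  }
  list(cv = out, correlations = cm)
}

#' Restrict a rate table to typical reporting days
#'
#' Filters to diaries flagged as typical days and reports the proportion of
#' classified diaries (typical or non-typical; unknowns are not counted in
#' the denominator) that were typical.
#'
#' @param rates rate table.
#' @return list with rates (the filtered table) and proportion.
#' @export
typicalDayFilter <- function(rates) {
  classified <- rates$typical_day %in% c("typical", "non_typical")
  n_typ <- sum(rates$typical_day == "typical", na.rm = TRUE)
  prop <- if (any(classified)) n_typ / sum(classified) else NA_real_
  list(rates = rates[rates$typical_day %in% "typical", , drop = FALSE],
       proportion = prop)
}

#' Per-wave distribution summaries
#'
#' Histogram-style summaries per wave for a rate: sample size, mean,
#' quartiles, and binned frequencies (integer bins for counts and locations,
#' log-spaced bins for durations).
#'
#' @param rates rate table.
#' @param variable column to summarise.
#' @param breaks optional break vector.
#' @return data.frame with one row per wave x bin plus per-wave mean and n as
#'   attributes "means" and "n".
#' @export
waveSummaries <- function(rates, variable = "K", breaks = NULL) {
  x <- rates[[variable]]
  keep <- !is.na(x)
  x <- x[keep]
  w <- as.character(rates$wave)[keep]
  if (is.null(breaks)) {
    breaks <- if (variable == "D")
      c(0, 2^seq(-2, ceiling(log2(max(x) + 1)))) else
      c(0:max(1, max(x)), Inf)
  }
  bin <- cut(x, breaks = breaks, right = FALSE, include.lowest = TRUE)
  tab <- as.data.frame(table(wave = w, bin = bin), stringsAsFactors = FALSE)
  attr(tab, "means") <- tapply(x, w, mean)
  attr(tab, "n") <- tapply(x, w, length)
  tab
}
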