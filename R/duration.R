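#' Duration category boundaries
#'
#' Defines the ordered duration categories (in minutes) under which contact
#' durations are recorded. The default follows the common contact-survey
#' convention: under 5 minutes, 5-14, 15-59, 60-239, and 240 minutes or more
#' (the last category right-open). Category indices in event tables refer to
#' rows of this table.
#'
#' @param breaks strictly increasing numeric vector of boundaries in minutes,
#'   starting at 0 and ending at Inf. Ignored when lower/upper are given.
#' @param lower,upper explicit per-category interval bounds; allow zero-width
#'   (point) categories representing exactly observed durations.
#' @return data.frame with columns category (1..k), lower, upper, label.
#' @export
durationCategories <- function(breaks = c(0, 5, 15, 60, 240, Inf),
                               lower = NULL, upper = NULL) {
  if (is.null(lower) != is.null(upper))
    .stopf("lower and upper must be given together")
  if (is.null(lower)) {
    if (breaks[1] != 0) .stopf("first duration boundary must be 0")
    if (length(breaks) < 2 || any(diff(breaks) <= 0))
      .stopf("duration boundaries must be strictly increasing")
    lower <- breaks[-length(breaks)]
    upper <- breaks[-1]
  } else {
    if (length(lower) != length(upper) || any(upper < lower) ||
        any(lower < 0))
      .stopf("invalid category bounds")
  }
  k <- length(lower)
  data.frame(
    category = seq_len(k),
    lower = lower,
    upper = upper,
    label = ifelse(upper == lower, sprintf("=%g", lower),
            ifelse(is.finite(upper), sprintf("[%g,%g)", lower, upper),
                   sprintf("%g+", lower))),
    stringsAsFactors = FALSE
  )
}

## Censored-exponential log-likelihood for category counts.
## Finite-width cells contribute n * log(exp(-r*a) - exp(-r*b)); the open
## tail n * (-r*a); zero-width cells are exact observations with density
## contribution n * (log r - r*a).
.censExpLogLik <- function(rate, counts, lower, upper) {
  width <- upper - lower
  ll <- 0
  for (c in seq_along(counts)) {
    if (counts[c] == 0) next
    if (width[c] == 0) {
      ll <- ll + counts[c] * (log(rate) - rate * lower[c])
    } else if (is.infinite(upper[c])) {
      ll <- ll - counts[c] * rate * lower[c]
    } else {
      ll <- ll + counts[c] * log(exp(-rate * lower[c]) - exp(-rate * upper[c]))
    }
  }
  ll
}

## E[T | a <= T < b] under Exponential(rate); closed form, stable for small
## rate * width via expm1.
.truncExpMean <- function(rate, lower, upper) {
  width <- upper - lower
  m <- numeric(length(lower))
  for (c in seq_along(lower)) {
    if (width[c] == 0) {
      m[c] <- lower[c]
    } else if (is.infinite(upper[c])) {
      m[c] <- lower[c] + 1 / rate
    } else {
      d <- width[c]
      ## a + 1/r - d * exp(-r d) / (1 - exp(-r d))
      m[c] <- lower[c] + 1 / rate - d * exp(-rate * d) / (-expm1(-rate * d))
    }
  }
  m
}

#' Fit an exponential duration model to categorized durations by EM
#'
#' Maximum-likelihood fit of an exponential distribution to interval-censored
#' duration data: each observation is known only to lie in a duration
#' category [a, b). The E-step replaces each censored duration by its
#' conditional expectation under the current rate; the M-step sets the rate
#' to N divided by the summed expected durations. The iteration converges to
#' the interval-censored MLE and the censored log-likelihood is
#' non-decreasing across iterations (asserted).
#'
#' @param counts integer vector of observations per category (same order as
#'   the category table).
#' @param categories category table from [durationCategories()].
#' @param tol relative change in rate below which iteration stops.
#' @param maxIter iteration cap.
#' @param rateInit optional starting rate; default is based on category
#'   midpoints.
#' @return a [DurationModel-class].
#' @export
fitCensoredExponential <- function(counts, categories = durationCategories(),
                                   tol = 1e-8, maxIter = 10000L,
                                   rateInit = NULL) {
  counts <- as.numeric(counts)
  if (length(counts) != nrow(categories))
    .stopf("counts length (%d) does not match the category table (%d)",
           length(counts), nrow(categories))
  if (any(counts < 0)) .stopf("negative category counts")
  N <- sum(counts)
  if (N <= 0) .stopf("no observations")
  lower <- categories$lower
  upper <- categories$upper
  finite_mass <- sum(counts[is.finite(upper) | lower > 0])
  if (finite_mass == 0)
    .stopf("all observations lie in an unbounded category starting at 0; the rate is not identifiable")
  if (all(counts[is.finite(upper)] == 0))
    .stopf("all observations lie in the open tail; the MLE rate degenerates to 0")

  if (is.null(rateInit)) {
    mid <- ifelse(is.finite(upper), (lower + upper) / 2, lower * 1.5 + 30)
    rateInit <- N / sum(counts * pmax(mid, 1e-8))
  }
  rate <- rateInit
  trace <- .censExpLogLik(rate, counts, lower, upper)
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    m <- .truncExpMean(rate, lower, upper)
    new_rate <- N / sum(counts * m)
    ll <- .censExpLogLik(new_rate, counts, lower, upper)
    if (ll < trace[length(trace)] - 1e-8 * (1 + abs(ll)))
      .stopf("internal error: censored log-likelihood decreased at iteration %d", it)
    trace <- c(trace, ll)
    done <- abs(new_rate - rate) / rate < tol
    rate <- new_rate
    if (done) { converged <- TRUE; break }
  }
  new("DurationModel", rate = rate, logLik = trace[length(trace)],
      nIterations = it, converged = converged, categories = categories,
      logLikTrace = trace)
}

#' Category counts of recorded durations in a panel
#'
#' Tabulates events' duration categories over the category table; one count
#' per event regardless of group size (a group interaction contributes a
#' single duration, like an individual contact event).
#'
#' @param panel a [DiaryPanel-class].
#' @param categories category table from [durationCategories()].
#' @return integer vector of counts, one per category (unknown categories are
#'   dropped).
#' @export
durationCategoryCounts <- function(panel, categories = durationCategories()) {
  dc <- events(panel)$duration_category
  as.integer(table(factor(dc, levels = categories$category)))
}

## Inverse-CDF draw from Exponential(rate) truncated to [a, b).
.rtruncexp <- function(n, rate, lower, upper) {
  u <- stats::runif(n)
  p_ab <- -expm1(-rate * (upper - lower)) # P(T < b | T >= a), Inf-safe
  p_ab[is.infinite(upper)] <- 1
  lower - log1p(-u * p_ab) / rate
}

#' Impute event durations from a fitted duration model
#'
#' Assigns each contact event a duration in minutes drawn from the fitted
#' exponential model truncated to the event's duration-category interval,
#' using inverse-CDF sampling so every draw respects its interval bounds
#' exactly. The whole assignment is repeated for a number of replicates to
#' carry imputation uncertainty forward; per-diary totals (in hours) are
#' accumulated for every replicate. Group events contribute one duration
#' regardless of group size. Events with an unknown duration category are
#' drawn from the untruncated exponential and flagged.
#'
#' @param panel a [DiaryPanel-class].
#' @param model a [DurationModel-class] from [fitCensoredExponential()].
#' @param categories category table (defaults to the model's).
#' @param nReplicates number of imputation replicates.
#' @param seed integer seed; replicate r uses a seed derived from (seed, r)
#'   so any replicate can be reproduced independently.
#' @return an [ImputationSet-class].
#' @export
imputeDurations <- function(panel, model, categories = NULL,
                            nReplicates = 200L, seed = 1L) {
  stopifnot(is(panel, "DiaryPanel"), is(model, "DurationModel"))
  if (is.null(categories)) categories <- model@categories
  if (nReplicates < 1) .stopf("nReplicates must be >= 1")
  e <- events(panel)
  d <- diaries(panel)
  rate <- model@rate

  cat_idx <- match(e$duration_category, categories$category)
  flagged <- is.na(cat_idx)
  lo <- ifelse(flagged, 0, categories$lower[cat_idx])
  hi <- ifelse(flagged, Inf, categories$upper[cat_idx])

  ne <- nrow(e)
  draws <- matrix(0, nrow = ne, ncol = nReplicates)
  diary_key <- paste(d$participant_id, d$wave)
  ekey <- factor(paste(e$participant_id, e$wave), levels = diary_key)
  totals <- matrix(0, nrow = length(diary_key), ncol = nReplicates)

  for (r in seq_len(nReplicates)) {
    set.seed(.childSeed(seed, 100L + r))
    x <- if (ne) .rtruncexp(ne, rate, lo, hi) else numeric(0)
    ## zero-width (point) categories are deterministic
    pt <- lo == hi
    x[pt] <- lo[pt]
    draws[, r] <- x
    if (ne) {
      agg <- rowsum(x, ekey)
      totals[match(rownames(agg), diary_key), r] <- agg[, 1] / 60
    }
  }

  new("ImputationSet",
      events = data.frame(participant_id = e$participant_id, wave = e$wave,
                          event_id = e$event_id,
                          duration_category = e$duration_category,
                          flagged = flagged, stringsAsFactors = FALSE),
      draws = draws, diaryTotals = totals,
      diaryKey = data.frame(participant_id = d$participant_id,
                            wave = as.character(d$wave),
                            stringsAsFactors = FALSE),
      seed = as.integer(seed), rate = rate)
}

#' Per-diary total contact duration with replicate uncertainty
#'
#' Sums imputed event durations within each diary and summarises across
#' replicates: the mean total duration D (hours) plus the 2.5 and 97.5
#' percentile of the replicate distribution.
#'
#' @param imputations an [ImputationSet-class].
#' @return data.frame with columns participant_id, wave, D, D_low, D_high.
#' @export
totalDuration <- function(imputations) {
  stopifnot(is(imputations, "ImputationSet"))
  tot <- imputations@diaryTotals
  data.frame(
    imputations@diaryKey,
    D = rowMeans(tot),
    D_low = apply(tot, 1, stats::quantile, probs = 0.025, names = FALSE),
    D_high = apply(tot, 1, stats::quantile, probs = 0.975, names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Fill the D column of a rate table from imputed durations
#'
#' @param rates a rate table from [deriveRates()].
#' @param imputations an [ImputationSet-class] (or output of
#'   [totalDuration()]).
#' @return the rate table with D set to the across-replicate mean total
#'   duration in hours (0 for diaries with no events).
#' @export
addDurations <- function(rates, imputations) {
  td <- if (is(imputations, "ImputationSet")) totalDuration(imputations)
        else imputations
  idx <- match(paste(rates$participant_id, rates$wave),
               paste(td$participant_id, td$wave))
  rates$D <- td$D[idx]
  rates$D[is.na(rates$D) & rates$K == 0] <- 0
  rates
}
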