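## Internal helpers shared across modules.

## Locale-proof weekday label for a Date.
.weekdayOf <- function(x) {
  .WEEKDAYS[as.integer(format(as.Date(x), "%w")) + 1L]
}

## Participant age -> participant mixing age group ("5-19", ...). Ages below
## the first break (the 2-4 year olds) return NA and drop out of age-grouped
## analyses, matching the exclusion of that thinly sampled group.
.participantAgeGroup <- function(age,
                                 breaks = .PARTICIPANT_AGE_BREAKS,
                                 labels = .PARTICIPANT_AGE_GROUPS) {
  cut(age, breaks = c(breaks[1], breaks[-1]), labels = labels,
      right = FALSE, include.lowest = FALSE)
}

## Participant age -> the contact age group the participant themself belongs
## to (used by the synthetic generator's assortativity and NGM collapsing).
.ownContactGroup <- function(age) {
  cut(age, breaks = c(0, 6, 20, 40, 65, Inf), labels = .CONTACT_AGE_GROUPS,
      right = FALSE)
}

## Stop with a consistent message style.
.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assertColumns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    .stopf("%s is missing mandatory column(s): %s", what,
           paste(missing, collapse = ", "))
  invisible(TRUE)
}

## Equal-count quantile membership with deterministic tie-break: ranks use
## ties.method = "first" in data order, so integer-valued rates (heavily
## tied) still give bins as equal as n allows.
.ntile <- function(x, q) {
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(q * r / length(x)))
}

## Coefficient of variation with the sample (n-1) standard deviation.
.cv <- function(x) {
  m <- mean(x)
  if (length(x) < 2L || m <= 0) return(NA_real_)
  stats::sd(x) / m
}

## Row-wise categorical draw: wmat has one row per draw, one column per
## category (non-negative weights, not necessarily normalised). Returns the
## sampled column index per row.
.sampleCategorical <- function(wmat) {
  cs <- wmat
  for (j in seq_len(ncol(wmat))[-1]) cs[, j] <- cs[, j] + cs[, j - 1L]
  u <- stats::runif(nrow(wmat)) * cs[, ncol(wmat)]
  as.integer(rowSums(cs < u) + 1L)
}

## Derive a stream-specific 32-bit seed from a base seed.
.childSeed <- function(seed, stream) {
  (as.integer(seed) + 1013L * as.integer(stream)) %% .Machine$integer.max
}
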