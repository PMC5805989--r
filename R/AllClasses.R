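#' @import methods
NULL

## Column contracts for the three long-format tables held by a DiaryPanel.
.PARTICIPANT_COLS <- c("participant_id", "household_id", "age_years", "sex",
                       "household_size")
.DIARY_COLS <- c("participant_id", "wave", "reporting_day", "weekday",
                 "typical_day")
.EVENT_COLS <- c("participant_id", "wave", "event_id", "group_size",
                 "contact_age_group", "setting", "duration_category", "touch",
                 "location_label", "frequency")

.SEX_LEVELS <- c("male", "female", "unrecorded")
.TYPICAL_LEVELS <- c("typical", "non_typical", "unknown")
.SETTING_LEVELS <- c("home", "school", "work", "other")
.WEEKDAYS <- c("Sun", "Mon", "Tue", "Wed", "Thu", "Fri", "Sat")
.CONTACT_AGE_GROUPS <- c("0-5", "6-19", "20-39", "40-64", "65+")
.PARTICIPANT_AGE_BREAKS <- c(5, 20, 40, 65, Inf)
.PARTICIPANT_AGE_GROUPS <- c("5-19", "20-39", "40-64", "65+")

#' DiaryPanel: a validated longitudinal contact-diary panel
#'
#' Holds the three long-format tables of a multi-wave contact-diary survey:
#' one row per participant, one row per diary (participant x wave), and one
#' row per contact event. A contact event is an encounter with a distinct
#' individual or group of individuals in one geographical location during the
#' reporting day; group events carry the number of individuals they represent
#' in \code{group_size}.
#'
#' @slot participants data.frame with columns \code{participant_id},
#'   \code{household_id}, \code{age_years}, \code{sex}, \code{household_size}.
#' @slot diaries data.frame with columns \code{participant_id}, \code{wave},
#'   \code{reporting_day} (Date), \code{weekday}, \code{typical_day}.
#' @slot events data.frame with columns \code{participant_id}, \code{wave},
#'   \code{event_id}, \code{group_size}, \code{contact_age_group},
#'   \code{setting}, \code{duration_category}, \code{touch},
#'   \code{location_label}, \code{frequency}.
#' @slot rejected data.frame of input rows that failed validation, with a
#'   \code{reason} column.
#' @slot excluded character vector of participant ids flagged for exclusion
#'   because of incomplete demographic information (missing age or sex).
#'
#' @seealso [readDiaryPanel()], [generatePanel()], [deriveRates()]
#' @export
setClass("DiaryPanel",
  representation(
    participants = "data.frame",
    diaries = "data.frame",
    events = "data.frame",
    rejected = "data.frame",
    excluded = "character"
  ),
  prototype(
    participants = data.frame(),
    diaries = data.frame(),
    events = data.frame(),
    rejected = data.frame(),
    excluded = character(0)
  )
)

setValidity("DiaryPanel", function(object) {
  msgs <- character(0)
  p <- object@participants
  d <- object@diaries
  e <- object@events
  if (!all(.PARTICIPANT_COLS %in% names(p)))
    msgs <- c(msgs, paste("participants missing columns:",
      paste(setdiff(.PARTICIPANT_COLS, names(p)), collapse = ", ")))
  if (!all(.DIARY_COLS %in% names(d)))
    msgs <- c(msgs, paste("diaries missing columns:",
      paste(setdiff(.DIARY_COLS, names(d)), collapse = ", ")))
  if (!all(.EVENT_COLS %in% names(e)))
    msgs <- c(msgs, paste("events missing columns:",
      paste(setdiff(.EVENT_COLS, names(e)), collapse = ", ")))
  if (length(msgs))
    return(msgs)
  if (anyDuplicated(p$participant_id))
    msgs <- c(msgs, "duplicate participant_id in participants")
  if (nrow(d) && anyDuplicated(d[, c("participant_id", "wave")]))
    msgs <- c(msgs, "more than one diary per (participant, wave)")
  if (nrow(d) && !all(d$participant_id %in% p$participant_id))
    msgs <- c(msgs, "diaries reference unknown participants")
  if (nrow(e)) {
    key_d <- paste(d$participant_id, d$wave)
    key_e <- paste(e$participant_id, e$wave)
    if (!all(key_e %in% key_d))
      msgs <- c(msgs, "events reference (participant, wave) pairs without a diary")
    if (any(e$group_size < 1, na.rm = TRUE))
      msgs <- c(msgs, "event group_size below 1")
  }
  ## weekday label must agree with the reporting date when both are present
  if (nrow(d)) {
    has_both <- !is.na(d$reporting_day) & !is.na(d$weekday)
    if (any(has_both)) {
      expected <- .weekdayOf(d$reporting_day[has_both])
      if (!all(expected == d$weekday[has_both]))
        msgs <- c(msgs, "weekday inconsistent with reporting_day")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' MixingMatrix: age-mixing ratios relative to proportionate mixing
#'
#' A participant-age-group by contact-age-group matrix of mixing ratios. Cell
#' (a, b) is the observed share of group-a participants' contacts that fall in
#' contact age group b, divided by the census population proportion of group
#' b. Ratio 1 means mixing proportionate to the population age structure;
#' values above 1 indicate more contact between the two groups than expected
#' at random. Optional 95\% bootstrap confidence bounds accompany the point
#' estimates.
#'
#' @slot ratio numeric matrix of ratio point estimates (rows: participant age
#'   groups; columns: contact age groups). \code{NA} marks a participant group
#'   with no observed contacts.
#' @slot ciLow,ciHigh numeric matrices of percentile bootstrap bounds (same
#'   shape as \code{ratio}; zero-row matrices when no bootstrap was run).
#' @slot wave character, the survey wave summarised.
#' @slot filter character, \code{"all"} or \code{"touch"} (touch contacts only).
#' @slot nBoot integer, number of bootstrap resamples (0 if none).
#' @seealso [mixingRatioMatrix()], [bootstrapMixing()]
#' @export
setClass("MixingMatrix",
  representation(
    ratio = "matrix",
    ciLow = "matrix",
    ciHigh = "matrix",
    wave = "character",
    filter = "character",
    nBoot = "integer"
  )
)

setValidity("MixingMatrix", function(object) {
  msgs <- character(0)
  if (any(object@ratio < 0, na.rm = TRUE))
    msgs <- c(msgs, "negative mixing ratio")
  if (nrow(object@ciLow)) {
    if (!identical(dim(object@ciLow), dim(object@ratio)) ||
        !identical(dim(object@ciHigh), dim(object@ratio)))
      msgs <- c(msgs, "CI matrices must match the ratio matrix shape")
    else {
      ok <- is.na(object@ratio) | is.na(object@ciLow) |
        (object@ciLow <= object@ratio + 1e-12 &
         object@ratio <= object@ciHigh + 1e-12)
      if (!all(ok))
        msgs <- c(msgs, "CI bounds do not bracket the point estimate")
    }
  }
  if (!object@filter %in% c("all", "touch"))
    msgs <- c(msgs, "filter must be 'all' or 'touch'")
  if (length(msgs)) msgs else TRUE
})

#' DurationModel: exponential fit to interval-censored contact durations
#'
#' The maximum-likelihood exponential rate for contact-event durations
#' observed only as ordinal duration categories with known boundaries in
#' minutes, obtained by expectation-maximization.
#'
#' @slot rate fitted exponential rate, per minute (mean duration = 1/rate).
#' @slot logLik censored-data log-likelihood at the fitted rate.
#' @slot nIterations number of EM iterations run.
#' @slot converged logical convergence flag.
#' @slot categories the category boundary table used
#'   (see [durationCategories()]).
#' @slot logLikTrace per-iteration log-likelihood values (non-decreasing).
#' @seealso [fitCensoredExponential()], [imputeDurations()]
#' @export
setClass("DurationModel",
  representation(
    rate = "numeric",
    logLik = "numeric",
    nIterations = "integer",
    converged = "logical",
    categories = "data.frame",
    logLikTrace = "numeric"
  )
)

setValidity("DurationModel", function(object) {
  msgs <- character(0)
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    msgs <- c(msgs, "rate must be a single positive number")
  if (length(object@logLikTrace) > 1 &&
      any(diff(object@logLikTrace) <
            -1e-8 * (1 + max(abs(object@logLikTrace)))))
    msgs <- c(msgs, "log-likelihood decreased across EM iterations")
  if (length(msgs)) msgs else TRUE
})

#' ImputationSet: replicate imputations of event durations
#'
#' Event durations drawn from the fitted exponential model truncated to each
#' event's duration-category interval, replicated to carry imputation
#' uncertainty into per-diary total durations.
#'
#' @slot events data.frame of the imputed events (participant_id, wave,
#'   event_id, duration_category, plus a \code{flagged} logical marking events
#'   whose category was unknown and were drawn untruncated).
#' @slot draws numeric matrix, one row per event, one column per replicate, in
#'   minutes.
#' @slot diaryTotals numeric matrix, one row per diary, one column per
#'   replicate, total contact duration in hours. Row order matches
#'   \code{diaryKey}.
#' @slot diaryKey data.frame (participant_id, wave) keying diaryTotals rows.
#' @slot seed integer seed used.
#' @slot rate the exponential rate the draws came from.
#' @seealso [imputeDurations()], [totalDuration()]
#' @export
setClass("ImputationSet",
  representation(
    events = "data.frame",
    draws = "matrix",
    diaryTotals = "matrix",
    diaryKey = "data.frame",
    seed = "integer",
    rate = "numeric"
  )
)
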