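#' Construct a validated DiaryPanel from raw tables
#'
#' Assembles the participant, diary and event tables into a [DiaryPanel-class],
#' applying row-level validation. Rows violating invariants (non-positive
#' group size or household size, events without a matching diary, weekday
#' labels inconsistent with the reporting date, under-age participants) are
#' moved to the rejected table with a reason rather than failing the build;
#' participants missing age or sex are retained but flagged for exclusion
#' from analyses that need the missing field. Structural problems -- missing
#' mandatory columns or more than one diary for the same participant and wave
#' -- are hard errors.
#'
#' @param participants data.frame with columns participant_id, household_id,
#'   age_years, sex, household_size.
#' @param diaries data.frame with columns participant_id, wave, reporting_day
#'   (ISO-8601 date), typical_day; an optional weekday column is checked
#'   against reporting_day, otherwise weekday is derived from the date.
#' @param events data.frame with columns participant_id, wave, event_id,
#'   group_size, contact_age_group, setting, duration_category, touch,
#'   location_label, frequency.
#' @param minAge minimum participant age in years (study design minimum; set
#'   to 0 to relax). Participants below it are rejected.
#' @return a [DiaryPanel-class].
#' @export
diaryPanel <- function(participants, diaries, events, minAge = 2) {
  .assertColumns(participants, .PARTICIPANT_COLS, "participants")
  .assertColumns(diaries, setdiff(.DIARY_COLS, "weekday"), "diaries")
  .assertColumns(events, .EVENT_COLS, "events")

  participants <- as.data.frame(participants, stringsAsFactors = FALSE)
  diaries <- as.data.frame(diaries, stringsAsFactors = FALSE)
  events <- as.data.frame(events, stringsAsFactors = FALSE)

  participants$age_years <- suppressWarnings(as.numeric(participants$age_years))
  participants$household_size <-
    suppressWarnings(as.integer(participants$household_size))
  diaries$reporting_day <- as.Date(diaries$reporting_day)
  events$group_size <- suppressWarnings(as.integer(events$group_size))
  events$duration_category <-
    suppressWarnings(as.integer(events$duration_category))
  events$touch <- as.logical(events$touch)

  rejected <- list()
  reject <- function(df, bad, reason) {
    if (any(bad)) {
      r <- df[bad, , drop = FALSE]
      r$reason <- reason
      rejected[[length(rejected) + 1L]] <<- r[, c("participant_id", "reason")]
    }
    df[!bad, , drop = FALSE]
  }

  bad_hh <- !is.na(participants$household_size) & participants$household_size < 1
  participants <- reject(participants, bad_hh, "household_size<1")
  bad_age <- !is.na(participants$age_years) & participants$age_years < minAge
  if (minAge > 0)
    participants <- reject(participants, bad_age,
                           sprintf("age_years<%g", minAge))

  if (anyDuplicated(diaries[, c("participant_id", "wave")]))
    .stopf("duplicate diary for the same (participant, wave) pair")
  diaries <- reject(diaries, !diaries$participant_id %in%
                      participants$participant_id, "unknown_participant")

  derived_wd <- .weekdayOf(diaries$reporting_day)
  if ("weekday" %in% names(diaries)) {
    both <- !is.na(diaries$weekday) & !is.na(diaries$reporting_day)
    diaries <- reject(diaries, both & diaries$weekday != derived_wd[seq_len(nrow(diaries))],
                      "weekday_mismatch")
  }
  diaries$weekday <- ifelse(is.na(diaries$reporting_day),
                            if ("weekday" %in% names(diaries)) diaries$weekday
                            else NA_character_,
                            .weekdayOf(diaries$reporting_day))
  diaries$typical_day[!diaries$typical_day %in% .TYPICAL_LEVELS] <- "unknown"
  diaries <- diaries[, .DIARY_COLS]

  events <- reject(events, is.na(events$group_size) | events$group_size < 1,
                   "group_size<1")
  key_d <- paste(diaries$participant_id, diaries$wave)
  events <- reject(events, !paste(events$participant_id, events$wave) %in% key_d,
                   "no_matching_diary")
  ## unrecognised contact-age labels behave as unknown downstream
  bad_cag <- !is.na(events$contact_age_group) &
    !events$contact_age_group %in% c(.CONTACT_AGE_GROUPS, "unknown")
  events$contact_age_group[bad_cag] <- "unknown"
  events <- events[, .EVENT_COLS]

  excluded <- participants$participant_id[
    is.na(participants$age_years) |
      is.na(participants$sex) | !participants$sex %in% c("male", "female")]

  rejected <- if (length(rejected)) do.call(rbind, rejected)
              else data.frame(participant_id = character(0),
                              reason = character(0))
  new("DiaryPanel", participants = participants, diaries = diaries,
      events = events, rejected = rejected,
      excluded = as.character(excluded))
}

#' Read a contact-diary panel from CSV files
#'
#' Reads the three-table CSV dialect (participants.csv, diaries.csv,
#' events.csv) from a directory or from explicitly named paths, and validates
#' it via [diaryPanel()].
#'
#' @param dir directory containing participants.csv, diaries.csv, events.csv;
#'   ignored when all three paths are given.
#' @param participantsFile,diariesFile,eventsFile explicit file paths.
#' @param minAge passed to [diaryPanel()].
#' @return a [DiaryPanel-class].
#' @export
readDiaryPanel <- function(dir = NULL, participantsFile = NULL,
                           diariesFile = NULL, eventsFile = NULL,
                           minAge = 2) {
  pick <- function(explicit, name) {
    if (!is.null(explicit)) return(explicit)
    if (is.null(dir)) .stopf("either dir or %s must be given", name)
    file.path(dir, name)
  }
  pf <- pick(participantsFile, "participants.csv")
  df <- pick(diariesFile, "diaries.csv")
  ef <- pick(eventsFile, "events.csv")
  for (f in c(pf, df, ef))
    if (!file.exists(f)) .stopf("input file not found: %s", f)
  rd <- function(f) utils::read.csv(f, stringsAsFactors = FALSE,
                                    na.strings = c("NA", ""))
  diaryPanel(rd(pf), rd(df), rd(ef), minAge = minAge)
}

#' Write a DiaryPanel back to its CSV dialect
#'
#' Writes participants.csv, diaries.csv and events.csv such that
#' [readDiaryPanel()] on the output reproduces the panel field for field.
#'
#' @param panel a [DiaryPanel-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
writeDiaryPanel <- function(panel, dir) {
  stopifnot(is(panel, "DiaryPanel"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("participants.csv", "diaries.csv", "events.csv"))
  utils::write.csv(participants(panel), paths[1], row.names = FALSE, na = "")
  utils::write.csv(diaries(panel), paths[2], row.names = FALSE, na = "")
  utils::write.csv(events(panel), paths[3], row.names = FALSE, na = "")
  invisible(paths)
}

#' Read a census age distribution
#'
#' Reads a two-column CSV (age_group, population_count) and normalises counts
#' to proportions over the contact age groups.
#'
#' @param path CSV path.
#' @return data.frame with columns age_group and proportion (summing to 1).
#' @export
readCensus <- function(path) {
  if (!file.exists(path)) .stopf("census file not found: %s", path)
  cen <- utils::read.csv(path, stringsAsFactors = FALSE)
  .assertColumns(cen, c("age_group", "population_count"), "census")
  if (any(cen$population_count <= 0))
    .stopf("census population counts must be positive")
  data.frame(age_group = as.character(cen$age_group),
             proportion = cen$population_count / sum(cen$population_count),
             stringsAsFactors = FALSE)
}

#' Default census-style age distribution
#'
#' A synthetic population age distribution over the five contact age groups,
#' shaped like an aged urban population. It stands in for a real census table
#' wherever one is not supplied; analyses of real data should pass their own
#' census through [readCensus()].
#'
#' @return data.frame with columns age_group and proportion.
#' @export
defaultCensus <- function() {
  data.frame(
    age_group = .CONTACT_AGE_GROUPS,
    proportion = c(0.052, 0.138, 0.303, 0.378, 0.129),
    stringsAsFactors = FALSE
  )
}

#' Derive per-diary contact rates from event records
#'
#' Produces one row per diary with the three core rates: K, the number of
#' contacts (each event contributes its group size, so a group of five counts
#' five contacts); L, the number of distinct locations (distinct
#' location_label strings within the diary); and setting-stratified contact
#' counts K_home, K_schoolwork (school and work merged) and K_other. Events
#' with an unrecorded setting count towards K but no stratum, so the strata
#' sum to K only when every setting is recorded. Total contact duration D is
#' left NA here and filled by [addDurations()] after duration imputation.
#'
#' @param panel a [DiaryPanel-class].
#' @return data.frame (the rate table) with columns participant_id, wave, K,
#'   L, K_home, K_schoolwork, K_other, D, weekday, typical_day, age_years,
#'   sex, household_size.
#' @export
deriveRates <- function(panel) {
  stopifnot(is(panel, "DiaryPanel"))
  d <- diaries(panel)
  e <- events(panel)
  key <- paste(d$participant_id, d$wave)
  ekey <- factor(paste(e$participant_id, e$wave), levels = key)

  sumBy <- function(x, subset = TRUE) {
    v <- rep(0, length(key))
    if (!nrow(e)) return(v)
    s <- subset & !is.na(ekey)
    if (!any(s)) return(v)
    agg <- rowsum(as.numeric(x[s]), ekey[s])
    v[match(rownames(agg), key)] <- agg[, 1]
    v
  }

  K <- sumBy(e$group_size)
  K_home <- sumBy(e$group_size, e$setting %in% "home")
  K_schoolwork <- sumBy(e$group_size, e$setting %in% c("school", "work"))
  K_other <- sumBy(e$group_size, e$setting %in% "other")

  L <- rep(0L, length(key))
  if (nrow(e)) {
    has_loc <- !is.na(e$location_label) & !is.na(ekey)
    if (any(has_loc)) {
      uniq <- unique(data.frame(k = as.integer(ekey)[has_loc],
                                loc = e$location_label[has_loc]))
      tab <- table(factor(uniq$k, levels = seq_along(key)))
      L <- as.integer(tab)
    }
  }

  p <- participants(panel)
  idx <- match(d$participant_id, p$participant_id)
  data.frame(
    participant_id = d$participant_id,
    wave = as.character(d$wave),
    K = as.integer(K),
    L = L,
    K_home = as.integer(K_home),
    K_schoolwork = as.integer(K_schoolwork),
    K_other = as.integer(K_other),
    D = NA_real_,
    weekday = d$weekday,
    typical_day = d$typical_day,
    age_years = p$age_years[idx],
    sex = p$sex[idx],
    household_size = p$household_size[idx],
    stringsAsFactors = FALSE
  )
}

#' Write / read a rate table
#'
#' CSV persistence for the per-diary rate table; write followed by read is a
#' lossless round trip.
#'
#' @param rates a rate table from [deriveRates()].
#' @param path CSV file path.
#' @return `writeRateTable`: invisibly, the path; `readRateTable`: the rate
#'   table data.frame.
#' @export
writeRateTable <- function(rates, path) {
  utils::write.csv(rates, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeRateTable
#' @export
readRateTable <- function(path) {
  if (!file.exists(path)) .stopf("rate table not found: %s", path)
  r <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("NA", ""))
  .assertColumns(r, c("participant_id", "wave", "K", "L"), "rate table")
  r$wave <- as.character(r$wave)
  if ("D" %in% names(r)) r$D <- as.numeric(r$D)
  r
}
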