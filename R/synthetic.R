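#' Configuration for the synthetic diary-panel generator
#'
#' Bundles the parameters of the generative model used to emulate a
#' multi-wave contact-diary survey. The generator draws, for participant i in
#' wave j, a latent Gaussian contact intensity on the log(1+K) scale,
#'
#'   log(1 + K_ij) = mu_age + weekday effect + wave effect
#'                   + locationCoupling * (L_ij - 1) + b_i + e_ij,
#'
#' with participant intercepts b_i ~ N(0, sigma2Between) shared across waves
#' and residuals e_ij ~ N(0, sigma2Within) -- exactly the random-intercept
#' structure the longitudinal module fits, so parameter recovery is a clean
#' test surface. The number of contact locations L_ij is drawn first
#' (1 + Poisson, zero if the realised diary is empty) and contacts are then
#' generated conditional on L, encoding the positive contacts-locations
#' association. Realised contacts are partitioned into events, a Poisson
#' number of which are reported as groups (long right tail of contact
#' counts); true event durations are exponential and recorded only as ordinal
#' duration categories; contact ages mix proportionately to the census with
#' a configurable own-age-group excess.
#'
#' Defaults emulate the scale and structure of a four-wave urban diary study:
#' 857 households / ~1450 individuals, ~30\% wave-to-wave dropout with
#' replacement recruitment, mean ~12.5 contacts in ~2.9 locations per diary,
#' within-individual variance about twice the between-individual variance,
#' under one group report per diary with mean group size ~10, and ~73\% of
#' diaries flagged as typical days.
#'
#' @param nHouseholds number of households.
#' @param meanHouseholdSize mean of the truncated-geometric household size
#'   distribution (support 1, 2, ...).
#' @param householdSizeProbs optional probability vector over household sizes
#'   1..length(householdSizeProbs); overrides the geometric default (use a
#'   point mass for fixed-size households).
#' @param ageGroupWeights named numeric, sampling weights of participant age
#'   groups (must sum to 1 after normalisation).
#' @param nWaves number of survey waves (labelled R1, R2, ...).
#' @param dropoutPerWave probability that a wave's participant skips the next
#'   wave; lapsed and fresh participants are recruited to keep wave sizes
#'   roughly stable (open cohort).
#' @param initialParticipation fraction of the population interviewed in wave 1.
#' @param meanLogContacts named numeric, baseline of log(1+K) per participant
#'   age group (at one location, reference weekday and wave).
#' @param weekdayEffects named numeric length 7 (Sun..Sat), additive effects
#'   on the log(1+K) scale.
#' @param waveEffects numeric length nWaves, additive wave effects.
#' @param sigma2Between variance of the participant random intercept.
#' @param sigma2Within residual variance.
#' @param meanLocations mean of L = 1 + Poisson(meanLocations - 1).
#' @param locationCoupling additive effect of each location beyond the first
#'   on log(1+K).
#' @param groupsPerDiary mean number of group-reported events per diary
#'   (Poisson).
#' @param meanGroupSize mean size of a group event (2 + Poisson).
#' @param durationRate exponential rate of true event durations, per minute.
#' @param categories duration category table from [durationCategories()] used
#'   to bin true durations.
#' @param assortativityStrength s >= 0; contact ages are drawn with weights
#'   census * (1 + s * own-group indicator). s = 0 is exact proportionate
#'   mixing.
#' @param census data.frame(age_group, proportion) over contact age groups.
#' @param typicalDayProb probability a diary is flagged a typical day
#'   (non-typical otherwise, with a sliver of unknowns).
#' @param startDate first reporting day of wave 1; waves occupy consecutive
#'   12-week windows.
#' @return a list of class "syntheticConfig".
#' @seealso [generatePopulation()], [generatePanel()]
#' @export
syntheticConfig <- function(nHouseholds = 857,
                            meanHouseholdSize = 1450 / 857,
                            householdSizeProbs = NULL,
                            ageGroupWeights = c("5-19" = 0.065,
                                                "20-39" = 0.195,
                                                "40-64" = 0.58,
                                                "65+" = 0.16),
                            nWaves = 4,
                            dropoutPerWave = 0.30,
                            initialParticipation = 0.735,
                            meanLogContacts = c("5-19" = 2.25,
                                                "20-39" = 2.10,
                                                "40-64" = 2.10,
                                                "65+" = 1.75),
                            weekdayEffects = c(Sun = -0.15, Mon = 0.05,
                                               Tue = 0.05, Wed = 0.05,
                                               Thu = 0.05, Fri = 0,
                                               Sat = -0.1),
                            waveEffects = NULL,
                            sigma2Between = 0.17,
                            sigma2Within = 0.33,
                            meanLocations = 3.4,
                            locationCoupling = 0.12,
                            groupsPerDiary = 0.3,
                            meanGroupSize = 10,
                            durationRate = 1 / 45,
                            categories = durationCategories(),
                            assortativityStrength = 4,
                            census = defaultCensus(),
                            typicalDayProb = 0.734,
                            startDate = as.Date("2012-05-01")) {
  if (is.null(waveEffects))
    waveEffects <- c(0, 0.10, 0, 0)[seq_len(nWaves)]
  if (sigma2Between < 0 || sigma2Within < 0)
    .stopf("variance components must be non-negative")
  if (dropoutPerWave < 0 || dropoutPerWave >= 1)
    .stopf("dropoutPerWave must lie in [0, 1)")
  if (any(ageGroupWeights < 0) || sum(ageGroupWeights) <= 0)
    .stopf("degenerate age group weights")
  ageGroupWeights <- ageGroupWeights / sum(ageGroupWeights)
  if (length(waveEffects) != nWaves)
    .stopf("waveEffects must have length nWaves")
  if (!is.null(householdSizeProbs) &&
      (any(householdSizeProbs < 0) || sum(householdSizeProbs) <= 0))
    .stopf("degenerate household size distribution")
  cfg <- list(nHouseholds = nHouseholds,
              meanHouseholdSize = meanHouseholdSize,
              householdSizeProbs = householdSizeProbs,
              ageGroupWeights = ageGroupWeights, nWaves = nWaves,
              dropoutPerWave = dropoutPerWave,
              initialParticipation = initialParticipation,
              meanLogContacts = meanLogContacts,
              weekdayEffects = weekdayEffects, waveEffects = waveEffects,
              sigma2Between = sigma2Between, sigma2Within = sigma2Within,
              meanLocations = meanLocations,
              locationCoupling = locationCoupling,
              groupsPerDiary = groupsPerDiary, meanGroupSize = meanGroupSize,
              durationRate = durationRate, categories = categories,
              assortativityStrength = assortativityStrength, census = census,
              typicalDayProb = typicalDayProb, startDate = startDate)
  class(cfg) <- "syntheticConfig"
  cfg
}

## Age range spanned by each participant age group when drawing decimal ages.
.AGE_RANGES <- list("5-19" = c(5, 20), "20-39" = c(20, 40),
                    "40-64" = c(40, 65), "65+" = c(65, 85))

#' Generate a synthetic study population
#'
#' Draws households (truncated-geometric sizes) and their members (ages from
#' the configured age-group weights, uniform in decimal years within group;
#' sex at the survey's observed imbalance). Deterministic under seed.
#'
#' @param config a [syntheticConfig()].
#' @param seed integer seed.
#' @return participants data.frame in the [diaryPanel()] dialect.
#' @export
generatePopulation <- function(config = syntheticConfig(), seed = 1) {
  stopifnot(inherits(config, "syntheticConfig"))
  set.seed(.childSeed(seed, 1L))
  H <- config$nHouseholds
  if (!is.null(config$householdSizeProbs)) {
    pr <- config$householdSizeProbs / sum(config$householdSizeProbs)
    sizes <- sample(seq_along(pr), H, replace = TRUE, prob = pr)
  } else {
    m <- config$meanHouseholdSize
    if (m < 1) .stopf("meanHouseholdSize must be >= 1")
    ## shifted geometric: P(s) = (1-p) p^(s-1), s >= 1, mean 1/(1-p)
    p <- 1 - 1 / m
    sizes <- if (p <= 0) rep(1L, H) else 1L + stats::rgeom(H, prob = 1 - p)
  }
  n <- sum(sizes)
  hh <- rep(sprintf("h%04d", seq_len(H)), sizes)
  groups <- sample(names(config$ageGroupWeights), n, replace = TRUE,
                   prob = config$ageGroupWeights)
  lo <- vapply(.AGE_RANGES[groups], `[`, numeric(1), 1)
  hi <- vapply(.AGE_RANGES[groups], `[`, numeric(1), 2)
  age <- stats::runif(n, lo, hi)
  data.frame(
    participant_id = sprintf("p%05d", seq_len(n)),
    household_id = hh,
    age_years = round(age, 2),
    sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.39, 0.61)),
    household_size = rep(sizes, sizes),
    stringsAsFactors = FALSE
  )
}

## Open-cohort wave membership: wave 1 samples initialParticipation of the
## population; each later wave keeps the previous wave's participants with
## probability 1 - dropout and tops up towards a mildly declining target from
## the not-yet-active pool (then lapsed participants).
.waveMembership <- function(n, config) {
  active <- vector("list", config$nWaves)
  w1 <- sort(sample.int(n, round(config$initialParticipation * n)))
  active[[1]] <- w1
  ever <- w1
  for (w in seq_len(config$nWaves)[-1]) {
    prev <- active[[w - 1]]
    keep <- prev[stats::runif(length(prev)) > config$dropoutPerWave]
    target <- round(length(active[[1]]) * 0.93^(w - 1))
    need <- max(0L, target - length(keep))
    pool <- setdiff(seq_len(n), union(keep, ever))
    if (length(pool) < need) pool <- setdiff(seq_len(n), keep)
    recruits <- if (need > 0) sample(pool, min(need, length(pool))) else integer(0)
    active[[w]] <- sort(c(keep, recruits))
    ever <- union(ever, active[[w]])
  }
  active
}

## Reporting day within the wave's 12-week window matching a sampled weekday.
.reportingDays <- function(nd, wave, weekday, startDate) {
  window_start <- startDate + (wave - 1L) * 84L
  wd0 <- as.integer(format(window_start, "%w"))
  target <- match(weekday, .WEEKDAYS) - 1L
  offset <- (target - wd0) %% 7L
  window_start + offset + 7L * sample.int(12L, nd, replace = TRUE) - 7L
}

#' Generate a synthetic diary panel
#'
#' Simulates diaries and contact events for a population under the generative
#' model described in [syntheticConfig()]. Deterministic under seed.
#'
#' @param population participants data.frame from [generatePopulation()].
#' @param config a [syntheticConfig()].
#' @param seed integer seed.
#' @return a validated [DiaryPanel-class].
#' @export
generatePanel <- function(population = generatePopulation(config, seed),
                          config = syntheticConfig(), seed = 1) {
  stopifnot(inherits(config, "syntheticConfig"))
  set.seed(.childSeed(seed, 2L))
  n <- nrow(population)
  waves_lab <- sprintf("R%d", seq_len(config$nWaves))
  member <- .waveMembership(n, config)

  b <- stats::rnorm(n, 0, sqrt(config$sigma2Between))
  own_group <- as.character(.ownContactGroup(population$age_years))
  page_group <- as.character(.participantAgeGroup(population$age_years))

  cen_prop <- config$census$proportion
  names(cen_prop) <- config$census$age_group

  diary_list <- vector("list", config$nWaves)
  event_list <- vector("list", config$nWaves)

  cat_lower <- config$categories$lower
  cat_upper <- config$categories$upper

  for (w in seq_len(config$nWaves)) {
    idx <- member[[w]]
    nd <- length(idx)
    if (!nd) next
    weekday <- sample(.WEEKDAYS, nd, replace = TRUE,
                      prob = c(0.14, 0.17, 0.16, 0.12, 0.13, 0.13, 0.15))
    L <- 1L + stats::rpois(nd, config$meanLocations - 1)
    mu <- config$meanLogContacts[page_group[idx]]
    mu[is.na(mu)] <- mean(config$meanLogContacts) # ages outside groups
    eta <- mu + config$weekdayEffects[weekday] + config$waveEffects[w] +
      config$locationCoupling * (L - 1L) + b[idx] +
      stats::rnorm(nd, 0, sqrt(config$sigma2Within))
    K <- pmax(0L, as.integer(round(expm1(eta))))
    L[K == 0L] <- 0L

    typ <- sample(c("typical", "non_typical", "unknown"), nd, replace = TRUE,
                  prob = c(config$typicalDayProb,
                           1 - config$typicalDayProb - 0.003, 0.003))
    rep_day <- .reportingDays(nd, w, weekday, config$startDate)

    diary_list[[w]] <- data.frame(
      participant_id = population$participant_id[idx],
      wave = waves_lab[w],
      reporting_day = rep_day,
      weekday = weekday,
      typical_day = typ,
      stringsAsFactors = FALSE
    )

    ## partition each diary's K contacts into events: nGroups group events
    ## (size 2 + Poisson, capped by what is left), remainder individual
    has <- which(K > 0L)
    if (!length(has)) next
    nGroups <- stats::rpois(length(has), config$groupsPerDiary)
    ev_n <- integer(length(has))
    sizes_list <- vector("list", length(has))
    loc_list <- vector("list", length(has))
    for (ii in seq_along(has)) {
      k <- K[has[ii]]
      gsz <- integer(0)
      g <- nGroups[ii]
      while (g > 0L && k >= 2L) {
        s <- min(k, 2L + stats::rpois(1L, config$meanGroupSize - 2))
        gsz <- c(gsz, s)
        k <- k - s
        g <- g - 1L
      }
      sizes_list[[ii]] <- c(gsz, rep(1L, k))
      nev <- length(sizes_list[[ii]])
      ev_n[ii] <- nev
      ## every drawn location hosts at least one event when possible, so the
      ## diary's distinct-location count reproduces the drawn L
      Ld <- L[has[ii]]
      li <- c(seq_len(min(Ld, nev)),
              if (nev > Ld) sample.int(Ld, nev - Ld, replace = TRUE))
      loc_list[[ii]] <- sample(li)
    }
    sizes <- unlist(sizes_list)
    ne <- length(sizes)
    di <- rep(has, ev_n)                       # diary index of each event
    pid <- population$participant_id[idx[di]]

    ## contact ages: census proportions with own-group excess
    s_assort <- config$assortativityStrength
    own_ev <- own_group[idx[di]]
    wmat <- matrix(cen_prop[.CONTACT_AGE_GROUPS], nrow = ne,
                   ncol = length(.CONTACT_AGE_GROUPS), byrow = TRUE)
    colnames(wmat) <- .CONTACT_AGE_GROUPS
    boost <- outer(own_ev, .CONTACT_AGE_GROUPS, "==")
    wmat <- wmat * (1 + s_assort * boost)
    cag <- .CONTACT_AGE_GROUPS[.sampleCategorical(wmat)]

    ## true durations, recorded only as categories
    tdur <- stats::rexp(ne, config$durationRate)
    dcat <- findInterval(tdur, cat_lower)

    ## settings: crude age-dependent pattern (children: school, adults: work)
    age_ev <- population$age_years[idx[di]]
    p_school <- ifelse(age_ev < 20, 0.3, 0.01)
    p_work <- ifelse(age_ev >= 20 & age_ev < 65, 0.3, 0.02)
    p_home <- 0.25
    p_other <- pmax(0.05, 1 - p_school - p_work - p_home)
    um <- cbind(p_home, p_school, p_work, p_other)
    setting <- c("home", "school", "work", "other")[.sampleCategorical(um)]

    loc <- paste0("loc", unlist(loc_list))

    event_list[[w]] <- data.frame(
      participant_id = pid,
      wave = waves_lab[w],
      event_id = sprintf("%s_%s_e%d", pid, waves_lab[w],
                         sequence(rle(di)$lengths)),
      group_size = sizes,
      contact_age_group = cag,
      setting = setting,
      duration_category = dcat,
      touch = stats::runif(ne) < 0.4,
      location_label = loc,
      frequency = sample.int(5L, ne, replace = TRUE),
      stringsAsFactors = FALSE
    )
  }

  diaries <- do.call(rbind, diary_list[!vapply(diary_list, is.null, TRUE)])
  evs <- event_list[!vapply(event_list, is.null, TRUE)]
  events <- if (length(evs)) do.call(rbind, evs) else
    data.frame(participant_id = character(0), wave = character(0),
               event_id = character(0), group_size = integer(0),
               contact_age_group = character(0), setting = character(0),
               duration_category = integer(0), touch = logical(0),
               location_label = character(0), frequency = integer(0),
               stringsAsFactors = FALSE)

  keep <- population$participant_id %in% diaries$participant_id
  diaryPanel(population[keep, , drop = FALSE], diaries, events, minAge = 0)
}
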