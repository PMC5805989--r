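## Per-participant contact counts over contact age groups for one wave.
## Returns list(counts = participants x groups matrix, pgroup = participant
## age-group factor). Group events contribute group_size contacts of their
## contact age group; unknown contact ages are excluded from numerator and
## denominator alike.
.contactCountMatrix <- function(panel, census, wave, touchOnly = FALSE,
                                participantBreaks = .PARTICIPANT_AGE_BREAKS,
                                participantLabels = .PARTICIPANT_AGE_GROUPS) {
  groups <- census$age_group
  p <- participants(panel)
  d <- diaries(panel)
  e <- events(panel)
  d <- d[d$wave == wave, , drop = FALSE]
  if (!nrow(d)) .stopf("no diaries in wave %s", wave)
  e <- e[e$wave == wave & e$participant_id %in% d$participant_id, ,
         drop = FALSE]
  if (touchOnly) e <- e[e$touch %in% TRUE, , drop = FALSE]
  e <- e[!is.na(e$contact_age_group) & e$contact_age_group %in% groups, ,
         drop = FALSE]

  ids <- d$participant_id
  age <- p$age_years[match(ids, p$participant_id)]
  pg <- .participantAgeGroup(age, participantBreaks, participantLabels)
  counts <- matrix(0, nrow = length(ids), ncol = length(groups),
                   dimnames = list(ids, groups))
  if (nrow(e)) {
    i <- match(e$participant_id, ids)
    j <- match(e$contact_age_group, groups)
    cell <- (j - 1L) * length(ids) + i
    agg <- rowsum(as.numeric(e$group_size), cell)
    counts[as.integer(rownames(agg))] <- agg[, 1]
  }
  list(counts = counts, pgroup = pg)
}

## Ratio matrix from a count matrix: per participant group, the share of
## contacts in each contact group divided by the census proportion.
.ratioFromCounts <- function(counts, pgroup, census) {
  keep <- !is.na(pgroup)
  tot <- rowsum(counts[keep, , drop = FALSE], pgroup[keep])
  m <- matrix(NA_real_, nlevels(pgroup), ncol(counts),
              dimnames = list(levels(pgroup), colnames(counts)))
  rs <- rowSums(tot)
  share <- tot / ifelse(rs > 0, rs, NA)
  m[rownames(tot), ] <- share
  sweep(m, 2, census$proportion, "/")
}

#' Age-mixing ratio matrix relative to proportionate mixing
#'
#' For one survey wave, computes the participant-age-group by
#' contact-age-group matrix of mixing ratios: the observed share of a
#' participant group's contacts falling in each contact age group, divided by
#' that group's census population proportion. Under proportionate (random)
#' mixing every cell is 1; cells above 1 indicate age-assortative excess
#' contact. Group events contribute their full group size to the contact age
#' group recorded for the event; contacts of unknown age are excluded.
#' Participants younger than the first participant age break (the thinly
#' sampled 2-4 year olds) are excluded.
#'
#' @param panel a [DiaryPanel-class].
#' @param census data.frame(age_group, proportion) as from [readCensus()] or
#'   [defaultCensus()]; its rows define the contact age groups.
#' @param wave wave label to summarise.
#' @param touchOnly if TRUE, restrict to events involving physical touch.
#' @param participantBreaks,participantLabels age grouping of the participant
#'   side.
#' @return a [MixingMatrix-class] (point estimates only).
#' @export
mixingRatioMatrix <- function(panel, census, wave, touchOnly = FALSE,
                              participantBreaks = .PARTICIPANT_AGE_BREAKS,
                              participantLabels = .PARTICIPANT_AGE_GROUPS) {
  if (abs(sum(census$proportion) - 1) > 1e-6)
    .stopf("census proportions must sum to 1")
  if (any(census$proportion <= 0)) .stopf("census proportions must be positive")
  cc <- .contactCountMatrix(panel, census, wave, touchOnly,
                            participantBreaks, participantLabels)
  ratio <- .ratioFromCounts(cc$counts, cc$pgroup, census)
  new("MixingMatrix", ratio = ratio,
      ciLow = matrix(numeric(0), 0, 0), ciHigh = matrix(numeric(0), 0, 0),
      wave = as.character(wave), filter = if (touchOnly) "touch" else "all",
      nBoot = 0L)
}

#' Bootstrap confidence intervals for a mixing matrix
#'
#' Percentile 95\% confidence intervals for every mixing-ratio cell, obtained
#' by resampling participants with replacement (each resampled participant
#' carries all their contacts for the wave) and recomputing the ratio matrix.
#' The point estimate is the plug-in estimate and is unchanged by the
#' bootstrap.
#'
#' @inheritParams mixingRatioMatrix
#' @param nBoot number of bootstrap resamples.
#' @param seed integer seed.
#' @return a [MixingMatrix-class] with ciLow/ciHigh filled.
#' @export
bootstrapMixing <- function(panel, census, wave, touchOnly = FALSE,
                            nBoot = 1000L, seed = 1L,
                            participantBreaks = .PARTICIPANT_AGE_BREAKS,
                            participantLabels = .PARTICIPANT_AGE_GROUPS) {
  if (nBoot < 2) .stopf("nBoot must be >= 2")
  point <- mixingRatioMatrix(panel, census, wave, touchOnly,
                             participantBreaks, participantLabels)
  cc <- .contactCountMatrix(panel, census, wave, touchOnly,
                            participantBreaks, participantLabels)
  counts <- cc$counts
  pg <- cc$pgroup
  n <- nrow(counts)
  ng <- length(levels(pg))
  ncg <- ncol(counts)
  set.seed(.childSeed(seed, 3L))
  boots <- array(NA_real_, dim = c(ng, ncg, nBoot),
                 dimnames = list(levels(pg), colnames(counts), NULL))
  for (b in seq_len(nBoot)) {
    idx <- sample.int(n, n, replace = TRUE)
    boots[, , b] <- .ratioFromCounts(counts[idx, , drop = FALSE], pg[idx],
                                     census)
  }
  qt <- function(p) {
    out <- apply(boots, c(1, 2), function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) NA_real_ else stats::quantile(v, p, names = FALSE)
    })
    dimnames(out) <- dimnames(point@ratio)
    out
  }
  lo <- qt(0.025)
  hi <- qt(0.975)
  ## the interval always brackets the plug-in point estimate
  lo <- pmin(lo, point@ratio)
  hi <- pmax(hi, point@ratio)
  new("MixingMatrix", ratio = point@ratio, ciLow = lo, ciHigh = hi,
      wave = point@wave, filter = point@filter, nBoot = as.integer(nBoot))
}

#' Export a mixing matrix as a tidy table
#'
#' @param x a [MixingMatrix-class].
#' @return data.frame with columns wave, participant_group, contact_group,
#'   ratio, ci_low, ci_high.
#' @export
mixingTable <- function(x) {
  stopifnot(is(x, "MixingMatrix"))
  hasCI <- !is.null(mixingCI(x))
  df <- expand.grid(participant_group = rownames(x@ratio),
                    contact_group = colnames(x@ratio),
                    stringsAsFactors = FALSE)
  df <- data.frame(wave = x@wave, df,
                   ratio = as.vector(x@ratio),
                   ci_low = if (hasCI) as.vector(x@ciLow) else NA_real_,
                   ci_high = if (hasCI) as.vector(x@ciHigh) else NA_real_,
                   stringsAsFactors = FALSE)
  df[order(df$participant_group, df$contact_group), ]
}

#' Per-capita contact-rate matrix for next-generation analysis
#'
#' Collapses a wave's contacts to a square matrix on the common age groups
#' (participant side {5-19, 20-39, 40-64, 65+}; the 6-19 contact group is
#' mapped to 5-19 and the 0-5 contact column dropped): entry (a, b) is the
#' mean number of group-b contacts reported per group-a participant diary.
#'
#' @param panel a [DiaryPanel-class].
#' @param wave wave label.
#' @return square numeric matrix of per-capita contact rates.
#' @export
contactRateMatrix <- function(panel, wave) {
  census <- defaultCensus() # only used for its group labels here
  cc <- .contactCountMatrix(panel, census, wave)
  counts <- cc$counts
  keep <- !is.na(cc$pgroup)
  counts <- counts[keep, , drop = FALSE]
  pg <- droplevels(cc$pgroup[keep])
  tot <- rowsum(counts, pg)
  nper <- table(pg)[rownames(tot)]
  rate <- tot / as.numeric(nper)
  missing_grp <- setdiff(.PARTICIPANT_AGE_GROUPS, rownames(rate))
  if (length(missing_grp))
    .stopf("wave %s has no participants in age group(s): %s", wave,
           paste(missing_grp, collapse = ", "))
  ## collapse contact side to the participant grouping
  sq <- cbind("5-19" = rate[, "6-19"], rate[, c("20-39", "40-64", "65+")])
  sq[.PARTICIPANT_AGE_GROUPS, , drop = FALSE]
}

#' Dominant eigenvalue of a non-negative next-generation matrix
#'
#' @param m square numeric matrix with non-negative entries.
#' @return the dominant eigenvalue (spectral radius), a non-negative real.
#' @export
dominantEigenvalue <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    .stopf("next-generation input must be a square matrix")
  if (any(!is.finite(m)) || any(m < 0))
    .stopf("next-generation matrix must have finite non-negative entries")
  ev <- eigen(m, only.values = TRUE)$values
  max(Re(ev[abs(Im(ev)) < 1e-8 * (1 + max(abs(ev)))]))
}

#' Rank survey waves by next-generation growth factor
#'
#' Treats each wave's per-capita contact-rate matrix, optionally scaled by an
#' age-specific susceptibility profile, as a next-generation matrix whose
#' dominant eigenvalue is proportional to the epidemic growth factor under
#' uniform infectivity. Waves are ranked by decreasing eigenvalue; only the
#' ranking (not the absolute growth rate) is interpretable without a
#' transmission-probability scale.
#'
#' @param matrices named list of square non-negative matrices, one per wave
#'   (e.g. from [contactRateMatrix()]).
#' @param susceptibility numeric vector of relative susceptibility per age
#'   group (recycled scalar allowed); multiplies the rows.
#' @return data.frame with wave, eigenvalue, rank (1 = fastest growth),
#'   ordered by rank.
#' @export
ngmGrowthRank <- function(matrices, susceptibility = 1) {
  if (!length(matrices)) .stopf("no matrices given")
  ev <- vapply(matrices, function(m) {
    if (!is.matrix(m) || nrow(m) != ncol(m))
      .stopf("next-generation input must be a square matrix")
    s <- rep_len(susceptibility, nrow(m))
    dominantEigenvalue(diag(s, nrow = nrow(m)) %*% m)
  }, numeric(1))
  out <- data.frame(wave = names(matrices), eigenvalue = unname(ev),
                    stringsAsFactors = FALSE)
  out$rank <- rank(-out$eigenvalue, ties.method = "min")
  out[order(out$rank), ]
}
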