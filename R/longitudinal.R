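## Location-count covariate: 0,1,...,5,6+ as an ordered set of labels.
.locationCategory <- function(L) {
  factor(ifelse(L >= 6, "6+", as.character(L)),
         levels = c(as.character(0:5), "6+"))
}

## Assemble the model frame for a random-intercept fit.
.riModelFrame <- function(rates, response, covariates) {
  mf <- data.frame(
    participant_id = rates$participant_id,
    y = log1p(rates[[response]]),
    stringsAsFactors = FALSE
  )
  if ("age_group" %in% covariates)
    mf$age_group <- stats::relevel(
      factor(.participantAgeGroup(rates$age_years),
             levels = .PARTICIPANT_AGE_GROUPS), ref = "40-64")
  if ("sex" %in% covariates)
    mf$sex <- stats::relevel(factor(rates$sex, levels = c("male", "female")),
                             ref = "male")
  if ("weekday" %in% covariates)
    mf$weekday <- stats::relevel(factor(rates$weekday, levels = .WEEKDAYS),
                                 ref = "Mon")
  if ("wave" %in% covariates)
    mf$wave <- factor(rates$wave)
  if ("location_category" %in% covariates)
    mf$location_category <- stats::relevel(.locationCategory(rates$L),
                                           ref = "1")
  if ("household_size" %in% covariates)
    mf$household_size <- as.numeric(rates$household_size)
  mf
}

#' Fit a Gaussian random-intercept model to a log(1+y) contact outcome
#'
#' Fits, by restricted maximum likelihood, the linear mixed model
#' log(1 + y_ij) = x_ij' beta + b_i + e_ij with participant-specific random
#' intercepts b_i ~ N(0, sigma2_between) and residuals
#' e_ij ~ N(0, sigma2_within), where y is a per-diary rate (contacts K,
#' total duration D, locations L, or a setting-stratified contact count).
#' Only participants with at least minObs non-missing observations inform the
#' fit. Default fixed effects are categorical participant age group, sex,
#' reporting weekday and survey wave; the categorized number of contact
#' locations (0,1,...,5,6+) is added for the K and D responses, and household
#' size for home contacts. A custom design can be supplied via `covariates`
#' (any subset of age_group, sex, weekday, wave, location_category,
#' household_size) or, for externally built bases such as an age spline, via
#' `extraDesign`, a numeric matrix with one row per rate-table row whose
#' columns enter the fixed effects unchanged.
#'
#' @param rates rate table from [deriveRates()] (with D filled via
#'   [addDurations()] if modelling D).
#' @param response one of "K", "D", "L", "K_home", "K_schoolwork", "K_other".
#' @param covariates character vector of fixed effects; NULL for the default
#'   set for the response.
#' @param extraDesign optional numeric matrix of additional fixed-effect
#'   columns (e.g. a spline basis in age).
#' @param minObs minimum diaries per participant.
#' @param reml fit by REML (default) or ML.
#' @return object of class "riFit": list with fit (the lmer model), response,
#'   covariates, data (the model frame used) and nParticipants.
#' @export
fitRandomIntercept <- function(rates, response = "K", covariates = NULL,
                               extraDesign = NULL, minObs = 2, reml = TRUE) {
  if (!response %in% names(rates)) .stopf("no column '%s' in rates", response)
  if (is.null(covariates)) {
    covariates <- c("age_group", "sex", "weekday", "wave")
    if (response %in% c("K", "D"))
      covariates <- c(covariates, "location_category")
    if (response == "K_home")
      covariates <- c(covariates, "household_size")
  }
  if (response == "L" && "location_category" %in% covariates)
    .stopf("the location-count covariate cannot enter the model for L")

  mf <- .riModelFrame(rates, response, covariates)
  if (!is.null(extraDesign)) {
    extraDesign <- as.matrix(extraDesign)
    if (nrow(extraDesign) != nrow(mf))
      .stopf("extraDesign must have one row per rate-table row")
    colnames(extraDesign) <- colnames(extraDesign) %||%
      paste0("xd", seq_len(ncol(extraDesign)))
    mf <- cbind(mf, extraDesign)
    covariates <- c(covariates, colnames(extraDesign))
  }
  mf <- mf[stats::complete.cases(mf), , drop = FALSE]
  nobs <- table(mf$participant_id)
  mf <- mf[mf$participant_id %in% names(nobs)[nobs >= minObs], , drop = FALSE]
  if (!nrow(mf)) .stopf("no participants with >= %d observations", minObs)
  ## a factor covariate observed at a single level can only produce aliased
  ## dummy columns; name them rather than letting model.matrix fail opaquely
  for (cov in covariates) {
    col <- mf[[cov]]
    if (is.factor(col)) {
      obs <- unique(as.character(col[!is.na(col)]))
      if (length(obs) < 2)
        .stopf("fixed-effect design is rank deficient; aliased column(s): %s",
               paste(paste0(cov, setdiff(levels(col), obs)), collapse = ", "))
    }
  }
  mf <- droplevels(mf)

  fixed <- if (length(covariates))
    paste(sprintf("`%s`", covariates), collapse = " + ") else "1"
  form <- stats::as.formula(paste("y ~", fixed, "+ (1 | participant_id)"))

  X <- stats::model.matrix(
    stats::as.formula(paste("~", fixed)), data = mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    .stopf("fixed-effect design is rank deficient; aliased column(s): %s",
           paste(aliased, collapse = ", "))
  }

  fit <- lme4::lmer(form, data = mf, REML = reml,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  structure(list(fit = fit, response = response, covariates = covariates,
                 data = mf,
                 nParticipants = length(unique(mf$participant_id))),
            class = "riFit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.riFit <- function(x, ...) {
  cat(sprintf("Random-intercept model for log(1 + %s)\n", x$response))
  cat(sprintf("  %d observations, %d participants\n", nrow(x$data),
              x$nParticipants))
  vs <- varianceShares(x)
  cat(sprintf("  sigma2 between %.4f (%.1f%%), within %.4f (%.1f%%)\n",
              vs$sigma2_between, 100 * vs$between_share,
              vs$sigma2_within, 100 * vs$within_share))
  invisible(x)
}

#' Between/within-individual variance decomposition
#'
#' Extracts the participant-intercept variance (between-individual) and the
#' residual variance (within-individual) from a fitted random-intercept
#' model, and expresses each as a share of their sum. The within share is
#' the fraction of (covariate-adjusted) variability in the log(1+y) rate
#' attributable to day-to-day variation inside individuals rather than to
#' stable differences between them.
#'
#' @param model an "riFit" from [fitRandomIntercept()].
#' @return list with sigma2_between, sigma2_within, between_share,
#'   within_share.
#' @export
varianceShares <- function(model) {
  stopifnot(inherits(model, "riFit"))
  vc <- lme4::VarCorr(model$fit)
  s2b <- as.numeric(vc$participant_id)
  s2w <- attr(vc, "sc")^2
  tot <- s2b + s2w
  list(sigma2_between = s2b, sigma2_within = s2w,
       between_share = s2b / tot, within_share = s2w / tot)
}

#' Comparator covariate profile
#'
#' The reference against which percentage contributions are computed: a
#' 50-year-old male reporting contacts on a Monday in the first study wave,
#' with a household size of one and a single contact location.
#'
#' @return named list of covariate values.
#' @export
comparatorProfile <- function() {
  list(age_group = "40-64", age_years = 50, sex = "male", weekday = "Mon",
       wave = "R1", location_category = "1", household_size = 1)
}

.profileRow <- function(model, profile) {
  base <- comparatorProfile()
  base[names(profile)] <- profile
  if (!is.null(base$age_years) && !"age_group" %in% names(profile))
    base$age_group <- as.character(.participantAgeGroup(base$age_years))
  need <- model$covariates
  missing <- setdiff(need, names(base))
  if (length(missing))
    .stopf("profile does not specify fixed effect(s): %s",
           paste(missing, collapse = ", "))
  row <- as.data.frame(base[need], stringsAsFactors = FALSE)
  names(row) <- need
  ## align factor levels with the fitted model frame so prediction design
  ## matrices have the full contrast structure
  for (cov in need) {
    col <- model$data[[cov]]
    if (is.factor(col)) {
      if (!row[[cov]] %in% levels(col))
        .stopf("level '%s' of %s was not in the fitted data", row[[cov]], cov)
      row[[cov]] <- factor(row[[cov]], levels = levels(col))
    }
  }
  row
}

#' Percentage contribution of a covariate profile
#'
#' Predicts the response-scale rate (back-transforming the model's log(1+y)
#' prediction with exp(.) - 1, random intercept set to zero) for a covariate
#' profile and expresses it as a percentage of the prediction for a
#' comparator profile. 100\% means the profile is predicted to report the
#' same rate as the comparator.
#'
#' @param model an "riFit".
#' @param profile named list of covariate values; unspecified entries fall
#'   back to the comparator's values.
#' @param comparator named list of covariate values (default
#'   [comparatorProfile()]).
#' @return the percentage (a single number).
#' @export
percentageContribution <- function(model, profile,
                                   comparator = comparatorProfile()) {
  stopifnot(inherits(model, "riFit"))
  ndp <- .profileRow(model, profile)
  ndc <- .profileRow(model, comparator)
  pr <- stats::predict(model$fit, newdata = ndp, re.form = NA)
  cr <- stats::predict(model$fit, newdata = ndc, re.form = NA)
  unname(100 * expm1(pr) / expm1(cr))
}

#' Percentage contributions for every level of the model's covariates
#'
#' Varies one covariate at a time away from the comparator profile and
#' tabulates the percentage contribution of each level.
#'
#' @param model an "riFit".
#' @param comparator comparator profile.
#' @return data.frame with covariate, level, percentage.
#' @export
contributionTable <- function(model, comparator = comparatorProfile()) {
  stopifnot(inherits(model, "riFit"))
  rows <- list()
  for (cov in model$covariates) {
    col <- model$data[[cov]]
    lev <- if (is.factor(col)) levels(col) else
      sort(unique(stats::na.omit(col)))
    for (l in lev) {
      prof <- stats::setNames(list(l), cov)
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = cov, level = as.character(l),
        percentage = percentageContribution(model, prof, comparator),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

## Participants x waves matrix of a rate, restricted to participants observed
## in every wave of the table.
.completeWaveMatrix <- function(rates, variable) {
  wv <- sort(unique(as.character(rates$wave)))
  x <- rates[[variable]]
  keep <- !is.na(x)
  tab <- tapply(x[keep], list(rates$participant_id[keep],
                              as.character(rates$wave)[keep]), mean)
  tab <- tab[, wv, drop = FALSE]
  tab[stats::complete.cases(tab), , drop = FALSE]
}

## Permute each column independently (destroys within-participant linkage,
## preserves each wave's marginal distribution exactly).
.permuteColumns <- function(m) {
  for (j in seq_len(ncol(m))) m[, j] <- m[sample.int(nrow(m)), j]
  m
}

#' Accumulation of contact rates over waves versus a permutation null
#'
#' For participants observed in all waves, accumulates a per-diary rate over
#' horizons of 1..W waves and measures the between-participant coefficient of
#' variation of the cumulative sum at each horizon. If individuals re-draw
#' their contacts independently each wave, this CV shrinks like 1/sqrt(W);
#' persistent individual differences slow the shrinkage. The null model
#' permutes each wave's observations across participants, removing
#' within-participant dependence while preserving every wave's marginal
#' distribution, and is summarised by a Monte-Carlo envelope.
#'
#' @param rates rate table.
#' @param variable rate column.
#' @param nullReps number of permutation replicates.
#' @param seed integer seed.
#' @return object of class "accumulationResult": list with horizons,
#'   observed_cv, null_mean, null_low, null_high (2.5/97.5 percentiles),
#'   nullReps, nParticipants.
#' @export
accumulationAnalysis <- function(rates, variable = "K", nullReps = 200L,
                                 seed = 1L) {
  m <- .completeWaveMatrix(rates, variable)
  if (nrow(m) < 2) .stopf("fewer than 2 participants with all waves")
  W <- ncol(m)
  cumcv <- function(mm) {
    cs <- t(apply(mm, 1, cumsum))
    if (W == 1) cs <- matrix(cs, ncol = 1)
    apply(cs, 2, function(v) stats::sd(v) / mean(v))
  }
  observed <- cumcv(m)
  set.seed(.childSeed(seed, 4L))
  nulls <- matrix(NA_real_, nullReps, W)
  for (r in seq_len(nullReps)) nulls[r, ] <- cumcv(.permuteColumns(m))
  structure(list(
    horizons = seq_len(W),
    observed_cv = unname(observed),
    null_mean = colMeans(nulls),
    null_low = apply(nulls, 2, stats::quantile, probs = 0.025, names = FALSE),
    null_high = apply(nulls, 2, stats::quantile, probs = 0.975, names = FALSE),
    nullReps = nullReps, nParticipants = nrow(m), variable = variable
  ), class = "accumulationResult")
}

#' Quantile consistency of individual contact rates across waves
#'
#' For participants observed in all W waves, assigns each participant a
#' within-wave quantile bin of the rate (q equal-count bins; ties broken by
#' first occurrence) and computes the percentage of participants whose bin is
#' identical in every wave, over a grid of quantile counts q. Under
#' independent waves this consistency converges to 100 * (1/q)^(W-1); the
#' same permutation null as [accumulationAnalysis()] provides the reference
#' distribution.
#'
#' @param rates rate table.
#' @param variable rate column.
#' @param nQuantiles integer vector, the grid of quantile counts.
#' @param nullReps permutation replicates.
#' @param seed integer seed.
#' @return object of class "quantileConsistency": list with nQuantiles,
#'   observed (percent), null_mean, null_low, null_high, nullReps,
#'   nParticipants.
#' @export
quantileConsistency <- function(rates, variable = "K", nQuantiles = 2:10,
                                nullReps = 200L, seed = 1L) {
  m <- .completeWaveMatrix(rates, variable)
  if (nrow(m) < 2) .stopf("fewer than 2 participants with all waves")
  consist <- function(mm, q) {
    memb <- apply(mm, 2, .ntile, q = q)
    100 * mean(apply(memb, 1, function(v) all(v == v[1])))
  }
  observed <- vapply(nQuantiles, function(q) consist(m, q), numeric(1))
  set.seed(.childSeed(seed, 5L))
  nulls <- matrix(NA_real_, nullReps, length(nQuantiles))
  for (r in seq_len(nullReps)) {
    mp <- .permuteColumns(m)
    nulls[r, ] <- vapply(nQuantiles, function(q) consist(mp, q), numeric(1))
  }
  structure(list(
    nQuantiles = nQuantiles, observed = observed,
    null_mean = colMeans(nulls),
    null_low = apply(nulls, 2, stats::quantile, probs = 0.025, names = FALSE),
    null_high = apply(nulls, 2, stats::quantile, probs = 0.975, names = FALSE),
    nullReps = nullReps, nParticipants = nrow(m), variable = variable
  ), class = "quantileConsistency")
}
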