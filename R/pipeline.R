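#' Pipeline configuration
#'
#' Bundles inputs, tuning parameters and replicate counts for a full run of
#' the diary analysis pipeline.
#'
#' @param inputDir directory with participants.csv / diaries.csv / events.csv;
#'   NULL to generate a synthetic panel instead.
#' @param synthetic a [syntheticConfig()] used when inputDir is NULL.
#' @param censusFile path to a census CSV; NULL uses [defaultCensus()].
#' @param categories duration category table.
#' @param nBoot mixing bootstrap resamples.
#' @param nReplicates duration imputation replicates.
#' @param nullReps permutation null replicates.
#' @param responses responses to model in the longitudinal stage.
#' @param typicalOnly restrict summaries/longitudinal stages to typical days.
#' @param stages character vector of stages to run (subset of data, rates,
#'   duration, summaries, mixing, longitudinal).
#' @return list of class "pipelineConfig".
#' @export
pipelineConfig <- function(inputDir = NULL, synthetic = syntheticConfig(),
                           censusFile = NULL,
                           categories = durationCategories(),
                           nBoot = 1000L, nReplicates = 200L,
                           nullReps = 200L,
                           responses = c("K", "D", "L"),
                           typicalOnly = FALSE,
                           stages = c("data", "rates", "duration",
                                      "summaries", "mixing",
                                      "longitudinal")) {
  if (nBoot < 1 || nReplicates < 1 || nullReps < 1)
    .stopf("replicate counts must be >= 1")
  structure(list(inputDir = inputDir, synthetic = synthetic,
                 censusFile = censusFile, categories = categories,
                 nBoot = as.integer(nBoot),
                 nReplicates = as.integer(nReplicates),
                 nullReps = as.integer(nullReps), responses = responses,
                 typicalOnly = typicalOnly, stages = stages),
            class = "pipelineConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

.writeJSON <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
}

#' Run the full diary analysis pipeline
#'
#' Executes the pipeline stages -- input (read or synthesise the panel and
#' census), rate derivation, duration modelling and imputation, population
#' summaries, mixing matrices with bootstrap CIs plus next-generation growth
#' ranking, and longitudinal models with variance decomposition, percentage
#' contributions, accumulation and quantile-consistency analyses -- writing
#' all outputs and a run manifest (versions, seed, config hash) to outDir.
#' Deterministic given the seed. Any stage failure aborts with the stage
#' name and cause.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if needed).
#' @param seed integer master seed for every stochastic stage.
#' @return invisibly, a list with the in-memory results (panel, rates,
#'   summaries, mixing, durationModel, models, accumulation, quantiles,
#'   manifest).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir, seed = 1L) {
  stopifnot(inherits(config, "pipelineConfig"))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  res <- list()
  on <- function(s) s %in% config$stages

  panel <- census <- NULL
  if (on("data")) .stage("data", {
    panel <- if (!is.null(config$inputDir))
      readDiaryPanel(config$inputDir)
    else
      generatePanel(config = config$synthetic, seed = seed)
    census <- if (!is.null(config$censusFile)) {
      if (!file.exists(config$censusFile))
        .stopf("census input not found: %s", config$censusFile)
      readCensus(config$censusFile)
    } else defaultCensus()
    res$panel <- panel
  })

  rates <- NULL
  if (on("rates")) .stage("rates", {
    rates <- deriveRates(panel)
    writeRateTable(rates, file.path(outDir, "rates.csv"))
    res$rates <- rates
  })

  if (on("duration")) .stage("duration", {
    counts <- durationCategoryCounts(panel, config$categories)
    model <- fitCensoredExponential(counts, config$categories)
    imp <- imputeDurations(panel, model, config$categories,
                           nReplicates = config$nReplicates, seed = seed)
    td <- totalDuration(imp)
    rates <- addDurations(rates, td)
    writeRateTable(rates, file.path(outDir, "rates.csv"))
    utils::write.csv(td, file.path(outDir, "durations.csv"),
                     row.names = FALSE)
    .writeJSON(list(rate_per_minute = model@rate,
                    mean_duration_minutes = 1 / model@rate,
                    log_likelihood = model@logLik,
                    iterations = model@nIterations,
                    converged = model@converged,
                    categories = config$categories,
                    n_replicates = config$nReplicates),
               file.path(outDir, "duration_model.json"))
    res$durationModel <- model
    res$rates <- rates
  })

  srates <- rates
  if (isTRUE(config$typicalOnly) && !is.null(rates))
    srates <- typicalDayFilter(rates)$rates

  if (on("summaries")) .stage("summaries", {
    wv <- sort(unique(srates$wave))
    pairs <- if (length(wv) >= 2) utils::combn(wv, 2, simplify = FALSE)
             else list()
    vars <- intersect(c("K", "D", "L"), names(srates))
    vars <- vars[vapply(vars, function(v) any(!is.na(srates[[v]])), TRUE)]
    summ <- list(
      mean_of_participant_means =
        stats::setNames(lapply(vars, function(v)
          meanOfParticipantMeans(srates, v)), vars),
      wave_homogeneity =
        stats::setNames(lapply(vars, function(v) {
          ht <- waveHomogeneityTest(srates, v)
          list(statistic = ht$statistic, df = ht$df, p_value = ht$p.value)
        }), vars),
      between_wave_correlation = lapply(pairs, function(pp) {
        bw <- betweenWaveCorrelation(srates, "K", pp)
        list(waves = pp, estimate = bw$estimate, conf_int = bw$conf.int,
             n = bw$n)
      }),
      cv_correlations = participantCV(srates, vars)$correlations,
      typical_day_proportion = typicalDayFilter(rates)$proportion
    )
    .writeJSON(summ, file.path(outDir, "summaries.json"))
    res$summaries <- summ
  })

  if (on("mixing")) .stage("mixing", {
    if (is.null(census)) .stopf("census input missing")
    wv <- waves(panel)
    mm <- lapply(wv, function(w)
      bootstrapMixing(panel, census, w, nBoot = config$nBoot, seed = seed))
    names(mm) <- wv
    tabs <- do.call(rbind, lapply(mm, mixingTable))
    utils::write.csv(tabs, file.path(outDir, "mixing_matrices.csv"),
                     row.names = FALSE)
    crm <- lapply(wv, function(w) contactRateMatrix(panel, w))
    names(crm) <- wv
    gr <- ngmGrowthRank(crm)
    utils::write.csv(gr, file.path(outDir, "growth_rank.csv"),
                     row.names = FALSE)
    res$mixing <- mm
    res$growthRank <- gr
  })

  if (on("longitudinal")) .stage("longitudinal", {
    models <- list()
    varjson <- list()
    contribs <- list()
    for (resp in config$responses) {
      if (!resp %in% names(srates) || all(is.na(srates[[resp]]))) next
      fitted <- fitRandomIntercept(srates, resp)
      models[[resp]] <- fitted
      vs <- varianceShares(fitted)
      varjson[[resp]] <- vs
      ct <- contributionTable(fitted)
      ct$response <- resp
      contribs[[resp]] <- ct
    }
    .writeJSON(varjson, file.path(outDir, "variance_decomposition.json"))
    utils::write.csv(do.call(rbind, contribs),
                     file.path(outDir, "contributions.csv"),
                     row.names = FALSE)
    acc <- accumulationAnalysis(srates, "K", nullReps = config$nullReps,
                                seed = seed)
    qc <- quantileConsistency(srates, "K", nullReps = config$nullReps,
                              seed = seed)
    .writeJSON(unclass(acc), file.path(outDir, "accumulation.json"))
    .writeJSON(unclass(qc), file.path(outDir, "quantile_consistency.json"))
    res$models <- models
    res$varianceShares <- varjson
    res$accumulation <- acc
    res$quantiles <- qc
  })

  manifest <- .stage("manifest", {
    cfg_json <- file.path(outDir, "config.json")
    cfg <- unclass(config)
    cfg$synthetic <- unclass(cfg$synthetic)
    cfg$synthetic$startDate <- as.character(cfg$synthetic$startDate)
    .writeJSON(cfg, cfg_json)
    man <- list(
      package = "diarycontacts",
      version = as.character(utils::packageVersion("diarycontacts")),
      r_version = R.version.string,
      seed = seed,
      config_md5 = unname(tools::md5sum(cfg_json)),
      stages = config$stages,
      created = "run manifest"
    )
    .writeJSON(man, file.path(outDir, "manifest.json"))
    man
  })
  res$manifest <- manifest
  invisible(res)
}
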