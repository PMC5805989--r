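#' Accessors for DiaryPanel tables
#'
#' @param object a [DiaryPanel-class].
#' @return the corresponding data.frame (`participants`, `diaries`, `events`,
#'   `rejectedRows`) or character vector of flagged participant ids
#'   (`excludedParticipants`).
#' @name panel-accessors
#' @aliases participants diaries events rejectedRows excludedParticipants
NULL

#' @rdname panel-accessors
#' @export
setGeneric("participants", function(object) standardGeneric("participants"))
#' @rdname panel-accessors
#' @export
setGeneric("diaries", function(object) standardGeneric("diaries"))
#' @rdname panel-accessors
#' @export
setGeneric("events", function(object) standardGeneric("events"))
#' @rdname panel-accessors
#' @export
setGeneric("rejectedRows", function(object) standardGeneric("rejectedRows"))
#' @rdname panel-accessors
#' @export
setGeneric("excludedParticipants",
           function(object) standardGeneric("excludedParticipants"))

#' @rdname panel-accessors
#' @export
setMethod("participants", "DiaryPanel", function(object) object@participants)
#' @rdname panel-accessors
#' @export
setMethod("diaries", "DiaryPanel", function(object) object@diaries)
#' @rdname panel-accessors
#' @export
setMethod("events", "DiaryPanel", function(object) object@events)
#' @rdname panel-accessors
#' @export
setMethod("rejectedRows", "DiaryPanel", function(object) object@rejected)
#' @rdname panel-accessors
#' @export
setMethod("excludedParticipants", "DiaryPanel", function(object) object@excluded)

#' Waves present in a panel
#'
#' @param object a [DiaryPanel-class].
#' @return sorted character vector of wave labels with at least one diary.
#' @export
setGeneric("waves", function(object) standardGeneric("waves"))

#' @rdname waves
#' @export
setMethod("waves", "DiaryPanel", function(object) {
  sort(unique(as.character(object@diaries$wave)))
})

setMethod("show", "DiaryPanel", function(object) {
  cat("DiaryPanel\n")
  cat("  participants:", nrow(object@participants), "\n")
  cat("  diaries:     ", nrow(object@diaries),
      sprintf("(waves: %s)\n", paste(waves(object), collapse = ", ")))
  cat("  events:      ", nrow(object@events), "\n")
  if (nrow(object@rejected))
    cat("  rejected input rows:", nrow(object@rejected), "\n")
  if (length(object@excluded))
    cat("  participants flagged for exclusion:", length(object@excluded), "\n")
  invisible(object)
})

#' Mixing ratio accessors
#'
#' @param object a [MixingMatrix-class].
#' @return `mixingRatios`: the ratio matrix; `mixingCI`: list with `low` and
#'   `high` matrices (NULL when no bootstrap was run).
#' @name mixing-accessors
NULL

#' @rdname mixing-accessors
#' @export
setGeneric("mixingRatios", function(object) standardGeneric("mixingRatios"))
#' @rdname mixing-accessors
#' @export
setGeneric("mixingCI", function(object) standardGeneric("mixingCI"))

#' @rdname mixing-accessors
#' @export
setMethod("mixingRatios", "MixingMatrix", function(object) object@ratio)
#' @rdname mixing-accessors
#' @export
setMethod("mixingCI", "MixingMatrix", function(object) {
  if (!nrow(object@ciLow)) return(NULL)
  list(low = object@ciLow, high = object@ciHigh)
})

setMethod("show", "MixingMatrix", function(object) {
  cat(sprintf("MixingMatrix (wave %s, %s contacts%s)\n", object@wave,
              object@filter,
              if (object@nBoot > 0)
                sprintf(", %d bootstrap resamples", object@nBoot) else ""))
  print(round(object@ratio, 3))
  invisible(object)
})

#' Fitted exponential rate of a duration model
#'
#' @param object a [DurationModel-class].
#' @return the rate per minute.
#' @export
setGeneric("durationRate", function(object) standardGeneric("durationRate"))

#' @rdname durationRate
#' @export
setMethod("durationRate", "DurationModel", function(object) object@rate)

setMethod("show", "DurationModel", function(object) {
  cat("DurationModel (interval-censored exponential, EM fit)\n")
  cat(sprintf("  rate: %.6g per minute (mean duration %.1f min)\n",
              object@rate, 1 / object@rate))
  cat(sprintf("  log-likelihood: %.4f after %d iterations (%s)\n",
              object@logLik, object@nIterations,
              if (object@converged) "converged" else "NOT converged"))
  invisible(object)
})

setMethod("show", "ImputationSet", function(object) {
  cat("ImputationSet\n")
  cat(sprintf("  events: %d, replicates: %d, rate: %.6g per minute\n",
              nrow(object@draws), ncol(object@draws), object@rate))
  cat(sprintf("  diaries: %d (totals in hours)\n", nrow(object@diaryTotals)))
  invisible(object)
})
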