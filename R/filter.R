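## The seven filtering methods and the stage-wise cascade.

.METHOD_TABLE <- list(
  I   = list(thr = 0.05, cmp = "ge", cf = 0.9, gc = 0.7),
  II  = list(thr = 0.05, cmp = "eq", cf = 1.0, gc = 0.7),
  III = list(thr = 0.15, cmp = "ge", cf = 0.9, gc = 0.7),
  IV  = list(thr = 0.15, cmp = "eq", cf = 1.0, gc = 0.7),
  V   = list(thr = 0.25, cmp = "ge", cf = 0.9, gc = 0.7),
  VI  = list(thr = 0.25, cmp = "eq", cf = 1.0, gc = 0.7),
  VII = list(thr = 0.25, cmp = "eq", cf = 1.0, gc = NA_real_)
)

#' Built-in filter-method configurations
#'
#' Seven named methods covering the crossed design of no-call threshold
#' (0.05 / 0.15 / 0.25) and call-frequency rule (`>= 0.9` / exactly 1), all
#' with average GC `>= 0.7` except method VII (average GC disabled) and all
#' with GenTrain `>= 0.25`. Retained-MAF levels are 0.01 and 0.05.
#'
#' @param name one of `"I"` .. `"VII"`.
#' @return a [MethodConfig].
#' @examples
#' methodConfig("VI")
#' @export
methodConfig <- function(name) {
  stopIfNot(length(name) == 1L && name %in% names(.METHOD_TABLE),
            paste0("unknown method '", name,
                   "'; built-ins are ", paste(names(.METHOD_TABLE),
                                              collapse = ", ")))
  p <- .METHOD_TABLE[[name]]
  new("MethodConfig", name = name, noCallThreshold = p$thr,
      callFreqComparator = p$cmp, callFreqValue = p$cf,
      avgGcMin = p$gc, genTrainMin = 0.25, mafLevels = c(0.01, 0.05))
}

.mafStageName <- function(level) paste0("maf_", format(level, trim = TRUE))

#' Apply one filter method as a stage-wise cascade
#'
#' Stages are applied conjunctively in order call frequency, average GC,
#' GenTrain, then each retained-MAF level, so each stage's surviving set is
#' nested in the previous one. The `= 1` call-frequency rule is the exact
#' integer condition "zero no-calls", never a floating comparison. A SNP with
#' undefined average GC or MAF (nothing called / monomorphic) fails the
#' corresponding stage. When the method disables average GC the stage passes
#' everything through (recorded for count parity across methods).
#'
#' @param metrics per-SNP metrics from [snpMetrics()], computed at the
#'   method's own no-call threshold -- a mismatch is an error.
#' @param config a [MethodConfig].
#' @return a [CascadeResult].
#' @export
applyMethod <- function(metrics, config) {
  stopIfNot(is(config, "MethodConfig"), "config must be a MethodConfig")
  if (nrow(metrics) > 0L &&
      !all(metrics$threshold_used == config@noCallThreshold)) {
    stop("metrics were computed at no-call threshold ",
         unique(metrics$threshold_used)[1], " but method ", config@name,
         " requires ", config@noCallThreshold, call. = FALSE)
  }
  ids <- as.character(metrics$snp_id)
  passCf <- if (config@callFreqComparator == "eq") metrics$n_nocall == 0L
            else metrics$call_frequency >= config@callFreqValue
  passGc <- if (is.na(config@avgGcMin)) rep(TRUE, nrow(metrics))
            else !is.na(metrics$avg_gc) & metrics$avg_gc >= config@avgGcMin
  passGt <- metrics$gentrain >= config@genTrainMin
  stages <- list(call_frequency = ids[passCf])
  keep <- passCf & passGc
  stages$avg_gc <- ids[keep]
  keep <- keep & passGt
  stages$gentrain <- ids[keep]
  for (lev in sort(config@mafLevels)) {
    keep <- keep & !is.na(metrics$maf) & metrics$maf >= lev
    stages[[.mafStageName(lev)]] <- ids[keep]
  }
  new("CascadeResult", methodName = config@name,
      threshold = config@noCallThreshold, stages = stages)
}

#' Run several filter methods on one call set
#'
#' Recomputes metrics once per distinct no-call threshold, then applies each
#' method's cascade.
#'
#' @param x a [SnpCallSet].
#' @param names method names (default: all seven built-ins).
#' @return named list of [CascadeResult], one per method.
#' @seealso [cascadeTable()] for the count matrix across methods.
#' @export
compareMethods <- function(x, names = c("I", "II", "III", "IV", "V", "VI",
                                        "VII")) {
  stopIfNot(length(names) >= 1L, "at least one method name is required")
  configs <- lapply(names, methodConfig)
  thresholds <- unique(vapply(configs, slot, numeric(1), "noCallThreshold"))
  metricsByThr <- lapply(setNames(thresholds, thresholds),
                         function(t) snpMetrics(x, t))
  res <- lapply(configs, function(cfg) {
    applyMethod(metricsByThr[[as.character(cfg@noCallThreshold)]], cfg)
  })
  setNames(res, names)
}

#' Stage-by-method count matrix for a set of cascade results
#'
#' @param cascades named list of [CascadeResult] (e.g. from
#'   [compareMethods()]).
#' @return integer matrix, stages as rows, methods as columns.
#' @export
cascadeTable <- function(cascades) {
  stages <- names(cascades[[1]]@stages)
  out <- vapply(cascades, function(cr) cascadeCounts(cr)[stages], integer(length(stages)))
  rownames(out) <- stages
  out
}

#' Write cascade counts as TSV and JSON
#' @param cascades named list of [CascadeResult].
#' @param tsvPath,jsonPath output paths (`NULL` to skip one).
#' @export
writeCascadeCounts <- function(cascades, tsvPath = NULL, jsonPath = NULL) {
  tab <- cascadeTable(cascades)
  if (!is.null(tsvPath)) {
    df <- data.frame(stage = rownames(tab), tab, check.names = FALSE)
    write.table(df, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(jsonPath)) {
    obj <- apply(tab, 2, as.list)
    writeLines(toJSON(obj, auto_unbox = TRUE, pretty = TRUE), jsonPath)
  }
  invisible(tab)
}
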