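## Central S4 containers.

#' Genotype calls with per-genotype quality scores
#'
#' `SnpCallSet` extends [SummarizedExperiment::SummarizedExperiment] with three
#' required assays: `allele1` and `allele2` (character matrices of called
#' bases, `"-"` for a vendor-level no-call) and `score` (numeric matrix of
#' per-genotype GenCall-style quality scores in \[0, 1\]). Rows are SNPs,
#' columns are samples. The SNP manifest (allele pair, probe flanks, GenTrain
#' score) travels in `rowData`.
#'
#' Vendor no-calls (`allele1 == "-"`) are kept distinct from
#' threshold-induced no-calls; both count as no-calls in every metric.
#'
#' @export
setClass("SnpCallSet", contains = "SummarizedExperiment")

setValidity("SnpCallSet", function(object) {
  msgs <- character()
  need <- c("allele1", "allele2", "score")
  if (!all(need %in% assayNames(object))) {
    return(paste("assays must include", paste(need, collapse = ", ")))
  }
  a1 <- assay(object, "allele1")
  a2 <- assay(object, "allele2")
  sc <- assay(object, "score")
  if (!is.numeric(sc)) msgs <- c(msgs, "'score' assay must be numeric")
  else if (any(sc < 0 | sc > 1, na.rm = TRUE)) {
    msgs <- c(msgs, "genotype scores must lie in [0, 1]")
  }
  if (any(is.na(sc))) msgs <- c(msgs, "genotype scores must not be NA")
  if (!identical(a1 == "-", a2 == "-")) {
    msgs <- c(msgs, "allele1 is '-' iff allele2 is '-' (vendor no-call)")
  }
  rd <- rowData(object)
  needRd <- c("allele_a", "allele_b", "gentrain")
  if (!all(needRd %in% colnames(rd))) {
    msgs <- c(msgs, paste("rowData must carry", paste(needRd, collapse = ", ")))
  } else {
    if (any(rd$allele_a == rd$allele_b)) {
      msgs <- c(msgs, "manifest allele_a must differ from allele_b")
    }
    if (any(rd$gentrain < 0 | rd$gentrain > 1, na.rm = TRUE)) {
      msgs <- c(msgs, "gentrain scores must lie in [0, 1]")
    }
    okA <- a1 == "-" | a1 == matrix(rd$allele_a, nrow(a1), ncol(a1)) |
      a1 == matrix(rd$allele_b, nrow(a1), ncol(a1))
    okB <- a2 == "-" | a2 == matrix(rd$allele_a, nrow(a2), ncol(a2)) |
      a2 == matrix(rd$allele_b, nrow(a2), ncol(a2))
    if (!all(okA) || !all(okB)) {
      msgs <- c(msgs, "called alleles must belong to the SNP's manifest pair")
    }
  }
  if (ncol(object) < 1L) msgs <- c(msgs, "at least one sample is required")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SnpCallSet
#'
#' @param allele1,allele2 character matrices (SNPs x samples) of called
#'   alleles; `"-"` marks a vendor no-call in both.
#' @param score numeric matrix of per-genotype quality scores in \[0, 1\].
#' @param manifest a [S4Vectors::DataFrame] (or data.frame) of manifest
#'   records as returned by [readSnpManifest()]; must contain `snp_id`,
#'   `allele_a`, `allele_b`, `gentrain` and one row per matrix row.
#' @return a validated `SnpCallSet`.
#' @examples
#' m <- S4Vectors::DataFrame(snp_id = "rs1", allele_a = "A", allele_b = "G",
#'                           gentrain = 0.8)
#' x <- SnpCallSet(matrix("A", 1, 2), matrix(c("A", "G"), 1, 2),
#'                 matrix(0.9, 1, 2), m)
#' @export
SnpCallSet <- function(allele1, allele2, score, manifest) {
  manifest <- DataFrame(manifest)
  stopIfNot(nrow(manifest) == nrow(score),
            "manifest must have one row per SNP row of the matrices")
  rn <- as.character(manifest$snp_id)
  dimn <- list(rn, colnames(score))
  dimnames(allele1) <- dimn
  dimnames(allele2) <- dimn
  dimnames(score) <- dimn
  rownames(manifest) <- rn
  se <- SummarizedExperiment(
    assays = list(allele1 = allele1, allele2 = allele2, score = score),
    rowData = manifest)
  new("SnpCallSet", se)
}

#' @describeIn SnpCallSet SNP identifiers (row names).
#' @param x a `SnpCallSet`.
#' @export
snpIds <- function(x) rownames(x)

#' @describeIn SnpCallSet sample identifiers (column names).
#' @export
sampleIds <- function(x) colnames(x)

#' @describeIn SnpCallSet numeric matrix of per-genotype quality scores.
#' @export
callScores <- function(x) assay(x, "score")

#' @describeIn SnpCallSet per-SNP GenTrain scores, named by SNP id.
#' @export
genTrainScores <- function(x) setNames(rowData(x)$gentrain, rownames(x))

#' @describeIn SnpCallSet character matrix of diploid genotype classes
#'   (`"AA"`, `"AB"`, `"BB"`; `NA` for a vendor no-call), classified against
#'   the manifest allele pair.
#' @export
genotypeMatrix <- function(x) {
  a1 <- assay(x, "allele1")
  a2 <- assay(x, "allele2")
  aA <- matrix(rowData(x)$allele_a, nrow(x), ncol(x))
  nB <- (a1 != aA) + (a2 != aA)
  g <- matrix(c("AA", "AB", "BB")[nB + 1L], nrow(x), ncol(x),
              dimnames = dimnames(a1))
  g[a1 == "-"] <- NA_character_
  g
}

setMethod("show", "SnpCallSet", function(object) {
  cat("SnpCallSet:", nrow(object), "SNPs x", ncol(object), "samples\n")
  vendor <- sum(assay(object, "allele1") == "-")
  cat("  vendor no-calls:", vendor, "\n")
  cat("  score range: [",
      paste(signif(range(assay(object, "score")), 3), collapse = ", "),
      "]\n", sep = "")
})

#' Filter-method configuration
#'
#' One of the seven filtering methods (I-VII): a no-call threshold under which
#' per-genotype scores are treated as missing, a call-frequency rule (either
#' `>= value` or the exact `= 1`, implemented as zero no-calls), an optional
#' average-GC minimum, a GenTrain minimum and the retained-MAF levels.
#'
#' @slot name method label ("I".."VII" for the built-ins).
#' @slot noCallThreshold GenCall cutoff; scores strictly below it are no-calls.
#' @slot callFreqComparator `"ge"` or `"eq"` (exact complete-call test).
#' @slot callFreqValue required call frequency (0.9 or 1 for the built-ins).
#' @slot avgGcMin minimum average GC, or `NA` when the stage is disabled.
#' @slot genTrainMin minimum per-SNP GenTrain score.
#' @slot mafLevels MAF thresholds at which retained sets are reported.
#' @export
setClass("MethodConfig", representation(
  name = "character",
  noCallThreshold = "numeric",
  callFreqComparator = "character",
  callFreqValue = "numeric",
  avgGcMin = "numeric",
  genTrainMin = "numeric",
  mafLevels = "numeric"
))

setValidity("MethodConfig", function(object) {
  msgs <- character()
  thr <- c(object@noCallThreshold, object@callFreqValue,
           object@genTrainMin, object@mafLevels)
  if (any(thr < 0 | thr > 1)) msgs <- c(msgs, "all thresholds must be in [0, 1]")
  if (!is.na(object@avgGcMin) &&
      (object@avgGcMin < 0 || object@avgGcMin > 1)) {
    msgs <- c(msgs, "avgGcMin must be in [0, 1] or NA")
  }
  if (!object@callFreqComparator %in% c("ge", "eq")) {
    msgs <- c(msgs, "callFreqComparator must be 'ge' or 'eq'")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "MethodConfig", function(object) {
  cf <- if (object@callFreqComparator == "eq") "= 1 (zero no-calls)"
        else paste(">=", object@callFreqValue)
  cat("MethodConfig", object@name, "\n",
      "  no-call threshold : >= ", object@noCallThreshold, "\n",
      "  call frequency    : ", cf, "\n",
      "  average GC        : ",
      if (is.na(object@avgGcMin)) "disabled" else paste(">=", object@avgGcMin),
      "\n",
      "  GenTrain          : >= ", object@genTrainMin, "\n",
      "  MAF levels        : ", paste(object@mafLevels, collapse = ", "),
      "\n", sep = "")
})

#' Result of a stage-wise filter cascade
#'
#' Surviving SNP-id sets after each conjunctive stage, in application order:
#' call frequency, average GC (pass-through when the method disables it),
#' GenTrain, then each retained-MAF level. Each stage's set is nested within
#' the previous one.
#'
#' @slot methodName label of the method applied.
#' @slot threshold the no-call threshold the metrics were computed under.
#' @slot stages named list of character vectors of surviving SNP ids.
#' @export
setClass("CascadeResult", representation(
  methodName = "character",
  threshold = "numeric",
  stages = "list"
))

setValidity("CascadeResult", function(object) {
  st <- object@stages
  if (length(st) > 1L) {
    for (i in seq_len(length(st) - 1L)) {
      if (!all(st[[i + 1L]] %in% st[[i]])) {
        return(sprintf("stage '%s' is not nested within stage '%s'",
                       names(st)[i + 1L], names(st)[i]))
      }
    }
  }
  TRUE
})

#' @describeIn CascadeResult per-stage surviving counts (named integer).
#' @param x a `CascadeResult`.
#' @export
cascadeCounts <- function(x) {
  vapply(x@stages, length, integer(1))
}

#' @describeIn CascadeResult surviving SNP ids at a stage (default: the final
#'   stage of the cascade).
#' @param stage stage name, e.g. `"call_frequency"` or `"maf_0.01"`.
#' @export
survivors <- function(x, stage = NULL) {
  if (is.null(stage)) stage <- names(x@stages)[length(x@stages)]
  stopIfNot(stage %in% names(x@stages),
            paste0("unknown cascade stage '", stage, "'"))
  x@stages[[stage]]
}

setMethod("show", "CascadeResult", function(object) {
  cat("CascadeResult for method", object@methodName,
      "(no-call threshold", object@threshold, ")\n")
  n <- cascadeCounts(object)
  for (i in seq_along(n)) {
    cat(sprintf("  %-16s %d\n", names(n)[i], n[i]))
  }
})
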