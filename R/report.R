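## Derived statistics in the style the study field reports them:
## percentages of assayed SNPs, stage reductions, and observed-vs-expected
## polymorphism proportions. All rounding is half-away-from-zero.

#' Reporting configuration
#'
#' @param totalAssayed number of SNPs assayed on the array (default 777962,
#'   the bovine HD chip content).
#' @param divergenceTimeMyr evolutionary divergence between source and target
#'   species in million years (default 42.7, cattle vs alpaca); carried for
#'   reporting only.
#' @param expectedPolymorphicFraction expected proportion of polymorphic SNPs
#'   at this divergence, on the same printed convention as the observed
#'   proportions (default 0.000515); an input, typically from an
#'   exponential-decay model of polymorphism retention over divergence time.
#' @param percentDigits decimal places for percentages (default 1).
#' @param fractionDigits decimal places for polymorphism proportions
#'   (default 6).
#' @return a named list of class `ReportConfig`.
#' @export
reportConfig <- function(totalAssayed = 777962L, divergenceTimeMyr = 42.7,
                         expectedPolymorphicFraction = 0.000515,
                         percentDigits = 1L, fractionDigits = 6L) {
  stopIfNot(totalAssayed > 0L, "totalAssayed must be positive")
  stopIfNot(expectedPolymorphicFraction > 0 &&
              expectedPolymorphicFraction < 1,
            "expectedPolymorphicFraction must be in (0, 1)")
  structure(list(totalAssayed = as.integer(totalAssayed),
                 divergenceTimeMyr = divergenceTimeMyr,
                 expectedPolymorphicFraction = expectedPolymorphicFraction,
                 percentDigits = as.integer(percentDigits),
                 fractionDigits = as.integer(fractionDigits)),
            class = "ReportConfig")
}

#' Percentage of a total
#'
#' `100 * count / total`, rounded half away from zero to `dp` decimals.
#'
#' @param count,total non-negative counts, `count <= total`, `total > 0`.
#' @param dp decimal places.
#' @return percentage.
#' @examples
#' percentOfTotal(530106, 777962)  # 68.1
#' @export
percentOfTotal <- function(count, total, dp = 1L) {
  stopIfNot(all(total > 0), "total must be positive")
  stopIfNot(all(count >= 0 & count <= total),
            "count must lie in [0, total]")
  roundHalfAway(100 * count / total, dp)
}

#' Stage reduction percentage
#'
#' `100 * (1 - after / before)`, rounded half away from zero to `dp`
#' decimals.
#'
#' @param before,after counts with `0 <= after <= before`, `before > 0`.
#' @param dp decimal places.
#' @return percentage reduction.
#' @examples
#' reductionPercent(23429, 6756)      # 71.2
#' reductionPercent(22435, 1970, 0)   # 91
#' @export
reductionPercent <- function(before, after, dp = 1L) {
  stopIfNot(all(before > 0), "'before' must be positive")
  stopIfNot(all(after >= 0 & after <= before),
            "'after' must lie in [0, before]")
  roundHalfAway(100 * (1 - after / before), dp)
}

#' Observed polymorphism proportion and observed/expected ratio
#'
#' The observed proportion is `nPoly / totalAssayed`, reported to
#' `fractionDigits` decimals (the field's convention labels this raw ratio
#' with a percent sign; the number itself is the ratio). The ratio compares
#' it to an expected proportion on the same convention.
#'
#' @param nPoly number of polymorphic SNPs.
#' @param totalAssayed SNPs assayed.
#' @param expectedFraction expected proportion (same convention), > 0.
#' @param fractionDigits decimals for the reported observed proportion.
#' @return list with `observed_fraction` (rounded) and `ratio`
#'   (observed / expected, unrounded input fractions).
#' @examples
#' polymorphismRate(6756, 777962, 0.000515)$observed_fraction  # 0.008684
#' @export
polymorphismRate <- function(nPoly, totalAssayed, expectedFraction,
                             fractionDigits = 6L) {
  stopIfNot(expectedFraction > 0, "expectedFraction must be positive")
  stopIfNot(nPoly <= totalAssayed, "nPoly cannot exceed totalAssayed")
  obs <- nPoly / totalAssayed
  list(observed_fraction = roundHalfAway(obs, fractionDigits),
       ratio = obs / expectedFraction)
}

#' Assemble the structured end-of-pipeline report
#'
#' Collects every stage's counts and derived percentages into one
#' deterministic nested list, shaped like the field's summary tables: a
#' methods-by-stages count block, a per-genome uniqueness block
#' (multi-scaffold / multi-within-scaffold / unique / absent), the
#' cross-genome retained count, chromosome assignment and gene annotation
#' tallies, conservation and Hardy-Weinberg summaries, and polymorphism
#' proportions. Missing stages (`NULL` arguments) leave explicit `NA` gaps
#' rather than failing.
#'
#' @param cascades named list of [CascadeResult] (or `NULL`).
#' @param uniqueness named list of uniqueness tables (one per genome) from
#'   [classifyUniqueness()] (or `NULL`).
#' @param retained character vector of retained SNP ids (or `NULL`).
#' @param assignments chromosome assignment table (or `NULL`).
#' @param annotations nearest-gene table (or `NULL`).
#' @param conservation named logical vector of per-SNP conservation flags
#'   (or `NULL`).
#' @param hwe per-SNP metrics rows of the retained set, for equilibrium
#'   reporting (or `NULL`).
#' @param config a [reportConfig()].
#' @return nested list ready for JSON serialisation.
#' @export
buildSummary <- function(cascades = NULL, uniqueness = NULL, retained = NULL,
                         assignments = NULL, annotations = NULL,
                         conservation = NULL, hwe = NULL,
                         config = reportConfig()) {
  rep <- list(config = list(
    total_assayed = config$totalAssayed,
    divergence_time_myr = config$divergenceTimeMyr,
    expected_polymorphic_fraction = config$expectedPolymorphicFraction))

  if (!is.null(cascades)) {
    tab <- cascadeTable(cascades)
    rep$methods <- list(
      counts = apply(tab, 2, as.list),
      percent_of_assayed = lapply(as.list(as.data.frame(tab)), function(col) {
        setNames(as.list(percentOfTotal(col, config$totalAssayed,
                                        config$percentDigits)),
                 rownames(tab))
      }))
  } else rep$methods <- NA

  if (!is.null(uniqueness)) {
    rep$genomes <- lapply(uniqueness, function(u) {
      as.list(vapply(c("multi_scaffold", "multi_within_scaffold", "unique",
                       "absent"),
                     function(cl) sum(u$class == cl), integer(1)))
    })
  } else rep$genomes <- NA

  rep$retained <- if (!is.null(retained)) list(
    n_common_to_both = length(retained),
    observed_polymorphism = polymorphismRate(
      length(retained), config$totalAssayed,
      config$expectedPolymorphicFraction, config$fractionDigits)
  ) else NA

  rep$chromosomes <- if (!is.null(assignments)) list(
    n_assigned = sum(assignments$chromosome != "unassigned"),
    n_unassigned = sum(assignments$chromosome == "unassigned"),
    distribution = as.list(chromosomeDistribution(assignments))
  ) else NA

  rep$genes <- if (!is.null(annotations)) list(
    n_within_gene = sum(annotations$within_gene, na.rm = TRUE),
    n_distinct_genes = length(unique(
      annotations$gene_id[which(annotations$within_gene)]))
  ) else NA

  rep$conservation <- if (!is.null(conservation)) list(
    n_checked = length(conservation),
    n_conserved = sum(conservation)
  ) else NA

  rep$hwe <- if (!is.null(hwe)) list(
    n_tested = sum(!is.na(hwe$hwe_in_equilibrium)),
    n_out_of_equilibrium = sum(!hwe$hwe_in_equilibrium, na.rm = TRUE)
  ) else NA

  rep
}

#' Write a summary report as JSON
#'
#' Serialisation is deterministic: identical summaries produce byte-identical
#' files.
#'
#' @param summary list from [buildSummary()].
#' @param path output JSON path.
#' @export
writeSummary <- function(summary, path) {
  writeLines(toJSON(summary, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                    na = "null"), path)
  invisible(path)
}
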