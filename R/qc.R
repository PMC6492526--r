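## Per-SNP quality metrics under a configurable no-call threshold.

#' Called-genotype mask under a no-call threshold
#'
#' A genotype is a call iff its quality score is `>= threshold` (scores
#' exactly at the threshold are calls) and it is not a vendor no-call.
#'
#' @param x a [SnpCallSet].
#' @param threshold no-call threshold in \[0, 1\].
#' @return logical matrix, `TRUE` where the genotype counts as a call.
#' @export
calledMask <- function(x, threshold) {
  stopIfNot(is.numeric(threshold) && length(threshold) == 1L &&
              threshold >= 0 && threshold <= 1,
            "threshold must be a single number in [0, 1]")
  (callScores(x) >= threshold) & (assay(x, "allele1") != "-")
}

#' Call frequency
#'
#' The number of genotype calls divided by the sum of no-calls and calls,
#' per SNP; exactly 1 iff there are zero no-calls.
#'
#' @param nCalled,nNoCall integer vectors of per-SNP call / no-call counts.
#' @return numeric vector of fractions.
#' @export
callFrequency <- function(nCalled, nNoCall) {
  tot <- nCalled + nNoCall
  stopIfNot(all(tot >= 1L), "call frequency needs at least one sample")
  nCalled / tot
}

#' GenCall score percentiles of one SNP
#'
#' 10th and 50th percentiles of quality scores across called genotypes only,
#' with linear interpolation between closest order statistics at rank
#' `p * (n - 1)` (the type-7 convention), and their simple average.
#'
#' @param scores numeric vector of called-genotype scores.
#' @return named numeric `c(gc10, gc50, avg_gc)`; all `NA` when no genotype
#'   is called (such a SNP automatically fails any average-GC filter).
#' @export
gcPercentiles <- function(scores) {
  if (length(scores) == 0L) {
    return(c(gc10 = NA_real_, gc50 = NA_real_, avg_gc = NA_real_))
  }
  q <- quantile(scores, c(0.1, 0.5), type = 7, names = FALSE)
  c(gc10 = q[1], gc50 = q[2], avg_gc = (q[1] + q[2]) / 2)
}

#' Minor allele frequency from genotype counts
#'
#' `maf = min(countA, countB) / (2 * n)` with `countA = 2 * nAA + nAB`,
#' over called genotypes.
#'
#' @param nAA,nAB,nBB genotype counts (vectorised).
#' @return MAF in \[0, 0.5\]; `NA` where no genotype is called.
#' @export
minorAlleleFrequency <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  countA <- 2 * nAA + nAB
  countB <- 2 * nBB + nAB
  ifelse(n == 0L, NA_real_, pmin(countA, countB) / (2 * n))
}

#' Hardy-Weinberg chi-square test from genotype counts
#'
#' One-degree-of-freedom chi-square of observed genotype counts against
#' Hardy-Weinberg expectations computed from the sample allele frequencies,
#' without continuity correction. Monomorphic SNPs (one allele absent) are
#' not testable and return `NA` throughout -- never "failed".
#'
#' @param nAA,nAB,nBB genotype counts (vectorised).
#' @param alpha significance level for the equilibrium flag.
#' @return data.frame with columns `chi2`, `p`, `in_equilibrium` (logical,
#'   `NA` when not applicable).
#' @export
hweTest <- function(nAA, nAB, nBB, alpha = 0.05) {
  n <- nAA + nAB + nBB
  countA <- 2 * nAA + nAB
  countB <- 2 * nBB + nAB
  applicable <- n > 0L & countA > 0L & countB > 0L
  p <- countA / (2 * n)
  q <- 1 - p
  eAA <- n * p^2
  eAB <- n * 2 * p * q
  eBB <- n * q^2
  chi2 <- (nAA - eAA)^2 / eAA + (nAB - eAB)^2 / eAB + (nBB - eBB)^2 / eBB
  chi2[!applicable] <- NA_real_
  pval <- pchisq(chi2, df = 1, lower.tail = FALSE)
  data.frame(chi2 = chi2, p = pval,
             in_equilibrium = ifelse(applicable, pval >= alpha, NA))
}

#' Per-SNP quality metrics table
#'
#' Applies the no-call threshold, then computes for every SNP: call counts
#' and call frequency, the 10th/50th GenCall percentiles and their average,
#' genotype counts, minor allele frequency and the Hardy-Weinberg test.
#' Per-SNP undefined states (no called genotype, monomorphic) propagate as
#' `NA` flags; the batch never aborts.
#'
#' @param x a [SnpCallSet].
#' @param threshold no-call threshold in \[0, 1\].
#' @return a [S4Vectors::DataFrame], one row per SNP, with
#'   `threshold_used` recording the threshold (guarded by [applyMethod()]).
#' @export
snpMetrics <- function(x, threshold) {
  mask <- calledMask(x, threshold)
  sc <- callScores(x)
  geno <- genotypeMatrix(x)
  geno[!mask] <- NA_character_
  nCalled <- as.integer(rowSums(mask))
  nNoCall <- ncol(x) - nCalled
  nAA <- as.integer(rowSums(geno == "AA", na.rm = TRUE))
  nAB <- as.integer(rowSums(geno == "AB", na.rm = TRUE))
  nBB <- as.integer(rowSums(geno == "BB", na.rm = TRUE))
  gc <- t(vapply(seq_len(nrow(x)),
                 function(i) gcPercentiles(sc[i, mask[i, ]]),
                 numeric(3)))
  hwe <- hweTest(nAA, nAB, nBB)
  DataFrame(
    snp_id = rownames(x),
    threshold_used = rep(threshold, nrow(x)),
    n_called = nCalled,
    n_nocall = nNoCall,
    call_frequency = callFrequency(nCalled, nNoCall),
    gc10 = gc[, 1], gc50 = gc[, 2], avg_gc = gc[, 3],
    gentrain = rowData(x)$gentrain,
    n_AA = nAA, n_AB = nAB, n_BB = nBB,
    maf = minorAlleleFrequency(nAA, nAB, nBB),
    hwe_chi2 = hwe$chi2, hwe_p = hwe$p,
    hwe_in_equilibrium = hwe$in_equilibrium,
    row.names = rownames(x))
}

#' Write a per-SNP metrics table as TSV (audit output)
#' @param metrics DataFrame from [snpMetrics()].
#' @param path output TSV path.
#' @export
writeSnpMetrics <- function(metrics, path) {
  write.table(as.data.frame(metrics), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
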