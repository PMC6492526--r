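## Shared fixtures and independent oracles. All fixtures are built in code.

randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

rcChr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(s, function(x) paste(rev(comp[strsplit(x, "")[[1]]]), collapse = ""),
         "", USE.NAMES = FALSE)
}

## manifest of n SNPs with fixed or random 50-nt flanks
makeManifest <- function(n, alleleA = "A", alleleB = "G", gentrain = 0.8,
                         flankLen = 50L) {
  ids <- sprintf("rs%03d", seq_len(n))
  S4Vectors::DataFrame(
    snp_id = ids,
    allele_a = rep_len(alleleA, n), allele_b = rep_len(alleleB, n),
    flank_up = vapply(seq_len(n), function(i) randSeq(flankLen), ""),
    flank_down = vapply(seq_len(n), function(i) randSeq(flankLen), ""),
    gentrain = rep_len(gentrain, n),
    source_chrom = NA_character_, source_pos = NA_integer_,
    eligible26 = flankLen >= 25L, row.names = ids)
}

## SnpCallSet from a genotype-class matrix ("AA"/"AB"/"BB"/NA for vendor
## no-call) and a score matrix
makeCallSet <- function(geno, score, manifest) {
  aA <- matrix(manifest$allele_a, nrow(geno), ncol(geno))
  aB <- matrix(manifest$allele_b, nrow(geno), ncol(geno))
  a1 <- ifelse(is.na(geno), "-", ifelse(geno == "BB", aB, aA))
  a2 <- ifelse(is.na(geno), "-", ifelse(geno == "AA", aA, aB))
  colnames(a1) <- colnames(a2) <- colnames(score) <-
    sprintf("sample%02d", seq_len(ncol(geno)))
  SnpCallSet(a1, a2, score, manifest)
}

## independent sliding search oracle: every (possibly overlapping) occurrence
## of pat in text, 1-based starts, via base-R literal regexpr
allOccurrences <- function(text, pat) {
  out <- integer(0)
  from <- 1L
  repeat {
    r <- regexpr(pat, substr(text, from, nchar(text)), fixed = TRUE)
    if (r == -1L) break
    pos <- from + as.integer(r) - 1L
    out <- c(out, pos)
    from <- pos + 1L
  }
  out
}

## independent order-statistic percentile (linear interpolation at rank
## p * (n - 1)), written without stats::quantile
interpPercentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- p * (n - 1)
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  x[lo] + (h - (lo - 1)) * (x[hi] - x[lo])
}

## brute-force per-SNP metric oracle, independent of snpMetrics()
oracleMetrics <- function(x, threshold) {
  sc <- SummarizedExperiment::assay(x, "score")
  a1 <- SummarizedExperiment::assay(x, "allele1")
  a2 <- SummarizedExperiment::assay(x, "allele2")
  aA <- S4Vectors::DataFrame(SummarizedExperiment::rowData(x))$allele_a
  gt <- SummarizedExperiment::rowData(x)$gentrain
  res <- lapply(seq_len(nrow(x)), function(i) {
    called <- which(sc[i, ] >= threshold & a1[i, ] != "-")
    nAA <- sum(a1[i, called] == aA[i] & a2[i, called] == aA[i])
    nBB <- sum(a1[i, called] != aA[i] & a2[i, called] != aA[i])
    nAB <- length(called) - nAA - nBB
    cA <- 2 * nAA + nAB
    cB <- 2 * nBB + nAB
    s <- sc[i, called]
    gc10 <- if (length(s)) interpPercentile(s, 0.1) else NA_real_
    gc50 <- if (length(s)) interpPercentile(s, 0.5) else NA_real_
    data.frame(
      n_called = length(called),
      call_frequency = length(called) / ncol(x),
      gc10 = gc10, gc50 = gc50,
      avg_gc = (gc10 + gc50) / 2,
      gentrain = gt[i],
      maf = if (length(called)) min(cA, cB) / (2 * length(called)) else NA_real_)
  })
  do.call(rbind, res)
}

## a tiny hand-built genome with one planted SNP context
plantGenome <- function(manifestRow, scaffoldLen = 3000L, at = 1500L,
                        revcomp = FALSE, mutateOffset = 0L) {
  ctx <- paste0(manifestRow$flank_up, manifestRow$allele_a,
                manifestRow$flank_down)
  v <- nchar(manifestRow$flank_up) + 1L   # 1-based variant index in ctx
  if (mutateOffset != 0L) {
    i <- v + mutateOffset
    old <- substr(ctx, i, i)
    substr(ctx, i, i) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  if (revcomp) ctx <- rcChr(ctx)
  s <- randSeq(scaffoldLen)
  substr(s, at + 1L, at + nchar(ctx)) <- ctx   # 0-based insert at `at`
  g <- Biostrings::DNAStringSet(s)
  names(g) <- "scf1"
  ## 0-based variant coordinate on the plus strand
  vpos <- if (revcomp) at + (nchar(ctx) - v) else at + v - 1L
  list(genome = g, variant_pos = vpos)
}
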