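test_that("generator is reproducible and archetypes force their signatures", {
  s1 <- simulateGenotypeReport(40, seed = 71)
  s2 <- simulateGenotypeReport(40, seed = 71)
  expect_identical(callScores(s1$calls), callScores(s2$calls))
  expect_identical(as.data.frame(s1$manifest), as.data.frame(s2$manifest))
  expect_identical(as.data.frame(s1$truth), as.data.frame(s2$truth))

  mono <- simulateGenotypeReport(
    25, archetypeMix = c(clean_polymorphic = 0, monomorphic = 1,
                         noisy_cluster = 0, low_call = 0), seed = 73)
  for (thr in c(0, 0.15, 0.25)) {
    m <- snpMetrics(mono$calls, thr)
    expect_true(all(m$maf == 0 | is.na(m$maf)))
  }

  ## all clean with one planted heterozygote: MAF = 0.0125 at full call rate
  clean <- simulateGenotypeReport(
    30, archetypeMix = c(clean_polymorphic = 1, monomorphic = 0,
                         noisy_cluster = 0, low_call = 0),
    trueMaf = 0.0125, seed = 79)
  m <- snpMetrics(clean$calls, 0.15)
  full <- m$n_nocall == 0L & m$n_AB == 1L & m$n_BB == 0L
  expect_gt(sum(full), 0)
  expect_true(all(m$maf[full] == 0.0125))
})

test_that("invalid archetype mixes are rejected", {
  expect_error(simulateGenotypeReport(
    10, archetypeMix = c(clean_polymorphic = 0.7, monomorphic = 0.7,
                         noisy_cluster = 0, low_call = 0), seed = 1),
    "sum to 1")
  expect_error(simulateGenotypeReport(10), "seed")
})

test_that("archetype pass rates through method VI sit in analytic binomial bounds", {
  sim <- simulateGenotypeReport(
    400, archetypeMix = c(clean_polymorphic = 0.5, monomorphic = 0,
                          noisy_cluster = 0, low_call = 0.5), seed = 83)
  cr <- compareMethods(sim$calls, "VI")$VI
  tr <- as.data.frame(sim$truth)
  passed <- tr$archetype[tr$snp_id %in% survivors(cr, "maf_0.01")]
  cf <- tr$archetype[tr$snp_id %in% survivors(cr, "call_frequency")]
  nClean <- sum(tr$archetype == "clean_polymorphic")
  nLow <- sum(tr$archetype == "low_call")

  ## clean: passes call frequency = 1 iff all 40 Beta(18, 2) scores >= 0.25;
  ## with >= 1 heterozygote sampled, MAF >= 1/80 = 0.0125 >= 0.01, so the
  ## only MAF failure mode is drawing an all-homozygous sample; average that
  ## over the generator's true-MAF grid. (Average-GC failures are orders of
  ## magnitude rarer than the binomial slack and are neglected.)
  pCf <- (1 - pbeta(0.25, 18, 2))^40
  grid <- (4:40) / 80
  pMono <- mean(vapply(grid, function(p) (1 - p)^80 + p^80, numeric(1)))
  pFull <- pCf * (1 - pMono)
  nPassClean <- sum(passed == "clean_polymorphic")
  expect_gte(nPassClean, qbinom(0.005, nClean, pFull))
  expect_lte(nPassClean, qbinom(0.995, nClean, pFull))

  ## low call: a genotype is a call iff not vendor no-call (rate 0.15) and
  ## its Beta(1, 3) score >= 0.25; all 40 at once is essentially impossible
  pLow <- ((1 - pbeta(0.25, 1, 3)) * 0.85)^40
  expect_lte(sum(cf == "low_call"), qbinom(0.995, nLow, pLow))
})

test_that("genome simulation is reproducible and honours the planting plan", {
  m <- simulateGenotypeReport(30, seed = 89)
  g1 <- simulateGenomes(m$manifest, m$truth, seed = 91)
  g2 <- simulateGenomes(m$manifest, m$truth, seed = 91)
  expect_identical(as.character(g1$genomeA), as.character(g2$genomeA))
  expect_identical(as.character(g1$outgroup), as.character(g2$outgroup))
  expect_identical(as.data.frame(g1$truth), as.data.frame(g2$truth))

  tr <- as.data.frame(g1$truth)
  planted <- tr[tr$fate != "absent", ]
  expect_true(all(!is.na(planted$scaffold_A)))
  expect_true(all(is.na(tr$scaffold_A[tr$fate == "absent"])))

  ## planted coordinates are exact: the genome base at each planted + locus
  ## is the manifest A allele (or its complement on -)
  for (k in head(which(tr$fate == "unique_both"), 10)) {
    scf <- tr$scaffold_A[k]; v <- tr$variant_pos_A[k]
    base <- as.character(Biostrings::subseq(g1$genomeA[[scf]], v + 1, v + 1))
    expected <- m$manifest$allele_a[k]
    if (tr$strand_A[k] == "-") expected <- rcChr(expected)
    expect_equal(base, expected)
  }

  expect_error(simulateGenomes(m$manifest, m$truth, nScaffolds = 1L,
                               scaffoldLength = 500L, seed = 3),
               "too short")
})

test_that("simulated fates drive the planted end-to-end outcomes", {
  sim <- simulateGenotypeReport(60, seed = 97)
  g <- simulateGenomes(sim$manifest, sim$truth, seed = 101)
  tr <- as.data.frame(g$truth)
  q <- buildFlankQueries(sim$manifest)
  lociA <- locateSnp(g$genomeA, q)
  uniq <- classifyUniqueness(lociA, sim$manifest$snp_id)
  cls <- setNames(uniq$class, uniq$snp_id)

  expect_true(all(cls[tr$snp_id[tr$fate %in% c("unique_both",
                                               "conserved_in_outgroup",
                                               "far_mutated")]] == "unique"))
  expect_true(all(cls[tr$snp_id[tr$fate %in% c("near_mutated", "absent")]]
                  == "absent"))
  expect_true(all(cls[tr$snp_id[tr$fate == "duplicated"]] %in%
                    c("multi_scaffold", "multi_within_scaffold")))

  ## conservation: verbatim outgroup copies are found, far-mutated are not
  lociDf <- as.data.frame(lociA)
  checkCons <- function(id) {
    row <- lociDf[lociDf$snp_id == id, ][1, ]
    ctx <- extractContext(g$genomeA, row$scaffold, row$variant_pos,
                          row$strand)
    conservationCheck(ctx$sequence, g$outgroup,
                      alleles = c(sim$manifest[id, "allele_a"],
                                  sim$manifest[id, "allele_b"]))
  }
  consIds <- tr$snp_id[tr$fate == "conserved_in_outgroup"]
  farIds <- tr$snp_id[tr$fate == "far_mutated"]
  expect_true(all(vapply(consIds, checkCons, logical(1))))
  expect_false(any(vapply(farIds, checkCons, logical(1))))
})

test_that("annotation simulation writes valid, reproducible files", {
  set.seed(103)
  g <- Biostrings::DNAStringSet(
    setNames(vapply(1:6, function(i) randSeq(15000), ""),
             sprintf("scf%d", 1:6)))
  a1 <- simulateAnnotation(g, seed = 107)
  a2 <- simulateAnnotation(g, seed = 107)
  expect_identical(a1$map, a2$map)
  expect_equal(a1$genes$gene_id, a2$genes$gene_id)
  ## genes are non-overlapping within scaffolds and inside bounds
  gr <- a1$genes
  expect_true(all(GenomicRanges::start(gr) >= 1))
  expect_true(all(GenomicRanges::end(gr) <= 15000))
  byScf <- split(gr, as.character(GenomicRanges::seqnames(gr)))
  for (s in names(byScf)) {
    x <- byScf[[s]]
    o <- order(GenomicRanges::start(x))
    expect_true(all(GenomicRanges::start(x)[o][-1] >
                      GenomicRanges::end(x)[o][-length(x)]))
  }
})
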