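test_that("no-call threshold keeps scores at the cutoff and drops below it", {
  set.seed(1)
  manifest <- makeManifest(1)
  geno <- matrix("AA", 1, 3)
  score <- matrix(c(0.05, 0.15, 0.25), 1, 3)
  x <- makeCallSet(geno, score, manifest)
  expect_equal(as.vector(calledMask(x, 0.15)), c(FALSE, TRUE, TRUE))
  expect_true(all(calledMask(x, 0)))           # threshold 0: everything called
  v <- makeCallSet(matrix(NA_character_, 1, 3), score, manifest)
  expect_false(any(calledMask(v, 0)))          # vendor no-calls never called
})

test_that("thresholded no-call counts match a brute-force filter over scores", {
  set.seed(99)
  manifest <- makeManifest(5)
  score <- matrix(runif(5 * 20), 5, 20)
  x <- makeCallSet(matrix("AA", 5, 20), score, manifest)
  for (thr in c(0.05, 0.15, 0.25)) {
    mask <- calledMask(x, thr)
    for (i in 1:5) {
      expect_identical(sum(!mask[i, ]), sum(score[i, ] < thr))
    }
  }
})

test_that("call frequency is the exact count ratio", {
  expect_equal(callFrequency(36L, 4L), 0.9)
  expect_equal(callFrequency(40L, 0L), 1.0)
  expect_error(callFrequency(0L, 0L), "at least one sample")
  set.seed(3)
  nc <- rbinom(20, 40, 0.8)
  expect_equal(callFrequency(nc, 40L - nc), nc / 40)
})

test_that("GC percentiles follow the declared interpolation rule", {
  expect_equal(unname(gcPercentiles(rep(0.8, 7))), c(0.8, 0.8, 0.8))
  s <- seq(0.1, 1.0, by = 0.1)
  g <- gcPercentiles(s)
  expect_equal(unname(g["gc10"]), interpPercentile(s, 0.1))
  expect_equal(unname(g["gc50"]), interpPercentile(s, 0.5))
  expect_equal(unname(g["gc10"]), 0.19)
  expect_equal(unname(g["gc50"]), 0.55)
  set.seed(8)
  for (k in 1:20) {
    s <- runif(sample(1:50, 1))
    g <- gcPercentiles(s)
    expect_equal(unname(g["gc10"]), interpPercentile(s, 0.1))
    expect_equal(unname(g["gc50"]), interpPercentile(s, 0.5))
    expect_equal(unname(g["avg_gc"]), (g[["gc10"]] + g[["gc50"]]) / 2)
  }
  expect_true(all(is.na(gcPercentiles(numeric(0)))))
})

test_that("minor allele frequency from genotype counts", {
  expect_equal(minorAlleleFrequency(39, 1, 0), 0.0125)  # one het in 40
  expect_equal(minorAlleleFrequency(40, 0, 0), 0)       # monomorphic
  expect_equal(minorAlleleFrequency(30, 8, 2), 0.15)    # 12 of 80 alleles
  expect_true(is.na(minorAlleleFrequency(0, 0, 0)))
  set.seed(4)
  n <- cbind(rbinom(50, 30, 0.5), rbinom(50, 5, 0.5), rbinom(50, 10, 0.5))
  maf <- minorAlleleFrequency(n[, 1], n[, 2], n[, 3])
  expect_true(all(maf >= 0 & maf <= 0.5))
})

test_that("Hardy-Weinberg chi-square matches closed-form hand computations", {
  h <- hweTest(10, 20, 10)
  expect_equal(h$chi2, 0, tolerance = 1e-12)
  expect_equal(h$p, 1)
  expect_true(h$in_equilibrium)

  h <- hweTest(30, 4, 6)
  expect_equal(h$chi2, 18.90625, tolerance = 1e-9)
  expect_lt(h$p, 0.05)
  expect_false(h$in_equilibrium)

  h <- hweTest(39, 1, 0)
  ## hand-derived: p = 79/80; terms 0.00625^2/39.00625 + 0.0125^2/0.9875 +
  ## 0.00625^2/0.00625
  expect_equal(h$chi2, 0.00625^2 / 39.00625 + 0.0125^2 / 0.9875 + 0.00625,
               tolerance = 1e-12)
  expect_true(h$in_equilibrium)

  h <- hweTest(40, 0, 0)   # monomorphic: not applicable, never "failed"
  expect_true(is.na(h$chi2) && is.na(h$in_equilibrium))
})

test_that("per-SNP metrics equal independent recomputation and stay coherent", {
  sim <- simulateGenotypeReport(120, seed = 21)
  x <- sim$calls
  for (thr in c(0.05, 0.25)) {
    m <- snpMetrics(x, thr)
    o <- oracleMetrics(x, thr)
    expect_equal(m$n_called, o$n_called)
    expect_equal(m$call_frequency, o$call_frequency)
    expect_equal(m$gc10, o$gc10)
    expect_equal(m$gc50, o$gc50)
    expect_equal(m$avg_gc, o$avg_gc)
    expect_equal(m$maf, o$maf)
    ## invariants
    expect_true(all(m$n_called + m$n_nocall == ncol(x)))
    expect_true(all(m$n_AA + m$n_AB + m$n_BB == m$n_called))
    ok <- !is.na(m$avg_gc)
    expect_equal(m$avg_gc[ok], (m$gc10[ok] + m$gc50[ok]) / 2)
    expect_true(all(m$hwe_chi2 >= 0, na.rm = TRUE))
    expect_true(all(m$hwe_p > 0 & m$hwe_p <= 1, na.rm = TRUE))
  }
})

test_that("call frequency is non-increasing in the threshold", {
  sim <- simulateGenotypeReport(80, seed = 31)
  m05 <- snpMetrics(sim$calls, 0.05)
  m15 <- snpMetrics(sim$calls, 0.15)
  m25 <- snpMetrics(sim$calls, 0.25)
  expect_true(all(m05$call_frequency >= m15$call_frequency))
  expect_true(all(m15$call_frequency >= m25$call_frequency))
  full25 <- m25$snp_id[m25$call_frequency == 1]
  full15 <- m15$snp_id[m15$call_frequency == 1]
  full05 <- m05$snp_id[m05$call_frequency == 1]
  expect_true(all(full25 %in% full15))
  expect_true(all(full15 %in% full05))
})

test_that("metrics on an empty call set give an empty table", {
  manifest <- makeManifest(1)
  x <- makeCallSet(matrix("AA", 1, 2), matrix(0.9, 1, 2), manifest)
  m <- snpMetrics(x[0, ], 0.15)
  expect_equal(nrow(m), 0L)
})
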