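test_that("flank queries are built suffix+allele / revcomp(allele+prefix)", {
  m <- S4Vectors::DataFrame(
    snp_id = "rs1", allele_a = "A", allele_b = "G",
    flank_up = "ACGTACGTACGTACGTACGTACGTA",     # 25 nt
    flank_down = "GGGGGCCCCCAAAAATTTTTGGGGG",   # 25 nt
    gentrain = 0.9, source_chrom = NA_character_,
    source_pos = NA_integer_, eligible26 = TRUE)
  q <- buildFlankQueries(m, lengths = 21)
  qup <- q[q$side == "upstream" & q$allele == "A", ]
  expect_equal(qup$sequence, "CGTACGTACGTACGTACGTAA")
  qdn <- q[q$side == "downstream" & q$allele == "A", ]
  expect_equal(qdn$sequence, "AAAAATTTTTGGGGGCCCCCT")

  q8 <- buildFlankQueries(m, lengths = c(21, 26))
  expect_equal(nrow(q8), 8L)
  ## every query carries the allele (or its complement) at the 3' end
  last <- substr(q8$sequence, q8$length, q8$length)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expect_true(all(ifelse(q8$side == "upstream", last,
                         comp[last]) == q8$allele_base))

  ## too-short flank omits that (side, length) query with a warning
  m$flank_up <- substr(m$flank_up, 1, 20)
  expect_warning(q <- buildFlankQueries(m, lengths = c(21, 26)), "omitted")
  expect_equal(sum(q$side == "upstream" & q$length == 26), 0L)
  expect_equal(sum(q$side == "upstream" & q$length == 21), 2L)
})

test_that("exact search finds planted occurrences on both strands", {
  set.seed(17)
  query <- randSeq(21)
  bg1 <- randSeq(5000)
  bg2 <- randSeq(5000)
  substr(bg1, 1001, 1021) <- query
  substr(bg2, 2001, 2021) <- rcChr(query)
  g <- Biostrings::DNAStringSet(c(s1 = bg1, s2 = bg2))
  h <- searchExact(g, query)
  expect_equal(nrow(h), 2L)
  hp <- h[h$strand == "+", ]
  expect_equal(hp$scaffold, "s1")
  expect_equal(hp$variant_pos, 1000 + 20)    # 0-based 3' end
  hm <- h[h$strand == "-", ]
  expect_equal(hm$scaffold, "s2")
  expect_equal(hm$variant_pos, 2000)          # 0-based first base of rc hit
  expect_equal(nrow(searchExact(g, randSeq(25))), 0L)
  expect_error(searchExact(g, "ACGTN"), "A, C, G, T")
})

test_that("exact search agrees with a sliding-window oracle", {
  set.seed(23)
  bg <- randSeq(20000)
  g <- Biostrings::DNAStringSet(c(chr = bg))
  for (k in 1:30) {
    L <- sample(c(21L, 26L), 1)
    q <- if (k <= 15) substr(bg, 500 * k, 500 * k + L - 1)  # present
         else randSeq(L)                                     # mostly absent
    h <- searchExact(g, q)
    fw <- allOccurrences(bg, q)
    rv <- allOccurrences(bg, rcChr(q))
    expect_equal(sort(h$start[h$strand == "+"]), sort(fw - 1L))
    expect_equal(sort(h$start[h$strand == "-"]), sort(rv - 1L))
  }
})

test_that("N in the genome never matches and N queries are rejected", {
  g <- Biostrings::DNAStringSet(c(s = "AAANAAA"))
  h <- searchExact(g, "AAA")
  expect_equal(sum(h$strand == "+"), 2L)  # N breaks the middle occurrence
  expect_equal(sum(h$strand == "-"), 0L)  # rc query TTT absent
  expect_error(searchExact(g, "AANA"), "A, C, G, T")
})

test_that("locus consolidation needs co-located hits from both sides", {
  set.seed(29)
  m <- makeManifest(1)
  q <- buildFlankQueries(m)

  intact <- plantGenome(m[1, ])
  loci <- locateSnp(intact$genome, q)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$variant_pos, intact$variant_pos)
  expect_equal(loci$strand, "+")
  expect_true(loci$supported_21 && loci$supported_26)
  expect_equal(loci$alleles, "A")

  ## mutation 10 nt from the variant (inside the 21-mer window): no locus
  near <- plantGenome(m[1, ], mutateOffset = 10L)
  expect_equal(nrow(locateSnp(near$genome, q)), 0L)

  ## mutation 23 nt away: 21-mer pair intact, 26-mer pair broken
  mid <- plantGenome(m[1, ], mutateOffset = 23L)
  lociMid <- locateSnp(mid$genome, q)
  expect_equal(nrow(lociMid), 1L)
  expect_true(lociMid$supported_21)
  expect_false(lociMid$supported_26)
  expect_equal(nrow(locateSnp(mid$genome, q, require26 = TRUE)), 0L)
})

test_that("reverse-complement planting yields a minus-strand locus", {
  set.seed(31)
  m <- makeManifest(1)
  q <- buildFlankQueries(m)
  rcPlant <- plantGenome(m[1, ], revcomp = TRUE)
  loci <- locateSnp(rcPlant$genome, q)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$strand, "-")
  expect_equal(loci$variant_pos, rcPlant$variant_pos)
})

test_that("strand symmetry: reverse-complementing the genome mirrors loci", {
  set.seed(37)
  m <- makeManifest(3)
  q <- buildFlankQueries(m)
  sim <- simulateGenomes(m, S4Vectors::DataFrame(
    snp_id = m$snp_id, archetype = "clean_polymorphic", true_maf = 0.2,
    fate = "unique_both"), nScaffolds = 2L, scaffoldLength = 5000L,
    seed = 37)
  g <- sim$genomeA
  loci <- as.data.frame(locateSnp(g, q))
  gRc <- Biostrings::reverseComplement(g)
  names(gRc) <- names(g)
  lociRc <- as.data.frame(locateSnp(gRc, q))
  expect_equal(nrow(loci), nrow(lociRc))
  lens <- setNames(Biostrings::width(g), names(g))
  mirrored <- data.frame(
    snp_id = loci$snp_id, scaffold = loci$scaffold,
    variant_pos = lens[loci$scaffold] - 1L - loci$variant_pos,
    strand = ifelse(loci$strand == "+", "-", "+"),
    row.names = NULL)
  o1 <- mirrored[order(mirrored$snp_id), ]
  o2 <- lociRc[order(lociRc$snp_id),
               c("snp_id", "scaffold", "variant_pos", "strand")]
  rownames(o1) <- rownames(o2) <- NULL
  o1$variant_pos <- as.integer(o1$variant_pos)
  expect_equal(o1, o2)
})

test_that("uniqueness classes follow locus counts and scaffold spread", {
  mk <- function(...) data.frame(..., stringsAsFactors = FALSE)
  one <- mk(snp_id = "a", scaffold = "s1", variant_pos = 1L, strand = "+")
  expect_equal(classifyUniqueness(one, "a")$class, "unique")
  two <- rbind(one, mk(snp_id = "a", scaffold = "s2", variant_pos = 5L,
                       strand = "+"))
  expect_equal(classifyUniqueness(two, "a")$class, "multi_scaffold")
  twoIn <- rbind(one, mk(snp_id = "a", scaffold = "s1", variant_pos = 9L,
                         strand = "-"))
  expect_equal(classifyUniqueness(twoIn, "a")$class, "multi_within_scaffold")
  expect_equal(classifyUniqueness(one, c("a", "b"))$class,
               c("unique", "absent"))
})

test_that("cross-genome intersection keeps only SNPs unique in both", {
  ua <- data.frame(snp_id = c("a", "b", "c"),
                   class = c("unique", "unique", "multi_scaffold"))
  ub <- data.frame(snp_id = c("a", "b", "c"),
                   class = c("unique", "absent", "unique"))
  expect_equal(intersectGenomes(ua, ub), "a")
})

test_that("26-mer support implies 21-mer support at the same locus", {
  set.seed(41)
  m <- makeManifest(4)
  q <- buildFlankQueries(m)
  sim <- simulateGenomes(m, S4Vectors::DataFrame(
    snp_id = m$snp_id, archetype = "clean_polymorphic", true_maf = 0.2,
    fate = "unique_both"), nScaffolds = 2L, scaffoldLength = 8000L,
    seed = 41)
  loci <- locateSnp(sim$genomeA, q)
  expect_true(all(!loci$supported_26 | loci$supported_21))
})

test_that("context extraction centres the variant and honours strand", {
  set.seed(43)
  bg <- randSeq(300)
  g <- Biostrings::DNAStringSet(c(s = bg))
  ctx <- extractContext(g, "s", 60L)
  expect_equal(nchar(ctx$sequence), 101L)
  expect_false(ctx$truncated)
  expect_equal(ctx$sequence, substr(bg, 11, 111))   # 0-based 10..110
  expect_equal(ctx$variant_index, 50L)
  expect_equal(substr(ctx$sequence, 51, 51), substr(bg, 61, 61))

  minus <- extractContext(g, "s", 60L, strand = "-")
  expect_equal(minus$sequence, rcChr(ctx$sequence))
  expect_equal(minus$variant_index, 50L)

  edge <- extractContext(g, "s", 10L)
  expect_true(edge$truncated)
  expect_equal(nchar(edge$sequence), 61L)   # positions 0..60
  expect_equal(edge$variant_index, 10L)
})

test_that("conservation requires a perfect 101-nt presence in the outgroup", {
  set.seed(47)
  ctx <- randSeq(101)
  og <- Biostrings::DNAStringSet(c(o = paste0(randSeq(400), ctx,
                                              randSeq(400))))
  expect_true(conservationCheck(ctx, og))
  ## allele substitution at the centre still counts
  sub <- ctx
  substr(sub, 51, 51) <- setdiff(c("A", "C", "G", "T"),
                                 substr(ctx, 51, 51))[1]
  expect_true(conservationCheck(sub, og,
                                alleles = substr(ctx, 51, 51)))
  ## a substitution away from the centre breaks conservation
  off <- ctx
  substr(off, 31, 31) <- setdiff(c("A", "C", "G", "T"),
                                 substr(ctx, 31, 31))[1]
  expect_false(conservationCheck(off, og))
  ## reverse-complement presence counts
  ogRc <- Biostrings::DNAStringSet(c(o = paste0(randSeq(100), rcChr(ctx))))
  expect_true(conservationCheck(ctx, ogRc))
  ## absent entirely
  expect_false(conservationCheck(randSeq(101),
                                 Biostrings::DNAStringSet(c(o = randSeq(500)))))
  expect_error(conservationCheck(randSeq(61), og), "full")
})
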