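## Synthetic-data generators with planted ground truth. Defaults emulate the
## study design the package targets: 40 diploid samples on a high-density
## array, per-SNP quality archetypes, and scaffold-level genome triples
## (two target assemblies plus an outgroup) with planted 101-nt contexts.

.ARCHETYPES <- c("clean_polymorphic", "monomorphic", "noisy_cluster",
                 "low_call")
.FATES <- c("unique_both", "duplicated", "near_mutated", "far_mutated",
            "absent", "conserved_in_outgroup")

## per-archetype generator parameters: Beta score distributions (support on
## [0, 1], analytic tail probabilities), vendor no-call rate, GenTrain range
.ARCH_PARAMS <- list(
  clean_polymorphic = list(beta = c(18, 2), vendor = 0.00, gt = c(0.55, 0.95)),
  monomorphic       = list(beta = c(18, 2), vendor = 0.00, gt = c(0.55, 0.95)),
  noisy_cluster     = list(beta = c(2, 2),  vendor = 0.05, gt = c(0.25, 0.75)),
  low_call          = list(beta = c(1, 3),  vendor = 0.15, gt = c(0.25, 0.75))
)

.randomSeq <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Simulate a genotype report with full ground truth
#'
#' Draws per-SNP archetypes (clean polymorphic, monomorphic, noisy cluster,
#' low call rate), genotypes in Hardy-Weinberg proportions at each SNP's true
#' MAF (all-homozygous for monomorphic SNPs), and per-genotype quality scores
#' from archetype-specific Beta distributions: clean SNPs score high
#' (Beta(18, 2)), noisy SNPs broadly (Beta(2, 2)), low-call SNPs put most
#' mass below 0.25 (Beta(1, 3)). Noisy and low-call archetypes also carry
#' vendor no-calls. GenTrain scores are drawn uniformly within
#' archetype-specific ranges, all at or above 0.25, so that any SNP passing
#' an average-GC filter also passes the GenTrain filter. Every SNP gets a
#' random allele pair, 50-nt probe flanks, and a flank fate consumed by
#' [simulateGenomes()]. Fully reproducible from the seed.
#'
#' @param nSnps number of SNPs.
#' @param nSamples number of diploid samples (default 40).
#' @param archetypeMix named proportions over the four archetypes; must sum
#'   to 1.
#' @param fateMix named proportions over flank fates (`unique_both`,
#'   `duplicated`, `near_mutated`, `far_mutated`, `absent`,
#'   `conserved_in_outgroup`); must sum to 1.
#' @param trueMaf optional fixed true MAF for every polymorphic SNP; when
#'   `NULL`, drawn per SNP from allele-count multiples of `1 / (2 *
#'   nSamples)` between 0.05 and 0.5.
#' @param seed integer seed (required).
#' @return list with `calls` (a [SnpCallSet]), `manifest` (DataFrame) and
#'   `truth` (DataFrame of per-SNP labels: archetype, `true_maf`, `fate`,
#'   planted allele, plus a `genotypes` matrix attribute of true genotype
#'   classes).
#' @export
simulateGenotypeReport <- function(nSnps, nSamples = 40L,
                                   archetypeMix = c(clean_polymorphic = 0.50,
                                                    monomorphic = 0.20,
                                                    noisy_cluster = 0.15,
                                                    low_call = 0.15),
                                   fateMix = c(unique_both = 0.62,
                                               duplicated = 0.10,
                                               near_mutated = 0.10,
                                               far_mutated = 0.06,
                                               absent = 0.04,
                                               conserved_in_outgroup = 0.08),
                                   trueMaf = NULL, seed) {
  stopIfNot(!missing(seed), "a seed is required")
  stopIfNot(setequal(names(archetypeMix), .ARCHETYPES) &&
              abs(sum(archetypeMix) - 1) < 1e-9,
            "archetypeMix must cover the four archetypes and sum to 1")
  stopIfNot(setequal(names(fateMix), .FATES) &&
              abs(sum(fateMix) - 1) < 1e-9,
            "fateMix must cover the six fates and sum to 1")
  set.seed(seed)
  snpIds <- sprintf("snp%05d", seq_len(nSnps))
  sampleIds <- sprintf("sample%02d", seq_len(nSamples))
  archetype <- sample(.ARCHETYPES, nSnps, replace = TRUE,
                      prob = archetypeMix[.ARCHETYPES])
  fate <- sample(.FATES, nSnps, replace = TRUE, prob = fateMix[.FATES])

  alleleA <- character(nSnps); alleleB <- character(nSnps)
  flankUp <- character(nSnps); flankDown <- character(nSnps)
  gentrain <- numeric(nSnps); maf <- numeric(nSnps)
  geno <- matrix(NA_character_, nSnps, nSamples,
                 dimnames = list(snpIds, sampleIds))
  a1 <- matrix(NA_character_, nSnps, nSamples,
               dimnames = list(snpIds, sampleIds))
  a2 <- a1
  score <- matrix(NA_real_, nSnps, nSamples,
                  dimnames = list(snpIds, sampleIds))

  mafGrid <- seq_len(nSamples) / (2 * nSamples)   # allele-count multiples
  mafGrid <- mafGrid[mafGrid >= 0.05 & mafGrid <= 0.5]

  for (i in seq_len(nSnps)) {
    pair <- sample(DNA_BASES, 2)
    alleleA[i] <- pair[1]; alleleB[i] <- pair[2]
    flankUp[i] <- .randomSeq(50)
    flankDown[i] <- .randomSeq(50)
    pars <- .ARCH_PARAMS[[archetype[i]]]
    gentrain[i] <- runif(1, pars$gt[1], pars$gt[2])
    if (archetype[i] == "monomorphic") {
      maf[i] <- 0
      g <- rep(sample(c("AA", "BB"), 1), nSamples)
    } else {
      maf[i] <- if (is.null(trueMaf)) sample(mafGrid, 1) else trueMaf
      pB <- maf[i]
      g <- sample(c("AA", "AB", "BB"), nSamples, replace = TRUE,
                  prob = c((1 - pB)^2, 2 * pB * (1 - pB), pB^2))
    }
    geno[i, ] <- g
    s <- round(rbeta(nSamples, pars$beta[1], pars$beta[2]), 4)
    vendor <- runif(nSamples) < pars$vendor
    a1[i, ] <- ifelse(vendor, "-",
                      ifelse(g == "BB", alleleB[i], alleleA[i]))
    a2[i, ] <- ifelse(vendor, "-",
                      ifelse(g == "AA", alleleA[i], alleleB[i]))
    score[i, ] <- s
  }

  manifest <- DataFrame(
    snp_id = snpIds, allele_a = alleleA, allele_b = alleleB,
    flank_up = flankUp, flank_down = flankDown, gentrain = round(gentrain, 4),
    source_chrom = NA_character_, source_pos = NA_integer_,
    eligible26 = TRUE, row.names = snpIds)
  truth <- DataFrame(
    snp_id = snpIds, archetype = archetype, true_maf = maf, fate = fate,
    row.names = snpIds)
  attr(truth, "genotypes") <- geno
  list(calls = SnpCallSet(a1, a2, score, manifest), manifest = manifest,
       truth = truth)
}

## place n non-overlapping windows of width w on scaffolds of length len,
## keeping >= margin from the edges and >= gap between windows
.placeWindows <- function(nPerScaffold, scaffoldLength, w, margin = 60L,
                          gap = 30L) {
  lapply(nPerScaffold, function(n) {
    if (n == 0L) return(integer(0))
    avail <- scaffoldLength - 2L * margin - n * w - (n - 1L) * gap
    stopIfNot(avail >= 0L, "scaffold too short for the planting plan")
    cuts <- sort(sample.int(avail + 1L, n, replace = TRUE) - 1L)
    margin + cuts + (seq_len(n) - 1L) * (w + gap)
  })
}

.mutateAt <- function(seqStr, idx1) {
  old <- substr(seqStr, idx1, idx1)
  substr(seqStr, idx1, idx1) <- sample(setdiff(DNA_BASES, old), 1)
  seqStr
}

#' Simulate genome triples with planted flank contexts
#'
#' Builds two target assemblies and an outgroup from i.i.d. uniform
#' background sequence, then plants each SNP's 101-nt context (5' flank +
#' planted allele + 3' flank) according to its fate:
#' `unique_both` -- one copy in each target genome; `duplicated` -- two
#' copies in each target genome (scaffolds drawn at random, so the repeat may
#' land within one scaffold or across two); `near_mutated` -- one copy per
#' target genome carrying a
#' substitution within 20 nt of the variant (inside the 21-mer window, so no
#' locus is recoverable); `far_mutated` -- one copy per target genome with a
#' substitution 26-50 nt away (both query lengths intact, 101-nt conservation
#' broken) and the unmutated context planted in the outgroup;
#' `absent` -- not planted; `conserved_in_outgroup` -- like `unique_both`
#' plus a verbatim outgroup copy. About 30% of plantings are inserted in
#' reverse-complement orientation to exercise strand handling. At simulated
#' sizes the chance of an accidental 21-mer background match is negligible
#' (about L * 4^-21 per query), so the planted truth is exact.
#'
#' @param manifest manifest from [simulateGenotypeReport()].
#' @param truth truth table from the same call (provides fates).
#' @param nScaffolds,scaffoldLength scaffold plan per genome (defaults: 24
#'   scaffolds of 30 kb).
#' @param revCompFraction fraction of plantings inserted reverse-complemented.
#' @param seed integer seed (required).
#' @return list with `genomeA`, `genomeB`, `outgroup` (DNAStringSet; scaffold
#'   ids `refA_scf...`, `refB_scf...`, `outg_scf...`) and `truth`: the input
#'   truth extended with per-genome planted coordinates
#'   (`scaffold_A`, `variant_pos_A`, `strand_A`, same for `_B`), the expected
#'   uniqueness class per genome and the expected conservation flag.
#' @export
simulateGenomes <- function(manifest, truth, nScaffolds = 24L,
                            scaffoldLength = 30000L, revCompFraction = 0.3,
                            seed) {
  stopIfNot(!missing(seed), "a seed is required")
  stopIfNot(all(truth$fate %in% .FATES), "every SNP needs a valid fate")
  stopIfNot(all(nchar(manifest$flank_up) >= 50L &
                  nchar(manifest$flank_down) >= 50L),
            "simulateGenomes needs 50-nt flanks on both sides")
  set.seed(seed)
  n <- nrow(manifest)
  planted <- manifest$allele_a    # the haploid reference carries allele A
  context <- paste0(substr(manifest$flank_up,
                           nchar(manifest$flank_up) - 49L,
                           nchar(manifest$flank_up)),
                    planted,
                    substr(manifest$flank_down, 1L, 50L))

  mkGenome <- function(prefix) {
    g <- DNAStringSet(vapply(seq_len(nScaffolds),
                             function(i) .randomSeq(scaffoldLength),
                             character(1)))
    names(g) <- sprintf("%s_scf%02d", prefix, seq_len(nScaffolds))
    g
  }
  genomes <- list(A = mkGenome("refA"), B = mkGenome("refB"))
  outgroup <- mkGenome("outg")

  ## near/far mutation offsets, shared across both target genomes so the
  ## fate is consistent; offset is signed (side) + distance from the variant
  mutOffset <- integer(n)
  for (i in seq_len(n)) {
    if (truth$fate[i] == "near_mutated") {
      mutOffset[i] <- sample(c(-1, 1), 1) * sample(1:20, 1)
    } else if (truth$fate[i] == "far_mutated") {
      mutOffset[i] <- sample(c(-1, 1), 1) * sample(26:50, 1)
    }
  }
  mutContext <- context
  for (i in seq_len(n)) {
    if (mutOffset[i] != 0L) {
      mutContext[i] <- .mutateAt(context[i], 51L + mutOffset[i])
    }
  }

  revComped <- runif(n) < revCompFraction

  plantInto <- function(genome, plantings) {
    ## plantings: data.frame(snp, seqStr, scaffoldIdx assigned later)
    nP <- nrow(plantings)
    scfIdx <- sample.int(nScaffolds, nP, replace = TRUE)
    seqs <- as.character(genome)
    coords <- data.frame(snp = plantings$snp,
                         scaffold = names(genome)[scfIdx],
                         variant_pos = NA_integer_,
                         strand = plantings$strand,
                         stringsAsFactors = FALSE)
    for (s in unique(scfIdx)) {
      rows <- which(scfIdx == s)
      pos <- .placeWindows(length(rows), nchar(seqs[s]), 101L)[[1]]
      ord <- sample(length(rows))   # decouple row order from position order
      for (k in seq_along(rows)) {
        r <- rows[ord[k]]
        p0 <- pos[k]                # 0-based insert start
        ins <- plantings$seqStr[r]
        if (plantings$strand[r] == "-") ins <- revComp(ins)
        substr(seqs[s], p0 + 1L, p0 + 101L) <- ins
        coords$variant_pos[r] <- p0 + 50L
      }
    }
    list(genome = DNAStringSet(seqs), coords = coords)
  }

  perGenomeCoords <- list()
  for (gid in c("A", "B")) {
    rows <- list()
    for (i in seq_len(n)) {
      f <- truth$fate[i]
      if (f == "absent") next
      seqStr <- if (f %in% c("near_mutated", "far_mutated")) mutContext[i]
                else context[i]
      strand <- if (revComped[i]) "-" else "+"
      rows[[length(rows) + 1L]] <- data.frame(
        snp = truth$snp_id[i], seqStr = seqStr, strand = strand,
        stringsAsFactors = FALSE)
      if (f == "duplicated") {
        rows[[length(rows) + 1L]] <- data.frame(
          snp = truth$snp_id[i], seqStr = seqStr, strand = "+",
          stringsAsFactors = FALSE)
      }
    }
    plantings <- do.call(rbind, rows)
    res <- plantInto(genomes[[gid]], plantings)
    genomes[[gid]] <- res$genome
    perGenomeCoords[[gid]] <- res$coords
  }

  ## outgroup plantings: verbatim context for conserved_in_outgroup and for
  ## far_mutated (whose target-genome copies differ by one substitution)
  ogRows <- which(truth$fate %in% c("conserved_in_outgroup", "far_mutated"))
  if (length(ogRows)) {
    plantings <- data.frame(snp = truth$snp_id[ogRows],
                            seqStr = context[ogRows],
                            strand = ifelse(runif(length(ogRows)) < 0.5,
                                            "+", "-"),
                            stringsAsFactors = FALSE)
    outgroup <- plantInto(outgroup, plantings)$genome
  }

  firstCoord <- function(coords, id) {
    hit <- coords[coords$snp == id, , drop = FALSE]
    if (nrow(hit) == 0L) {
      data.frame(scaffold = NA_character_, variant_pos = NA_integer_,
                 strand = NA_character_)
    } else hit[1L, c("scaffold", "variant_pos", "strand")]
  }
  extend <- function(gid) {
    coords <- perGenomeCoords[[gid]]
    got <- do.call(rbind, lapply(truth$snp_id, firstCoord, coords = coords))
    names(got) <- paste0(c("scaffold_", "variant_pos_", "strand_"), gid)
    got
  }
  truthOut <- cbind(as.data.frame(truth), extend("A"), extend("B"))
  truthOut$expected_class <- c(
    unique_both = "unique", duplicated = "multi", near_mutated = "absent",
    far_mutated = "unique", absent = "absent",
    conserved_in_outgroup = "unique")[truthOut$fate]
  truthOut$expected_conserved <- truthOut$fate == "conserved_in_outgroup"
  rownames(truthOut) <- truthOut$snp_id

  list(genomeA = genomes$A, genomeB = genomes$B, outgroup = outgroup,
       truth = DataFrame(truthOut))
}

#' Simulate a synteny map and gene annotation for a simulated assembly
#'
#' Genes are non-overlapping intervals placed on the scaffolds of the given
#' assembly at the requested density; a fraction `mapCoverage` of scaffolds
#' receives a chromosome label (VPA1..VPA36, VPAX) with a random evidence
#' tag.
#'
#' @param genome a named [Biostrings::DNAStringSet] (typically `genomeA`).
#' @param genesPer10kb expected number of genes per 10 kb of scaffold
#'   (default 1).
#' @param mapCoverage fraction of scaffolds present in the synteny map.
#' @param seed integer seed (required).
#' @return list with `map` (data.frame: scaffold, chromosome, evidence) and
#'   `genes` (`GRanges` with `gene_id`, 1-based inclusive coordinates).
#' @export
simulateAnnotation <- function(genome, genesPer10kb = 1, mapCoverage = 0.73,
                               seed) {
  stopIfNot(!missing(seed), "a seed is required")
  stopIfNot(mapCoverage >= 0 && mapCoverage <= 1,
            "mapCoverage must be in [0, 1]")
  set.seed(seed)
  scf <- names(genome)
  lens <- lengths(genome)

  geneRows <- list()
  gid <- 0L
  for (s in seq_along(scf)) {
    nG <- max(0L, round(lens[s] / 10000 * genesPer10kb))
    if (nG == 0L) next
    ## 2 * nG sorted distinct cut points give non-overlapping intervals
    cuts <- sort(sample.int(lens[s] - 1L, 2L * nG))
    starts <- cuts[seq(1L, 2L * nG, by = 2L)]
    ends <- cuts[seq(2L, 2L * nG, by = 2L)]
    ok <- ends > starts
    for (k in which(ok)) {
      gid <- gid + 1L
      geneRows[[gid]] <- data.frame(scaffold = scf[s], start = starts[k],
                                    end = ends[k], stringsAsFactors = FALSE)
    }
  }
  genes <- if (length(geneRows)) {
    gdf <- do.call(rbind, geneRows)
    gr <- GRanges(gdf$scaffold, IRanges(gdf$start, gdf$end), strand = "*")
    gr$gene_id <- sprintf("gene%05d", seq_along(gr))
    names(gr) <- gr$gene_id
    gr
  } else GRanges()

  inMap <- runif(length(scf)) < mapCoverage
  map <- data.frame(
    scaffold = scf[inMap],
    chromosome = sample(c(paste0("VPA", 1:36), "VPAX"), sum(inMap),
                        replace = TRUE),
    evidence = sample(c("synteny", "cytogenetic"), sum(inMap),
                      replace = TRUE, prob = c(0.8, 0.2)),
    stringsAsFactors = FALSE)
  list(map = map, genes = genes)
}
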