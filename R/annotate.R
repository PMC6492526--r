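## Chromosome assignment via synteny map and nearest-gene annotation.

#' Assign located SNPs to chromosomes through a scaffold synteny map
#'
#' Scaffold lookup: a scaffold absent from the map yields `"unassigned"`
#' with `NA` evidence.
#'
#' @param map synteny map from [readSyntenyMap()].
#' @param loci locus table (needs `snp_id`, `scaffold`), typically the
#'   retained unique loci in the assembly the map refers to.
#' @return data.frame with columns `snp_id`, `scaffold`, `chromosome`,
#'   `evidence`.
#' @export
assignChromosome <- function(map, loci) {
  ldf <- as.data.frame(loci)
  i <- match(ldf$scaffold, map$scaffold)
  data.frame(
    snp_id = ldf$snp_id,
    scaffold = ldf$scaffold,
    chromosome = ifelse(is.na(i), "unassigned", map$chromosome[i]),
    evidence = ifelse(is.na(i), NA_character_, map$evidence[i]),
    stringsAsFactors = FALSE)
}

#' Tally SNP assignments per chromosome label
#'
#' @param assignments table from [assignChromosome()].
#' @return named integer vector of counts (including `"unassigned"`),
#'   chromosome labels sorted, `"unassigned"` last.
#' @export
chromosomeDistribution <- function(assignments) {
  if (nrow(assignments) == 0L) return(setNames(integer(0), character(0)))
  tab <- table(assignments$chromosome)
  lab <- sort(setdiff(names(tab), "unassigned"))
  if ("unassigned" %in% names(tab)) lab <- c(lab, "unassigned")
  setNames(as.integer(tab[lab]), lab)
}

## distance from a 0-based point to a gene interval given in GFF3 1-based
## inclusive coordinates; 0 when the point lies inside
.geneDistance <- function(variantPos, geneStart1, geneEnd1) {
  start0 <- geneStart1 - 1L
  end0 <- geneEnd1            # half-open end
  pmax(0L, start0 - variantPos, variantPos - (end0 - 1L))
}

#' Most proximal annotated gene for each located SNP
#'
#' Distance is measured from the variant base to the closest edge of the
#' gene's full span, strand-agnostic; 0 when the variant lies within the
#' gene. Ties break to the gene with the smaller start coordinate, then
#' lexicographically smaller `gene_id`. A SNP on a scaffold with no genes
#' gets `NA` annotation.
#'
#' @param genes `GRanges` from [readGeneAnnotation()].
#' @param loci locus table (needs `snp_id`, `scaffold`, `variant_pos`).
#' @return data.frame with columns `snp_id`, `gene_id`, `distance`,
#'   `within_gene`.
#' @export
nearestGene <- function(genes, loci) {
  ldf <- as.data.frame(loci)
  gScaffold <- as.character(seqnames(genes))
  res <- lapply(seq_len(nrow(ldf)), function(k) {
    onScf <- which(gScaffold == ldf$scaffold[k])
    if (length(onScf) == 0L) {
      return(data.frame(snp_id = ldf$snp_id[k], gene_id = NA_character_,
                        distance = NA_integer_, within_gene = NA,
                        stringsAsFactors = FALSE))
    }
    g <- genes[onScf]
    d <- .geneDistance(ldf$variant_pos[k], start(g), end(g))
    ord <- order(d, start(g), g$gene_id)
    best <- ord[1]
    data.frame(snp_id = ldf$snp_id[k], gene_id = g$gene_id[best],
               distance = as.integer(d[best]), within_gene = d[best] == 0L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
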