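## Readers and writers for every external format the pipeline touches.
## Internal coordinates are 0-based half-open; file interfaces keep each
## format's native convention (GFF3 and FASTA indexes are 1-based inclusive).

#' Read a SNP manifest
#'
#' Parses a CSV manifest with columns `SnpID`, `SourceSeq`, `GenTrain` and
#' optionally `SourceChrom`, `SourcePos`. `SourceSeq` uses bracket notation
#' `LEFT[X/Y]RIGHT`: the probe context 5' of the variant, the two alleles, and
#' the context 3' of the variant, all on the source strand. Flanks shorter
#' than 25 nt are accepted with a warning and flagged ineligible for 26-mer
#' flank queries (`eligible26 = FALSE`).
#'
#' @param path CSV file path.
#' @return a [S4Vectors::DataFrame] with columns `snp_id`, `allele_a`,
#'   `allele_b`, `flank_up`, `flank_down`, `gentrain`, `source_chrom`,
#'   `source_pos`, `eligible26`, in file order.
#' @export
readSnpManifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("SnpID", "SourceSeq", "GenTrain")
  stopIfNot(all(need %in% names(df)),
            paste("manifest must have columns", paste(need, collapse = ", ")))
  m <- regexec("^([ACGTNacgtn]*)\\[([ACGTacgt])/([ACGTacgt])\\]([ACGTNacgtn]*)$",
               df$SourceSeq)
  parts <- regmatches(df$SourceSeq, m)
  bad <- which(lengths(parts) != 5L)
  if (length(bad)) {
    stop("malformed SourceSeq bracket expression at manifest row ", bad[1],
         ": '", df$SourceSeq[bad[1]], "'", call. = FALSE)
  }
  flankUp <- toupper(vapply(parts, `[`, "", 2L))
  alleleA <- toupper(vapply(parts, `[`, "", 3L))
  alleleB <- toupper(vapply(parts, `[`, "", 4L))
  flankDown <- toupper(vapply(parts, `[`, "", 5L))
  empty <- which(nchar(flankUp) == 0L | nchar(flankDown) == 0L)
  if (length(empty)) {
    stop("manifest row ", empty[1],
         ": flanks are required on both sides of the bracket", call. = FALSE)
  }
  same <- which(alleleA == alleleB)
  if (length(same)) {
    stop("manifest row ", same[1], ": allele_a must differ from allele_b",
         call. = FALSE)
  }
  gentrain <- as.numeric(df$GenTrain)
  if (any(is.na(gentrain) | gentrain < 0 | gentrain > 1)) {
    stop("GenTrain scores must be numeric in [0, 1]", call. = FALSE)
  }
  elig <- nchar(flankUp) >= 25L & nchar(flankDown) >= 25L
  if (any(!elig)) {
    warning(sum(!elig), " manifest record(s) have a flank shorter than 25 nt",
            " and are ineligible for 26-mer queries", call. = FALSE)
  }
  DataFrame(
    snp_id = df$SnpID,
    allele_a = alleleA,
    allele_b = alleleB,
    flank_up = flankUp,
    flank_down = flankDown,
    gentrain = gentrain,
    source_chrom = if ("SourceChrom" %in% names(df)) df$SourceChrom
                   else NA_character_,
    source_pos = if ("SourcePos" %in% names(df)) as.integer(df$SourcePos)
                 else NA_integer_,
    eligible26 = elig,
    row.names = df$SnpID)
}

#' Write a SNP manifest
#'
#' Inverse of [readSnpManifest()]; emits the bracketed `SourceSeq` column.
#'
#' @param manifest manifest DataFrame.
#' @param path output CSV path.
#' @export
writeSnpManifest <- function(manifest, path) {
  out <- data.frame(
    SnpID = manifest$snp_id,
    SourceSeq = paste0(manifest$flank_up, "[", manifest$allele_a, "/",
                       manifest$allele_b, "]", manifest$flank_down),
    GenTrain = manifest$gentrain,
    stringsAsFactors = FALSE)
  if (!all(is.na(manifest$source_chrom))) out$SourceChrom <- manifest$source_chrom
  if (!all(is.na(manifest$source_pos))) out$SourcePos <- manifest$source_pos
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format genotype report
#'
#' Reads a tab-separated report with one row per SNP x sample (columns
#' `SnpID`, `SampleID`, `Allele1`, `Allele2`, `Score`) and assembles a
#' [SnpCallSet]. Every (SNP, sample) pair must appear exactly once; alleles
#' are validated against the manifest pair; scores must lie in \[0, 1\].
#' Row order in the file is irrelevant: SNPs take manifest order, samples are
#' sorted.
#'
#' @param path TSV file path.
#' @param manifest manifest DataFrame from [readSnpManifest()].
#' @return a [SnpCallSet].
#' @export
readGenotypeReport <- function(path, manifest) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(Allele1 = "character",
                                  Allele2 = "character"))
  need <- c("SnpID", "SampleID", "Allele1", "Allele2", "Score")
  stopIfNot(all(need %in% names(df)),
            paste("report must have columns", paste(need, collapse = ", ")))
  df$Score <- as.numeric(df$Score)
  badScore <- which(is.na(df$Score) | df$Score < 0 | df$Score > 1)
  if (length(badScore)) {
    stop("score outside [0, 1] at report line ", badScore[1] + 1L,
         " (SNP ", df$SnpID[badScore[1]], ", sample ",
         df$SampleID[badScore[1]], ")", call. = FALSE)
  }
  unknown <- setdiff(df$SnpID, manifest$snp_id)
  if (length(unknown)) {
    stop("report names SNP(s) absent from the manifest: ",
         paste(head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  snps <- intersect(manifest$snp_id, unique(df$SnpID))
  samples <- sort(unique(df$SampleID))
  halfNo <- which((df$Allele1 == "-") != (df$Allele2 == "-"))
  if (length(halfNo)) {
    stop("half no-call at report line ", halfNo[1] + 1L,
         ": '-' must appear in both allele columns", call. = FALSE)
  }
  pairA <- setNames(manifest$allele_a, manifest$snp_id)[df$SnpID]
  pairB <- setNames(manifest$allele_b, manifest$snp_id)[df$SnpID]
  badAl <- which(!((df$Allele1 == "-" | df$Allele1 == pairA | df$Allele1 == pairB) &
                   (df$Allele2 == "-" | df$Allele2 == pairA | df$Allele2 == pairB)))
  if (length(badAl)) {
    stop("allele not in manifest pair at report line ", badAl[1] + 1L,
         " (SNP ", df$SnpID[badAl[1]], ": ", df$Allele1[badAl[1]], "/",
         df$Allele2[badAl[1]], " vs manifest ", pairA[badAl[1]], "/",
         pairB[badAl[1]], ")", call. = FALSE)
  }
  i <- match(df$SnpID, snps)
  j <- match(df$SampleID, samples)
  key <- (i - 1L) * length(samples) + j
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop("duplicate (SNP, sample) pair at report line ", d + 1L, call. = FALSE)
  }
  if (length(key) != length(snps) * length(samples)) {
    stop("incomplete report: expected ", length(snps) * length(samples),
         " rows (", length(snps), " SNPs x ", length(samples),
         " samples), found ", length(key), call. = FALSE)
  }
  mk <- function(v, init) {
    m <- matrix(init, length(snps), length(samples),
                dimnames = list(snps, samples))
    m[cbind(i, j)] <- v
    m
  }
  SnpCallSet(mk(df$Allele1, NA_character_), mk(df$Allele2, NA_character_),
             mk(df$Score, NA_real_),
             manifest[match(snps, manifest$snp_id), , drop = FALSE])
}

#' Write a long-format genotype report
#'
#' Inverse of [readGenotypeReport()]: one row per SNP x sample, SNPs in row
#' order, samples in column order.
#'
#' @param x a [SnpCallSet].
#' @param path output TSV path.
#' @export
writeGenotypeReport <- function(x, path) {
  out <- data.frame(
    SnpID = rep(rownames(x), each = ncol(x)),
    SampleID = rep(colnames(x), nrow(x)),
    Allele1 = as.vector(t(assay(x, "allele1"))),
    Allele2 = as.vector(t(assay(x, "allele2"))),
    Score = as.vector(t(assay(x, "score"))),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genome assembly FASTA
#'
#' @param path FASTA path.
#' @return an uppercased [Biostrings::DNAStringSet] named by the first token
#'   of each header. Duplicate scaffold ids are an error; non-IUPAC characters
#'   are rejected by the underlying parser.
#' @export
readGenomeFasta <- function(path) {
  g <- readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  dup <- names(g)[duplicated(names(g))]
  if (length(dup)) {
    stop("duplicate scaffold id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  DNAStringSet(toupper(as.character(g)))
}

#' Write a genome assembly FASTA
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @param path output path.
#' @export
writeGenomeFasta <- function(genome, path) {
  writeXStringSet(genome, path)
  invisible(path)
}

#' Read a scaffold-to-chromosome synteny map
#'
#' TSV with columns `scaffold`, `chromosome`, `evidence` (evidence is
#' `synteny` or `cytogenetic`). A scaffold mapped to two different
#' chromosomes is an error; exact duplicate rows collapse.
#'
#' @param path TSV path.
#' @return data.frame with one row per scaffold.
#' @export
readSyntenyMap <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("scaffold", "chromosome", "evidence")
  stopIfNot(all(need %in% names(df)),
            paste("synteny map must have columns", paste(need, collapse = ", ")))
  df <- unique(df[, need])
  conf <- df$scaffold[duplicated(df$scaffold)]
  if (length(conf)) {
    stop("scaffold(s) mapped to conflicting chromosomes: ",
         paste(unique(conf), collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(df$evidence), c("synteny", "cytogenetic"))
  if (length(bad)) {
    stop("unknown evidence tag(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Write a scaffold-to-chromosome synteny map
#' @param map data.frame as returned by [readSyntenyMap()].
#' @param path output TSV path.
#' @export
writeSyntenyMap <- function(map, path) {
  write.table(map[, c("scaffold", "chromosome", "evidence")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotation from GFF3
#'
#' Imports `gene` features only. Coordinates stay 1-based inclusive inside
#' the returned [GenomicRanges::GRanges] (the GFF3 convention); downstream
#' distance arithmetic converts internally. A gene feature with `end <=
#' start` is rejected.
#'
#' @param path GFF3 path.
#' @return `GRanges` with an mcols column `gene_id`.
#' @export
readGeneAnnotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  if (any(width(gr) < 2L)) {
    bad <- which(width(gr) < 2L)[1]
    stop("gene feature with end <= start: ", gr$ID[bad], call. = FALSE)
  }
  id <- gr$ID
  if (is.null(id)) id <- gr$Name
  stopIfNot(!is.null(id) && !anyNA(id), "gene features must carry an ID")
  mcols(gr) <- DataFrame(gene_id = as.character(id))
  names(gr) <- gr$gene_id
  gr
}

#' Write gene annotation as GFF3
#' @param genes `GRanges` with a `gene_id` mcols column.
#' @param path output GFF3 path.
#' @export
writeGeneAnnotation <- function(genes, path) {
  out <- genes
  mcols(out) <- DataFrame(source = "xenoSNP", type = "gene",
                          ID = genes$gene_id)
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}
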