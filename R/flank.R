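## Flank-query construction, exact genome search, locus consolidation,
## uniqueness classification, cross-genome intersection and 101-nt contexts.

#' Build allele-terminated flank queries for exact genome search
#'
#' For each requested length L and each allele X of a manifest record, two
#' queries are built with the variant base at their 3' end:
#' the upstream query is the last `L - 1` nt of the 5' flank followed by X;
#' the downstream query is read on the negative strand -- the reverse
#' complement of X followed by the first `L - 1` nt of the 3' flank. With the
#' default lengths 21 and 26 a fully eligible record yields 8 queries. A
#' flank too short for a length omits that (side, length) query with a
#' warning.
#'
#' @param manifest manifest DataFrame (one or more records).
#' @param lengths query lengths; default `c(21, 26)` -- 20 or 25 perfectly
#'   matching nucleotides plus the variant base.
#' @return a [S4Vectors::DataFrame] with columns `snp_id`, `side`
#'   (`"upstream"`/`"downstream"`), `allele` (`"A"`/`"B"` role),
#'   `allele_base`, `length`, `sequence`.
#' @export
buildFlankQueries <- function(manifest, lengths = c(21L, 26L)) {
  stopIfNot(all(lengths >= 2L), "query lengths must be >= 2")
  rows <- list()
  skipped <- 0L
  for (r in seq_len(nrow(manifest))) {
    up <- manifest$flank_up[r]
    down <- manifest$flank_down[r]
    for (L in as.integer(lengths)) {
      for (role in c("A", "B")) {
        base <- if (role == "A") manifest$allele_a[r] else manifest$allele_b[r]
        if (nchar(up) >= L - 1L) {
          seqUp <- paste0(substr(up, nchar(up) - L + 2L, nchar(up)), base)
          rows[[length(rows) + 1L]] <- data.frame(
            snp_id = manifest$snp_id[r], side = "upstream", allele = role,
            allele_base = base, length = L, sequence = seqUp,
            stringsAsFactors = FALSE)
        } else skipped <- skipped + 1L
        if (nchar(down) >= L - 1L) {
          seqDown <- revComp(paste0(base, substr(down, 1L, L - 1L)))
          rows[[length(rows) + 1L]] <- data.frame(
            snp_id = manifest$snp_id[r], side = "downstream", allele = role,
            allele_base = base, length = L, sequence = seqDown,
            stringsAsFactors = FALSE)
        } else skipped <- skipped + 1L
      }
    }
  }
  if (skipped > 0L) {
    warning(skipped, " flank quer(ies) omitted: flank shorter than length - 1",
            call. = FALSE)
  }
  if (length(rows) == 0L) {
    return(DataFrame(snp_id = character(), side = character(),
                     allele = character(), allele_base = character(),
                     length = integer(), sequence = character()))
  }
  DataFrame(do.call(rbind, rows))
}

#' Exact occurrences of a short query in a genome
#'
#' Finds every perfect occurrence of `query` on the plus strand and of its
#' reverse complement on the plus strand (reported as minus-strand hits).
#' Because the variant base sits at the query's 3' end, a plus-strand match
#' starting at 0-based `s` implies the variant at `s + L - 1`; a minus-strand
#' match implies it at `s`. `N` in the genome never matches.
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @param query a single A/C/G/T string.
#' @return data.frame with columns `scaffold`, `strand`, `start`
#'   (0-based match start of the occurrence on the plus strand) and
#'   `variant_pos` (0-based coordinate of the implied variant base).
#' @export
searchExact <- function(genome, query) {
  stopIfNot(length(query) == 1L && grepl("^[ACGT]+$", query),
            "query must be a single string over A, C, G, T")
  L <- nchar(query)
  scanStrand <- function(pat, strand) {
    m <- vmatchPattern(pat, genome, fixed = TRUE)
    starts <- lapply(m, IRanges::start)
    n <- lengths(starts)
    s <- unlist(starts, use.names = FALSE)
    if (is.null(s)) s <- integer(0)
    data.frame(scaffold = rep(names(genome), n),
               strand = rep(strand, length(s)),
               start = s - 1L,
               variant_pos = if (strand == "+") s - 1L + L - 1L else s - 1L,
               stringsAsFactors = FALSE)
  }
  rbind(scanStrand(query, "+"), scanStrand(revComp(query), "-"))
}

.flipStrand <- function(s) ifelse(s == "+", "-", "+")

## batch exact search: all queries at once per width group via a PDict
## (Aho-Corasick), forward and reverse-complement. Same hit semantics as
## searchExact(); returns one data.frame with a query-index column.
.batchHits <- function(genome, seqs) {
  out <- list()
  scfNames <- names(genome)
  for (L in unique(nchar(seqs))) {
    idx <- which(nchar(seqs) == L)
    fwd <- seqs[idx]
    rc <- revComp(fwd)
    uniq <- unique(c(fwd, rc))
    pd <- Biostrings::PDict(DNAStringSet(uniq))
    fwdOf <- match(fwd, uniq)   # pattern slot of each query, + orientation
    rcOf <- match(rc, uniq)     # pattern slot of its reverse complement
    for (s in seq_along(genome)) {
      starts <- Biostrings::startIndex(Biostrings::matchPDict(pd, genome[[s]]))
      emit <- function(slotOf, strand) {
        hitN <- lengths(starts)[slotOf]
        keep <- which(hitN > 0L)
        if (length(keep) == 0L) return(NULL)
        st <- unlist(starts[slotOf[keep]], use.names = FALSE)
        data.frame(qIdx = rep(idx[keep], hitN[keep]),
                   scaffold = scfNames[s], strand = strand,
                   start = st - 1L,
                   variant_pos = if (strand == "+") st - 1L + L - 1L
                                 else st - 1L,
                   stringsAsFactors = FALSE)
      }
      out[[length(out) + 1L]] <- emit(fwdOf, "+")
      out[[length(out) + 1L]] <- emit(rcOf, "-")
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(qIdx = integer(), scaffold = character(),
                      strand = character(), start = integer(),
                      variant_pos = integer(), stringsAsFactors = FALSE)
  }
  out
}

#' Consolidate flank-query hits into SNP loci
#'
#' A locus is emitted where an upstream-derived hit and a downstream-derived
#' hit imply the same (scaffold, variant position, orientation). Upstream
#' queries anchor the locus in the orientation of their hit; downstream
#' queries, being read on the negative strand, anchor it in the opposite
#' orientation. `supported_21`/`supported_26` record which lengths co-matched
#' on both sides; the co-located 21-nt pair is the minimum evidence unless
#' `require26 = TRUE`. Queries containing `N` are skipped (never match).
#'
#' @param genome a named [Biostrings::DNAStringSet] (one assembly).
#' @param queries query table from [buildFlankQueries()].
#' @param require26 require the 26-nt pair instead of the 21-nt minimum.
#' @return a [S4Vectors::DataFrame] of loci: `snp_id`, `scaffold`,
#'   `variant_pos` (0-based), `strand`, `supported_21`, `supported_26`,
#'   `alleles` (comma-joined matched allele roles).
#' @export
locateSnp <- function(genome, queries, require26 = FALSE) {
  qdf <- as.data.frame(queries)
  hasN <- grepl("N", qdf$sequence, fixed = TRUE)
  if (any(hasN)) {
    warning(sum(hasN), " quer(ies) containing N skipped", call. = FALSE)
    qdf <- qdf[!hasN, , drop = FALSE]
  }
  hits <- if (nrow(qdf) > 0L) .batchHits(genome, qdf$sequence)
          else NULL
  if (!is.null(hits) && nrow(hits) > 0L) {
    hits$snp_id <- qdf$snp_id[hits$qIdx]
    hits$side <- qdf$side[hits$qIdx]
    hits$allele <- qdf$allele[hits$qIdx]
    hits$length <- qdf$length[hits$qIdx]
    hits$locus_strand <- ifelse(hits$side == "upstream", hits$strand,
                                .flipStrand(hits$strand))
  } else hits <- NULL
  empty <- DataFrame(snp_id = character(), scaffold = character(),
                     variant_pos = integer(), strand = character(),
                     supported_21 = logical(), supported_26 = logical(),
                     alleles = character())
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  key <- paste(hits$snp_id, hits$scaffold, hits$variant_pos,
               hits$locus_strand, sep = "\r")
  out <- lapply(split(hits, key), function(h) {
    lens <- sort(unique(h$length))
    sup <- vapply(lens, function(L) {
      any(h$side == "upstream" & h$length == L) &&
        any(h$side == "downstream" & h$length == L)
    }, logical(1))
    supported <- lens[sup]
    minOk <- if (require26) 26L %in% supported else 21L %in% supported
    if (!minOk) return(NULL)
    both <- h[h$length %in% supported, ]
    data.frame(snp_id = h$snp_id[1], scaffold = h$scaffold[1],
               variant_pos = h$variant_pos[1], strand = h$locus_strand[1],
               supported_21 = 21L %in% supported,
               supported_26 = 26L %in% supported,
               alleles = paste(sort(unique(both$allele)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out <- out[order(out$snp_id, out$scaffold, out$variant_pos, out$strand), ]
  rownames(out) <- NULL
  DataFrame(out)
}

#' Classify per-SNP locus uniqueness in one genome
#'
#' `unique` means exactly one locus; more than one locus is `multi_scaffold`
#' when the loci spread over several scaffolds and `multi_within_scaffold`
#' when they repeat within one; no locus is `absent`. Only `unique` SNPs are
#' retained downstream.
#'
#' @param loci locus table from [locateSnp()].
#' @param snpIds the full set of SNP ids under consideration (so that SNPs
#'   with no locus are classified `absent`).
#' @return data.frame with columns `snp_id`, `class`, `n_loci`.
#' @export
classifyUniqueness <- function(loci, snpIds) {
  ldf <- as.data.frame(loci)
  nLoci <- table(factor(ldf$snp_id, levels = snpIds))
  cls <- vapply(snpIds, function(id) {
    rows <- ldf[ldf$snp_id == id, , drop = FALSE]
    if (nrow(rows) == 0L) "absent"
    else if (nrow(rows) == 1L) "unique"
    else if (length(unique(rows$scaffold)) > 1L) "multi_scaffold"
    else "multi_within_scaffold"
  }, character(1))
  data.frame(snp_id = snpIds, class = unname(cls),
             n_loci = as.integer(nLoci[snpIds]), stringsAsFactors = FALSE)
}

#' Intersect uniqueness calls across two genomes
#'
#' Retains the SNPs classified `unique` in both assemblies.
#'
#' @param callsA,callsB uniqueness tables from [classifyUniqueness()].
#' @return character vector of retained SNP ids.
#' @export
intersectGenomes <- function(callsA, callsB) {
  intersect(callsA$snp_id[callsA$class == "unique"],
            callsB$snp_id[callsB$class == "unique"])
}

#' Extract the variant-centred sequence context
#'
#' Returns the `2 * flank + 1` nt window around a located variant (101 nt at
#' the default), reverse-complemented for minus-strand loci so the returned
#' sequence reads in the probe orientation with the variant base at 0-based
#' index `flank`. A variant within `flank` of a scaffold edge yields a
#' truncated context flagged `truncated = TRUE`; such SNPs are excluded from
#' conservation checks.
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @param scaffold scaffold id.
#' @param variantPos 0-based variant coordinate.
#' @param strand `"+"` or `"-"`.
#' @param flank context radius in nt (default 50).
#' @return list with `sequence`, `truncated`, and `variant_index` (0-based
#'   position of the variant base within `sequence`).
#' @export
extractContext <- function(genome, scaffold, variantPos, strand = "+",
                           flank = 50L) {
  stopIfNot(scaffold %in% names(genome),
            paste0("scaffold '", scaffold, "' not in genome"))
  len <- length(genome[[scaffold]])
  stopIfNot(variantPos >= 0L && variantPos < len,
            "variant position outside scaffold bounds")
  lo <- max(0L, variantPos - flank)
  hi <- min(len - 1L, variantPos + flank)
  s <- as.character(subseq(genome[[scaffold]], lo + 1L, hi + 1L))
  idx <- variantPos - lo
  if (strand == "-") {
    s <- revComp(s)
    idx <- hi - variantPos
  }
  list(sequence = s, truncated = (variantPos - flank < 0L) ||
         (variantPos + flank > len - 1L), variant_index = idx)
}

#' Check conservation of a variant context in another genome
#'
#' Conserved iff the full-length context, with either allele substituted at
#' the variant position (and on either strand), occurs at least once in the
#' other genome by perfect match.
#'
#' @param context a full (untruncated) context string of length
#'   `2 * flank + 1`.
#' @param otherGenome a [Biostrings::DNAStringSet] (e.g. an outgroup
#'   assembly).
#' @param alleles bases to substitute at the centre; the context's own centre
#'   base is always tried.
#' @param flank context radius used at extraction (default 50).
#' @return `TRUE` (conserved) or `FALSE`.
#' @export
conservationCheck <- function(context, otherGenome, alleles = character(),
                              flank = 50L) {
  stopIfNot(nchar(context) == 2L * flank + 1L,
            "conservation check requires a full, untruncated context")
  centre <- substr(context, flank + 1L, flank + 1L)
  cands <- unique(c(centre, toupper(alleles)))
  for (b in cands) {
    s <- context
    substr(s, flank + 1L, flank + 1L) <- b
    if (grepl("N", s, fixed = TRUE)) next
    if (sum(vcountPattern(s, otherGenome, fixed = TRUE)) > 0L ||
        sum(vcountPattern(revComp(s), otherGenome, fixed = TRUE)) > 0L) {
      return(TRUE)
    }
  }
  FALSE
}

#' Write loci as BED (0-based half-open, variant as a 1-bp interval)
#' @param loci locus table from [locateSnp()].
#' @param path output BED path.
#' @export
writeLociBed <- function(loci, path) {
  ldf <- as.data.frame(loci)
  bed <- data.frame(ldf$scaffold, ldf$variant_pos, ldf$variant_pos + 1L,
                    ldf$snp_id, 0L, ldf$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
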