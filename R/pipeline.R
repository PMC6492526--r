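## End-to-end orchestration: metrics -> method cascades -> flank validation
## on the selected method's MAF-retained set -> cross-genome intersection ->
## context extraction -> conservation -> chromosome assignment -> nearest
## genes -> summary report. Every stage's output is persisted.

#' Assemble a pipeline configuration
#'
#' Inputs may be file paths (read with the package's readers) or the
#' corresponding in-memory objects. The cascade is computed for all
#' `methods`; flank validation then runs on the `validateMethod` cascade's
#' survivors at MAF >= `mafLevel`. The defaults pair the most stringent
#' built-in method (VI) with the 0.01 retained-MAF level; methods validated
#' individually in batch comparisons conventionally use 0.05.
#'
#' @param report genotype report TSV path or a [SnpCallSet].
#' @param manifest manifest CSV path or DataFrame (required when `report` is
#'   a path).
#' @param genomeA,genomeB target assembly FASTA paths or DNAStringSet.
#' @param outgroup optional outgroup assembly for conservation checks.
#' @param syntenyMap optional synteny map TSV path or data.frame.
#' @param genes optional gene annotation GFF3 path or GRanges.
#' @param methods method names to run (default all seven built-ins).
#' @param validateMethod the method whose MAF survivors get flank-validated.
#' @param mafLevel retained-MAF level for validation (0.01 or 0.05).
#' @param minFlank 21 (default) or 26: minimum co-located query length.
#' @param report_config a [reportConfig()].
#' @param outDir output directory for per-stage artifacts.
#' @return a list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(report, manifest = NULL, genomeA, genomeB,
                           outgroup = NULL, syntenyMap = NULL, genes = NULL,
                           methods = c("I", "II", "III", "IV", "V", "VI",
                                       "VII"),
                           validateMethod = "VI", mafLevel = 0.01,
                           minFlank = 21L, report_config = reportConfig(),
                           outDir) {
  structure(list(report = report, manifest = manifest, genomeA = genomeA,
                 genomeB = genomeB, outgroup = outgroup,
                 syntenyMap = syntenyMap, genes = genes, methods = methods,
                 validateMethod = validateMethod, mafLevel = mafLevel,
                 minFlank = as.integer(minFlank),
                 report_config = report_config, outDir = outDir),
            class = "PipelineConfig")
}

#' Validate a pipeline configuration
#'
#' Pure validation with no side effects: problems are returned as a
#' character vector, never raised. An empty vector means the configuration
#' is runnable.
#'
#' @param config a [pipelineConfig()].
#' @return character vector of problems (empty when valid).
#' @export
validateConfig <- function(config) {
  problems <- character()
  if (!inherits(config, "PipelineConfig")) {
    return("config must be built with pipelineConfig()")
  }
  for (field in c("report", "manifest", "genomeA", "genomeB", "outgroup",
                  "syntenyMap", "genes")) {
    v <- config[[field]]
    if (is.character(v) && length(v) == 1L && !file.exists(v)) {
      problems <- c(problems, paste0("input file for '", field,
                                     "' does not exist: ", v))
    }
  }
  badM <- setdiff(config$methods, names(.METHOD_TABLE))
  if (length(badM)) {
    problems <- c(problems, paste0("unknown method name(s): ",
                                   paste(badM, collapse = ", ")))
  }
  if (!config$validateMethod %in% config$methods) {
    problems <- c(problems, paste0("validateMethod '", config$validateMethod,
                                   "' is not among the methods to run"))
  }
  if (!config$mafLevel %in% c(0.01, 0.05)) {
    problems <- c(problems, "mafLevel must be 0.01 or 0.05")
  }
  if (!config$minFlank %in% c(21L, 26L)) {
    problems <- c(problems, "minFlank must be 21 or 26")
  }
  if (is.character(config$report) && is.null(config$manifest)) {
    problems <- c(problems, "a manifest is required to read a report path")
  }
  problems
}

.loadInput <- function(v, reader, ...) {
  if (is.null(v) || !is.character(v)) v else reader(v, ...)
}

#' Run the full discovery pipeline
#'
#' Executes metrics, all requested method cascades, flank validation of the
#' selected method's MAF-retained survivors against both assemblies,
#' uniqueness classification and cross-genome intersection, 101-nt context
#' extraction, conservation against the outgroup (when given), chromosome
#' assignment, nearest-gene annotation and the summary report.
#' Hardy-Weinberg equilibrium is evaluated on the final retained set and
#' reported, never used as a filter. Re-running with identical inputs
#' produces byte-identical artifacts.
#'
#' @param config a validated [pipelineConfig()].
#' @param verbose log per-stage counts to the console.
#' @return (invisibly) a list with every intermediate: `metrics`,
#'   `cascades`, `validated` ids, `loci` and `uniqueness` per genome,
#'   `retained`, `contexts`, `conservation`, `assignments`, `annotations`,
#'   `summary`.
#' @export
runPipeline <- function(config, verbose = FALSE) {
  problems <- validateConfig(config)
  if (length(problems)) {
    stop("invalid pipeline configuration:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  say <- function(...) if (verbose) message("[xenoSNP] ", ...)
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  outFile <- function(f) file.path(config$outDir, f)

  manifest <- .loadInput(config$manifest, readSnpManifest)
  x <- if (is.character(config$report)) {
    readGenotypeReport(config$report, manifest)
  } else config$report
  if (is.null(manifest)) manifest <- rowData(x)
  genomeA <- .loadInput(config$genomeA, readGenomeFasta)
  genomeB <- .loadInput(config$genomeB, readGenomeFasta)
  outgroup <- .loadInput(config$outgroup, readGenomeFasta)
  syntenyMap <- .loadInput(config$syntenyMap, readSyntenyMap)
  genes <- .loadInput(config$genes, readGeneAnnotation)
  say("inputs: ", nrow(x), " SNPs x ", ncol(x), " samples")

  ## -- method cascades ------------------------------------------------------
  cascades <- compareMethods(x, config$methods)
  writeCascadeCounts(cascades, outFile("cascade_counts.tsv"),
                     outFile("cascade_counts.json"))
  vmCfg <- methodConfig(config$validateMethod)
  metrics <- snpMetrics(x, vmCfg@noCallThreshold)
  writeSnpMetrics(metrics, outFile("metrics.tsv"))
  validated <- survivors(cascades[[config$validateMethod]],
                         .mafStageName(config$mafLevel))
  say("method ", config$validateMethod, " MAF >= ", config$mafLevel,
      " survivors: ", length(validated))

  ## -- flank validation -----------------------------------------------------
  queries <- buildFlankQueries(
    manifest[manifest$snp_id %in% validated, , drop = FALSE])
  loci <- list(A = locateSnp(genomeA, queries,
                             require26 = config$minFlank == 26L),
               B = locateSnp(genomeB, queries,
                             require26 = config$minFlank == 26L))
  writeLociBed(loci$A, outFile("loci_genomeA.bed"))
  writeLociBed(loci$B, outFile("loci_genomeB.bed"))
  uniqueness <- lapply(loci, classifyUniqueness, snpIds = validated)
  for (g in names(uniqueness)) {
    write.table(uniqueness[[g]], outFile(paste0("uniqueness_genome", g,
                                                ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  retained <- intersectGenomes(uniqueness$A, uniqueness$B)
  writeLines(retained, outFile("retained_snps.txt"))
  say("retained (unique in both genomes): ", length(retained))

  ## -- contexts + conservation (coordinates on genome A) --------------------
  lociA <- as.data.frame(loci$A)
  lociA <- lociA[lociA$snp_id %in% retained, , drop = FALSE]
  contexts <- lapply(seq_len(nrow(lociA)), function(k) {
    extractContext(genomeA, lociA$scaffold[k], lociA$variant_pos[k],
                   lociA$strand[k])
  })
  names(contexts) <- lociA$snp_id
  ctxLines <- unlist(lapply(names(contexts), function(id) {
    c(paste0(">", id, if (contexts[[id]]$truncated) " truncated" else ""),
      contexts[[id]]$sequence)
  }))
  writeLines(if (is.null(ctxLines)) character() else ctxLines,
             outFile("contexts.fasta"))
  conservation <- NULL
  if (!is.null(outgroup)) {
    full <- names(contexts)[!vapply(contexts, `[[`, logical(1), "truncated")]
    conservation <- vapply(full, function(id) {
      alleles <- c(manifest[id, "allele_a"], manifest[id, "allele_b"])
      conservationCheck(contexts[[id]]$sequence, outgroup, alleles)
    }, logical(1))
    say("conserved in outgroup: ", sum(conservation), " of ",
        length(conservation))
  }

  ## -- annotation -----------------------------------------------------------
  assignments <- annotations <- NULL
  if (!is.null(syntenyMap)) {
    assignments <- assignChromosome(syntenyMap, lociA)
    write.table(assignments, outFile("chromosome_assignments.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    dist <- chromosomeDistribution(assignments)
    write.table(data.frame(chromosome = names(dist), n = as.integer(dist)),
                outFile("chromosome_distribution.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(genes)) {
    annotations <- nearestGene(genes, lociA)
    write.table(annotations, outFile("nearest_genes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  ## -- summary --------------------------------------------------------------
  hweRetained <- metrics[metrics$snp_id %in% retained, , drop = FALSE]
  summary <- buildSummary(cascades = cascades, uniqueness = uniqueness,
                          retained = retained, assignments = assignments,
                          annotations = annotations,
                          conservation = conservation, hwe = hweRetained,
                          config = config$report_config)
  writeSummary(summary, outFile("summary.json"))
  say("summary written to ", outFile("summary.json"))

  invisible(list(metrics = metrics, cascades = cascades,
                 validated = validated, loci = loci,
                 uniqueness = uniqueness, retained = retained,
                 contexts = contexts, conservation = conservation,
                 assignments = assignments, annotations = annotations,
                 summary = summary))
}
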