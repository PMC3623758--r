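## End-to-end pipeline orchestration.

#' Pipeline configuration
#'
#' Aggregates every tunable threshold of the pipeline, with the study-scale
#' defaults: contigs under 2.5X mean coverage per individual discarded,
#' genotypes called at posterior 0.95 with at least 10 reads (30 in the
#' high-coverage control), paralogy filter at p < 0.001, NI_0.2 MAF cutoff
#' 0.2, SFS projection to 12 sequences.
#'
#' @param minMeanCoverage contig-level coverage filter (X per individual).
#' @param posteriorThreshold,minCoverage,mode,seed see [callerConfig()].
#' @param paralogFilter apply the paralogy filter (disable to reproduce the
#'   no-filter control).
#' @param paralogAlpha significance level of the paralogy test.
#' @param mafCutoff minor-allele-frequency cutoff for NI_0.2.
#' @param projectionN SFS projection sample size.
#' @param nBootstrap contig bootstrap replicates for confidence intervals.
#' @param dsOutlierFilter apply the dS-outlier contig filter (needs an
#'   outgroup).
#' @return a list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(minMeanCoverage = 2.5, posteriorThreshold = 0.95,
                           minCoverage = 10L, mode = "threshold",
                           paralogFilter = TRUE, paralogAlpha = 0.001,
                           mafCutoff = 0.2, projectionN = 12L,
                           nBootstrap = 1000L, dsOutlierFilter = TRUE,
                           seed = 1L) {
  structure(list(minMeanCoverage = minMeanCoverage,
                 caller = callerConfig(posteriorThreshold, minCoverage,
                                       mode, seed),
                 paralogFilter = paralogFilter,
                 paralogAlpha = paralogAlpha, mafCutoff = mafCutoff,
                 projectionN = as.integer(projectionN),
                 nBootstrap = as.integer(nBootstrap),
                 dsOutlierFilter = dsOutlierFilter,
                 seed = as.integer(seed)),
            class = "pipelineConfig")
}

#' Run the full pipeline on base counts
#'
#' Stage order: coverage-based contig filter, per-contig error-rate
#' estimation, genotype calling, SNP identification, paralogy testing, ORF
#' restriction and codon-alignment construction, alignment cleaning, SNP
#' classification and per-contig statistics, dS-outlier filtering,
#' species-level summary, and site-frequency spectra with Tajima's D.
#' Identical inputs, configuration and seed give identical outputs. Record
#' counts of every stage are collected in the returned `log`.
#'
#' @param countsList named list of [ContigCounts] (duplicate-collapsed), or
#'   a count-table TSV path.
#' @param sequences optional contig `DNAStringSet` (or FASTA path); needed
#'   when `orfs` is missing (ORFs are then predicted with [longestOrf()]).
#' @param orfs optional ORF table (data.frame contig/start/end 0-based
#'   half-open, or a BED/GFF3 path).
#' @param outgroups optional named character vector of outgroup sequences
#'   pre-aligned to contig coordinates.
#' @param config a [pipelineConfig()].
#' @param outDir optional output directory for artifacts (VCF, TSV tables,
#'   JSON run summary).
#' @return list with elements `log`, `errorModels`, `calls`, `snps`,
#'   `alignments`, `contigStats`, `summary`, `sfs`, `heterozygosity`.
#' @export
runPipeline <- function(countsList, sequences = NULL, orfs = NULL,
                        outgroups = NULL, config = pipelineConfig(),
                        outDir = NULL) {
  log <- list()
  note <- function(stage, n) {
    log[[length(log) + 1L]] <<- data.frame(stage = stage, n = n)
    message(sprintf("[rnapopgen] %-28s %d", stage, n))
  }
  if (is.character(countsList)) countsList <- readCountTable(countsList)
  if (is.character(sequences)) sequences <- readContigFasta(sequences)
  if (is.character(orfs)) orfs <- readOrfAnnotations(orfs)
  note("contigs in", length(countsList))

  flt <- filterLowCoverageContigs(countsList, config$minMeanCoverage)
  countsList <- flt$retained
  note("contigs >= coverage filter", length(countsList))

  if (is.null(orfs)) {
    if (is.null(sequences)) stop("either 'orfs' or 'sequences' required")
    orfs <- do.call(rbind, lapply(names(countsList), function(ctg) {
      o <- longestOrf(sequences[[ctg]])
      if (is.null(o)) return(NULL)
      data.frame(contig = ctg, start = o$start, end = o$end)
    }))
  }

  errorModels <- list(); calls <- list(); snpTabs <- list()
  for (ctg in names(countsList)) {
    em <- estimateErrorRate(countsList[[ctg]])
    cl <- callGenotypes(countsList[[ctg]], em, config = config$caller)
    errorModels[[ctg]] <- em
    calls[[ctg]] <- cl
    sn <- identifySnps(cl)
    sn <- testContigParalogs(sn, countsList[[ctg]], cl,
                             alpha = config$paralogAlpha)
    snpTabs[[ctg]] <- sn
  }
  snps <- do.call(rbind, c(snpTabs, list(make.row.names = FALSE)))
  if (is.null(snps)) snps <- cbind(identifySnps0(), emptyParalogCols())
  note("SNPs called", nrow(snps))

  if (config$paralogFilter) {
    part <- applyParalogFilter(snps)
    snps <- part$retained
    flagged <- part$flagged
  } else {
    snps$paralogTested <- !is.na(snps$applicable) & snps$applicable
    snps$paralogFlag <- FALSE
    flagged <- snps[0, , drop = FALSE]
  }
  note("SNPs after paralog filter", nrow(snps))

  ## codon alignments, masking paralog-flagged sites
  alignments <- list()
  for (ctg in names(countsList)) {
    orf <- orfs[orfs$contig == ctg, , drop = FALSE]
    if (nrow(orf) == 0L) next
    og <- if (!is.null(outgroups) && ctg %in% names(outgroups))
      outgroups[[ctg]] else NULL
    aln <- buildCodonAlignment(calls[[ctg]], orf[1, ], og)
    if (is.null(aln)) next
    aln <- cleanAlignment(aln)
    if (is.null(aln)) next
    if (config$paralogFilter) {
      bad <- flagged$site[flagged$contig == ctg]
      if (length(bad)) {
        rows <- which(aln@sitePos %in% bad)
        if (length(rows)) aln@haplotypes[rows, ] <- NA_character_
      }
    }
    alignments[[ctg]] <- aln
  }
  note("contigs with cleaned alignment", length(alignments))

  cs <- do.call(rbind, lapply(alignments, contigStats,
                              mafCutoff = config$mafCutoff))
  if (!is.null(cs) && config$dsOutlierFilter && any(!is.na(cs$dS)))
    cs <- dsOutlierFilter(cs)
  note("contigs analyzed", if (is.null(cs)) 0L else nrow(cs))

  summary <- if (!is.null(cs) && nrow(cs) >= 2L)
    speciesSummary(cs, nBootstrap = config$nBootstrap, seed = config$seed)
  else NULL

  ## spectra from all biallelic SNPs of the cleaned alignments
  sfsSnps <- do.call(rbind, lapply(alignments[names(alignments) %in%
                                              (if (is.null(cs)) character()
                                               else cs$contig)],
                                   alignmentSnps, completeOnly = FALSE))
  sfs <- NULL
  if (!is.null(sfsSnps) && nrow(sfsSnps)) {
    mk <- function(d) {
      s <- projectAndFold(d, n = config$projectionN)
      list(sfs = s, tajimaD = tajimasD(s))
    }
    sfs <- list(all = mk(sfsSnps),
                syn = mk(sfsSnps[sfsSnps$class == "SYN", , drop = FALSE]),
                nonsyn = mk(sfsSnps[sfsSnps$class == "NONSYN", ,
                                    drop = FALSE]))
  }

  hz <- if (length(calls)) perIndividualHeterozygosity(unname(calls))
        else NULL

  res <- list(log = do.call(rbind, log), errorModels = errorModels,
              calls = calls, snps = snps, flagged = flagged,
              alignments = alignments, contigStats = cs,
              summary = summary, sfs = sfs, heterozygosity = hz)
  if (!is.null(outDir)) writePipelineArtifacts(res, countsList, outDir)
  res
}

identifySnps0 <- function() {
  data.frame(contig = character(), site = integer(), allele1 = character(),
             allele2 = character(), nAlleles = integer(),
             multiallelic = logical(), nMissing = integer(),
             nHaplotypes = integer(), minorCount = integer(),
             maf = numeric(), stringsAsFactors = FALSE)
}

## Serialise pipeline outputs to a directory.
writePipelineArtifacts <- function(res, countsList, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  allSnps <- rbind(res$snps, res$flagged)
  if (nrow(allSnps)) allSnps <- allSnps[order(allSnps$contig, allSnps$site), ]
  writeSnpVcf(allSnps, res$calls, file.path(outDir, "snps.vcf"))
  wt <- function(d, f) utils::write.table(
    d, file.path(outDir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(allSnps, "paralog_tests.tsv")
  if (!is.null(res$contigStats)) wt(res$contigStats, "contig_stats.tsv")
  if (!is.null(res$summary)) {
    wt(res$summary$summary, "species_summary.tsv")
    if (!is.null(res$summary$ci)) wt(res$summary$ci, "species_summary_ci.tsv")
  }
  if (!is.null(res$sfs)) {
    writeSfsTable(res$sfs$syn$sfs, file.path(outDir, "sfs_syn.tsv"))
    writeSfsTable(res$sfs$nonsyn$sfs, file.path(outDir, "sfs_nonsyn.tsv"))
  }
  jsonlite::write_json(
    list(log = res$log,
         tajimaD = if (!is.null(res$sfs))
           list(syn = res$sfs$syn$tajimaD,
                nonsyn = res$sfs$nonsyn$tajimaD) else NULL),
    file.path(outDir, "run_summary.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(outDir)
}
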