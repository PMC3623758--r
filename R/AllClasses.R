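#' @import methods
NULL

## Base and genotype orderings used throughout the package.  Genotypes are the
## 10 unordered diploid base pairs; the 16 ordered pairs collapse onto these
## because read likelihoods cannot distinguish XY from YX.
BASES <- c("A", "C", "G", "T")
GENOTYPES <- c("AA", "AC", "AG", "AT", "CC", "CG", "CT", "GG", "GT", "TT")

## allele composition of each genotype: 10 x 4 dosage matrix (rows sum to 2)
GT_DOSAGE <- local({
  m <- matrix(0L, 10L, 4L, dimnames = list(GENOTYPES, BASES))
  for (g in GENOTYPES) {
    a <- strsplit(g, "")[[1]]
    m[g, a[1]] <- m[g, a[1]] + 1L
    m[g, a[2]] <- m[g, a[2]] + 1L
  }
  m
})

#' ContigCounts: per-site, per-individual base counts for one contig
#'
#' The sole input of the genotype caller: for every site of one assembled
#' contig and every individual, the number of mapped reads supporting each of
#' the four bases (A, C, G, T order). Counts are stored as a
#' sites x individuals x 4 integer array. Sites are 0-based internally.
#'
#' @slot contig single contig identifier.
#' @slot individuals ordered character vector of individual identifiers.
#' @slot counts integer array of dimension `c(sites, individuals, 4)`.
#'
#' @seealso [recordsToCounts()], [readCountTable()], [coverageMatrix()]
#' @export
setClass("ContigCounts",
  representation(contig = "character", individuals = "character",
                 counts = "array"))

setValidity("ContigCounts", function(object) {
  d <- dim(object@counts)
  msg <- character(0)
  if (length(object@contig) != 1L)
    msg <- c(msg, "'contig' must be a single identifier")
  if (length(d) != 3L || d[3] != 4L)
    msg <- c(msg, "'counts' must be a sites x individuals x 4 array")
  else if (d[2] != length(object@individuals))
    msg <- c(msg, "dim 2 of 'counts' must match length(individuals)")
  if (anyNA(object@counts) || any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative and non-missing")
  if (length(msg)) msg else TRUE
})

#' ErrorModel: maximum-likelihood per-contig error rate
#'
#' The sequencing/mapping error rate epsilon shared across sites of one
#' contig, estimated by profile maximum likelihood (allele frequencies
#' maximised out per site by EM).
#'
#' @slot contig contig identifier.
#' @slot epsilon error probability per read base, in [0, 0.75).
#' @slot logLik maximised log-likelihood (nats).
#' @slot converged logical, alternating maximisation convergence status.
#' @slot iterations outer iterations used.
#'
#' @seealso [estimateErrorRate()]
#' @export
setClass("ErrorModel",
  representation(contig = "character", epsilon = "numeric",
                 logLik = "numeric", converged = "logical",
                 iterations = "integer"))

setValidity("ErrorModel", function(object) {
  if (object@epsilon < 0 || object@epsilon >= 0.75)
    return("epsilon must lie in [0, 0.75)")
  if (!is.finite(object@logLik))
    return("logLik must be finite")
  TRUE
})

#' GenotypeCalls: posterior genotype calls for one contig
#'
#' Diploid genotype calls for every site and individual of one contig.
#' Genotypes are unordered base pairs ("AC") or `NA` for missing data
#' (insufficient coverage or no genotype reaching the posterior threshold).
#'
#' @slot contig contig identifier.
#' @slot individuals individual identifiers (column order of the matrices).
#' @slot genotype character matrix sites x individuals; `NA` = missing.
#' @slot posterior numeric matrix of the posterior probability of the
#'   called (or best-supported) genotype.
#' @slot coverage integer matrix of per-site per-individual read counts.
#' @slot freqs numeric matrix sites x 4 of ML allele frequencies.
#' @slot epsilon the error rate used for calling.
#'
#' @seealso [callGenotypes()], [identifySnps()]
#' @export
setClass("GenotypeCalls",
  representation(contig = "character", individuals = "character",
                 genotype = "matrix", posterior = "matrix",
                 coverage = "matrix", freqs = "matrix", epsilon = "numeric"))

setValidity("GenotypeCalls", function(object) {
  d <- dim(object@genotype)
  if (!all(dim(object@posterior) == d) || !all(dim(object@coverage) == d))
    return("genotype, posterior and coverage matrices must share dimensions")
  if (d[2] != length(object@individuals))
    return("columns must match individuals")
  ok <- is.na(object@genotype) | object@genotype %in% GENOTYPES
  if (!all(ok)) return("genotypes must be unordered base pairs or NA")
  TRUE
})

#' CodonAlignment: pseudo-haplotype codon alignment for one contig
#'
#' Within-ORF alignment of two pseudo-haplotypes per individual (phase is
#' arbitrary; every downstream statistic is phase-free) plus an optional
#' outgroup sequence pre-aligned to contig coordinates. States are single
#' bases or `NA`; codons containing any `NA` are treated as wholly missing.
#'
#' @slot contig contig identifier.
#' @slot haplotypes character matrix, nucleotide sites x haplotypes, with
#'   column names `<individual>_1`, `<individual>_2`.
#' @slot outgroup character vector of outgroup bases aligned to the same
#'   sites, or `character(0)` when no outgroup is available.
#' @slot sitePos integer vector of 0-based contig coordinates of each row.
#'
#' @seealso [buildCodonAlignment()], [cleanAlignment()]
#' @export
setClass("CodonAlignment",
  representation(contig = "character", haplotypes = "matrix",
                 outgroup = "character", sitePos = "integer"))

setValidity("CodonAlignment", function(object) {
  L <- nrow(object@haplotypes)
  if (L %% 3L != 0L)
    return("alignment length must be a multiple of 3")
  if (length(object@sitePos) != L)
    return("sitePos must have one entry per alignment row")
  if (length(object@outgroup) && length(object@outgroup) != L)
    return("outgroup must be empty or of alignment length")
  ok <- is.na(object@haplotypes) | object@haplotypes %in% BASES
  if (!all(ok)) return("haplotype states must be A/C/G/T or NA")
  TRUE
})

#' FoldedSFS: folded site-frequency spectrum at fixed projected size
#'
#' Fractional minor-allele-count spectrum after hypergeometric projection of
#' every SNP to a common number of sequences `n`. Mass projected into the
#' monomorphic classes (0 and n) is discarded without renormalisation, so the
#' total mass can be below the number of SNPs used.
#'
#' @slot n projected haplotype count (pipeline default 12).
#' @slot mass numeric vector of fractional masses for minor-allele classes
#'   `1..floor(n/2)`.
#' @slot nUsed number of SNPs that entered the projection.
#' @slot nDiscarded number of SNPs sampled in fewer than `n` sequences.
#'
#' @seealso [projectAndFold()], [tajimasD()]
#' @export
setClass("FoldedSFS",
  representation(n = "integer", mass = "numeric", nUsed = "integer",
                 nDiscarded = "integer"))

setValidity("FoldedSFS", function(object) {
  if (length(object@mass) != object@n %/% 2L)
    return("mass must have floor(n/2) classes")
  if (any(object@mass < -1e-12))
    return("masses must be non-negative")
  TRUE
})

setMethod("show", "ContigCounts", function(object) {
  d <- dim(object@counts)
  cat("ContigCounts '", object@contig, "': ", d[1], " sites x ", d[2],
      " individuals; total reads per site per individual (mean) ",
      round(mean(apply(object@counts, c(1, 2), sum)), 2), "X\n", sep = "")
})

setMethod("show", "ErrorModel", function(object) {
  cat("ErrorModel '", object@contig, "': epsilon = ",
      signif(object@epsilon, 4), ", logLik = ", round(object@logLik, 2),
      if (!object@converged) " (not converged)", "\n", sep = "")
})

setMethod("show", "GenotypeCalls", function(object) {
  d <- dim(object@genotype)
  cat("GenotypeCalls '", object@contig, "': ", d[1], " sites x ", d[2],
      " individuals; ", sum(is.na(object@genotype)), " missing calls; ",
      "epsilon = ", signif(object@epsilon, 4), "\n", sep = "")
})

setMethod("show", "CodonAlignment", function(object) {
  cat("CodonAlignment '", object@contig, "': ", nrow(object@haplotypes) %/% 3L,
      " codon sites x ", ncol(object@haplotypes), " haplotypes",
      if (length(object@outgroup)) " + outgroup", "\n", sep = "")
})

setMethod("show", "FoldedSFS", function(object) {
  cat("FoldedSFS (n = ", object@n, "): ", object@nUsed, " SNPs projected, ",
      object@nDiscarded, " discarded\n", sep = "")
  print(round(stats::setNames(object@mass, seq_along(object@mass)), 3))
})
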