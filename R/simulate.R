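## Generative models with known truth for every pipeline stage.
##
## Datasets are simulated directly at the read-count level (no FASTQ): each
## contig is a single ORF built from fourfold-degenerate codon families, so
## third codon positions are synonymous sites and first/second positions
## non-synonymous sites. Polymorphic sites follow the neutral 1/k
## frequency law by default, genotypes are drawn under Hardy-Weinberg with
## optional inbreeding, read counts are Poisson-distributed per individual
## with beta-binomial allele-expression bias for heterozygotes, and a
## symmetric error channel with the true epsilon corrupts read bases.
## Collapsed paralogous sites mix reads of two fixed loci with a mixing
## proportion p shared across individuals.

## codon families whose 3rd position is fully synonymous and whose 1st/2nd
## position changes are non-synonymous (stop-creating changes excluded at
## mutation draw); CT/CG families are avoided because of their first-position
## synonymies.
FOURFOLD_FAMILIES <- c("GG", "GC", "CC", "AC", "GT", "TC")

#' Simulation configuration
#'
#' Defaults describe the package's reference simulation scenario: 10
#' diploid individuals, 200 contigs of 201 coding sites (67 codons), 10X
#' mean coverage per individual, error rate 0.005, synonymous theta 0.01
#' and non-synonymous theta 0.002, no inbreeding, no expression bias, no
#' paralogs.
#'
#' @param nIndividuals diploid individuals.
#' @param nContigs contigs to simulate.
#' @param contigLength contig length in bases (a multiple of 3, >= 15; the
#'   first codon is ATG and the last a stop, so `contigLength/3 - 2` codons
#'   carry variation).
#' @param coverage mean per-site per-individual coverage (X).
#' @param coveragePerIndividual optional vector of per-individual means,
#'   overriding `coverage` (unbalanced designs).
#' @param coverageSdLog standard deviation (log scale) of the per-contig
#'   expression factor multiplying every individual's coverage (mean 1).
#'   RNA-seq depth tracks expression, so coverage is correlated across
#'   individuals within a contig; 0.8 is a moderate spread for contigs
#'   already past the 2.5X filter. Within a contig, depth is drawn per
#'   codon block, emulating the read-length autocorrelation of mapped
#'   coverage.
#' @param epsilon true per-base error rate.
#' @param thetaSyn,thetaNonsyn per-site scaled mutation rates at synonymous
#'   (third) and non-synonymous (first/second) codon positions.
#' @param nonsynShift exponent of the frequency law at non-synonymous
#'   sites: derived counts are drawn proportional to `1/k^nonsynShift`
#'   (1 = neutral; larger values mimic purifying selection keeping
#'   non-synonymous variants rare).
#' @param fis true inbreeding coefficient in `[0, 1]`.
#' @param rho beta-binomial overdispersion of allele expression in `[0, 1)`.
#' @param paralogFraction fraction of contigs carrying one collapsed
#'   fixed-difference paralogous site.
#' @param paralogP mixing proportion of locus 1 at collapsed sites.
#' @param pcrDuplicateRate geometric duplication rate for
#'   [addPcrDuplicates()] stress inputs.
#' @param seed RNG seed (mandatory; all streams derive from it).
#' @return a list of class `simulationConfig`.
#' @export
simulationConfig <- function(nIndividuals = 10L, nContigs = 200L,
                             contigLength = 201L, coverage = 10,
                             coveragePerIndividual = NULL,
                             coverageSdLog = 0.8,
                             epsilon = 0.005, thetaSyn = 0.01,
                             thetaNonsyn = 0.002, nonsynShift = 1,
                             fis = 0, rho = 0,
                             paralogFraction = 0, paralogP = 0.5,
                             pcrDuplicateRate = 0, seed = 1L) {
  stopifnot(contigLength %% 3L == 0L, contigLength >= 15L,
            epsilon >= 0, epsilon < 0.75, fis >= 0, fis <= 1,
            rho >= 0, rho < 1, paralogFraction >= 0, paralogFraction <= 1,
            paralogP > 0, paralogP < 1, pcrDuplicateRate >= 0,
            pcrDuplicateRate < 1)
  if (is.null(coveragePerIndividual))
    coveragePerIndividual <- rep(coverage, nIndividuals)
  stopifnot(length(coveragePerIndividual) == nIndividuals,
            all(coveragePerIndividual >= 0))
  structure(list(nIndividuals = as.integer(nIndividuals),
                 nContigs = as.integer(nContigs),
                 contigLength = as.integer(contigLength),
                 coveragePerIndividual = coveragePerIndividual,
                 coverageSdLog = coverageSdLog,
                 epsilon = epsilon, thetaSyn = thetaSyn,
                 thetaNonsyn = thetaNonsyn, nonsynShift = nonsynShift,
                 fis = fis, rho = rho,
                 paralogFraction = paralogFraction, paralogP = paralogP,
                 pcrDuplicateRate = pcrDuplicateRate,
                 seed = as.integer(seed)),
            class = "simulationConfig")
}

## beta-binomial draws, elementwise over size
rbetabinom <- function(n, size, m, rho) {
  if (rho < 1e-12) return(stats::rbinom(n, size, m))
  a <- m * (1 - rho) / rho
  b <- (1 - m) * (1 - rho) / rho
  stats::rbinom(n, size, stats::rbeta(n, a, b))
}

## Apply the symmetric error channel to origin reads of one base and
## accumulate into the counts array. r: S x I matrix of reads whose true
## base index is baseIdx[s]; counts: S x I x 4 array (modified and returned).
scatterReads <- function(counts, r, baseIdx, eps) {
  S <- nrow(r); I <- ncol(r)
  correct <- matrix(stats::rbinom(S * I, as.vector(r), 1 - eps), S, I)
  errs <- r - correct
  sIdx <- rep(seq_len(S), I)
  iIdx <- rep(seq_len(I), each = S)
  counts[cbind(sIdx, iIdx, baseIdx[sIdx])] <-
    counts[cbind(sIdx, iIdx, baseIdx[sIdx])] + as.vector(correct)
  bad <- which(errs > 0)
  for (cell in bad) {
    s <- (cell - 1L) %% S + 1L
    i <- (cell - 1L) %/% S + 1L
    others <- setdiff(1:4, baseIdx[s])
    e <- as.vector(stats::rmultinom(1L, errs[cell], rep(1 / 3, 3)))
    counts[s, i, others] <- counts[s, i, others] + e
  }
  counts
}

## draw a sample-level derived-allele count; probability proportional to
## 1/k^shift (shift = 1 is the neutral law; shift > 1 emulates purifying
## selection holding variants at lower frequencies)
drawDerivedCount <- function(nHap, shift = 1) {
  k <- seq_len(nHap - 1L)
  sample(k, 1L, prob = 1 / k^shift)
}

#' Simulate a full read-count dataset with truth
#'
#' Generates contigs (single-ORF coding sequences), true genotypes, and
#' per-site per-individual base counts under the configuration's coverage,
#' error, expression-bias and paralogy models. Deterministic under the
#' configured seed.
#'
#' @param config a [simulationConfig()].
#' @return list with `counts` (named list of [ContigCounts]), `truth`
#'   (named list per contig: sequence, genotype matrix, polySites
#'   data.frame, epsilon), `sequences` (`DNAStringSet`), and `orfs`
#'   (data.frame contig/start/end, 0-based half-open).
#' @export
simulateDataset <- function(config) {
  set.seed(config$seed)
  nI <- config$nIndividuals
  L <- config$contigLength
  nHap <- 2L * nI
  inds <- sprintf("ind%02d", seq_len(nI))
  a1 <- sum(1 / seq_len(nHap - 1L))
  pSyn <- min(1, config$thetaSyn * a1)
  pNon <- min(1, config$thetaNonsyn * a1)
  countsList <- vector("list", config$nContigs)
  truth <- vector("list", config$nContigs)
  seqs <- character(config$nContigs)
  ids <- sprintf("contig%04d", seq_len(config$nContigs))
  for (ct in seq_len(config$nContigs)) {
    nCodon <- L %/% 3L
    fams <- sample(FOURFOLD_FAMILIES, nCodon - 2L, replace = TRUE)
    third <- sample(BASES, nCodon - 2L, replace = TRUE)
    codons <- c("ATG", paste0(fams, third), "TAA")
    seqChars <- strsplit(paste(codons, collapse = ""), "")[[1]]
    refIdx <- match(seqChars, BASES)
    ## candidate variable sites (0-based): middle codons only
    midCodon <- 2:(nCodon - 1L)
    synSites <- 3L * (midCodon - 1L) + 2L
    nonSites <- c(3L * (midCodon - 1L), 3L * (midCodon - 1L) + 1L)
    isParalogContig <- stats::runif(1) < config$paralogFraction
    poly <- data.frame(site = integer(), ref = character(),
                       alt = character(), k = integer(),
                       class = character(), paralog = logical(),
                       stringsAsFactors = FALSE)
    dosage <- matrix(0L, L, nI)          # alt dosage; 3L marks paralog site
    addPoly <- function(site0, cls) {
      codon <- codons[site0 %/% 3L + 1L]
      pos <- site0 %% 3L + 1L
      ref <- seqChars[site0 + 1L]
      cand <- setdiff(BASES, ref)
      cand <- cand[vapply(cand, function(b)
        classifySnp(codon, pos, c(ref, b)) == cls, TRUE)]
      if (length(cand) == 0L) return(NULL)
      list(alt = if (length(cand) == 1L) cand else sample(cand, 1L),
           k = drawDerivedCount(nHap, if (cls == "NONSYN")
                                  config$nonsynShift else 1))
    }
    for (cls in c("SYN", "NONSYN")) {
      sites <- if (cls == "SYN") synSites else nonSites
      pp <- if (cls == "SYN") pSyn else pNon
      hit <- sites[stats::runif(length(sites)) < pp]
      for (s0 in hit) {
        drawn <- addPoly(s0, cls)
        if (is.null(drawn)) next
        ## genotype assignment
        if (config$fis == 0) {
          hap <- integer(nHap)
          hap[sample.int(nHap, drawn$k)] <- 1L
          d <- hap[seq(1L, nHap, 2L)] + hap[seq(2L, nHap, 2L)]
        } else {
          f <- drawn$k / nHap
          inbred <- stats::runif(nI) < config$fis
          d <- ifelse(inbred, 2L * stats::rbinom(nI, 1L, f),
                      stats::rbinom(nI, 2L, f))
        }
        dosage[s0 + 1L, ] <- d
        poly[nrow(poly) + 1L, ] <- list(s0, seqChars[s0 + 1L], drawn$alt,
                                        drawn$k, cls, FALSE)
      }
    }
    ## collapsed paralogous site: fixed difference, shared mixing p
    if (isParalogContig) {
      free <- setdiff(synSites, poly$site)
      if (length(free)) {
        s0 <- if (length(free) == 1L) free else sample(free, 1L)
        ref <- seqChars[s0 + 1L]
        alt <- sample(setdiff(BASES, ref), 1L)
        dosage[s0 + 1L, ] <- 3L
        poly[nrow(poly) + 1L, ] <- list(s0, ref, alt, NA_integer_, "SYN",
                                        TRUE)
      }
    }
    altIdx <- refIdx
    altIdx[poly$site + 1L] <- match(poly$alt, BASES)
    ## coverage: per-contig expression factor shared across individuals,
    ## depth drawn per codon block (read-scale autocorrelation)
    expr <- if (config$coverageSdLog > 0)
      stats::rlnorm(1, -config$coverageSdLog^2 / 2, config$coverageSdLog)
    else 1
    ## a collapsed contig receives reads from both loci everywhere
    if (isParalogContig) expr <- 2 * expr
    Ccod <- matrix(stats::rpois(nCodon * nI,
                                rep(expr * config$coveragePerIndividual,
                                    each = nCodon)),
                   nCodon, nI)
    C <- Ccod[rep(seq_len(nCodon), each = 3L), , drop = FALSE]
    rAlt <- matrix(0L, L, nI)
    hetC <- which(dosage == 1L)
    if (length(hetC))
      rAlt[hetC] <- rbetabinom(length(hetC), C[hetC], 0.5, config$rho)
    homA <- which(dosage == 2L)
    rAlt[homA] <- C[homA]
    parC <- which(dosage == 3L)
    if (length(parC))     # locus 1 fixed ref contributes proportion p
      rAlt[parC] <- rbetabinom(length(parC), C[parC], 1 - config$paralogP,
                               config$rho)
    rRef <- C - rAlt
    counts <- array(0L, dim = c(L, nI, 4L),
                    dimnames = list(NULL, inds, BASES))
    counts <- scatterReads(counts, rRef, refIdx, config$epsilon)
    counts <- scatterReads(counts, rAlt, altIdx, config$epsilon)
    ## true genotypes
    gt <- matrix(paste0(seqChars, seqChars), L, nI)
    if (nrow(poly)) for (r in seq_len(nrow(poly))) {
      s <- poly$site[r] + 1L
      pair <- sort(c(poly$ref[r], poly$alt[r]))
      gt[s, dosage[s, ] == 1L] <- paste0(pair[1], pair[2])
      gt[s, dosage[s, ] == 2L] <- paste0(poly$alt[r], poly$alt[r])
      gt[s, dosage[s, ] == 3L] <- NA_character_   # paralog: no true genotype
    }
    countsList[[ct]] <- new("ContigCounts", contig = ids[ct],
                            individuals = inds, counts = counts)
    truth[[ct]] <- list(sequence = paste(seqChars, collapse = ""),
                        genotype = gt, polySites = poly,
                        epsilon = config$epsilon)
    seqs[ct] <- paste(seqChars, collapse = "")
  }
  names(countsList) <- ids
  names(truth) <- ids
  sequences <- Biostrings::DNAStringSet(seqs)
  names(sequences) <- ids
  list(counts = countsList, truth = truth, sequences = sequences,
       orfs = data.frame(contig = ids, start = 0L, end = L,
                         stringsAsFactors = FALSE))
}

#' Simulate one collapsed paralogous site
#'
#' Two loci carry a fixed difference (locus 1 fixed for allele 1, locus 2
#' fixed for allele 2 by default, or Hardy-Weinberg genotypes at given
#' frequencies); locus 1 contributes a proportion `p` of every individual's
#' reads. Returns allele-1 / allele-2 read counts after expression bias and
#' the error channel.
#'
#' @param p mixing proportion of locus 1, in (0, 1).
#' @param coverage mean coverage (Poisson).
#' @param rho beta-binomial overdispersion.
#' @param epsilon error rate.
#' @param nIndividuals individuals.
#' @param f1,f2 allele-1 frequencies at the two loci (defaults: fixed
#'   difference).
#' @return list with `k` (allele-1 reads), `N` (allele-1 + allele-2 reads),
#'   `coverage`, and the per-locus dosages `x1`, `x2`.
#' @export
simulateParalogSite <- function(p, coverage = 20, rho = 0, epsilon = 0,
                                nIndividuals = 10L, f1 = 1, f2 = 0) {
  stopifnot(p > 0, p < 1)
  x1 <- stats::rbinom(nIndividuals, 2L, f1)
  x2 <- stats::rbinom(nIndividuals, 2L, f2)
  C <- stats::rpois(nIndividuals, coverage)
  q <- p * x1 / 2 + (1 - p) * x2 / 2
  o1 <- rbetabinom(nIndividuals, C, q, rho)   # allele-1-origin reads
  o2 <- C - o1
  r1 <- stats::rbinom(nIndividuals, o1, 1 - epsilon)
  e1 <- o1 - r1
  r2 <- stats::rbinom(nIndividuals, o2, 1 - epsilon)
  e2 <- o2 - r2
  ## a fraction 1/3 of a read's errors land on the partner allele
  k <- r1 + stats::rbinom(nIndividuals, e2, 1 / 3)
  k2 <- r2 + stats::rbinom(nIndividuals, e1, 1 / 3)
  list(k = k, N = k + k2, coverage = C, x1 = x1, x2 = x2)
}

#' Simulate one ordinary (one-locus) biallelic site
#'
#' Hardy-Weinberg genotypes at allele-1 frequency `f`, Poisson coverage,
#' beta-binomial allele expression in heterozygotes, error channel with
#' `epsilon`. Used for paralogy-test calibration: the default `f = NULL`
#' draws the frequency from the neutral 1/k law over sample allele counts
#' (the same law the dataset generator uses), so the simulated sites match
#' the SNP population the test meets in practice.
#'
#' @param f allele-1 frequency; `NULL` (default) draws it from the neutral
#'   spectrum.
#' @param coverage mean coverage.
#' @param rho overdispersion.
#' @param epsilon error rate.
#' @param nIndividuals individuals.
#' @param requireHet resample genotypes until at least one heterozygote is
#'   present (the paralogy test only applies to such sites).
#' @return list with `k`, `N`, `coverage`, `dosage`, `nHet`, `f`.
#' @export
simulateOneLocusSite <- function(f = NULL, coverage = 10, rho = 0,
                                 epsilon = 0, nIndividuals = 10L,
                                 requireHet = TRUE) {
  if (is.null(f)) f <- drawDerivedCount(2L * nIndividuals) / (2L * nIndividuals)
  repeat {
    x <- stats::rbinom(nIndividuals, 2L, f)
    if (!requireHet || any(x == 1L)) break
  }
  C <- stats::rpois(nIndividuals, coverage)
  o1 <- integer(nIndividuals)
  o1[x == 2L] <- C[x == 2L]
  het <- x == 1L
  if (any(het)) o1[het] <- rbetabinom(sum(het), C[het], 0.5, rho)
  o2 <- C - o1
  r1 <- stats::rbinom(nIndividuals, o1, 1 - epsilon)
  e1 <- o1 - r1
  r2 <- stats::rbinom(nIndividuals, o2, 1 - epsilon)
  e2 <- o2 - r2
  k <- r1 + stats::rbinom(nIndividuals, e2, 1 / 3)
  k2 <- r2 + stats::rbinom(nIndividuals, e1, 1 / 3)
  list(k = k, N = k + k2, coverage = C, dosage = x, nHet = sum(x == 1L),
       f = f)
}

#' Inject PCR duplicates into read records
#'
#' Each read gains `k` extra identical copies with `k` geometric at the
#' given rate (a stress model for the duplicate-collapsing filter, not a
#' claim about real libraries). `collapsePcrDuplicates()` composed with
#' this operation is the identity on its input.
#'
#' @param records read records (see [readRecords()]).
#' @param rate duplication rate in `[0, 1)`; 0 is the identity.
#' @param seed RNG seed.
#' @return the records with duplicates interleaved after their originals.
#' @export
addPcrDuplicates <- function(records, rate, seed = 1L) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0 || nrow(records) == 0L) return(records)
  set.seed(seed)
  extra <- stats::rgeom(nrow(records), 1 - rate)
  idx <- rep(seq_len(nrow(records)), times = 1L + extra)
  out <- records[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Named simulation presets
#'
#' Documented configurations used throughout the package's validation:
#' `neutral-10x` (the reference scenario: 10 individuals, constant 10X per
#' individual, error 0.005, synonymous theta 0.01), `high-coverage-30x`
#' (30X coverage, to be analysed with `minCoverage = 30`), `paralog-mix`
#' (20% of contigs are collapsed paralog pairs carrying one
#' fixed-difference site at p = 0.5, with doubled read depth since two loci
#' contribute reads), `inbred` (FIS = 0.3), and
#' `neutral-10x-expression`, the coverage-realistic variant of the
#' reference scenario in which contig depth varies with a lognormal
#' expression factor (sdlog 0.8); complete-site statistics (piS, piN, FIS)
#' are only well populated under this variant, because at a constant 10X
#' with the 10-read rule almost no site is called in all individuals.
#'
#' @param seed seed stored in every preset.
#' @return named list of [simulationConfig()] objects.
#' @export
scenarioPresets <- function(seed = 1L) {
  list(
    "neutral-10x" = simulationConfig(coverageSdLog = 0, seed = seed),
    "high-coverage-30x" = simulationConfig(coverage = 30, coverageSdLog = 0,
                                           seed = seed),
    "paralog-mix" = simulationConfig(paralogFraction = 0.2, paralogP = 0.5,
                                     coverageSdLog = 0, seed = seed),
    "inbred" = simulationConfig(fis = 0.3, coverageSdLog = 0, seed = seed),
    "neutral-10x-expression" = simulationConfig(coverageSdLog = 0.8,
                                                seed = seed))
}
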