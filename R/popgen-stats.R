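## Per-contig and species-level population genomic statistics.

#' Per-site nucleotide diversity from allele counts
#'
#' Mean pairwise difference among haplotypes at one biallelic site:
#' `pi = n1 n2 / C(n, 2)` with `n = n1 + n2`.
#'
#' @param n1,n2 haplotype counts of the two alleles.
#' @return per-site diversity.
#' @export
sitePi <- function(n1, n2) {
  n <- n1 + n2
  if (any(n < 2)) stop("site diversity needs at least 2 haplotypes")
  n1 * n2 / choose(n, 2)
}

#' Classify a single-base change as synonymous or non-synonymous
#'
#' Builds the two codons that differ only at the focal position (the other
#' two positions at their consensus states) and compares the encoded amino
#' acids under the standard genetic code. Any stop codon among the two, or
#' an ambiguous context (missing consensus base), yields `EXCLUDED`.
#'
#' @param codon consensus codon context (3-character string; the base at
#'   `posInCodon` is ignored).
#' @param posInCodon position of the variant within the codon (1, 2 or 3).
#' @param alleles the two bases.
#' @return `"SYN"`, `"NONSYN"` or `"EXCLUDED"`.
#' @export
classifySnp <- function(codon, posInCodon, alleles) {
  if (is.na(codon) || !grepl("^[ACGT]{3}$", codon) ||
      anyNA(alleles) || !all(alleles %in% BASES))
    return("EXCLUDED")
  c1 <- c2 <- strsplit(codon, "")[[1]]
  c1[posInCodon] <- alleles[1]
  c2[posInCodon] <- alleles[2]
  c1 <- paste(c1, collapse = ""); c2 <- paste(c2, collapse = "")
  if (c1 %in% STOP_CODONS || c2 %in% STOP_CODONS) return("EXCLUDED")
  if (translateCodon(c1) == translateCodon(c2)) "SYN" else "NONSYN"
}

## majority-rule consensus base of one alignment row (NA if no data)
consensusBase <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_character_)
  tab <- table(factor(x, levels = BASES))
  BASES[which.max(tab)]          # alphabetical on ties
}

#' Synonymous and non-synonymous site counts of an alignment
#'
#' Nei-Gojobori-style fractional counting on the consensus codon of each
#' codon site: each codon position contributes a synonymous weight equal to
#' the fraction of its possible single-base changes that are synonymous,
#' with stop-creating changes excluded from the denominator, so every
#' position contributes one site in total. Codons whose consensus is a stop
#' or contains a missing base contribute nothing. By default only complete
#' positions (no missing focal state) are counted, so the denominators
#' match the complete-site restriction of the diversity and divergence
#' numerators; set `completeOnly = FALSE` for the raw count over all
#' cleaned codons.
#'
#' @param aln a cleaned [CodonAlignment].
#' @param completeOnly count only positions without missing focal data.
#' @return named numeric vector `c(LS = ..., LN = ...)`.
#' @export
synNonsynSiteCounts <- function(aln, completeOnly = TRUE) {
  cons <- apply(aln@haplotypes, 1L, consensusBase)
  mask <- if (completeOnly) rowSums(is.na(aln@haplotypes)) == 0L
          else rep(TRUE, nrow(aln@haplotypes))
  codonSiteCounts(cons, mask)
}

## site counts from a vector of consensus bases (length multiple of 3);
## positions with mask FALSE contribute nothing
codonSiteCounts <- function(cons, mask = rep(TRUE, length(cons))) {
  nCodon <- length(cons) %/% 3L
  LS <- 0; LN <- 0
  for (cd in seq_len(nCodon)) {
    codon <- cons[(3L * cd - 2L):(3L * cd)]
    if (anyNA(codon)) next
    cstr <- paste(codon, collapse = "")
    if (cstr %in% STOP_CODONS) next
    aa <- translateCodon(cstr)
    for (pos in 1:3) {
      if (!mask[3L * cd - 3L + pos]) next
      nSyn <- 0L; nOk <- 0L
      for (b in setdiff(BASES, codon[pos])) {
        mut <- codon
        mut[pos] <- b
        mstr <- paste(mut, collapse = "")
        if (mstr %in% STOP_CODONS) next
        nOk <- nOk + 1L
        if (translateCodon(mstr) == aa) nSyn <- nSyn + 1L
      }
      if (nOk == 0L) next           # no admissible change at this position
      LS <- LS + nSyn / nOk
      LN <- LN + 1 - nSyn / nOk
    }
  }
  c(LS = LS, LN = LN)
}

#' SNPs of a codon alignment
#'
#' Tabulates polymorphic nucleotide sites of the alignment with their
#' synonymy classification on the consensus codon context. With
#' `completeOnly = TRUE` (the default, used for diversity statistics) only
#' complete biallelic sites enter; with `completeOnly = FALSE` sites with
#' missing haplotypes are kept (used for the site-frequency spectrum, where
#' the variable sample size is handled by projection), still requiring at
#' most two alleles among non-missing states.
#'
#' @param aln a cleaned [CodonAlignment].
#' @param completeOnly restrict to sites without missing data.
#' @return data.frame: contig, row (alignment row), sitePos (contig
#'   coordinate), allele1 (major), allele2 (minor), n1, n2, nHaplotypes,
#'   minorCount, maf, class (SYN/NONSYN/EXCLUDED), hetObs (fraction of
#'   individuals heterozygous), hetExp (2 p q).
#' @export
alignmentSnps <- function(aln, completeOnly = TRUE) {
  hap <- aln@haplotypes
  L <- nrow(hap)
  cons <- apply(hap, 1L, consensusBase)
  rows <- if (completeOnly) completeBiallelicSites(aln) else seq_len(L)
  out <- vector("list", length(rows))
  ii <- 0L
  for (r in rows) {
    x <- hap[r, ]
    obs <- x[!is.na(x)]
    if (length(obs) < 2L) next
    tab <- sort(table(factor(obs, levels = BASES))[unique(obs)],
                decreasing = TRUE)
    if (length(tab) != 2L) next
    a1 <- names(tab)[1]; a2 <- names(tab)[2]
    if (tab[1] == tab[2] && a1 > a2) { tmp <- a1; a1 <- a2; a2 <- tmp }
    n1 <- as.integer(max(tab)); n2 <- as.integer(min(tab))
    m <- n1 + n2
    cd <- (r - 1L) %/% 3L
    pos <- r - 3L * cd
    codon <- paste(cons[(3L * cd + 1L):(3L * cd + 3L)], collapse = "")
    cls <- classifySnp(codon, pos, c(a1, a2))
    ## genotype-level heterozygosity among individuals complete at the site
    i1 <- x[seq(1L, length(x), by = 2L)]
    i2 <- x[seq(2L, length(x), by = 2L)]
    ok <- !is.na(i1) & !is.na(i2)
    hetObs <- if (any(ok)) mean(i1[ok] != i2[ok]) else NA_real_
    p <- n1 / m
    ii <- ii + 1L
    out[[ii]] <- data.frame(
      contig = aln@contig, row = r, sitePos = aln@sitePos[r],
      allele1 = a1, allele2 = a2, n1 = n1, n2 = n2, nHaplotypes = m,
      minorCount = n2, maf = n2 / m, class = cls, hetObs = hetObs,
      hetExp = 2 * p * (1 - p), stringsAsFactors = FALSE)
  }
  if (ii == 0L)
    return(data.frame(contig = character(), row = integer(),
                      sitePos = integer(), allele1 = character(),
                      allele2 = character(), n1 = integer(), n2 = integer(),
                      nHaplotypes = integer(), minorCount = integer(),
                      maf = numeric(), class = character(),
                      hetObs = numeric(), hetExp = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out[seq_len(ii)])
}

#' Heterozygote deficiency FIS
#'
#' `FIS = 1 - sum(Hobs) / sum(Hexp)` across SNPs (ratio of sums, robust to
#' sites with tiny expected heterozygosity), where per SNP `Hobs` is the
#' fraction of individuals called heterozygous and `Hexp = 2 p q` from the
#' haplotype counts (plug-in, no small-sample correction).
#'
#' @param snps SNP table from [alignmentSnps()].
#' @param method `"ratio"` (default, ratio of sums) or `"mean"` (mean of
#'   per-SNP `1 - Hobs/Hexp`).
#' @param hexp `"plugin"` (default): `Hexp = 2 p q`; `"unbiased"`: Nei's
#'   small-sample-corrected `2 p q m/(m - 1)` with `m` the haplotype count,
#'   whose expectation matches `Hobs` exactly under random mating (the
#'   plug-in version has expectation `-1/(m - 1)` rather than 0).
#' @return FIS in `[-1, 1]`, or `NA` with no analyzable SNP.
#' @export
fisStat <- function(snps, method = c("ratio", "mean"),
                    hexp = c("plugin", "unbiased")) {
  method <- match.arg(method)
  hexp <- match.arg(hexp)
  ok <- !is.na(snps$hetObs) & snps$hetExp > 0
  if (!any(ok)) return(NA_real_)
  he <- snps$hetExp[ok]
  if (hexp == "unbiased")
    he <- he * snps$nHaplotypes[ok] / (snps$nHaplotypes[ok] - 1)
  if (method == "ratio")
    1 - sum(snps$hetObs[ok]) / sum(he)
  else
    mean(1 - snps$hetObs[ok] / he)
}

#' Per-individual heterozygosity
#'
#' Proportion of heterozygous positions among an individual's non-missing
#' genotype calls over the analyzed sites.
#'
#' @param calls a [GenotypeCalls] or list of them.
#' @param sites optional list (parallel to `calls`) of 1-based site indices
#'   to analyze; defaults to all sites.
#' @return named numeric vector, individual -> proportion (NA when an
#'   individual has no non-missing call).
#' @export
perIndividualHeterozygosity <- function(calls, sites = NULL) {
  if (is(calls, "GenotypeCalls")) calls <- list(calls)
  if (!is.null(sites) && length(sites) != length(calls))
    stop("'sites' must parallel 'calls'")
  het <- NULL; tot <- NULL
  for (j in seq_along(calls)) {
    gt <- calls[[j]]@genotype
    if (!is.null(sites)) gt <- gt[sites[[j]], , drop = FALSE]
    isHet <- !is.na(gt) & substr(gt, 1L, 1L) != substr(gt, 2L, 2L)
    h <- colSums(isHet)
    t <- colSums(!is.na(gt))
    if (is.null(het)) { het <- h; tot <- t } else { het <- het + h; tot <- tot + t }
  }
  out <- het / tot
  out[tot == 0] <- NA_real_
  out
}

#' Fixed differences to the outgroup
#'
#' A site is a fixed difference when the focal haplotypes are complete and
#' monomorphic, the outgroup base is present, and the two differ. Changes
#' are classified synonymous / non-synonymous on the focal consensus codon
#' context as for SNPs; stop-involving changes are excluded. No
#' multiple-hit correction is applied (the design assumes close outgroups).
#'
#' @param aln a cleaned [CodonAlignment] with outgroup.
#' @return named numeric vector `c(dScount, dNcount)`.
#' @export
fixedDifferences <- function(aln) {
  if (!length(aln@outgroup)) stop("alignment has no outgroup")
  hap <- aln@haplotypes
  cons <- apply(hap, 1L, consensusBase)
  dS <- 0L; dN <- 0L
  complete <- rowSums(is.na(hap)) == 0L
  for (r in which(complete & !is.na(aln@outgroup))) {
    x <- unique(hap[r, ])
    if (length(x) != 1L) next                 # polymorphic: not fixed
    og <- aln@outgroup[r]
    if (x == og) next
    cd <- (r - 1L) %/% 3L
    pos <- r - 3L * cd
    codon <- paste(cons[(3L * cd + 1L):(3L * cd + 3L)], collapse = "")
    cls <- classifySnp(codon, pos, c(x, og))
    if (cls == "SYN") dS <- dS + 1L
    if (cls == "NONSYN") dN <- dN + 1L
  }
  c(dScount = dS, dNcount = dN)
}

#' Per-contig population genomic statistics
#'
#' Computes, from a cleaned codon alignment, the synonymous and
#' non-synonymous site counts (LS, LN), per-site diversities piS and piN
#' (sum of per-SNP site diversities over the site count of the class),
#' segregating-site counts pS and pN, FIS, and with an outgroup the fixed
#' differences and rates dS, dN. Diversity uses complete biallelic sites
#' only.
#'
#' @param aln a cleaned [CodonAlignment].
#' @param mafCutoff minor-allele-frequency cutoff used for the additional
#'   pS/pN counts entering NI_0.2 (SNPs with MAF below it removed).
#' @return one-row data.frame (contig, length, nHaplotypes, LS, LN, piS,
#'   piN, FIS, pS, pN, pS02, pN02, dScount, dNcount, dS, dN, nSNPs,
#'   sumHobs, sumHexp).
#' @export
contigStats <- function(aln, mafCutoff = 0.2) {
  sc <- synNonsynSiteCounts(aln)
  snps <- alignmentSnps(aln, completeOnly = TRUE)
  syn <- snps[snps$class == "SYN", , drop = FALSE]
  non <- snps[snps$class == "NONSYN", , drop = FALSE]
  piSum <- function(d) if (nrow(d)) sum(sitePi(d$n1, d$n2)) else 0
  LS <- unname(sc["LS"]); LN <- unname(sc["LN"])
  piS <- if (LS > 0) piSum(syn) / LS else NA_real_
  piN <- if (LN > 0) piSum(non) / LN else NA_real_
  d <- c(dScount = NA_integer_, dNcount = NA_integer_)
  if (length(aln@outgroup)) d <- fixedDifferences(aln)
  ok <- !is.na(snps$hetObs) & snps$hetExp > 0
  data.frame(
    contig = aln@contig, length = nrow(aln@haplotypes),
    nHaplotypes = ncol(aln@haplotypes),
    LS = LS, LN = LN, piS = piS, piN = piN,
    FIS = fisStat(snps),
    pS = nrow(syn), pN = nrow(non),
    pS02 = sum(syn$maf >= mafCutoff), pN02 = sum(non$maf >= mafCutoff),
    dScount = unname(d["dScount"]), dNcount = unname(d["dNcount"]),
    dS = if (!is.na(d["dScount"]) && LS > 0) d[["dScount"]] / LS else NA_real_,
    dN = if (!is.na(d["dNcount"]) && LN > 0) d[["dNcount"]] / LN else NA_real_,
    nSNPs = nrow(snps),
    sumHobs = sum(snps$hetObs[ok]), sumHexp = sum(snps$hetExp[ok]),
    stringsAsFactors = FALSE)
}

#' McDonald-Kreitman neutrality indices
#'
#' `NI = (pN/pS) / (dN/dS)`; `NI_0.2` recomputes the polymorphism counts
#' after discarding SNPs with minor allele frequency below the cutoff
#' (default 0.2), which removes the segregating slightly-deleterious
#' variants that bias NI upward. `alpha = 1 - NI`, `alpha_0.2 = 1 -
#' NI_0.2`, and the adaptive substitution rate `omega_a = alpha dN/dS`
#' (also reported with `alpha_0.2`). Zero denominators yield `NA`, never an
#' error.
#'
#' @param pN,pS non-synonymous / synonymous segregating-site counts.
#' @param dN,dS non-synonymous / synonymous fixed-difference counts (or
#'   rates; only their ratio enters).
#' @param pN02,pS02 the counts after the MAF cutoff (default: no cutoff
#'   applied, i.e. same as pN, pS).
#' @return one-row data.frame: NI, NI02, alpha, alpha02, dNdS (only when
#'   rates given as counts this is the count ratio), omegaA, omegaA02.
#' @export
neutralityIndices <- function(pN, pS, dN, dS, pN02 = pN, pS02 = pS) {
  rat <- function(a, b) if (!is.na(b) && b > 0) a / b else NA_real_
  dnds <- rat(dN, dS)
  NI <- rat(rat(pN, pS), dnds)
  NI02 <- rat(rat(pN02, pS02), dnds)
  alpha <- 1 - NI
  alpha02 <- 1 - NI02
  data.frame(NI = NI, NI02 = NI02, alpha = alpha, alpha02 = alpha02,
             dNdS = dnds,
             omegaA = if (!is.na(alpha) && !is.na(dnds)) alpha * dnds
                      else NA_real_,
             omegaA02 = if (!is.na(alpha02) && !is.na(dnds)) alpha02 * dnds
                        else NA_real_)
}

#' Species-level summary with contig bootstrap
#'
#' Averages per-contig statistics across contigs weighting each statistic by
#' the contig's analyzed site count of the relevant class (LS for piS, LN
#' for piN), which gives equal weight to every SNP; ratio statistics are
#' ratios of weighted means. FIS is the ratio-of-sums across all SNPs of all
#' contigs. NI and derived quantities use counts summed across contigs
#' (`(sum pN / sum pS) / (sum dN / sum dS)`); an alternative averaging
#' per-contig ratios is available but known to be biased for short contigs.
#' Percentile confidence intervals are obtained by bootstrapping contigs
#' with replacement under a fixed seed.
#'
#' @param stats data.frame of per-contig rows from [contigStats()].
#' @param nBootstrap bootstrap replicates (0 to skip).
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level of the percentile intervals.
#' @return list with `summary` (one-row data.frame: meanPiS, meanPiN,
#'   piNPiS, meanFIS, NI, NI02, alpha, alpha02, dNdS, omegaA, omegaA02) and
#'   `ci` (data.frame of lower/upper bounds per statistic, NULL when
#'   `nBootstrap = 0`).
#' @export
speciesSummary <- function(stats, nBootstrap = 1000L, seed = 1L,
                           conf = 0.95) {
  if (nrow(stats) < 2L) stop("species summary needs at least 2 contigs")
  one <- function(d) {
    wmean <- function(x, w) {
      ok <- !is.na(x) & !is.na(w) & w > 0
      if (!any(ok)) return(NA_real_)
      sum(x[ok] * w[ok]) / sum(w[ok])
    }
    meanPiS <- wmean(d$piS, d$LS)
    meanPiN <- wmean(d$piN, d$LN)
    fis <- if (sum(d$sumHexp, na.rm = TRUE) > 0)
      1 - sum(d$sumHobs, na.rm = TRUE) / sum(d$sumHexp, na.rm = TRUE)
    else NA_real_
    ni <- neutralityIndices(sum(d$pN), sum(d$pS),
                            sum(d$dNcount, na.rm = TRUE),
                            sum(d$dScount, na.rm = TRUE),
                            sum(d$pN02), sum(d$pS02))
    cbind(data.frame(meanPiS = meanPiS, meanPiN = meanPiN,
                     piNPiS = if (!is.na(meanPiS) && meanPiS > 0)
                       meanPiN / meanPiS else NA_real_,
                     meanFIS = fis), ni)
  }
  est <- one(stats)
  ci <- NULL
  if (nBootstrap > 0L) {
    set.seed(seed)
    boot <- matrix(NA_real_, nBootstrap, ncol(est),
                   dimnames = list(NULL, names(est)))
    for (b in seq_len(nBootstrap)) {
      idx <- sample.int(nrow(stats), replace = TRUE)
      boot[b, ] <- as.numeric(one(stats[idx, , drop = FALSE]))
    }
    a <- (1 - conf) / 2
    ci <- data.frame(
      statistic = colnames(boot),
      lower = apply(boot, 2L, stats::quantile, probs = a, na.rm = TRUE),
      upper = apply(boot, 2L, stats::quantile, probs = 1 - a, na.rm = TRUE),
      row.names = NULL)
  }
  list(summary = est, ci = ci)
}

#' Pairwise genetic distance between two individuals
#'
#' `(Hb - Hw) / Hw`, where `Hb` is the probability of drawing two distinct
#' alleles when sampling one allele from each individual and `Hw` is the
#' average heterozygosity of the two individuals, both averaged across the
#' shared (mutually non-missing) sites before taking the ratio. `Hw = 0`
#' with `Hb = 0` gives 0; `Hw = 0` with `Hb > 0` (or no shared site) gives
#' `NA`.
#'
#' @param gi,gj genotype vectors of the two individuals over the same sites
#'   (two-character strings or NA).
#' @return the distance, a single number.
#' @export
pairwiseGeneticDistance <- function(gi, gj) {
  ok <- !is.na(gi) & !is.na(gj)
  if (!any(ok)) return(NA_real_)
  gi <- gi[ok]; gj <- gj[ok]
  a1i <- substr(gi, 1L, 1L); a2i <- substr(gi, 2L, 2L)
  a1j <- substr(gj, 1L, 1L); a2j <- substr(gj, 2L, 2L)
  hb <- ((a1i != a1j) + (a1i != a2j) + (a2i != a1j) + (a2i != a2j)) / 4
  hw <- ((a1i != a2i) + (a1j != a2j)) / 2
  Hb <- mean(hb); Hw <- mean(hw)
  if (Hw == 0) {
    if (Hb == 0) return(0)
    return(NA_real_)
  }
  (Hb - Hw) / Hw
}

#' Genetic distance matrix across individuals
#'
#' Applies [pairwiseGeneticDistance()] to every pair of individuals over the
#' SNP sites of one or more contigs.
#'
#' @param callsList list of [GenotypeCalls].
#' @param snpSites list (parallel to `callsList`) of 1-based SNP site
#'   indices per contig; defaults to all sites.
#' @return symmetric matrix of distances with individuals as dimnames.
#' @export
geneticDistanceMatrix <- function(callsList, snpSites = NULL) {
  if (is(callsList, "GenotypeCalls")) callsList <- list(callsList)
  inds <- callsList[[1]]@individuals
  gt <- do.call(rbind, lapply(seq_along(callsList), function(j) {
    m <- callsList[[j]]@genotype
    if (!is.null(snpSites)) m <- m[snpSites[[j]], , drop = FALSE]
    m
  }))
  n <- length(inds)
  D <- matrix(NA_real_, n, n, dimnames = list(inds, inds))
  diag(D) <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    D[i, j] <- D[j, i] <- pairwiseGeneticDistance(gt[, i], gt[, j])
  D
}
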