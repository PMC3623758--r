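## Likelihood-ratio test for hidden paralogy.
##
## A SNP produced by two collapsed paralogous loci (rather than one
## segregating locus) shows an excess of heterozygous calls and a read-count
## asymmetry that is correlated across individuals, because locus 1
## contributes the same proportion p of the reads in every individual. The
## test compares a one-locus biallelic model (null) with a two-locus model in
## which each locus is biallelic for the same two alleles, both models using
## a beta-binomial (two-category Dirichlet-multinomial) read-count
## distribution to absorb allele-specific expression bias and library
## amplification noise.

#' Beta-binomial log probability mass
#'
#' Mean/overdispersion parameterisation: shape parameters
#' `alpha = m (1 - rho) / rho`, `beta = (1 - m)(1 - rho) / rho`, so the
#' distribution has mean `N m` and tends to Binomial(N, m) as `rho -> 0`
#' and to the uniform on 0..N at `m = 0.5, rho = 1/3`. Degenerate means are
#' handled as log-zero, not errors: `m = 0` with `k > 0` (or `m = 1` with
#' `k < N`) returns `-Inf`.
#'
#' @param k successes (vectorised).
#' @param N trials.
#' @param m mean fraction in `[0, 1]`.
#' @param rho overdispersion in `[0, 1)`.
#' @return log-probability, vectorised over the longest argument.
#' @export
betabinomLogPmf <- function(k, N, m, rho) {
  n <- max(length(k), length(N), length(m), length(rho))
  k <- rep_len(k, n); N <- rep_len(N, n)
  m <- rep_len(m, n); rho <- rep_len(rho, n)
  stopifnot(all(k >= 0), all(k <= N), all(m >= 0), all(m <= 1),
            all(rho >= 0), all(rho < 1))
  out <- numeric(n)
  deg0 <- m <= 0
  deg1 <- m >= 1
  bin <- !deg0 & !deg1 & rho < 1e-10
  bb <- !deg0 & !deg1 & !bin
  if (any(deg0)) out[deg0] <- ifelse(k[deg0] == 0, 0, -Inf)
  if (any(deg1)) out[deg1] <- ifelse(k[deg1] == N[deg1], 0, -Inf)
  if (any(bin)) out[bin] <- stats::dbinom(k[bin], N[bin], m[bin], log = TRUE)
  if (any(bb)) {
    a <- m[bb] * (1 - rho[bb]) / rho[bb]
    b <- (1 - m[bb]) * (1 - rho[bb]) / rho[bb]
    out[bb] <- lchoose(N[bb], k[bb]) + lbeta(k[bb] + a, N[bb] - k[bb] + b) -
      lbeta(a, b)
  }
  out
}

## column-wise log-sum-exp of a matrix (genotype configurations x individuals)
colLogSumExp <- function(M) {
  G <- nrow(M)
  mx <- M[1L, ]
  if (G > 1L) for (g in 2:G) mx <- pmax(mx, M[g, ])
  fin <- is.finite(mx)
  out <- rep(-Inf, ncol(M))
  if (any(fin)) {
    Mf <- M[, fin, drop = FALSE] - rep(mx[fin], each = G)
    out[fin] <- log(.colSums(exp(Mf), G, sum(fin))) + mx[fin]
  }
  out
}

## fast beta-binomial log-pmf factory for fixed count data: returns a
## function(m, rho) -> length(m) x length(k) matrix of log probabilities
makeBBKernel <- function(k, N) {
  n <- length(k)
  lch <- lchoose(N, k)
  function(m, rho) {
    G <- length(m)
    K <- matrix(k, G, n, byrow = TRUE)
    NN <- matrix(N, G, n, byrow = TRUE)
    if (rho < 1e-10) {
      out <- stats::dbinom(K, NN, matrix(m, G, n), log = TRUE)
    } else {
      deg <- m <= 0 | m >= 1
      out <- matrix(-Inf, G, n)
      if (any(!deg)) {
        a <- m[!deg] * (1 - rho) / rho
        b <- (1 - m[!deg]) * (1 - rho) / rho
        Ks <- K[!deg, , drop = FALSE]
        Ns <- NN[!deg, , drop = FALSE]
        out[!deg, ] <- matrix(lch, sum(!deg), n, byrow = TRUE) +
          lbeta(Ks + a, Ns - Ks + b) - lbeta(a, b)
      }
      if (any(deg)) for (g in which(deg)) {
        out[g, ] <- if (m[g] <= 0) ifelse(k == 0, 0, -Inf)
                    else ifelse(k == N, 0, -Inf)
      }
    }
    out
  }
}

## Expected allele-1 read fraction after the within-pair error channel:
## a read from an a1 allele registers as a2 with probability epsPair = eps/3
## and vice versa.
pairMean <- function(q, epsPair) q * (1 - epsPair) + (1 - q) * epsPair

## HWE weights over allele-1 dosage 0/1/2
dosageWeights <- function(f) c((1 - f)^2, 2 * f * (1 - f), f^2)

## clamp into [lo, hi] (bounded optimisers may probe just outside bounds
## when forming numerical gradients)
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## negative log-likelihood of the one-locus model at (f, rho)
oneLocusNegLL <- function(par, bb, epsPair) {
  f <- clamp(par[1], 0, 1)
  rho <- clamp(par[2], 0, 0.95)
  w <- dosageWeights(f)
  m <- pairMean(c(0, 0.5, 1), epsPair)
  ll <- sum(colLogSumExp(log(w) + bb(m, rho)))
  if (!is.finite(ll)) 1e12 else -ll
}

QX <- as.vector(outer(0:2, 0:2, function(x1, x2) x1 / 2))
QY <- as.vector(outer(0:2, 0:2, function(x1, x2) x2 / 2))

## negative log-likelihood of the two-locus model at (p, f1, f2, rho)
twoLocusNegLL <- function(par, bb, epsPair) {
  p <- clamp(par[1], 0, 1)
  f1 <- clamp(par[2], 0, 1)
  f2 <- clamp(par[3], 0, 1)
  rho <- clamp(par[4], 0, 0.95)
  w <- as.vector(outer(dosageWeights(f1), dosageWeights(f2)))
  m <- pairMean(p * QX + (1 - p) * QY, epsPair)
  ll <- sum(colLogSumExp(log(w) + bb(m, rho)))
  if (!is.finite(ll)) 1e12 else -ll
}

RHO_GRID <- c(1e-4, 0.05, 0.2)

#' Fit the one-locus biallelic model to a SNP's read counts
#'
#' Maximises `prod_i sum_g HWE(g | f) BetaBin(k_i | N_i, m_g, rho)` over the
#' allele-1 frequency `f` and the overdispersion `rho`, where the genotype
#' means are `m_g = epsPair, 1/2, 1 - epsPair` for allele-1 dosage 0, 1, 2
#' and `epsPair = eps/3` is the within-pair error (the probability that a
#' read from one allele registers as the other, consistent with the
#' genotype caller's error channel). Coarse grid search followed by bounded
#' local refinement; deterministic.
#'
#' @param k per-individual reads carrying allele 1.
#' @param N per-individual reads carrying allele 1 or allele 2 (reads of
#'   other bases are excluded; they belong to the caller's error model).
#' @param epsilon the contig error rate.
#' @return list with `f`, `rho`, `logLik`.
#' @export
fitOneLocus <- function(k, N, epsilon) {
  keep <- N > 0
  if (sum(keep) < 1L) stop("no individual with informative coverage")
  k <- k[keep]; N <- N[keep]
  bb <- makeBBKernel(k, N)
  epsPair <- epsilon / 3
  grid <- expand.grid(f = seq(0, 1, by = 0.1), rho = RHO_GRID)
  vals <- mapply(function(f, r) oneLocusNegLL(c(f, r), bb, epsPair),
                 grid$f, grid$rho)
  st <- grid[which.min(vals), ]
  opt <- stats::optim(c(st$f, st$rho), oneLocusNegLL,
                      bb = bb, epsPair = epsPair,
                      method = "L-BFGS-B",
                      lower = c(0, 1e-9), upper = c(1, 0.9),
                      control = list(factr = 1e8))
  best <- if (opt$value <= min(vals)) opt
          else list(par = c(st$f, st$rho), value = min(vals))
  list(f = best$par[1], rho = best$par[2], logLik = -best$value)
}

#' Fit the two-locus (collapsed paralog) model to a SNP's read counts
#'
#' Both loci carry the same two alleles; locus 1 contributes a proportion
#' `p` of each individual's reads, constant across individuals. An
#' individual with genotypes of allele-1 dosage `x1`, `x2` at the two loci
#' has expected allele-1 read fraction `p x1/2 + (1 - p) x2/2`, error
#' adjusted, and counts are beta-binomial with shared overdispersion `rho`.
#' Genotypes are in Hardy-Weinberg proportions at each locus (frequencies
#' `f1`, `f2`). Coarse-grid multi-start (p in 0.1..0.9, f in 0, .25, .., 1,
#' rho in 1e-4, .05, .2) plus bounded local refinement; a start embedding
#' the fitted one-locus model at `p = 1` guarantees the nesting
#' `logL1 >= logL0`.
#'
#' @inheritParams fitOneLocus
#' @param nullFit optional result of [fitOneLocus()] on the same data, used
#'   for the nested start (computed if missing).
#' @return list with `p`, `f1`, `f2`, `rho`, `logLik`.
#' @export
fitTwoLocus <- function(k, N, epsilon, nullFit = NULL) {
  keep <- N > 0
  if (sum(keep) < 1L) stop("no individual with informative coverage")
  k <- k[keep]; N <- N[keep]
  bb <- makeBBKernel(k, N)
  epsPair <- epsilon / 3
  if (is.null(nullFit)) nullFit <- fitOneLocus(k, N, epsilon)
  fGrid <- c(0, 0.25, 0.5, 0.75, 1)
  ff <- expand.grid(f1 = fGrid, f2 = fGrid)
  W <- t(mapply(function(f1, f2)
    as.vector(outer(dosageWeights(f1), dosageWeights(f2))),
    ff$f1, ff$f2))
  bestVal <- Inf
  bestPar <- NULL
  for (p in seq(0.1, 0.9, by = 0.1)) {
    m <- pairMean(p * QX + (1 - p) * QY, epsPair)
    for (rho in RHO_GRID) {
      B <- bb(m, rho)
      ## loglik for all 25 (f1, f2) pairs at once
      mx <- B[1L, ]
      for (g in 2:9) mx <- pmax(mx, B[g, ])
      E <- exp(B - rep(mx, each = 9L))
      ll <- rowSums(log(W %*% E)) + sum(mx)
      j <- which.max(ll)
      if (-ll[j] < bestVal) {
        bestVal <- -ll[j]
        bestPar <- c(p, ff$f1[j], ff$f2[j], rho)
      }
    }
  }
  ## refine from the better of the grid optimum and the p = 1 embedding of
  ## the one-locus fit (which also guarantees the nesting logL1 >= logL0)
  nullPar <- c(1, nullFit$f, 0.5, max(nullFit$rho, 1e-6))
  nullVal <- -nullFit$logLik
  st <- if (bestVal <= nullVal) bestPar else nullPar
  opt <- tryCatch(
    stats::optim(st, twoLocusNegLL, bb = bb, epsPair = epsPair,
                 method = "L-BFGS-B",
                 lower = c(0, 0, 0, 1e-9), upper = c(1, 1, 1, 0.9),
                 control = list(factr = 1e8)),
    error = function(e) list(par = st, value = twoLocusNegLL(st, bb, epsPair)))
  best <- opt
  for (cand in list(list(par = bestPar, value = bestVal),
                    list(par = nullPar, value = nullVal)))
    if (cand$value < best$value) best <- cand
  list(p = clamp(best$par[1], 0, 1), f1 = clamp(best$par[2], 0, 1),
       f2 = clamp(best$par[3], 0, 1), rho = clamp(best$par[4], 0, 0.95),
       logLik = -best$value)
}

#' Likelihood-ratio test for hidden paralogy at one SNP
#'
#' Compares the one-locus and two-locus fits on the allele-1 / allele-2 read
#' counts of a biallelic SNP. The statistic `lambda = 2 (logL1 - logL0)` is
#' referred to a chi-squared distribution with 2 degrees of freedom (the
#' added mixing proportion and second allele frequency); this reference is
#' approximate because of boundary and mixture effects, and the package's
#' type-I-error simulation is the calibration instrument. The test applies
#' only to sites with at least one heterozygous genotype call; other sites
#' are returned as not applicable.
#'
#' @inheritParams fitOneLocus
#' @param nHet number of heterozygous genotype calls at the site.
#' @param alpha significance level for flagging (pipeline default 0.001).
#' @return data.frame row: lambda, df, pValue, flagged, applicable, plus the
#'   fitted parameters (f0, rho0, p, f1, f2, rho1).
#' @export
paralogLrt <- function(k, N, epsilon, nHet, alpha = 0.001) {
  if (nHet < 1L)
    return(data.frame(lambda = NA_real_, df = 2L, pValue = NA_real_,
                      flagged = FALSE, applicable = FALSE,
                      f0 = NA_real_, rho0 = NA_real_, p = NA_real_,
                      f1 = NA_real_, f2 = NA_real_, rho1 = NA_real_))
  fit0 <- fitOneLocus(k, N, epsilon)
  fit1 <- fitTwoLocus(k, N, epsilon, nullFit = fit0)
  lambda <- 2 * (fit1$logLik - fit0$logLik)
  pv <- stats::pchisq(max(lambda, 0), df = 2L, lower.tail = FALSE)
  data.frame(lambda = lambda, df = 2L, pValue = pv,
             flagged = pv < alpha, applicable = TRUE,
             f0 = fit0$f, rho0 = fit0$rho, p = fit1$p, f1 = fit1$f1,
             f2 = fit1$f2, rho1 = fit1$rho, row.names = NULL)
}

#' Test every SNP of a contig for hidden paralogy
#'
#' Extracts, for each biallelic SNP, the per-individual counts of reads
#' carrying allele 1 (`k`) and allele 1 or 2 (`N`) from the contig's base
#' counts (reads of other bases are excluded and their number recorded for
#' QC), counts heterozygous calls, and runs [paralogLrt()].
#'
#' @param snps SNP table from [identifySnps()] for one contig.
#' @param counts the contig's [ContigCounts].
#' @param calls the contig's [GenotypeCalls].
#' @param alpha significance level.
#' @return the SNP table with appended test columns (lambda, df, pValue,
#'   flagged, applicable, discardedReads).
#' @export
testContigParalogs <- function(snps, counts, calls, alpha = 0.001) {
  if (nrow(snps) == 0L) return(cbind(snps, emptyParalogCols()))
  eps <- calls@epsilon
  res <- vector("list", nrow(snps))
  disc <- integer(nrow(snps))
  for (r in seq_len(nrow(snps))) {
    s <- snps$site[r] + 1L
    if (isTRUE(snps$multiallelic[r])) {
      res[[r]] <- paralogLrt(0, 0, eps, nHet = 0L, alpha = alpha)
      next
    }
    b1 <- match(snps$allele1[r], BASES)
    b2 <- match(snps$allele2[r], BASES)
    kk <- counts@counts[s, , b1]
    NN <- kk + counts@counts[s, , b2]
    disc[r] <- sum(coverageMatrix(counts)[s, ]) - sum(NN)
    g <- calls@genotype[s, ]
    het <- sum(!is.na(g) & substr(g, 1, 1) != substr(g, 2, 2))
    res[[r]] <- paralogLrt(kk, NN, eps, nHet = het, alpha = alpha)
  }
  out <- cbind(snps, do.call(rbind, res))
  out$discardedReads <- disc
  out
}

emptyParalogCols <- function() {
  data.frame(lambda = numeric(), df = integer(), pValue = numeric(),
             flagged = logical(), applicable = logical(), f0 = numeric(),
             rho0 = numeric(), p = numeric(), f1 = numeric(), f2 = numeric(),
             rho1 = numeric(), discardedReads = integer())
}

#' Partition SNPs by the paralogy filter
#'
#' Flagged SNPs (significant likelihood-ratio test) are removed from the
#' analysis set; untested SNPs (no heterozygous call) are retained.
#'
#' @param snps annotated SNP table from [testContigParalogs()].
#' @return list with `retained` and `flagged` SNP tables; both carry
#'   `paralogTested` and `paralogFlag` columns for VCF FILTER annotation.
#' @export
applyParalogFilter <- function(snps) {
  snps$paralogTested <- !is.na(snps$applicable) & snps$applicable
  snps$paralogFlag <- snps$paralogTested & !is.na(snps$flagged) & snps$flagged
  list(retained = snps[!snps$paralogFlag, , drop = FALSE],
       flagged = snps[snps$paralogFlag, , drop = FALSE])
}
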