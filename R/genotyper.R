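## Maximum-likelihood error-rate estimation and posterior genotype calling.
##
## Model: reads at a site are independent draws from a base distribution set
## by the individual's diploid genotype and a symmetric error channel with
## per-base error rate epsilon shared across all sites of a contig:
##   homozygote XX:     P(read = X) = 1 - eps,          P(other) = eps/3
##   heterozygote XY:   P(read in {X,Y}) = (1 - 2eps/3)/2 each, P(other) = eps/3
## The multinomial coefficient is omitted throughout: it is constant across
## genotypes and independent of epsilon, so it affects neither posteriors nor
## the epsilon maximisation.

## ---- low-level likelihood kernels -------------------------------------

## x*log(p) with the 0*log(0) = 0 convention
xlogy <- function(x, p) {
  out <- x * log(p)
  out[x == 0] <- 0
  out
}

## log-likelihood array: sites x individuals x 10 genotypes
gtLogLikArray <- function(countsArr, epsilon) {
  d <- dim(countsArr)
  S <- d[1]; I <- d[2]
  cov <- countsArr[, , 1] + countsArr[, , 2] + countsArr[, , 3] +
    countsArr[, , 4]
  dim(cov) <- c(S, I)
  ll <- array(0, dim = c(S, I, 10L))
  logMiss <- if (epsilon > 0) log(epsilon / 3) else -Inf
  for (g in 1:10) {
    dos <- GT_DOSAGE[g, ]
    inb <- which(dos > 0L)
    if (length(inb) == 1L) {        # homozygote
      m <- countsArr[, , inb]
      pin <- 1 - epsilon
    } else {                        # heterozygote
      m <- countsArr[, , inb[1]] + countsArr[, , inb[2]]
      pin <- (1 - 2 * epsilon / 3) / 2
    }
    dim(m) <- c(S, I)
    mism <- cov - m
    term <- mism * logMiss
    term[mism == 0] <- 0
    ll[, , g] <- xlogy(m, pin) + term
  }
  ll
}

## HWE genotype priors from a sites x 4 frequency matrix: sites x 10
hwePriors <- function(freqs) {
  P <- matrix(0, nrow(freqs), 10L, dimnames = list(NULL, GENOTYPES))
  for (g in 1:10) {
    dos <- GT_DOSAGE[g, ]
    inb <- which(dos > 0L)
    P[, g] <- if (length(inb) == 1L) freqs[, inb]^2
              else 2 * freqs[, inb[1]] * freqs[, inb[2]]
  }
  P
}

## Posterior array and per-(site, individual) normalising constants.
## Returns list(post = S x I x 10, logNorm = S x I) where
## logNorm = log sum_g prior * exp(ll) is the per-observation log-likelihood.
gtPosteriors <- function(ll, priors) {
  d <- dim(ll)
  S <- d[1]; I <- d[2]
  mx <- ll[, , 1]
  for (g in 2:10) mx <- pmax(mx, ll[, , g])
  mx[!is.finite(mx)] <- 0
  W <- array(0, dim = d)
  for (g in 1:10) W[, , g] <- priors[, g] * exp(ll[, , g] - as.vector(mx))
  norm <- W[, , 1]
  for (g in 2:10) norm <- norm + W[, , g]
  post <- W / as.vector(norm)
  list(post = post, logNorm = log(norm) + mx)
}

## ---- exported per-site operations -------------------------------------

#' Genotype log-likelihoods for one base-count vector
#'
#' Log-likelihood of each of the 10 unordered diploid genotypes given the
#' four base counts at one site for one individual, under the shared-error
#' multinomial read model. The multinomial coefficient is omitted (constant
#' across genotypes). Zero coverage yields all-equal (zero) log-likelihoods.
#'
#' @param counts4 non-negative counts for A, C, G, T.
#' @param epsilon per-base error rate in `[0, 0.75)`.
#' @return named numeric vector of length 10 (AA, AC, ..., TT), in nats.
#' @examples
#' genotypeLogLikelihoods(c(5, 5, 0, 0), 0.01)
#' @export
genotypeLogLikelihoods <- function(counts4, epsilon) {
  stopifnot(length(counts4) == 4L, all(counts4 >= 0))
  if (epsilon < 0 || epsilon >= 0.75)
    stop("epsilon must lie in [0, 0.75)")
  arr <- array(as.numeric(counts4), dim = c(1L, 1L, 4L))
  stats::setNames(gtLogLikArray(arr, epsilon)[1, 1, ], GENOTYPES)
}

#' Maximum-likelihood allele frequencies at one site
#'
#' EM estimate of the four allele frequencies maximising the site likelihood
#' `prod_i sum_g HWE(g | f) L_i(g | eps)` across individuals, used as the
#' Hardy-Weinberg prior of the genotype caller. Deterministic given inputs.
#' A site with no covered individual returns uniform frequencies and is
#' flagged uninformative.
#'
#' @param siteCounts individuals x 4 matrix of base counts at one site.
#' @param epsilon per-base error rate.
#' @param tol EM convergence tolerance on max absolute frequency change.
#' @param maxIter maximum EM iterations.
#' @return list with `freqs` (4-vector summing to 1) and `informative` flag.
#' @export
estimateSiteFrequencies <- function(siteCounts, epsilon, tol = 1e-10,
                                    maxIter = 200L) {
  siteCounts <- matrix(as.numeric(siteCounts), ncol = 4L)
  arr <- array(0, dim = c(1L, nrow(siteCounts), 4L))
  arr[1, , ] <- siteCounts
  f <- contigSiteFrequencies(arr, epsilon, tol = tol, maxIter = maxIter)
  list(freqs = stats::setNames(f$freqs[1, ], BASES),
       informative = f$informative[1])
}

## Vectorised frequency EM for a whole contig.
## countsArr: sites x individuals x 4. Returns freqs (S x 4), informative (S).
contigSiteFrequencies <- function(countsArr, epsilon, tol = 1e-8,
                                  maxIter = 200L) {
  d <- dim(countsArr)
  S <- d[1]; I <- d[2]
  cov <- countsArr[, , 1] + countsArr[, , 2] + countsArr[, , 3] +
    countsArr[, , 4]
  dim(cov) <- c(S, I)
  covered <- cov > 0
  nInf <- rowSums(covered)
  informative <- nInf > 0
  ## init from pooled base proportions with a small floor
  pooled <- apply(countsArr, c(1, 3), sum)
  tot <- rowSums(pooled)
  freqs <- (pooled + 0.01) / (tot + 0.04)
  freqs[!informative, ] <- 0.25
  ll <- gtLogLikArray(countsArr, epsilon)
  mask <- covered * 1
  ## active-set EM: sites whose frequencies have converged are frozen
  active <- which(informative)
  for (it in seq_len(maxIter)) {
    if (length(active) == 0L) break
    llA <- ll[active, , , drop = FALSE]
    priors <- hwePriors(freqs[active, , drop = FALSE])
    post <- gtPosteriors(llA, priors)$post
    nA <- length(active)
    maskA <- mask[active, , drop = FALSE]
    newF <- matrix(0, nA, 4L)
    for (b in 1:4) {
      acc <- matrix(0, nA, I)
      for (g in 1:10)
        if (GT_DOSAGE[g, b] > 0L)
          acc <- acc + GT_DOSAGE[g, b] *
            array(post[, , g], dim = c(nA, I))
      newF[, b] <- rowSums(acc * maskA)
    }
    newF <- newF / (2 * nInf[active])
    delta <- apply(abs(newF - freqs[active, , drop = FALSE]), 1L, max)
    freqs[active, ] <- newF
    active <- active[delta >= tol]
  }
  colnames(freqs) <- BASES
  list(freqs = freqs, informative = informative)
}

## Total contig log-likelihood for given epsilon and per-site frequencies.
contigLogLik <- function(countsArr, epsilon, freqs) {
  ll <- gtLogLikArray(countsArr, epsilon)
  sum(gtPosteriors(ll, hwePriors(freqs))$logNorm)
}

#' Estimate the per-contig error rate by profile maximum likelihood
#'
#' Maximises the contig likelihood over the shared error rate epsilon with
#' per-site allele frequencies profiled out, by alternating (i) per-site
#' frequency EM given epsilon and (ii) bounded 1-D maximisation of epsilon
#' given the frequencies. Convergence when the outer log-likelihood gain
#' falls below `tol` (default 1e-6 nats) or after `maxOuter` rounds. A
#' contig with no covered site is an error.
#'
#' @param counts a [ContigCounts] object (post duplicate collapsing and
#'   coverage filtering).
#' @param epsMax upper bound of the epsilon search interval.
#' @param tol outer-loop convergence tolerance in log-likelihood units.
#' @param maxOuter maximum outer iterations.
#' @return an [ErrorModel].
#' @export
estimateErrorRate <- function(counts, epsMax = 0.2, tol = 1e-6,
                              maxOuter = 200L) {
  arr <- counts@counts
  storage.mode(arr) <- "double"
  cov <- coverageMatrix(counts)
  if (all(cov == 0))
    stop("contig ", counts@contig, " has no informative site")
  ## initialise from the pooled mismatch-to-consensus fraction
  pooled <- apply(arr, c(1, 3), sum)
  tot <- rowSums(pooled)
  mism <- sum(tot - apply(pooled, 1, max))
  eps <- min(max(mism / max(sum(tot), 1), 1e-6), epsMax)
  prevLL <- -Inf
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    fr <- contigSiteFrequencies(arr, eps)$freqs
    opt <- stats::optimize(function(e) contigLogLik(arr, e, fr),
                           interval = c(1e-9, epsMax), maximum = TRUE,
                           tol = 1e-9)
    ll0 <- contigLogLik(arr, 0, fr)          # boundary: error-free contig
    if (ll0 >= opt$objective) {
      eps <- 0; curLL <- ll0
    } else {
      eps <- opt$maximum; curLL <- opt$objective
    }
    if (curLL - prevLL < tol || it >= maxOuter) {
      converged <- curLL - prevLL < tol
      prevLL <- max(curLL, prevLL)
      break
    }
    prevLL <- curLL
  }
  new("ErrorModel", contig = counts@contig, epsilon = eps, logLik = prevLL,
      converged = converged, iterations = it)
}

#' Caller configuration
#'
#' @param posteriorThreshold minimum posterior probability of the best
#'   genotype for a call in threshold mode (in (0.5, 1]); below it the
#'   position is coded missing.
#' @param minCoverage minimum reads per position per individual for any call
#'   (10 by default; 30 in the high-coverage control).
#' @param mode `"threshold"` (call the best genotype if it clears the
#'   threshold) or `"sample"` (threshold-free control: draw one genotype from
#'   the posterior).
#' @param seed integer seed used by sample mode.
#' @return a list of class `callerConfig`.
#' @export
callerConfig <- function(posteriorThreshold = 0.95, minCoverage = 10L,
                         mode = c("threshold", "sample"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(posteriorThreshold > 0.5, posteriorThreshold <= 1,
            minCoverage >= 1L)
  structure(list(posteriorThreshold = posteriorThreshold,
                 minCoverage = as.integer(minCoverage), mode = mode,
                 seed = as.integer(seed)),
            class = "callerConfig")
}

#' Call genotypes for one contig
#'
#' Computes, for every site and individual, the posterior probability of each
#' of the 10 unordered genotypes as `HWE prior(g | f) x L(g | counts, eps)`
#' normalised, and calls genotypes according to the configuration: in
#' threshold mode the best-supported genotype is called when its posterior
#' reaches the threshold (default 0.95) and the position is coded missing
#' otherwise (exact posterior ties are missing too); in sample mode one
#' genotype is drawn from the posterior (threshold-free control). In both
#' modes a position with coverage below `minCoverage` is missing.
#'
#' @param counts a [ContigCounts].
#' @param errorModel an [ErrorModel] (or a bare epsilon value).
#' @param freqs optional sites x 4 frequency matrix; computed by EM when
#'   omitted.
#' @param config a [callerConfig()].
#' @return a [GenotypeCalls].
#' @export
callGenotypes <- function(counts, errorModel, freqs = NULL,
                          config = callerConfig()) {
  eps <- if (is(errorModel, "ErrorModel")) errorModel@epsilon
         else as.numeric(errorModel)
  arr <- counts@counts
  storage.mode(arr) <- "double"
  d <- dim(arr)
  S <- d[1]; I <- d[2]
  if (is.null(freqs))
    freqs <- contigSiteFrequencies(arr, eps)$freqs
  ll <- gtLogLikArray(arr, eps)
  post <- gtPosteriors(ll, hwePriors(freqs))$post
  cov <- coverageMatrix(counts)
  gt <- matrix(NA_character_, S, I, dimnames = list(NULL, counts@individuals))
  bestP <- matrix(NA_real_, S, I)
  flat <- matrix(post, S * I, 10L)
  if (config$mode == "threshold") {
    best <- max.col(flat, ties.method = "first")
    bestVal <- flat[cbind(seq_len(S * I), best)]
    ## an exact tie for the maximum means no best-supported genotype
    nmax <- rowSums(flat == bestVal)
    call <- GENOTYPES[best]
    call[bestVal < config$posteriorThreshold | nmax > 1L] <- NA_character_
    gt[] <- call
    bestP[] <- bestVal
  } else {
    set.seed(config$seed)
    draw <- apply(flat, 1, function(p) sample.int(10L, 1L, prob = p))
    gt[] <- GENOTYPES[draw]
    bestP[] <- flat[cbind(seq_len(S * I), draw)]
  }
  lowCov <- cov < config$minCoverage
  gt[lowCov] <- NA_character_
  new("GenotypeCalls", contig = counts@contig,
      individuals = counts@individuals, genotype = gt, posterior = bestP,
      coverage = cov, freqs = freqs, epsilon = eps)
}

#' Identify polymorphic sites among called genotypes
#'
#' A site is a SNP when at least two distinct alleles appear among the
#' non-missing called genotypes. Sites with more than two alleles are
#' flagged multi-allelic (they are excluded from downstream statistics,
#' which use biallelic sites only). Allele 1 is the major allele by
#' haplotype count (alphabetical on ties).
#'
#' @param calls a [GenotypeCalls].
#' @return data.frame with one row per SNP: contig, site (0-based), allele1,
#'   allele2 (NA when multi-allelic), nAlleles, multiallelic, nMissing,
#'   nHaplotypes (non-missing haplotypes m), minorCount, maf.
#' @export
identifySnps <- function(calls) {
  gt <- calls@genotype
  S <- nrow(gt)
  rows <- vector("list", S)
  for (s in seq_len(S)) {
    g <- gt[s, ]
    g <- g[!is.na(g)]
    if (length(g) == 0L) next
    cnt <- colSums(GT_DOSAGE[g, , drop = FALSE])
    alleles <- BASES[cnt > 0L]
    if (length(alleles) < 2L) next
    multi <- length(alleles) > 2L
    ord <- order(-cnt[cnt > 0L], alleles)
    a1 <- alleles[ord[1]]
    a2 <- if (!multi) alleles[ord[2]] else NA_character_
    m <- 2L * length(g)
    minor <- if (!multi) as.integer(cnt[a2]) else NA_integer_
    rows[[s]] <- data.frame(
      contig = calls@contig, site = s - 1L, allele1 = a1, allele2 = a2,
      nAlleles = length(alleles), multiallelic = multi,
      nMissing = sum(is.na(gt[s, ])), nHaplotypes = m,
      minorCount = minor,
      maf = if (!multi) minor / m else NA_real_,
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L)
    return(data.frame(contig = character(), site = integer(),
                      allele1 = character(), allele2 = character(),
                      nAlleles = integer(), multiallelic = logical(),
                      nMissing = integer(), nHaplotypes = integer(),
                      minorCount = integer(), maf = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
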