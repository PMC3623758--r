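test_that("genotype likelihoods follow the shared-error read model", {
  ## no-error limit
  ll <- genotypeLogLikelihoods(c(10, 0, 0, 0), 0)
  expect_equal(exp(ll[["AA"]]), 1)
  expect_equal(exp(ll[["AC"]]), 0.5^10)
  expect_equal(exp(ll[["CC"]]), 0)

  ## direct evaluation of the stated per-base probabilities
  ll2 <- genotypeLogLikelihoods(c(5, 5, 0, 0), 0.01)
  expect_equal(exp(ll2[["AC"]]), ((1 - 2 * 0.01 / 3) / 2)^10)
  expect_equal(exp(ll2[["AA"]]), 0.99^5 * (0.01 / 3)^5)

  ## no data: all genotypes equally likely
  expect_true(all(genotypeLogLikelihoods(c(0, 0, 0, 0), 0.01) == 0))

  expect_error(genotypeLogLikelihoods(c(1, 0, 0, 0), 0.8), "epsilon")
})

test_that("posterior ratios are unaffected by the multinomial coefficient", {
  ## including the constant C(n; n_A..n_T) shifts every genotype equally
  counts <- c(7, 3, 1, 0)
  ll <- genotypeLogLikelihoods(counts, 0.01)
  lcoef <- lgamma(sum(counts) + 1) - sum(lgamma(counts + 1))
  post1 <- exp(ll) / sum(exp(ll))
  post2 <- exp(ll + lcoef) / sum(exp(ll + lcoef))
  expect_equal(post1, post2)
})

test_that("site frequency EM matches grid-search maxima", {
  ## half A, half C individuals at high coverage
  siteCounts <- rbind(matrix(rep(c(20, 0, 0, 0), 5), 5, byrow = TRUE),
                      matrix(rep(c(0, 20, 0, 0), 5), 5, byrow = TRUE))
  f <- estimateSiteFrequencies(siteCounts, 0.005)
  expect_equal(unname(f$freqs[1:2]), c(0.5, 0.5), tolerance = 1e-3)

  ## single individual (3,3,0,0): compare with a 1-D grid search oracle
  ## over f_A = 1 - f_C (other frequencies are 0 at the optimum)
  siteLik <- function(fa, eps = 0.01) {
    pri <- c(fa^2, 2 * fa * (1 - fa), (1 - fa)^2)   # AA, AC, CC
    lik <- exp(genotypeLogLikelihoods(c(3, 3, 0, 0), eps)[c("AA", "AC", "CC")])
    sum(pri * lik)
  }
  grid <- seq(0, 1, by = 1e-3)
  fBest <- grid[which.max(vapply(grid, siteLik, 0))]
  f2 <- estimateSiteFrequencies(matrix(c(3, 3, 0, 0), 1), 0.01)
  expect_equal(unname(f2$freqs[1]), fBest, tolerance = 1e-3)
  expect_equal(unname(f2$freqs[1]), 0.5, tolerance = 1e-3)

  ## monomorphic data
  f3 <- estimateSiteFrequencies(matrix(rep(c(30, 0, 0, 0), 10), 10,
                                       byrow = TRUE), 0.001)
  expect_gt(f3$freqs[["A"]], 0.999)

  ## uninformative site
  f4 <- estimateSiteFrequencies(matrix(0, 4, 4), 0.01)
  expect_false(f4$informative)
  expect_equal(unname(f4$freqs), rep(0.25, 4))
})

test_that("error-rate estimation recovers the truth and hits the boundary", {
  ## homozygous contig, 99 matching + 1 mismatching read per site/individual
  set.seed(1)
  L <- 60L; nI <- 4L
  arr <- array(0L, dim = c(L, nI, 4L))
  for (s in seq_len(L)) for (i in seq_len(nI)) {
    arr[s, i, 1] <- 99L
    arr[s, i, 1 + (s + i) %% 3 + 1] <- 1L   # one mismatch, rotating base
  }
  em <- estimateErrorRate(makeCounts(arr))
  ## mismatch fraction equals eps under homozygosity: 1/100, factor 1-eps
  expect_equal(epsilonHat(em), 0.01, tolerance = 0.002)

  ## zero mismatching reads: boundary estimate 0
  em0 <- estimateErrorRate(homCounts(strrep("A", 50)))
  expect_equal(epsilonHat(em0), 0)

  ## contig with no covered site errors
  empty <- makeCounts(array(0L, dim = c(10, 2, 4)))
  expect_error(estimateErrorRate(empty), "informative")
})

test_that("epsilon estimate is invariant to relabeling and site order", {
  set.seed(5)
  sim <- simulateDataset(simulationConfig(nContigs = 1, contigLength = 60L,
                                          coverage = 15, coverageSdLog = 0,
                                          seed = 11))
  cc <- sim$counts[[1]]
  e1 <- epsilonHat(estimateErrorRate(cc))
  arr <- countsArray(cc)
  perm <- sample(dim(arr)[1])
  permI <- sample(dim(arr)[2])
  cc2 <- makeCounts(arr[perm, permI, ],
                    individuals = individualIds(cc)[permI])
  e2 <- epsilonHat(estimateErrorRate(cc2))
  expect_equal(e1, e2, tolerance = 1e-5)
})

test_that("threshold calling applies the 0.95 posterior and coverage rules", {
  ## (5,5) at eps 0.01, f = (.5,.5): het posterior ~ 1 -> called AC
  arr <- array(0L, dim = c(2, 1, 4))
  arr[1, 1, ] <- c(5L, 5L, 0L, 0L)
  arr[2, 1, ] <- c(9L, 0L, 0L, 0L)         # coverage 9 < 10
  cc <- makeCounts(arr)
  freqs <- rbind(c(0.5, 0.5, 0, 0), c(1, 0, 0, 0))
  cl <- callGenotypes(cc, 0.01, freqs = freqs, config = callerConfig())
  expect_equal(unname(genotypeMatrix(cl)[1, 1]), "AC")
  ## posterior of AC from direct evaluation: 1 - ~4.3e-10
  expect_gt(cl@posterior[1, 1], 1 - 1e-8)
  expect_true(is.na(genotypeMatrix(cl)[2, 1]))  # low coverage -> missing

  ## (12,1) with skewed priors: best posterior 0.925 < 0.95 -> missing
  arr2 <- array(0L, dim = c(1, 1, 4))
  arr2[1, 1, ] <- c(12L, 1L, 0L, 0L)
  cl2 <- callGenotypes(makeCounts(arr2), 0.001,
                       freqs = matrix(c(0.9, 0.1, 0, 0), 1))
  expect_true(is.na(genotypeMatrix(cl2)[1, 1]))
  expect_equal(cl2@posterior[1, 1], 0.925, tolerance = 2e-3)
})

test_that("sample mode draws from the posterior reproducibly", {
  arr <- array(0L, dim = c(1, 1, 4))
  arr[1, 1, ] <- c(7L, 6L, 0L, 0L)
  cc <- makeCounts(arr)
  cfg <- callerConfig(mode = "sample", seed = 7L)
  g1 <- genotypeMatrix(callGenotypes(cc, 0.01, config = cfg))
  g2 <- genotypeMatrix(callGenotypes(cc, 0.01, config = cfg))
  expect_identical(g1, g2)                  # bit-reproducible under the seed
  expect_false(is.na(g1[1, 1]))             # threshold-free: no missing call
  ## over many draws both AC and homozygotes appear per their posteriors
  draws <- vapply(1:50, function(s)
    genotypeMatrix(callGenotypes(cc, 0.05,
                                 config = callerConfig(mode = "sample",
                                                       seed = s)))[1, 1], "")
  expect_gt(mean(draws == "AC"), 0.5)
})

test_that("with eps = 0 simulation truth is recovered on observed alleles", {
  set.seed(9)
  sim <- simulateDataset(simulationConfig(nContigs = 2, contigLength = 99L,
                                          coverage = 25, coverageSdLog = 0,
                                          epsilon = 0, thetaSyn = 0.05,
                                          seed = 13))
  for (ctg in names(sim$counts)) {
    em <- estimateErrorRate(sim$counts[[ctg]])
    expect_equal(epsilonHat(em), 0)
    cl <- callGenotypes(sim$counts[[ctg]], em)
    gt <- genotypeMatrix(cl)
    tr <- sim$truth[[ctg]]$genotype
    ok <- !is.na(gt) & !is.na(tr)
    ## homozygotes always exact; heterozygotes exact when both alleles seen,
    ## which at 25X and eps 0 is essentially always among called genotypes
    expect_true(all(gt[ok] == tr[ok]))
  }
})

test_that("SNP identification flags polymorphism and multi-allelism", {
  gt <- rbind(rep("AA", 10),                    # monomorphic
              c(rep("AA", 9), "AC"),            # singleton SNP
              c(rep("AA", 8), "CC", "AG"),      # three alleles
              c(rep("CC", 4), rep(NA, 6)))      # monomorphic with missing
  calls <- makeCalls(gt)
  snps <- identifySnps(calls)
  expect_equal(snps$site, c(1L, 2L))
  s1 <- snps[snps$site == 1L, ]
  expect_equal(s1$allele1, "A"); expect_equal(s1$allele2, "C")
  expect_equal(s1$minorCount, 1L)
  expect_equal(s1$nHaplotypes, 20L)
  expect_false(s1$multiallelic)
  expect_true(snps$multiallelic[snps$site == 2L])
})

test_that("heterozygosity is uncorrelated with per-individual coverage", {
  ## unbalanced design: coverage varies 5-15X across individuals
  cfg <- simulationConfig(nContigs = 40, coveragePerIndividual = seq(5, 15,
                                                                     length.out = 10),
                          coverageSdLog = 0, seed = 21)
  sim <- simulateDataset(cfg)
  calls <- lapply(sim$counts, function(cc)
    callGenotypes(cc, estimateErrorRate(cc)))
  hz <- perIndividualHeterozygosity(unname(calls))
  ct <- cor.test(hz, seq(5, 15, length.out = 10))
  expect_gt(ct$p.value, 0.01)
})
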