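test_that("beta-binomial pmf has the documented limits and closed forms", {
  ## binomial limit
  expect_equal(betabinomLogPmf(3, 10, 0.5, 0), log(120 / 1024))
  expect_equal(betabinomLogPmf(3, 10, 0.5, 1e-12),
               dbinom(3, 10, 0.5, log = TRUE), tolerance = 1e-6)
  ## degenerate means are log-zero, not exceptions
  expect_equal(betabinomLogPmf(10, 10, 1, 0.3), 0)
  expect_equal(betabinomLogPmf(3, 10, 0, 0.3), -Inf)
  expect_equal(betabinomLogPmf(0, 10, 0, 0.3), 0)
  ## rho = 1/3 with m = 1/2 is the uniform beta: pmf 1/(N+1)
  expect_equal(exp(betabinomLogPmf(0:10, 10, 0.5, 1 / 3)), rep(1 / 11, 11))
  ## normalisation for assorted (m, rho)
  for (m in c(0.1, 0.5, 0.9)) for (rho in c(0.01, 0.2, 0.6)) {
    expect_equal(sum(exp(betabinomLogPmf(0:15, 15, m, rho))), 1,
                 tolerance = 1e-8)
  }
})

test_that("one-locus fit matches a grid-search oracle", {
  set.seed(2)
  ## simulated balanced het at 20X in 10 individuals
  s <- simulateOneLocusSite(f = 0.999, coverage = 20, rho = 0,
                            epsilon = 0.001, nIndividuals = 10,
                            requireHet = FALSE)
  ## force an all-k-equal-N monomorphic pattern
  fitMono <- fitOneLocus(s$N, s$N, 0.001)
  expect_gt(fitMono$f, 0.99)

  kk <- rbinom(10, 20, 0.5)
  NN <- rep(20L, 10)
  fit <- fitOneLocus(kk, NN, 0.005)
  ## independent coarse 2-D grid oracle
  best <- -Inf
  for (f in seq(0, 1, by = 0.02))
    for (rho in c(1e-6, seq(0.01, 0.5, by = 0.01))) {
      v <- sum(vapply(seq_along(kk), function(i) {
        w <- c((1 - f)^2, 2 * f * (1 - f), f^2)
        m <- c(0, 0.5, 1) * (1 - 2 * 0.005 / 3) + 0.005 / 3
        log(sum(w * exp(betabinomLogPmf(kk[i], NN[i], m, rho))))
      }, 0))
      best <- max(best, v)
    }
  expect_gte(fit$logLik, best - 1e-4)
  expect_lt(fit$rho, 0.1)
})

test_that("overdispersion is detected under allele-expression bias", {
  set.seed(4)
  s <- simulateOneLocusSite(f = 0.5, coverage = 40, rho = 0.15,
                            epsilon = 0.001, nIndividuals = 12)
  fit <- fitOneLocus(s$k, s$N, 0.001)
  expect_gt(fit$rho, 0.01)
})

test_that("two-locus fit recovers the mixing proportion and nests the null", {
  set.seed(6)
  s <- simulateParalogSite(p = 0.7, coverage = 30, rho = 0, epsilon = 0.005,
                           nIndividuals = 10)
  fit0 <- fitOneLocus(s$k, s$N, 0.005)
  fit1 <- fitTwoLocus(s$k, s$N, 0.005, nullFit = fit0)
  expect_gt(fit1$logLik, fit0$logLik + 5)       # collapse fits far better
  pHat <- max(fit1$p, 1 - fit1$p)               # p vs 1-p label symmetry
  expect_gt(pHat, 0.6); expect_lt(pHat, 0.8)

  ## one-locus data: improvement stays small and never negative
  set.seed(8)
  for (i in 1:20) {
    s0 <- simulateOneLocusSite(coverage = 12, rho = 0, epsilon = 0.005,
                               nIndividuals = 8)
    f0 <- fitOneLocus(s0$k, s0$N, 0.005)
    f1 <- fitTwoLocus(s0$k, s0$N, 0.005, nullFit = f0)
    expect_gte(f1$logLik, f0$logLik - 1e-6)     # nesting invariant
  }
})

test_that("balanced fixed-difference mimic of a heterozygote does not crash", {
  ## p = 0.5, f1 = 1, f2 = 0: every individual looks like a balanced het
  set.seed(10)
  s <- simulateParalogSite(p = 0.5, coverage = 20, rho = 0, epsilon = 0,
                           nIndividuals = 10)
  res <- paralogLrt(s$k, s$N, 0, nHet = 10)
  expect_true(res$applicable)
  expect_true(is.finite(res$lambda))
})

test_that("the LRT flags collapses, spares clean sites, skips hom-only sites", {
  set.seed(12)
  s <- simulateParalogSite(p = 0.5, coverage = 20, rho = 0, epsilon = 0.005,
                           nIndividuals = 10)
  res <- paralogLrt(s$k, s$N, 0.005, nHet = 10, alpha = 0.001)
  expect_true(res$flagged)
  expect_equal(res$df, 2L)
  expect_equal(res$pValue, pchisq(res$lambda, 2, lower.tail = FALSE))

  ## no heterozygote: not applicable, never flagged
  na <- paralogLrt(c(10, 10), c(10, 10), 0.005, nHet = 0)
  expect_false(na$applicable)
  expect_false(na$flagged)
})

test_that("filter partitioning discards flagged SNPs and keeps untested ones", {
  snps <- data.frame(contig = "c1", site = 0:2, stringsAsFactors = FALSE)
  snps$applicable <- c(TRUE, TRUE, FALSE)
  snps$flagged <- c(TRUE, FALSE, NA)
  snps$pValue <- c(2e-4, 0.5, NA)
  out <- applyParalogFilter(snps)
  expect_equal(out$retained$site, c(1L, 2L))   # p = 0.5 kept, untested kept
  expect_equal(out$flagged$site, 0L)           # p = 2e-4 discarded
  expect_true(all(out$retained$paralogFlag == FALSE))
})

test_that("contig-level testing extracts counts and het calls correctly", {
  ## two individuals het A/C with balanced reads, one hom A
  arr <- array(0L, dim = c(1, 3, 4))
  arr[1, 1, ] <- c(10L, 10L, 1L, 0L)    # one discarded G read
  arr[1, 2, ] <- c(11L, 9L, 0L, 0L)
  arr[1, 3, ] <- c(20L, 0L, 0L, 0L)
  cc <- makeCounts(arr, individuals = c("i1", "i2", "i3"))
  gt <- matrix(c("AC", "AC", "AA"), 1, 3,
               dimnames = list(NULL, c("i1", "i2", "i3")))
  calls <- makeCalls(gt)
  calls@contig <- "c1"
  snps <- identifySnps(calls)
  res <- testContigParalogs(snps, cc, calls)
  expect_equal(res$discardedReads, 1L)
  expect_true(res$applicable)
  expect_gte(res$lambda, -1e-6)
})
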