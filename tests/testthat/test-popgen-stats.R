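test_that("site diversity equals enumeration of all haplotype pairs", {
  expect_equal(sitePi(10, 10), 100 / 190)
  expect_equal(sitePi(19, 1), 19 / 190)
  expect_equal(sitePi(5, 0), 0)
  expect_error(sitePi(1, 0), "at least 2")
  set.seed(23)
  for (i in 1:20) {
    n1 <- sample(0:12, 1); n2 <- sample(1:12, 1)
    haps <- c(rep("A", n1), rep("C", n2))
    expect_equal(sitePi(n1, n2), piByEnumeration(haps))
  }
})

test_that("SNP classification uses the consensus codon and the stop rule", {
  expect_equal(classifySnp("GGA", 3, c("A", "G")), "SYN")     # Gly-Gly
  expect_equal(classifySnp("AAA", 1, c("A", "G")), "NONSYN")  # Lys-Glu
  expect_equal(classifySnp("TAC", 3, c("C", "A")), "EXCLUDED") # creates TAA
  expect_equal(classifySnp("NGA", 1, c("A", "G")), "EXCLUDED") # ambiguous
  expect_equal(classifySnp(NA, 1, c("A", "G")), "EXCLUDED")
})

test_that("site counting is Nei-Gojobori-style with stop exclusion", {
  codonCountsOracle <- function(codon) {
    ## independent enumeration of the 9 single-base changes
    code <- Biostrings::GENETIC_CODE
    ch <- strsplit(codon, "")[[1]]
    LS <- 0; LN <- 0
    for (pos in 1:3) {
      nSyn <- 0; nOk <- 0
      for (b in setdiff(c("A", "C", "G", "T"), ch[pos])) {
        mut <- ch; mut[pos] <- b
        mstr <- paste(mut, collapse = "")
        if (code[mstr] == "*") next
        nOk <- nOk + 1
        if (code[mstr] == code[codon]) nSyn <- nSyn + 1
      }
      if (nOk > 0) { LS <- LS + nSyn / nOk; LN <- LN + 1 - nSyn / nOk }
    }
    c(LS = LS, LN = LN)
  }
  ## GGG: third position fully synonymous
  aln <- makeAln(matrix(c("G", "G", "G"), 3, 4))
  expect_equal(synNonsynSiteCounts(aln), c(LS = 1, LN = 2))
  ## ATG: methionine has no synonym
  alnM <- makeAln(matrix(c("A", "T", "G"), 3, 4))
  expect_equal(synNonsynSiteCounts(alnM), c(LS = 0, LN = 3))
  ## additivity over 100 identical codons
  aln100 <- makeAln(matrix(rep(c("G", "G", "G"), 100), 300, 4))
  expect_equal(synNonsynSiteCounts(aln100)[["LS"]], 100)
  ## random codons against the enumeration oracle
  set.seed(29)
  for (i in 1:15) {
    cod <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                 collapse = "")
    if (cod %in% c("TAA", "TAG", "TGA")) next
    a <- makeAln(matrix(strsplit(cod, "")[[1]], 3, 4))
    expect_equal(synNonsynSiteCounts(a), codonCountsOracle(cod))
  }
  ## positions with missing data are excluded from the denominators
  hap <- matrix("G", 3, 4)
  hapNA <- hap; hapNA[3, 1] <- NA
  expect_equal(synNonsynSiteCounts(makeAln(hapNA)),
               c(LS = 0, LN = 2))
  expect_equal(synNonsynSiteCounts(makeAln(hapNA), completeOnly = FALSE),
               c(LS = 1, LN = 2))
})

test_that("contig diversity divides per-SNP pi by the class site counts", {
  ## 12 GGA codons, one synonymous SNP at the third position of codon 2
  hap <- matrix(rep(c("G", "G", "A"), 12), 36, 20)
  hap[6, 1:10] <- "G"                  # 10 G vs 10 A: site_pi = 100/190
  aln <- makeAln(hap)
  cs <- contigStats(aln)
  sc <- synNonsynSiteCounts(aln)
  expect_equal(cs$pS, 1L)
  expect_equal(cs$pN, 0L)
  expect_equal(cs$piS, (100 / 190) / sc[["LS"]])
  expect_equal(cs$piN, 0)
  expect_equal(cs$nSNPs, 1L)
  ## no SNPs at all
  cs0 <- contigStats(makeAln(matrix(rep(c("G", "G", "A"), 12), 36, 20)))
  expect_equal(c(cs0$piS, cs0$piN), c(0, 0))
})

test_that("FIS matches its defining fixtures and is ~0 under HWE", {
  ## 10 individuals all heterozygous: complete excess
  alnHet <- alnFromGenotypes(list(rep("AC", 10), rep("GG", 10),
                                  rep("AA", 10)))
  snpsHet <- alignmentSnps(alnHet)
  expect_equal(fisStat(snpsHet), -1)
  ## 5 hom ref + 5 hom alt: complete deficit
  alnHom <- alnFromGenotypes(list(c(rep("AA", 5), rep("CC", 5)),
                                  rep("GG", 10), rep("TT", 10)))
  expect_equal(fisStat(alignmentSnps(alnHom)), 1)
  ## HWE simulation: 500 SNPs, 10 individuals
  set.seed(37)
  gts <- replicate(501, {
    f <- runif(1, 0.15, 0.85)
    d <- rbinom(10, 2, f)
    c("AA", "AC", "CC")[d + 1]
  }, simplify = FALSE)
  aln <- alnFromGenotypes(gts)
  fis <- fisStat(alignmentSnps(aln), hexp = "unbiased")
  expect_lt(abs(fis), 0.05)
})

test_that("per-individual heterozygosity counts het calls only", {
  gt <- rbind(c("AC", "AA", NA),
              c("AA", "AG", NA),
              c("GG", "GG", NA))
  hz <- perIndividualHeterozygosity(makeCalls(gt))
  expect_equal(unname(hz), c(1 / 3, 1 / 3, NA))
  ## 2 het among 1000 non-missing
  gt2 <- matrix("AA", 1000, 1)
  gt2[1:2, 1] <- "AC"
  expect_equal(unname(perIndividualHeterozygosity(makeCalls(gt2))), 0.002)
})

test_that("fixed differences require focal monomorphism and an outgroup", {
  ## focal all GGA; outgroup GGG at codon 1 (syn 3rd pos), AAA->GAA-style
  ## change at codon 2 pos 1 (nonsyn)
  hap <- matrix(rep(c("G", "G", "A", "A", "A", "A"), 1), 6, 8)
  og <- c("G", "G", "G", "G", "A", "A")
  aln <- makeAln(hap, outgroup = og)
  fd <- fixedDifferences(aln)
  expect_equal(fd[["dScount"]], 1)
  expect_equal(fd[["dNcount"]], 1)
  ## a polymorphic focal site is not a fixed difference
  hap2 <- hap; hap2[3, 1] <- "G"
  fd2 <- fixedDifferences(makeAln(hap2, outgroup = og))
  expect_equal(fd2[["dScount"]], 0)
  expect_error(fixedDifferences(makeAln(hap)), "outgroup")
})

test_that("neutrality indices follow the McDonald-Kreitman arithmetic", {
  ni <- neutralityIndices(pN = 10, pS = 20, dN = 5, dS = 40)
  expect_equal(ni$NI, 4)
  expect_equal(ni$alpha, -3)
  ## neutral expectation: NI = 1, alpha = 0
  ni2 <- neutralityIndices(8, 16, 4, 8)
  expect_equal(ni2$NI, 1); expect_equal(ni2$alpha, 0)
  ## omega_a arithmetic on stated factors
  expect_equal(round(0.43 * 0.17, 4), 0.0731)
  ni3 <- neutralityIndices(0, 10, 2, 5)
  expect_equal(ni3$omegaA, (1 - 0) * 0.4)
  ## zero denominators give NA, not errors
  ni4 <- neutralityIndices(3, 0, 2, 5)
  expect_true(is.na(ni4$NI))
  ni5 <- neutralityIndices(3, 5, 2, 0)
  expect_true(is.na(ni5$NI))
  ## MAF cutoff can only reduce the polymorphism counts
  ni6 <- neutralityIndices(10, 20, 5, 40, pN02 = 4, pS02 = 16)
  expect_equal(ni6$NI02, (4 / 16) / (5 / 40))
  expect_equal(ni6$alpha02, 1 - ni6$NI02)
})

test_that("species summary weights by class site counts and bootstraps", {
  mk <- function(contig, LS, piS, LN = 100, piN = 0) {
    data.frame(contig = contig, length = 3 * LS, nHaplotypes = 20, LS = LS,
               LN = LN, piS = piS, piN = piN, FIS = 0, pS = 1, pN = 1,
               pS02 = 1, pN02 = 1, dScount = 4, dNcount = 2, dS = 0.04,
               dN = 0.02, nSNPs = 2, sumHobs = 0.5, sumHexp = 0.5)
  }
  stats <- rbind(mk("c1", 100, 0.01), mk("c2", 300, 0.02))
  s <- speciesSummary(stats, nBootstrap = 100, seed = 3)
  expect_equal(s$summary$meanPiS, 0.0175)
  ## identical contigs: zero-width intervals
  s2 <- speciesSummary(rbind(mk("c1", 100, 0.01), mk("c2", 100, 0.01)),
                       nBootstrap = 50, seed = 3)
  expect_equal(s2$ci$lower[s2$ci$statistic == "meanPiS"], 0.01)
  expect_equal(s2$ci$upper[s2$ci$statistic == "meanPiS"], 0.01)
  ## fixed seed: bit-reproducible intervals
  sA <- speciesSummary(stats, nBootstrap = 200, seed = 11)
  sB <- speciesSummary(stats, nBootstrap = 200, seed = 11)
  expect_identical(sA$ci, sB$ci)
  ## pooled-count NI across contigs
  expect_equal(s$summary$NI, (2 / 2) / (4 / 8))
})

test_that("length-weighted species pi equals pooled per-site pi", {
  set.seed(41)
  rows <- lapply(1:6, function(i) {
    LS <- sample(50:200, 1)
    piSum <- sum(runif(sample(0:3, 1), 0, 0.5))
    data.frame(LS = LS, piS = piSum / LS)
  })
  d <- do.call(rbind, rows)
  wmean <- sum(d$piS * d$LS) / sum(d$LS)
  pooled <- sum(d$piS * d$LS) / sum(d$LS)   # by construction identical
  expect_equal(wmean, pooled)
  ## and through speciesSummary
  stats <- data.frame(contig = paste0("c", 1:6), length = d$LS * 3,
                      nHaplotypes = 20, LS = d$LS, LN = 2 * d$LS,
                      piS = d$piS, piN = 0, FIS = 0, pS = 1, pN = 0,
                      pS02 = 1, pN02 = 0, dScount = NA, dNcount = NA,
                      dS = NA, dN = NA, nSNPs = 1, sumHobs = 0.1,
                      sumHexp = 0.1)
  s <- speciesSummary(stats, nBootstrap = 0)
  expect_equal(s$summary$meanPiS, wmean)
})

test_that("pairwise genetic distance matches draw enumeration", {
  ## both AC het at the single shared site: Hb = .5, Hw = 1 -> -0.5
  expect_equal(pairwiseGeneticDistance("AC", "AC"), -0.5)
  ## identical homozygotes everywhere: 0
  expect_equal(pairwiseGeneticDistance(c("AA", "GG"), c("AA", "GG")), 0)
  ## AA vs CC plus one shared het site: (0.75 - 0.5) / 0.5 = 0.5
  expect_equal(pairwiseGeneticDistance(c("AA", "AC"), c("CC", "AC")), 0.5)
  ## opposite homozygotes only: Hw = 0, Hb > 0 -> missing
  expect_true(is.na(pairwiseGeneticDistance("AA", "CC")))
  ## no shared sites -> missing
  expect_true(is.na(pairwiseGeneticDistance(NA_character_, "AC")))
  ## sites missing in one individual are skipped
  expect_equal(pairwiseGeneticDistance(c("AC", NA), c("AC", "GG")), -0.5)
  ## matrix wrapper is symmetric with zero diagonal
  gt <- rbind(c("AC", "AC", "AA"), c("GG", "GT", "GG"))
  D <- geneticDistanceMatrix(makeCalls(gt))
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 3))
})
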