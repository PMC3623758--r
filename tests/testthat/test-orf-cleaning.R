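test_that("longest ORF follows the ATG/stop conventions", {
  o <- longestOrf("ATGAAATAA")
  expect_equal(c(o$start, o$end), c(0L, 9L))

  ## no ATG, no stop: longest frame taken whole
  o2 <- longestOrf("CCCCCCCCC")
  expect_equal(c(o2$start, o2$end), c(0L, 9L))

  ## two equal-length candidates in different frames: leftmost wins
  o3 <- longestOrf("ATCATTTAAAGCAAGGGCCCTGTC")
  expect_equal(o3$start, 1L)
  expect_equal(o3$end, 22L)

  ## shorter than 3 codons: nothing
  expect_null(longestOrf("ATGTAA"))
  expect_error(longestOrf("AT"), "at least 3")
})

test_that("longest ORF agrees with brute-force enumeration", {
  bruteOrf <- function(s) {
    n <- nchar(s)
    ch <- strsplit(s, "")[[1]]
    best <- NULL
    for (fr in 0:2) {
      nc <- (n - fr) %/% 3
      if (nc < 1) next
      st <- fr + 3 * (seq_len(nc) - 1)
      cod <- substring(s, st + 1, st + 3)
      stopIdx <- which(cod %in% c("TAA", "TAG", "TGA"))
      bounds <- c(0, stopIdx, nc + 1)   # segment boundaries (exclusive)
      for (b in seq_len(length(bounds) - 1)) {
        lo <- bounds[b] + 1
        hi <- min(bounds[b + 1], nc)    # segment includes its stop codon
        if (lo > hi) next
        idx <- lo:hi
        atg <- idx[cod[idx] == "ATG"]
        from <- if (length(atg)) atg[1] else lo
        len <- (hi - from + 1) * 3
        if (len < 9) next
        cand <- c(st[from], st[hi] + 3)
        if (is.null(best) || len > best[2] - best[1] ||
            (len == best[2] - best[1] && cand[1] < best[1]))
          best <- cand
      }
    }
    best
  }
  set.seed(31)
  for (i in 1:40) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    o <- longestOrf(s)
    b <- bruteOrf(s)
    if (is.null(b)) expect_null(o)
    else expect_equal(c(o$start, o$end), b)
  }
})

test_that("codon alignment expands pseudo-haplotypes and masks codons", {
  gt <- rbind(c("AA", "AC"),
              c("GG", NA),
              c("TT", "TT"))
  calls <- makeCalls(gt)
  aln <- buildCodonAlignment(calls, list(start = 0L, end = 3L))
  hap <- aln@haplotypes
  ## individual 1: hom then het expansion, no missing data
  expect_equal(unname(hap[, 1]), c("A", "G", "T"))
  expect_equal(unname(hap[, 2]), c("A", "G", "T"))
  ## individual 2: het at row 1 gives one allele per pseudo-haplotype, but
  ## the missing genotype at row 2 blanks its whole codon (all three rows)
  expect_true(all(is.na(hap[, 3:4])))
  expect_false(anyNA(hap[, 1:2]))

  expect_error(buildCodonAlignment(calls, list(start = 0L, end = 6L)),
               "bounds")

  ## outgroup with a gap inside the ORF rejects the contig
  expect_null(buildCodonAlignment(calls, list(start = 0L, end = 3L),
                                  outgroupSeq = "A-G"))
  aln2 <- buildCodonAlignment(calls, list(start = 0L, end = 3L),
                              outgroupSeq = "ACG")
  expect_equal(aln2@outgroup, c("A", "C", "G"))
})

test_that("cleaning applies its steps in the documented order", {
  ## 4 individuals (8 haplotypes), 12 codon sites
  nC <- 12
  hap <- matrix("A", nC * 3, 8)
  ## codon sites 1-2: missing for >50% of haplotypes (5 of 8)
  hap[1:6, 1:5] <- NA
  ## individual 4 (cols 7-8): missing at 6 of the 10 remaining codons (60%)
  hap[7:24, 7:8] <- NA
  aln <- makeAln(hap)
  cleaned <- cleanAlignment(aln)
  expect_equal(nrow(cleaned@haplotypes) / 3, 10)       # 2 codon sites dropped
  expect_equal(ncol(cleaned@haplotypes), 6)            # individual 4 dropped

  ## exactly 50% missing is kept (strict 'above')
  hap2 <- matrix("C", 30, 8)
  hap2[1:3, 1:4] <- NA
  cl2 <- cleanAlignment(makeAln(hap2))
  expect_equal(nrow(cl2@haplotypes), 30)

  ## fewer than 10 codon sites after cleaning: alignment dropped
  hap3 <- matrix("G", 27, 4)
  expect_null(cleanAlignment(makeAln(hap3)))

  ## order dependence: the codon-site filter runs before the sequence
  ## filter. Haplotype 1 is missing at 12 of 22 codons (55%), but 10 of
  ## those codons are also missing for haplotypes 2 and 3 (75% missing) and
  ## are removed first, after which haplotype 1 is only 2/12 (17%) missing
  ## and survives. Filtering sequences first would have removed it.
  hap4 <- matrix("T", 66, 4)
  hap4[1:30, 1:3] <- NA                 # codons 1-10 missing for haps 1-3
  hap4[31:36, 1] <- NA                  # hap 1 also missing codons 11-12
  cl4 <- cleanAlignment(makeAln(hap4))
  expect_equal(nrow(cl4@haplotypes) / 3, 12)
  expect_equal(ncol(cl4@haplotypes), 4)
  ## the swapped order on the same fixture gives a different answer
  seqFirst <- colMeans(is.na(hap4[, , drop = FALSE])) > 0.5
  expect_true(seqFirst[1])

  ## with outgroup: ORF of 100 codons or fewer is rejected
  hap5 <- matrix("A", 300, 4)
  alnOg <- makeAln(hap5, outgroup = rep("A", 300))
  expect_null(cleanAlignment(alnOg))
  hap6 <- matrix("A", 303, 4)
  expect_s4_class(cleanAlignment(makeAln(hap6, outgroup = rep("A", 303))),
                  "CodonAlignment")
})

test_that("complete biallelic site selection is strict and order-invariant", {
  hap <- rbind(c("A", "A", "A", "A"),        # monomorphic complete
               c("A", "C", "A", "C"),        # biallelic complete
               c("A", "C", "G", "A"),        # triallelic
               c("A", "A", NA, "A"),         # missing
               c("C", "C", "C", "T"))        # biallelic complete
  aln <- makeAln(rbind(hap, "G"))            # pad to 6 rows (2 codons)
  sel <- completeBiallelicSites(aln)
  expect_equal(sel, c(1L, 2L, 5L, 6L))
  set.seed(17)
  perm <- sample(4)
  aln2 <- makeAln(rbind(hap, "G")[, perm])
  expect_equal(completeBiallelicSites(aln2), sel)
})

test_that("dS outlier filter discards contigs beyond median + 2 SD", {
  cs <- data.frame(contig = paste0("c", 1:4),
                   dS = c(0.05, 0.10, 0.10, 0.15))
  expect_equal(nrow(dsOutlierFilter(cs)), 4L)   # threshold 0.1816: none out

  cs2 <- rbind(cs, data.frame(contig = "c5", dS = 0.50))
  kept <- dsOutlierFilter(cs2)
  thr <- median(cs2$dS) + 2 * sd(cs2$dS)
  expect_true(all(kept$dS < thr))
  expect_false("c5" %in% kept$contig)

  ## equal dS everywhere: nothing discarded
  cs3 <- data.frame(contig = paste0("c", 1:5), dS = rep(0.2, 5))
  expect_equal(nrow(dsOutlierFilter(cs3)), 5L)

  ## fewer than 3 contigs: skipped with a warning
  expect_warning(out <- dsOutlierFilter(cs[1:2, ]), "skipped")
  expect_equal(nrow(out), 2L)
})
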