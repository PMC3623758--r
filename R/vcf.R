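## Minimal VCF 4.2 serialisation of called SNPs.

#' Write called SNPs to VCF
#'
#' Emits one VCF 4.2 record per SNP with 1-based positions on contig
#' coordinates, FORMAT `GT:DP`, missing genotypes as `./.`, INFO fields
#' `EPS` (the contig's estimated error rate) and `AF` (ML alternate-allele
#' frequency at the site), and FILTER `paralog` for SNPs flagged by the
#' paralogy test (`PASS` otherwise, `.` when untested).
#'
#' @param snps SNP table from [identifySnps()] (optionally carrying a
#'   `paralogFlag` logical column and `paralogTested` column from
#'   [applyParalogFilter()]).
#' @param callsList named list of [GenotypeCalls], one per contig.
#' @param path output file.
#' @param refList optional named list/vector of contig reference sequences
#'   (characters); when absent the major allele is written as REF.
#' @return invisibly, the path.
#' @export
writeSnpVcf <- function(snps, callsList, path, refList = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=rnapopgen",
    "##INFO=<ID=EPS,Number=1,Type=Float,Description=\"Per-contig ML error rate\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"ML alternate allele frequency\">",
    "##FILTER=<ID=paralog,Description=\"Likelihood-ratio test for hidden paralogy significant\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">"), con)
  inds <- if (length(callsList)) callsList[[1]]@individuals else character()
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", inds), collapse = "\t"), con)
  if (nrow(snps) == 0L) return(invisible(path))
  for (r in seq_len(nrow(snps))) {
    ctg <- snps$contig[r]
    calls <- callsList[[ctg]]
    s <- snps$site[r] + 1L
    ref <- if (!is.null(refList)) substr(as.character(refList[[ctg]]), s, s)
           else snps$allele1[r]
    gtRow <- calls@genotype[s, ]
    cnt <- colSums(GT_DOSAGE[gtRow[!is.na(gtRow)], , drop = FALSE])
    alts <- BASES[cnt > 0L & BASES != ref]
    alleles <- c(ref, alts)
    gtField <- vapply(gtRow, function(g) {
      if (is.na(g)) return("./.")
      a <- match(strsplit(g, "")[[1]], alleles) - 1L
      paste(sort(a), collapse = "/")
    }, "")
    dp <- calls@coverage[s, ]
    af <- calls@freqs[s, match(alts, BASES)]
    filt <- "."
    if (!is.null(snps$paralogTested) && isTRUE(snps$paralogTested[r]))
      filt <- if (isTRUE(snps$paralogFlag[r])) "paralog" else "PASS"
    writeLines(paste(c(
      ctg, s, ".", ref, paste(alts, collapse = ","), ".", filt,
      sprintf("EPS=%.6g;AF=%s", calls@epsilon,
              paste(sprintf("%.4g", af), collapse = ",")),
      "GT:DP", paste0(gtField, ":", dp)), collapse = "\t"), con)
  }
  invisible(path)
}
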