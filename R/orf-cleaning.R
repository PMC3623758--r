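## ORF handling, codon-alignment construction and cleaning filters.

STOP_CODONS <- c("TAA", "TAG", "TGA")

## translate one codon with the standard genetic code; NA if ambiguous
translateCodon <- function(codon) {
  if (is.na(codon) || !grepl("^[ACGT]{3}$", codon)) return(NA_character_)
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Find the longest open reading frame of a contig
#'
#' Scans the three forward frames (transcriptome contigs define the forward
#' strand). Within each frame, stop codons delimit segments; a candidate ORF
#' runs from the first ATG of a segment (or, as a documented fallback, from
#' the segment start when it contains no ATG) to the end of the segment,
#' including the terminating stop codon when present. The longest candidate
#' wins; ties are broken by leftmost start.
#'
#' @param sequence contig sequence (character or `DNAString`), length >= 3.
#' @return list with `start` and `end` (0-based half-open, length a multiple
#'   of 3), or `NULL` when no candidate reaches 3 codons.
#' @export
longestOrf <- function(sequence) {
  s <- toupper(as.character(sequence))
  n <- nchar(s)
  if (n < 3L) stop("sequence must be at least 3 bases")
  best <- NULL
  for (frame in 0:2) {
    nCodons <- (n - frame) %/% 3L
    if (nCodons < 1L) next
    starts <- frame + 3L * (seq_len(nCodons) - 1L)        # 0-based
    codons <- substring(s, starts + 1L, starts + 3L)
    isStop <- codons %in% STOP_CODONS
    seg <- cumsum(c(TRUE, utils::head(isStop, -1L)))       # segment index
    for (sg in unique(seg)) {
      idx <- which(seg == sg)
      atg <- idx[codons[idx] == "ATG"]
      from <- if (length(atg)) atg[1] else idx[1]
      to <- idx[length(idx)]                               # includes the stop
      len <- to - from + 1L
      if (len < 3L) next
      cand <- list(start = starts[from], end = starts[to] + 3L)
      candLen <- cand$end - cand$start
      if (is.null(best) || candLen > best$end - best$start ||
          (candLen == best$end - best$start && cand$start < best$start))
        best <- cand
    }
  }
  best
}

#' Read ORF annotations from BED or GFF3
#'
#' BED intervals are 0-based half-open; GFF3 is 1-based closed and is
#' converted. Import goes through `rtracklayer::import`.
#'
#' @param path annotation file.
#' @param format `"bed"` or `"gff3"` (guessed from the extension by default).
#' @return data.frame with columns contig, start, end (0-based half-open).
#' @export
readOrfAnnotations <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  gr <- rtracklayer::import(path, format = format)
  out <- data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  bad <- (out$end - out$start) %% 3L != 0L | out$end - out$start < 3L
  if (any(bad))
    stop("ORF annotations must span a positive multiple of 3: ",
         paste(out$contig[bad], collapse = ", "))
  out
}

#' Build the pseudo-haplotype codon alignment of one contig
#'
#' Restricts genotype calls to the ORF and expands each individual into two
#' pseudo-haplotypes: a homozygote contributes its base twice, a heterozygote
#' its two alleles in arbitrary order (every downstream statistic is
#' phase-free), and a missing genotype two missing states. Codons containing
#' any missing base are wholly missing. An optional outgroup sequence,
#' pre-aligned to contig coordinates, is carried alongside; alignment gaps or
#' other non-ACGT characters in the outgroup ORF cause rejection of the
#' contig (`NULL` is returned), mirroring the frameshift rule.
#'
#' @param calls a [GenotypeCalls].
#' @param orf list or one-row data.frame with 0-based half-open `start`,
#'   `end` (multiple of 3).
#' @param outgroupSeq optional outgroup sequence aligned to contig
#'   coordinates (character or `DNAString`, full contig length).
#' @return a [CodonAlignment], or `NULL` when the outgroup is rejected.
#' @export
buildCodonAlignment <- function(calls, orf, outgroupSeq = NULL) {
  S <- nrow(calls@genotype)
  if (orf$start < 0L || orf$end > S || (orf$end - orf$start) %% 3L != 0L)
    stop("ORF outside contig bounds or frame-inconsistent")
  rows <- (orf$start + 1L):orf$end
  gt <- calls@genotype[rows, , drop = FALSE]
  L <- length(rows)
  I <- length(calls@individuals)
  hap <- matrix(NA_character_, L, 2L * I)
  colnames(hap) <- paste0(rep(calls@individuals, each = 2L), "_",
                          rep(1:2, I))
  for (i in seq_len(I)) {
    g <- gt[, i]
    ok <- !is.na(g)
    hap[ok, 2L * i - 1L] <- substr(g[ok], 1L, 1L)
    hap[ok, 2L * i] <- substr(g[ok], 2L, 2L)
  }
  ## codon-level missing propagation
  codonOf <- rep(seq_len(L %/% 3L), each = 3L)
  for (h in seq_len(ncol(hap))) {
    missCodon <- unique(codonOf[is.na(hap[, h])])
    if (length(missCodon)) hap[codonOf %in% missCodon, h] <- NA_character_
  }
  outg <- character(0)
  if (!is.null(outgroupSeq)) {
    og <- strsplit(toupper(as.character(outgroupSeq)), "")[[1]]
    if (length(og) < orf$end) return(NULL)
    og <- og[rows]
    if (any(!og %in% BASES)) return(NULL)
    outg <- og
  }
  new("CodonAlignment", contig = calls@contig, haplotypes = hap,
      outgroup = outg, sitePos = as.integer(rows - 1L))
}

#' Clean a codon alignment
#'
#' Applies the cleaning filters in this exact order: (1) codon sites with a
#' proportion of missing focal haplotype states above 50% are discarded
#' (exactly 50% is kept); (2) focal haplotypes with a proportion of missing
#' data above 50% over the remaining codon sites are removed; (3) alignments
#' left with fewer than 10 codon sites are dropped. When an outgroup is
#' present, the contig is additionally required to have a predicted focal
#' ORF longer than 100 codons (checked on the alignment before cleaning).
#'
#' @param aln a [CodonAlignment].
#' @param minCodons minimum codon sites after cleaning (default 10).
#' @param minOrfCodonsWithOutgroup minimum pre-cleaning ORF length, in
#'   codons, for outgroup-bearing alignments (retained when strictly longer;
#'   default 100).
#' @return the cleaned [CodonAlignment], or `NULL` when dropped.
#' @export
cleanAlignment <- function(aln, minCodons = 10L,
                           minOrfCodonsWithOutgroup = 100L) {
  hap <- aln@haplotypes
  nCodon <- nrow(hap) %/% 3L
  if (length(aln@outgroup) && nCodon <= minOrfCodonsWithOutgroup)
    return(NULL)
  codonOf <- rep(seq_len(nCodon), each = 3L)
  ## codon x haplotype missingness (codon-level: any NA base)
  missing <- rowsum((is.na(hap)) * 1L, codonOf) > 0L
  keepCodon <- rowMeans(missing) <= 0.5
  if (!any(keepCodon)) return(NULL)
  keepRows <- codonOf %in% which(keepCodon)
  hap <- hap[keepRows, , drop = FALSE]
  missing <- missing[keepCodon, , drop = FALSE]
  keepHap <- colMeans(missing) <= 0.5
  hap <- hap[, keepHap, drop = FALSE]
  if (sum(keepCodon) < minCodons || ncol(hap) == 0L) return(NULL)
  new("CodonAlignment", contig = aln@contig, haplotypes = hap,
      outgroup = if (length(aln@outgroup)) aln@outgroup[keepRows]
                 else character(0),
      sitePos = aln@sitePos[keepRows])
}

#' Complete biallelic nucleotide sites of a cleaned alignment
#'
#' Returns the indices (rows of the alignment) of nucleotide sites with no
#' missing focal state and at most two distinct bases among focal
#' haplotypes. Monomorphic complete sites are included: they contribute to
#' the synonymous/non-synonymous site counts, not to the SNPs. Invariant
#' under haplotype reordering.
#'
#' @param aln a cleaned [CodonAlignment].
#' @return integer vector of row indices.
#' @export
completeBiallelicSites <- function(aln) {
  hap <- aln@haplotypes
  nAlleles <- apply(hap, 1L, function(x) length(unique(x[!is.na(x)])))
  which(rowSums(is.na(hap)) == 0L & nAlleles <= 2L)
}

#' Synonymous-divergence outlier filter
#'
#' Contigs with unusually high synonymous divergence to the outgroup are
#' dubious orthology assignments: those whose dS reaches the across-contig
#' median plus two standard deviations are discarded. With fewer than three
#' contigs carrying a dS value the filter is skipped with a warning.
#'
#' @param contigStats data.frame with columns `contig` and `dS`.
#' @return the retained subset of `contigStats`.
#' @export
dsOutlierFilter <- function(contigStats) {
  ds <- contigStats$dS
  have <- !is.na(ds)
  if (sum(have) < 3L) {
    warning("fewer than 3 contigs with dS; outlier filter skipped")
    return(contigStats)
  }
  thr <- stats::median(ds[have]) + 2 * stats::sd(ds[have])
  drop <- have & ds >= thr & stats::sd(ds[have]) > 0
  contigStats[!drop, , drop = FALSE]
}

#' Write a codon alignment as FASTA
#'
#' Haplotypes are named `<individual>_1`, `<individual>_2`; the outgroup, if
#' present, is written as `outgroup`. Missing states become `N`.
#'
#' @param aln a [CodonAlignment].
#' @param path output FASTA path.
#' @return invisibly, the path.
#' @export
writeAlignmentFasta <- function(aln, path) {
  hap <- aln@haplotypes
  hap[is.na(hap)] <- "N"
  seqs <- apply(hap, 2L, paste, collapse = "")
  if (length(aln@outgroup)) {
    og <- aln@outgroup
    og[is.na(og)] <- "N"
    seqs <- c(seqs, outgroup = paste(og, collapse = ""))
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
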