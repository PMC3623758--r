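## Shared fixture builders. Everything is generated in code; no data files.

## a ContigCounts object from a sites x individuals x 4 array
makeCounts <- function(arr, contig = "c1",
                       individuals = sprintf("ind%02d", seq_len(dim(arr)[2]))) {
  storage.mode(arr) <- "integer"
  dimnames(arr) <- list(NULL, individuals, c("A", "C", "G", "T"))
  new("ContigCounts", contig = contig, individuals = individuals,
      counts = arr)
}

## counts for a contig where every individual is homozygous for the
## given sequence, at uniform coverage, no errors
homCounts <- function(sequence, nInd = 4L, coverage = 20L, contig = "c1") {
  ch <- strsplit(sequence, "")[[1]]
  L <- length(ch)
  arr <- array(0L, dim = c(L, nInd, 4L))
  b <- match(ch, c("A", "C", "G", "T"))
  for (i in seq_len(nInd)) arr[cbind(seq_len(L), i, b)] <- coverage
  makeCounts(arr, contig = contig)
}

## a GenotypeCalls object straight from a genotype character matrix
makeCalls <- function(gt, contig = "c1", coverage = 20L, epsilon = 0.001) {
  gt <- as.matrix(gt)
  inds <- colnames(gt)
  if (is.null(inds)) inds <- sprintf("ind%02d", seq_len(ncol(gt)))
  colnames(gt) <- inds
  new("GenotypeCalls", contig = contig, individuals = inds, genotype = gt,
      posterior = matrix(1, nrow(gt), ncol(gt)),
      coverage = matrix(as.integer(coverage), nrow(gt), ncol(gt)),
      freqs = matrix(0.25, nrow(gt), 4L), epsilon = epsilon)
}

## a CodonAlignment from a haplotype matrix (rows = sites)
makeAln <- function(hap, contig = "c1", outgroup = character(0)) {
  hap <- as.matrix(hap)
  if (is.null(colnames(hap)))
    colnames(hap) <- paste0(rep(sprintf("ind%02d", seq_len(ncol(hap) / 2)),
                                each = 2), "_", rep(1:2, ncol(hap) / 2))
  new("CodonAlignment", contig = contig, haplotypes = hap,
      outgroup = outgroup, sitePos = seq_len(nrow(hap)) - 1L)
}

## expand per-individual genotypes (strings like "AC") at one site into
## haplotype rows; gts is a list of per-site genotype vectors
alnFromGenotypes <- function(gts, contig = "c1", outgroup = character(0)) {
  hap <- do.call(rbind, lapply(gts, function(g) {
    as.vector(rbind(substr(g, 1, 1), substr(g, 2, 2)))
  }))
  makeAln(hap, contig = contig, outgroup = outgroup)
}

## brute-force per-site pi by enumerating all haplotype pairs
piByEnumeration <- function(haps) {
  n <- length(haps)
  cnt <- 0L; tot <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    cnt <- cnt + (haps[i] != haps[j])
    tot <- tot + 1L
  }
  cnt / tot
}
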