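## Site-frequency spectra: hypergeometric projection, folding, Tajima's D.

#' Hypergeometric projection weights
#'
#' Probability that a SNP observed at allele count `i` among `m` sampled
#' haplotypes appears at count `j` in a random subsample of `n` haplotypes:
#' `w(j) = C(i, j) C(m - i, n - j) / C(m, n)` for `j = 0..n`. Computed in
#' log space so large `m` is safe; weights sum to 1.
#'
#' @param i observed allele count (0..m).
#' @param m sampled haplotypes at the SNP.
#' @param n target sample size, `n <= m`.
#' @return numeric vector of length `n + 1` (classes j = 0..n).
#' @export
projectionWeights <- function(i, m, n) {
  if (i < 0 || i > m) stop("need 0 <= i <= m")
  if (n > m) stop("cannot project into more sequences than sampled (n > m)")
  j <- 0:n
  w <- exp(lchoose(i, j) + lchoose(m - i, n - j) - lchoose(m, n))
  w[j > i | (n - j) > (m - i)] <- 0
  w
}

#' Project SNPs to a common sample size and fold
#'
#' Each SNP sampled in `m >= n` haplotypes distributes its unit mass over
#' subsample allele counts `j = 0..n` by hypergeometric projection; classes
#' `j` and `n - j` are merged into the minor class `min(j, n - j)`, the
#' monomorphic classes (0 and n) are dropped without renormalisation (the
#' SNP partially leaves the subsample), and SNPs sampled in fewer than `n`
#' haplotypes are discarded. Optionally the spectrum can be renormalised to
#' condition on segregation.
#'
#' @param snps data.frame with columns `minorCount` and `nHaplotypes`
#'   (as produced by [identifySnps()] or [alignmentSnps()]).
#' @param n projected haplotype count (study-scale default 12).
#' @param conditionOnSegregation renormalise each SNP's mass to sum to 1
#'   over the polymorphic classes (default FALSE).
#' @return a [FoldedSFS].
#' @export
projectAndFold <- function(snps, n = 12L, conditionOnSegregation = FALSE) {
  n <- as.integer(n)
  half <- n %/% 2L
  mass <- numeric(half)
  used <- 0L; disc <- 0L
  for (r in seq_len(nrow(snps))) {
    m <- snps$nHaplotypes[r]
    i <- snps$minorCount[r]
    if (is.na(m) || is.na(i)) next
    if (m < n) { disc <- disc + 1L; next }
    used <- used + 1L
    w <- projectionWeights(i, m, n)
    poly <- w[2:n]                              # classes 1..n-1
    if (conditionOnSegregation && sum(poly) > 0)
      poly <- poly / sum(poly)
    cls <- pmin(1:(n - 1L), n - (1:(n - 1L)))
    for (c in seq_len(half))
      mass[c] <- mass[c] + sum(poly[cls == c])
  }
  new("FoldedSFS", n = n, mass = mass, nUsed = used, nDiscarded = disc)
}

#' Fold an unfolded spectrum
#'
#' Merges derived-allele classes `k` and `n - k` into minor-allele classes
#' `1..floor(n/2)`; the central class of even `n` is not double-counted.
#' Folding preserves total mass and the pairwise diversity `theta_pi`.
#'
#' @param xi numeric vector of length `n - 1` (classes 1..n-1).
#' @param n haplotype count.
#' @return a [FoldedSFS].
#' @export
foldSfs <- function(xi, n) {
  n <- as.integer(n)
  stopifnot(length(xi) == n - 1L)
  half <- n %/% 2L
  cls <- pmin(1:(n - 1L), n - (1:(n - 1L)))
  mass <- vapply(seq_len(half), function(c) sum(xi[cls == c]), 0)
  new("FoldedSFS", n = n, mass = mass, nUsed = NA_integer_,
      nDiscarded = 0L)
}

## Tajima (1989) constants for sample size n
tajimaConstants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D from a (possibly fractional, possibly folded) spectrum
#'
#' `D = (theta_pi - theta_W) / sqrt(e1 S + e2 S (S - 1))` with the standard
#' constants from the sample size `n`; `theta_W = S / a1` with `S` the total
#' mass; `theta_pi` weights class `k` by `k (n - k) / C(n, 2)` (for a folded
#' spectrum the minor class `c` carries the same weight `c (n - c) / C(n,
#' 2)`, which the fold preserves). Fractional masses from projection are
#' allowed. `S = 0` returns `NA`; this index is zero for the neutral
#' Wright-Fisher spectrum `xi_k` proportional to `1/k`.
#'
#' @param sfs a [FoldedSFS], or a numeric unfolded spectrum of length
#'   `n - 1`.
#' @param n haplotype count (taken from the object for a [FoldedSFS]).
#' @return Tajima's D.
#' @export
tajimasD <- function(sfs, n = NULL) {
  if (is(sfs, "FoldedSFS")) {
    n <- sfs@n
    mass <- sfs@mass
    k <- seq_along(mass)
  } else {
    if (is.null(n)) stop("'n' required for a plain spectrum")
    stopifnot(length(sfs) == n - 1L)
    mass <- sfs
    k <- seq_len(n - 1L)
  }
  if (n < 4L) stop("Tajima's D needs n >= 4")
  S <- sum(mass)
  if (S <= 0) return(NA_real_)
  cst <- tajimaConstants(n)
  thetaPi <- sum(mass * k * (n - k)) / choose(n, 2)
  thetaW <- S / cst$a1
  (thetaPi - thetaW) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
}

#' Neutral Wright-Fisher expected spectrum
#'
#' Under the standard neutral model the expected number of SNPs at derived
#' allele count `k` is proportional to `1/k`: `xi_k = theta / k` for
#' `k = 1..n-1`.
#'
#' @param n haplotype count (>= 2).
#' @param theta scaled mutation rate.
#' @return numeric vector of length `n - 1`.
#' @export
neutralExpectedSfs <- function(n, theta) {
  stopifnot(n >= 2L, theta > 0)
  theta / seq_len(n - 1L)
}

#' Write a folded spectrum as TSV
#'
#' @param sfs a [FoldedSFS].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeSfsTable <- function(sfs, path) {
  utils::write.table(
    data.frame(class = seq_along(sfs@mass), mass = sfs@mass),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
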