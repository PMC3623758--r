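## Data model and I/O for read alignments and per-site base counts.
##
## Read alignment records are plain data.frames with columns
##   contig      contig identifier
##   start       0-based leftmost position on the contig
##   sequence    read bases over A/C/G/T/N (transcript strand; no indels)
##   individual  individual (library) identifier
## Coordinates are 0-based half-open everywhere inside the package; only the
## emitted VCF is 1-based.

#' Construct read alignment records
#'
#' Convenience constructor for the plain data.frame representation of mapped
#' reads used by [collapsePcrDuplicates()] and [recordsToCounts()].
#'
#' @param contig,start,sequence,individual vectors, recycled to a common
#'   length. `start` is 0-based.
#' @return a data.frame with columns contig, start, sequence, individual.
#' @export
readRecords <- function(contig, start, sequence, individual) {
  out <- data.frame(contig = as.character(contig), start = as.integer(start),
                    sequence = toupper(as.character(sequence)),
                    individual = as.character(individual),
                    stringsAsFactors = FALSE)
  if (any(out$start < 0L)) stop("read start positions must be >= 0")
  if (any(nchar(out$sequence) < 1L)) stop("read sequences must be non-empty")
  out
}

#' Collapse PCR duplicates
#'
#' Removes potential PCR duplicates by collapsing sets of identical reads
#' into a single read. Reads are identical when they agree on contig,
#' individual, mapping position and sequence; only the first occurrence is
#' retained, in input order. Duplicates are a within-library artifact, so the
#' individual identifier is part of the key.
#'
#' @param records data.frame of read alignment records (see [readRecords()]).
#' @param useSequence logical; when `FALSE`, collapse on mapping position
#'   alone (contig, individual, start). Default `TRUE`.
#' @return the deduplicated records, first occurrences in original order.
#' @export
collapsePcrDuplicates <- function(records, useSequence = TRUE) {
  if (nrow(records) == 0L) return(records)
  key <- if (useSequence)
    paste(records$contig, records$individual, records$start, records$sequence,
          sep = "\r")
  else
    paste(records$contig, records$individual, records$start, sep = "\r")
  out <- records[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tally read records into per-site base counts
#'
#' Builds one [ContigCounts] object per contig: `counts[s, i, b]` is the
#' number of retained reads of individual `i` covering site `s` (0-based)
#' with base `b`. N bases contribute to no count. A read extending past its
#' contig end is rejected with a message naming the offending record.
#'
#' @param records data.frame of (deduplicated) read alignment records.
#' @param contigLengths named integer vector, contig identifier -> length.
#' @param individuals optional character vector fixing individual order
#'   across contigs; defaults to sorted unique individuals in `records`.
#' @return named list of [ContigCounts], one per entry of `contigLengths`.
#' @export
recordsToCounts <- function(records, contigLengths, individuals = NULL) {
  if (is.null(names(contigLengths)) || anyNA(names(contigLengths)))
    stop("'contigLengths' must be a named vector")
  if (is.null(individuals))
    individuals <- sort(unique(records$individual))
  if (nrow(records)) {
    unknown <- setdiff(records$contig, names(contigLengths))
    if (length(unknown))
      stop("records reference unknown contigs: ",
           paste(unknown, collapse = ", "))
    ends <- records$start + nchar(records$sequence)
    bad <- which(ends > contigLengths[records$contig] | records$start < 0L)
    if (length(bad))
      stop(sprintf(
        "read exceeds contig bounds: contig=%s individual=%s start=%d len=%d",
        records$contig[bad[1]], records$individual[bad[1]],
        records$start[bad[1]], nchar(records$sequence[bad[1]])))
  }
  out <- vector("list", length(contigLengths))
  names(out) <- names(contigLengths)
  for (ctg in names(contigLengths)) {
    L <- contigLengths[[ctg]]
    if (L < 1L) stop("zero-length contig: ", ctg)
    counts <- array(0L, dim = c(L, length(individuals), 4L),
                    dimnames = list(NULL, individuals, BASES))
    rec <- records[records$contig == ctg, , drop = FALSE]
    if (nrow(rec)) {
      chars <- strsplit(rec$sequence, "")
      lens <- lengths(chars)
      site <- rep.int(rec$start, lens) + (sequence(lens) - 1L)
      base <- match(unlist(chars), BASES)            # N -> NA, dropped below
      ind <- match(rep.int(rec$individual, lens), individuals)
      keep <- !is.na(base) & !is.na(ind)
      idx <- cbind(site[keep] + 1L, ind[keep], base[keep])
      tab <- table(idx[, 1], idx[, 2], idx[, 3])
      if (length(tab)) {
        d1 <- as.integer(dimnames(tab)[[1]])
        d2 <- as.integer(dimnames(tab)[[2]])
        d3 <- as.integer(dimnames(tab)[[3]])
        counts[d1, d2, d3] <- counts[d1, d2, d3] + as.integer(tab)
      }
    }
    out[[ctg]] <- new("ContigCounts", contig = ctg, individuals = individuals,
                      counts = counts)
  }
  out
}

#' Read and write the count-table TSV
#'
#' The on-disk exchange format for base counts is a TSV with header
#' `contig<TAB>pos<TAB>individual<TAB>nA<TAB>nC<TAB>nG<TAB>nT` and one row
#' per (contig, 0-based position, individual) with coverage > 0. Sites with
#' zero coverage in every individual are implicit, so `readCountTable()`
#' accepts the contig lengths and individual roster explicitly; when omitted
#' they are inferred from the data (length = max position + 1).
#'
#' @param path file path.
#' @param contigLengths optional named integer vector of contig lengths.
#' @param individuals optional character vector fixing individual order.
#' @return `readCountTable()`: named list of [ContigCounts].
#'   `writeCountTable()`: invisibly, the path.
#' @export
readCountTable <- function(path, contigLengths = NULL, individuals = NULL) {
  lines <- readLines(path)
  header <- c("contig", "pos", "individual", "nA", "nC", "nG", "nT")
  if (length(lines) == 0L || !identical(strsplit(lines[1], "\t")[[1]], header))
    stop("count table must start with the header: ",
         paste(header, collapse = "\t"))
  if (length(lines) == 1L) {
    if (is.null(contigLengths)) return(list())
    return(recordsToCounts(readRecords(character(), integer(), character(),
                                       character())[0, ],
                           contigLengths, individuals))
  }
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 7L))
    stop("malformed count-table line ", which(nf != 7L)[1] + 1L)
  m <- matrix(unlist(fields), ncol = 7L, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  cnt <- suppressWarnings(matrix(as.integer(m[, 4:7]), ncol = 4L))
  bad <- which(is.na(pos) | rowSums(is.na(cnt)) > 0)
  if (length(bad))
    stop("malformed count-table line ", bad[1] + 1L)
  if (any(cnt < 0L))
    stop("negative count at line ", which(rowSums(cnt < 0L) > 0)[1] + 1L)
  if (any(pos < 0L))
    stop("negative position at line ", which(pos < 0L)[1] + 1L)
  df <- data.frame(contig = m[, 1], pos = pos, individual = m[, 3],
                   stringsAsFactors = FALSE)
  if (is.null(individuals)) individuals <- sort(unique(df$individual))
  if (is.null(contigLengths)) {
    contigLengths <- vapply(split(df$pos, df$contig), max, 0L) + 1L
  }
  out <- vector("list", length(contigLengths))
  names(out) <- names(contigLengths)
  for (ctg in names(contigLengths)) {
    L <- contigLengths[[ctg]]
    sel <- df$contig == ctg
    if (any(df$pos[sel] >= L))
      stop("position beyond contig length in contig ", ctg)
    counts <- array(0L, dim = c(L, length(individuals), 4L),
                    dimnames = list(NULL, individuals, BASES))
    if (any(sel)) {
      ind <- match(df$individual[sel], individuals)
      if (anyNA(ind)) stop("individual not in roster for contig ", ctg)
      for (b in 1:4)
        counts[cbind(df$pos[sel] + 1L, ind, b)] <-
          counts[cbind(df$pos[sel] + 1L, ind, b)] + cnt[sel, b]
    }
    out[[ctg]] <- new("ContigCounts", contig = ctg, individuals = individuals,
                      counts = counts)
  }
  out
}

#' @rdname readCountTable
#' @param countsList named list of [ContigCounts] to serialise.
#' @export
writeCountTable <- function(countsList, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("contig\tpos\tindividual\tnA\tnC\tnG\tnT", con)
  for (cc in countsList) {
    a <- cc@counts
    cov <- coverageMatrix(cc)
    idx <- which(cov > 0, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    rows <- sprintf("%s\t%d\t%s\t%d\t%d\t%d\t%d", cc@contig, idx[, 1] - 1L,
                    cc@individuals[idx[, 2]],
                    a[cbind(idx, 1L)], a[cbind(idx, 2L)],
                    a[cbind(idx, 3L)], a[cbind(idx, 4L)])
    writeLines(rows, con)
  }
  invisible(path)
}

#' Convert samtools text pileup to base counts
#'
#' Adapter from the 6-column samtools text pileup of one individual
#' (contig, 1-based position, reference base, depth, read bases, qualities)
#' to count-table rows. The read-base string is decoded in the usual way:
#' `.`/`,` count as the reference base, `ACGTacgt` as themselves, `^X` read
#' starts (the mapping-quality character is skipped), `$` read ends, `*` and
#' `#` deletion placeholders, `>`/`<` reference skips are ignored, and
#' `+n`/`-n` indel marks consume the following n bases without counting them.
#'
#' @param lines character vector of pileup lines (or a file read by the
#'   caller).
#' @param individual identifier recorded for every row.
#' @return data.frame with the count-table columns
#'   (contig, pos, individual, nA, nC, nG, nT); pos 0-based.
#' @export
pileupToCounts <- function(lines, individual) {
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 5L) stop("malformed pileup line ", i)
    ref <- toupper(f[3])
    out[[i]] <- c(contig = f[1], pos = as.integer(f[2]) - 1L,
                  decodePileupBases(f[5], ref))
  }
  n <- vapply(out, function(x) sum(as.integer(x[3:6])), 0L)
  df <- data.frame(
    contig = vapply(out, `[[`, "", 1),
    pos = as.integer(vapply(out, `[[`, "", 2)),
    individual = individual,
    nA = as.integer(vapply(out, `[[`, "", 3)),
    nC = as.integer(vapply(out, `[[`, "", 4)),
    nG = as.integer(vapply(out, `[[`, "", 5)),
    nT = as.integer(vapply(out, `[[`, "", 6)),
    stringsAsFactors = FALSE)
  df[n > 0L, , drop = FALSE]
}

## Decode one pileup base string into A/C/G/T counts.
decodePileupBases <- function(s, ref) {
  chars <- strsplit(s, "")[[1]]
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {           # read start: skip mapping-quality character
      i <- i + 2L
    } else if (ch == "$" || ch == "*" || ch == "#" || ch == ">" || ch == "<") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {   # indel: consume length then bases
      j <- i + 1L
      while (j <= n && chars[j] %in% as.character(0:9)) j <- j + 1L
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len
    } else {
      b <- toupper(ch)
      if (b == "." || b == ",") b <- ref
      if (b %in% BASES) counts[b] <- counts[b] + 1L
      i <- i + 1L
    }
  }
  counts
}

#' Coverage report and low-coverage contig filter
#'
#' Average coverage of a contig is the total length of mapped reads divided
#' by contig length, expressed per individual (here computed from base
#' counts, which equals mapped read length with N bases excluded). Contigs
#' with mean coverage per individual below the threshold are discarded; the
#' default 2.5X reproduces the pipeline's immediate coverage filter.
#'
#' @param countsList named list of [ContigCounts].
#' @param minMeanCoverage retention threshold in X per individual; contigs
#'   with mean coverage `>= minMeanCoverage` are retained.
#' @return a list with `retained` (the surviving [ContigCounts] list) and
#'   `report`, a data.frame with one row per input contig: contig, length,
#'   mean coverage per individual, retained flag, plus one column per
#'   individual with its mean coverage.
#' @export
filterLowCoverageContigs <- function(countsList, minMeanCoverage = 2.5) {
  if (length(countsList) == 0L)
    return(list(retained = countsList,
                report = data.frame(contig = character(),
                                    length = integer(),
                                    meanCoverage = numeric(),
                                    retained = logical())))
  reps <- lapply(countsList, function(cc) {
    L <- contigLength(cc)
    if (L == 0L) stop("zero-length contig: ", cc@contig)
    perInd <- colSums(coverageMatrix(cc)) / L
    data.frame(contig = cc@contig, length = L,
               meanCoverage = mean(perInd),
               retained = mean(perInd) >= minMeanCoverage,
               t(perInd), check.names = FALSE,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, reps)
  rownames(report) <- NULL
  list(retained = countsList[report$retained], report = report)
}

#' Read contig sequences from FASTA
#'
#' Thin wrapper over `Biostrings::readDNAStringSet` that uppercases the
#' sequences and keeps only the first word of each header as the contig
#' identifier.
#'
#' @param path FASTA file (wrapped or unwrapped).
#' @return a named `DNAStringSet`.
#' @export
readContigFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  Biostrings::DNAStringSet(toupper(x))
}
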