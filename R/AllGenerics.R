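#' Accessors for rnapopgen classes
#'
#' Small accessor family: `contigId()` returns the contig identifier,
#' `individualIds()` the ordered individuals, `countsArray()` the raw
#' sites x individuals x 4 base-count array, `coverageMatrix()` the per-site
#' per-individual read depth, `contigLength()` the number of sites,
#' `epsilonHat()` the estimated error rate, `genotypeMatrix()` the called
#' genotypes and `sfsMass()` the folded spectrum masses.
#'
#' @param x an rnapopgen object.
#' @return the slot contents described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("contigId", function(x) standardGeneric("contigId"))

#' @rdname accessors
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @rdname accessors
#' @export
setGeneric("countsArray", function(x) standardGeneric("countsArray"))

#' @rdname accessors
#' @export
setGeneric("coverageMatrix", function(x) standardGeneric("coverageMatrix"))

#' @rdname accessors
#' @export
setGeneric("contigLength", function(x) standardGeneric("contigLength"))

#' @rdname accessors
#' @export
setGeneric("epsilonHat", function(x) standardGeneric("epsilonHat"))

#' @rdname accessors
#' @export
setGeneric("genotypeMatrix", function(x) standardGeneric("genotypeMatrix"))

#' @rdname accessors
#' @export
setGeneric("sfsMass", function(x) standardGeneric("sfsMass"))

#' @rdname accessors
setMethod("contigId", "ContigCounts", function(x) x@contig)
#' @rdname accessors
setMethod("contigId", "GenotypeCalls", function(x) x@contig)
#' @rdname accessors
setMethod("contigId", "ErrorModel", function(x) x@contig)
#' @rdname accessors
setMethod("contigId", "CodonAlignment", function(x) x@contig)

#' @rdname accessors
setMethod("individualIds", "ContigCounts", function(x) x@individuals)
#' @rdname accessors
setMethod("individualIds", "GenotypeCalls", function(x) x@individuals)

#' @rdname accessors
setMethod("countsArray", "ContigCounts", function(x) x@counts)

#' @rdname accessors
setMethod("coverageMatrix", "ContigCounts", function(x) {
  m <- x@counts[, , 1L, drop = FALSE] + x@counts[, , 2L, drop = FALSE] +
    x@counts[, , 3L, drop = FALSE] + x@counts[, , 4L, drop = FALSE]
  dim(m) <- dim(x@counts)[1:2]
  colnames(m) <- x@individuals
  m
})
#' @rdname accessors
setMethod("coverageMatrix", "GenotypeCalls", function(x) x@coverage)

#' @rdname accessors
setMethod("contigLength", "ContigCounts", function(x) dim(x@counts)[1L])
#' @rdname accessors
setMethod("contigLength", "GenotypeCalls", function(x) nrow(x@genotype))

#' @rdname accessors
setMethod("epsilonHat", "ErrorModel", function(x) x@epsilon)
#' @rdname accessors
setMethod("epsilonHat", "GenotypeCalls", function(x) x@epsilon)

#' @rdname accessors
setMethod("genotypeMatrix", "GenotypeCalls", function(x) x@genotype)

#' @rdname accessors
setMethod("sfsMass", "FoldedSFS", function(x) x@mass)
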