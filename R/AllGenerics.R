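#' @importFrom BiocGenerics start end width
NULL

#' @rdname summarizeRepeats
#' @export
setGeneric("summarizeRepeats", function(x, ...)
  standardGeneric("summarizeRepeats"))

#' @rdname findRecombinogenicPairs
#' @export
setGeneric("findRecombinogenicPairs", function(x, ref, ...)
  standardGeneric("findRecombinogenicPairs"))

#' @rdname toHgvsG
#' @export
setGeneric("toHgvsG", function(x, ...) standardGeneric("toHgvsG"))

## ---- accessors -------------------------------------------------------

#' Accessors for RepeatTable objects
#'
#' \code{repeatFeatures} returns the feature \code{GRanges};
#' \code{repeatRegion} the analysed window.
#'
#' @param x a \code{\linkS4class{RepeatTable}}.
#' @return a \code{GRanges}.
#' @export
repeatFeatures <- function(x) {
  stopifnot(is(x, "RepeatTable"))
  x@features
}

#' @rdname repeatFeatures
#' @export
repeatRegion <- function(x) {
  stopifnot(is(x, "RepeatTable"))
  x@region
}

#' Accessors for DeletionCall objects
#'
#' \code{deletionRange} returns the canonical deleted interval
#' (\code{IRanges}); \code{deletionLength} its width in bp;
#' \code{microhomology} the breakpoint-overlap length; \code{ambiguityWindow}
#' the interval of equivalent deletion start positions; \code{hgvsG} the
#' genomic HGVS string; \code{refName} the reference record name.
#'
#' @param x a \code{\linkS4class{DeletionCall}}.
#' @export
deletionRange <- function(x) {
  stopifnot(is(x, "DeletionCall"))
  x@del
}

#' @rdname deletionRange
#' @export
deletionLength <- function(x) {
  stopifnot(is(x, "DeletionCall"))
  BiocGenerics::width(x@del)
}

#' @rdname deletionRange
#' @export
microhomology <- function(x) {
  stopifnot(is(x, "DeletionCall"))
  x@mhLen
}

#' @rdname deletionRange
#' @export
ambiguityWindow <- function(x) {
  stopifnot(is(x, "DeletionCall"))
  x@ambiguity
}

#' @rdname deletionRange
#' @export
hgvsG <- function(x) {
  stopifnot(is(x, "DeletionCall"))
  x@hgvsG
}

#' @rdname deletionRange
#' @export
refName <- function(x) {
  stopifnot(is(x, "DeletionCall"))
  x@refName
}

## ---- show methods ----------------------------------------------------

setMethod("show", "RepeatTable", function(object) {
  cat(sprintf("RepeatTable over %s:%d-%d (%d bp) with %d features\n",
              as.character(seqnames(object@region)),
              start(object@region), end(object@region),
              width(object@region), length(object@features)))
  if (length(object@features)) {
    fam <- table(mcols(object@features)$classFamily)
    cat("  classes:", paste(sprintf("%s (%d)", names(fam), fam),
                            collapse = ", "), "\n")
  }
})

setMethod("show", "RepeatSummary", function(object) {
  cat(sprintf("RepeatSummary of a %d bp region\n", object@regionLength))
  cat(sprintf("  interspersed: %d bp (%.2f%%)\n",
              object@interspersedBp, object@interspersedFraction))
  df <- object@byClass
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-16s %5d bp  %2d element(s)  %6.2f%%\n",
                df$class[i], df$coveredBp[i], df$elementCount[i],
                df$fraction[i]))
})

setMethod("show", "DeletionCall", function(object) {
  cat(sprintf("DeletionCall %s\n", object@hgvsG))
  cat(sprintf("  canonical: %d-%d (%d bp), microhomology %d bp\n",
              start(object@del), end(object@del), width(object@del),
              object@mhLen))
  cat(sprintf("  equivalent start placements: %d-%d (%d)\n",
              start(object@ambiguity), end(object@ambiguity),
              width(object@ambiguity)))
  if (nrow(object@mechanismHint))
    cat(sprintf("  mechanism hint: %s/%s pair, identity %.1f%%\n",
                object@mechanismHint$nameA[1], object@mechanismHint$nameB[1],
                object@mechanismHint$identity[1]))
})

setMethod("show", "ExonMap", function(object) {
  e <- object@exons
  cat(sprintf("ExonMap with %d exon(s), cDNA %d-%d\n",
              nrow(e), min(e$cStart), max(e$cEnd)))
})

setMethod("show", "Primer", function(object) {
  cat(sprintf("Primer %s (%s, %d nt, Ta %.0f C)\n", object@name,
              as.character(object@seq), length(object@seq),
              object@annealingTemp))
})

setMethod("show", "PrimerPair", function(object) {
  cat(sprintf("PrimerPair %s: %s / %s (expected wt %s bp, mut %s bp)\n",
              object@pairName, object@forward@name, object@reverse@name,
              ifelse(is.na(object@expectedWtSize), "-",
                     format(object@expectedWtSize)),
              ifelse(is.na(object@expectedMutSize), "-",
                     format(object@expectedMutSize))))
})

setMethod("show", "FounderReport", function(object) {
  cat(sprintf("FounderReport: %d/%d families support the top haplotype\n",
              object@familiesSupporting, object@familiesTotal))
  if (nrow(object@candidates)) {
    cat("  candidates:\n")
    for (i in seq_len(nrow(object@candidates)))
      cat(sprintf("    %s (%d families)\n", object@candidates$haplotype[i],
                  object@candidates$familiesSupporting[i]))
  } else cat("  no shared homozygous haplotype found\n")
})

setMethod("show", "SimulatedLocus", function(object) {
  cat(sprintf("SimulatedLocus: %d bp reference, %d planted repeats\n",
              length(object@reference), length(object@repeats@features)))
  cat(sprintf("  truth deletion: %d-%d (%d bp), microhomology %d bp\n",
              start(object@truth@del), end(object@truth@del),
              width(object@truth@del), object@truth@mhLen))
  cat(sprintf("  %d junction read(s), %d pedigree genotype rows\n",
              length(object@junctionReads), nrow(object@pedigree)))
})
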