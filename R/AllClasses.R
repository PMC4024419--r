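#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges ranges reduce
#' @importFrom GenomicRanges GRanges seqnames strand granges
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
NULL

#' Repeat annotation of a locus
#'
#' Container for a RepeatMasker-style repeat annotation of a single query
#' window: an ordered set of repeat features (as a \code{GRanges} whose
#' metadata columns carry the annotation fields) plus the analysed region.
#' Feature strand \code{-} corresponds to the \code{C} orientation token of
#' the file format.
#'
#' Metadata columns of \code{repeatFeatures()}: \code{swScore},
#' \code{pctDiv}, \code{pctDel}, \code{pctIns}, \code{repeatName},
#' \code{classFamily}, \code{repeatBegin}, \code{repeatEnd},
#' \code{repeatLeft}, \code{elementID}. \code{elementID} is the file's
#' linkage id: fragments of one interrupted element share an id and are
#' counted as a single element by \code{\link{summarizeRepeats}}.
#'
#' @slot region \code{GRanges} of length 1, the analysed query window
#'   (coordinates are 1-based inclusive, window-relative).
#' @slot features \code{GRanges} of repeat features, sorted by start.
#' @seealso \code{\link{parseRepeatMaskerOut}}, \code{\link{summarizeRepeats}},
#'   \code{\link{findRecombinogenicPairs}}
#' @exportClass RepeatTable
setClass("RepeatTable",
  representation(region = "GRanges", features = "GRanges"))

setValidity("RepeatTable", function(object) {
  msg <- NULL
  if (length(object@region) != 1L)
    msg <- c(msg, "'region' must be a GRanges of length 1")
  fts <- object@features
  need <- c("swScore", "pctDiv", "pctDel", "pctIns", "repeatName",
            "classFamily", "repeatBegin", "repeatEnd", "repeatLeft",
            "elementID")
  miss <- setdiff(need, colnames(mcols(fts)))
  if (length(miss))
    msg <- c(msg, paste0("missing feature columns: ",
                         paste(miss, collapse = ", ")))
  if (length(fts)) {
    if (any(BiocGenerics::start(fts) < BiocGenerics::start(object@region)) ||
        any(BiocGenerics::end(fts) > BiocGenerics::end(object@region)))
      msg <- c(msg, "all features must lie within 'region'")
    if (is.unsorted(BiocGenerics::start(fts)))
      msg <- c(msg, "features must be sorted by start")
    if (!length(miss) && any(mcols(fts)$elementID < 1L))
      msg <- c(msg, "elementID must be >= 1")
  }
  if (is.null(msg)) TRUE else msg
})

#' Repeat-landscape summary of a locus
#'
#' Per-class and per-family coverage of a repeat-annotated window, with
#' interspersed-repeat totals. Covered bases are counted once (overlapping
#' annotations merged per group before summing); element counts collapse
#' fragments sharing a linkage id. Interspersed coverage excludes the
#' \code{Simple_repeat} and \code{Low_complexity} classes.
#'
#' @slot regionLength integer, bp of the analysed window.
#' @slot byFamily data.frame: \code{classFamily}, \code{coveredBp},
#'   \code{elementCount}, \code{fraction} (percent, half-up to 2 decimals).
#' @slot byClass data.frame with the same columns aggregated by the class
#'   part (text before the first \code{/}).
#' @slot interspersedBp integer.
#' @slot interspersedFraction numeric percent.
#' @seealso \code{\link{summarizeRepeats}}
#' @exportClass RepeatSummary
setClass("RepeatSummary",
  representation(regionLength = "integer", byFamily = "data.frame",
                 byClass = "data.frame", interspersedBp = "integer",
                 interspersedFraction = "numeric"))

#' A mapped genomic deletion
#'
#' The result of mapping a deletion junction against its wild-type
#' reference: the canonical (most 3') placement, the deletion length, the
#' breakpoint microhomology length, and the window of equivalent
#' left-breakpoint placements. Removing any equivalent placement from the
#' reference yields the identical mutant sequence.
#'
#' @slot refName character, reference record name used in HGVS output.
#' @slot del \code{IRanges} of length 1: the canonical deleted interval
#'   (1-based inclusive reference coordinates).
#' @slot mhLen integer, microhomology (breakpoint overlap) length in bp;
#'   the deletion has \code{mhLen + 1} equivalent placements.
#' @slot ambiguity \code{IRanges} of length 1: the interval of equivalent
#'   deletion start positions (width \code{mhLen + 1}).
#' @slot hgvsG character, the genomic HGVS description of the canonical
#'   placement, e.g. \code{"REF:g.100_200del101"}.
#' @slot mechanismHint \code{DataFrame} (possibly empty) describing a
#'   repeat pair implicated as the recombination substrate.
#' @seealso \code{\link{mapDeletionJunction}}, \code{\link{microhomologyLength}}
#' @exportClass DeletionCall
setClass("DeletionCall",
  representation(refName = "character", del = "IRanges", mhLen = "integer",
                 ambiguity = "IRanges", hgvsG = "character",
                 mechanismHint = "DataFrame"))

setValidity("DeletionCall", function(object) {
  msg <- NULL
  if (length(object@del) != 1L) msg <- c(msg, "'del' must have length 1")
  if (length(object@ambiguity) != 1L)
    msg <- c(msg, "'ambiguity' must have length 1")
  if (length(object@del) == 1L && length(object@ambiguity) == 1L) {
    if (BiocGenerics::width(object@ambiguity) != object@mhLen + 1L)
      msg <- c(msg, "ambiguity width must equal mhLen + 1")
    s <- BiocGenerics::start(object@del)
    if (s < BiocGenerics::start(object@ambiguity) ||
        s > BiocGenerics::end(object@ambiguity))
      msg <- c(msg, "canonical start must lie inside the ambiguity window")
  }
  if (object@mhLen < 0L) msg <- c(msg, "mhLen must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Exon map of a transcript on its genomic reference
#'
#' Ordered exons with paired cDNA and genomic coordinates, used to resolve
#' cDNA-coordinate deletion descriptions (with signed intronic offsets) to
#' genomic spans. cDNA coordinates must be contiguous across exons and each
#' exon's cDNA and genomic widths must agree. Only plus-orientation maps
#' are supported (the cDNA runs left to right along the reference).
#'
#' @slot exons data.frame: \code{exon}, \code{cStart}, \code{cEnd},
#'   \code{gStart}, \code{gEnd} (all integer, 1-based inclusive).
#' @seealso \code{\link{cDeletionLength}}, \code{\link{parseHgvsC}}
#' @exportClass ExonMap
setClass("ExonMap", representation(exons = "data.frame"))

setValidity("ExonMap", function(object) {
  e <- object@exons
  msg <- NULL
  need <- c("exon", "cStart", "cEnd", "gStart", "gEnd")
  if (!all(need %in% names(e)))
    return(paste0("exons must have columns: ", paste(need, collapse = ", ")))
  if (nrow(e) == 0L) return("exon map must contain at least one exon")
  if (any(e$cEnd < e$cStart) || any(e$gEnd < e$gStart))
    msg <- c(msg, "exon ends must be >= starts")
  if (any((e$cEnd - e$cStart) != (e$gEnd - e$gStart)))
    msg <- c(msg, "cDNA and genomic widths must agree per exon")
  if (nrow(e) > 1L) {
    if (any(e$cStart[-1L] != e$cEnd[-nrow(e)] + 1L))
      msg <- c(msg, "cDNA coordinates must be contiguous across exons")
    if (any(e$gStart[-1L] <= e$gEnd[-nrow(e)]))
      msg <- c(msg, "exons must be non-overlapping and genomically ordered")
  }
  if (is.null(msg)) TRUE else msg
})

#' A PCR primer
#'
#' @slot name character.
#' @slot seq \code{DNAString}, 5' to 3'; alphabet A/C/G/T/N (N matches any
#'   template base during binding-site search).
#' @slot annealingTemp numeric, annealing temperature in degrees Celsius;
#'   carried as annotation only, never used thermodynamically.
#' @seealso \code{\link{primer}}, \code{\link{findBindingSites}}
#' @exportClass Primer
setClass("Primer",
  representation(name = "character", seq = "DNAString",
                 annealingTemp = "numeric"))

setValidity("Primer", function(object) {
  s <- as.character(object@seq)
  if (nchar(s) == 0L) return("primer sequence must be non-empty")
  if (grepl("[^ACGTN]", toupper(s)))
    return("primer alphabet is restricted to A/C/G/T/N")
  TRUE
})

#' A diagnostic primer pair
#'
#' @slot pairName character label of the pair.
#' @slot forward,reverse \code{Primer} objects (names must differ).
#' @slot expectedWtSize,expectedMutSize numeric expected product sizes in
#'   bp on the wild-type and deletion alleles (NA when not applicable);
#'   annotation only.
#' @seealso \code{\link{primerPair}}, \code{\link{predictAmplicons}}
#' @exportClass PrimerPair
setClass("PrimerPair",
  representation(pairName = "character", forward = "Primer",
                 reverse = "Primer", expectedWtSize = "numeric",
                 expectedMutSize = "numeric"))

setValidity("PrimerPair", function(object) {
  if (identical(object@forward@name, object@reverse@name))
    return("forward and reverse primer names must be distinct")
  TRUE
})

#' Founder-haplotype analysis report
#'
#' @slot profiles data.frame of per-individual, per-marker homozygosity
#'   statuses (see \code{\link{homozygosityProfile}}).
#' @slot candidates data.frame of candidate founder haplotypes
#'   (\code{haplotype} as dash-joined allele sizes, one column per marker,
#'   \code{familiesSupporting}).
#' @slot familiesTotal,familiesSupporting integer; \code{familiesSupporting}
#'   refers to the best-supported candidate (0 when none).
#' @seealso \code{\link{sharedHomozygousHaplotype}}
#' @exportClass FounderReport
setClass("FounderReport",
  representation(profiles = "data.frame", candidates = "data.frame",
                 familiesTotal = "integer", familiesSupporting = "integer"))

setValidity("FounderReport", function(object) {
  if (object@familiesSupporting > object@familiesTotal)
    return("familiesSupporting cannot exceed familiesTotal")
  TRUE
})

#' A fully ground-truthed synthetic locus
#'
#' Bundle emitted by \code{\link{simulateLocus}}: the repeat-laden
#' reference, its truth repeat annotation, the equal-crossover deletion
#' allele, the true deletion call, junction reads, pedigree genotypes and a
#' reproducible truth manifest.
#'
#' @slot config list, the \code{\link{simConfig}} used.
#' @slot reference \code{DNAString} wild-type reference.
#' @slot repeats \code{RepeatTable} truth annotation of planted repeats.
#' @slot deletedAllele \code{DNAString}, reference minus the truth interval.
#' @slot truth \code{DeletionCall}, the planted deletion (canonical
#'   placement, microhomology, ambiguity window).
#' @slot junctionReads \code{DNAStringSet}, mutant-allele fragments
#'   spanning the junction.
#' @slot pedigree data.frame of long-format microsatellite genotypes.
#' @slot manifest list of truth values, reproducible from (config, seed).
#' @seealso \code{\link{simulateLocus}}, \code{\link{writeSimulatedLocus}}
#' @exportClass SimulatedLocus
setClass("SimulatedLocus",
  representation(config = "list", reference = "DNAString",
                 repeats = "RepeatTable", deletedAllele = "DNAString",
                 truth = "DeletionCall", junctionReads = "DNAStringSet",
                 pedigree = "data.frame", manifest = "list"))

setValidity("SimulatedLocus", function(object) {
  if (length(object@deletedAllele) !=
      length(object@reference) - BiocGenerics::width(object@truth@del))
    return("deleted allele length must equal reference minus deletion length")
  TRUE
})
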