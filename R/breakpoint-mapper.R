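## Breakpoint mapper: junction-sequence deletion mapping, microhomology
## resolution, HGVS-style normalisation and coordinate arithmetic.

.asBases <- function(x) seqChars(x)

## Longest matching extension of `qry` against `ref` starting at ref
## position `at`, scanning forward. Non-ACGT characters terminate the
## extension; up to `maxMismatch` mismatches are tolerated before stopping
## (the extension ends just before the (maxMismatch+1)-th mismatch).
.extendMatch <- function(refB, qryB, at, maxMismatch = 0L) {
  n <- length(qryB)
  avail <- min(n, length(refB) - at + 1L)
  if (avail <= 0L) return(0L)
  rseg <- refB[at:(at + avail - 1L)]
  qseg <- qryB[seq_len(avail)]
  bad <- !(rseg %in% DNA_BASES4) | !(qseg %in% DNA_BASES4)
  mis <- which(rseg != qseg | bad)
  hardStop <- if (any(bad)) min(which(bad)) else avail + 1L
  if (length(mis) <= maxMismatch) {
    ext <- avail
  } else {
    ext <- mis[maxMismatch + 1L] - 1L
  }
  min(ext, hardStop - 1L)
}

## Find a unique anchor for one end of the junction: slides a k-mer window
## inward from the junction end until it occurs exactly once in the
## reference, then returns the implied reference position aligned with the
## junction's terminal base. `fromEnd` anchors the right end.
.findAnchor <- function(ref, jnB, k, fromEnd = FALSE, maxScan = 400L) {
  n <- length(jnB)
  if (n < k) stop("junction shorter than anchor k-mer")
  lastOffset <- min(maxScan, n - k)
  for (i in 0:lastOffset) {
    idx <- if (fromEnd) (n - k + 1L - i):(n - i) else (i + 1L):(i + k)
    pat <- paste(jnB[idx], collapse = "")
    if (grepl("[^ACGT]", pat)) next
    hits <- Biostrings::start(Biostrings::matchPattern(
      Biostrings::DNAString(pat), ref))
    if (length(hits) == 1L) {
      ## reference position aligned with junction position 1 (or n)
      aligned <- if (fromEnd) hits + k - 1L + i else hits - i
      return(aligned)
    }
  }
  stop("ambiguous mapping: no unique anchor k-mer found for the ",
       if (fromEnd) "right" else "left", " junction end")
}

#' Map a deletion from a junction sequence against the wild-type reference
#'
#' Given a mutant (junction) sequence that spans a single contiguous
#' deletion, anchors each junction end in the reference by a unique exact
#' k-mer seed, extends base-by-base identity inward from both anchors
#' (mirroring breakpoint determination as the last nucleotide of identity
#' between wild-type and mutant), and resolves the overlap of the two
#' extensions as the breakpoint microhomology. The reported placement is
#' the most-3' equivalent one (the HGVS convention); all equivalent
#' left-breakpoint placements are retained in the ambiguity window.
#'
#' By default extension is exact (it stops at the first mismatch), which is
#' appropriate for Sanger-consensus junctions. \code{maxMismatch > 0}
#' enables an error-tolerant mode in which up to that many mismatches are
#' absorbed per side before extension stops; tolerated mismatches can
#' lengthen the apparent extensions, so microhomology then reflects the
#' error-tolerant match, not literal sequence identity.
#'
#' @param ref wild-type reference (\code{DNAString} or character).
#' @param junction mutant sequence spanning the deletion with at least
#'   \code{anchorK} bp of deletion-free flank on each side.
#' @param anchorK anchor seed length (default 25).
#' @param refname reference record name used in the HGVS string.
#' @param maxMismatch mismatches tolerated per extension (default 0).
#' @return a \code{\linkS4class{DeletionCall}}.
#' @examples
#' mapDeletionJunction("AAAATTTTCCCC", "AAAACCCC", anchorK = 4,
#'                     refname = "toy")
#' @export
mapDeletionJunction <- function(ref, junction, anchorK = 25L,
                                refname = "ref", maxMismatch = 0L) {
  refB <- .asBases(ref)
  jnB <- .asBases(junction)
  n <- length(jnB)
  if (n < 2L * anchorK)
    stop("junction must provide at least anchorK bases of flank per side")
  refDNA <- Biostrings::DNAString(paste(refB, collapse = ""))
  pL <- .findAnchor(refDNA, jnB, anchorK, fromEnd = FALSE)
  q <- .findAnchor(refDNA, jnB, anchorK, fromEnd = TRUE)
  if (pL < 1L || q > length(refB))
    stop("ambiguous mapping: anchor alignment falls outside the reference")
  L <- .extendMatch(refB, jnB, pL, maxMismatch)
  R <- .extendMatch(rev(refB), rev(jnB), length(refB) - q + 1L, maxMismatch)
  delLen <- q - pL + 1L - n
  if (delLen == 0L && L == n)
    stop("no deletion detected: junction matches the reference contiguously")
  if (delLen <= 0L)
    stop("no deletion detected: anchors imply a non-positive deletion length")
  if (L + R < n)
    stop("junction inconsistent with a single contiguous deletion ",
         sprintf("(unexplained gap of %d bp at the junction)", n - L - R))
  mh <- L + R - n
  delStart <- pL + L                       # most-3' placement
  delEnd <- q - n + L
  amb <- IRanges(pL + (n - R), pL + L)     # all equivalent start placements
  new("DeletionCall", refName = refname,
      del = IRanges(delStart, delEnd), mhLen = as.integer(mh),
      ambiguity = amb,
      hgvsG = sprintf("%s:g.%d_%ddel%d", refname, delStart, delEnd, delLen),
      mechanismHint = DataFrame())
}

#' Breakpoint microhomology of a deletion
#'
#' Returns the total breakpoint-overlap length of a deletion interval: the
#' largest m such that the m bases immediately inside the deletion's 5' end
#' equal the m bases immediately following its 3' end, plus the symmetric
#' count on the left side. The deletion has \code{mh + 1} placements that
#' produce the same mutant sequence. Purely a function of the reference and
#' the interval.
#'
#' @param ref reference sequence (\code{DNAString} or character).
#' @param del deleted interval: an \code{IRanges} of length 1, or a
#'   2-vector \code{c(start, end)} (1-based inclusive).
#' @return integer microhomology length in bp.
#' @examples
#' microhomologyLength("AAGCTGCTTT", c(3, 5))  # deleting one "GCT" -> 3
#' @export
microhomologyLength <- function(ref, del) {
  refB <- .asBases(ref)
  d <- .asStartEnd(del)
  s <- d[1]; e <- d[2]
  if (s < 1L || e > length(refB) || s > e)
    stop("deletion interval out of bounds")
  r <- 0L
  while (s + r <= e && e + r + 1L <= length(refB) &&
         refB[s + r] == refB[e + r + 1L] && refB[s + r] %in% DNA_BASES4)
    r <- r + 1L
  l <- 0L
  while (s - l - 1L >= 1L && e - l >= s &&
         refB[s - l - 1L] == refB[e - l] && refB[e - l] %in% DNA_BASES4)
    l <- l + 1L
  as.integer(r + l)
}

.asStartEnd <- function(del) {
  if (is(del, "IRanges")) {
    stopifnot(length(del) == 1L)
    c(BiocGenerics::start(del), BiocGenerics::end(del))
  } else {
    stopifnot(length(del) == 2L)
    as.integer(del)
  }
}

#' Shift a deletion to its most-3' equivalent placement
#'
#' Slides the deleted interval rightward while the base entering the
#' deletion on the left equals the base leaving it on the right, i.e. while
#' the mutant sequence is unchanged. This is the normalisation rule used by
#' HGVS nomenclature for deletions. Idempotent.
#'
#' @inheritParams microhomologyLength
#' @return an \code{IRanges} of length 1: the normalised interval.
#' @export
normalize3Prime <- function(ref, del) {
  refB <- .asBases(ref)
  d <- .asStartEnd(del)
  s <- d[1]; e <- d[2]
  if (s < 1L || e > length(refB) || s > e)
    stop("deletion interval out of bounds")
  while (e + 1L <= length(refB) && refB[s] == refB[e + 1L] &&
         refB[s] %in% DNA_BASES4) {
    s <- s + 1L
    e <- e + 1L
  }
  IRanges(s, e)
}

#' Apply a deletion to a reference sequence
#'
#' @inheritParams microhomologyLength
#' @return character, the mutant sequence.
#' @export
deletedSequence <- function(ref, del) {
  refB <- .asBases(ref)
  d <- .asStartEnd(del)
  if (d[1] < 1L || d[2] > length(refB) || d[1] > d[2])
    stop("deletion interval out of bounds")
  paste(refB[-(d[1]:d[2])], collapse = "")
}

## ---- HGVS ------------------------------------------------------------

#' Format and parse genomic HGVS deletion descriptions
#'
#' \code{toHgvsG} renders a \code{\linkS4class{DeletionCall}} (or explicit
#' coordinates) as \code{"REF:g.<start>_<end>del<n>"}. \code{parseHgvsG}
#' parses such a string, computes the implied length
#' \code{end - start + 1}, and flags (without correcting) any mismatch with
#' a stated \code{del<n>} suffix. The two are mutual inverses on valid
#' strings.
#'
#' @param x a \code{DeletionCall} (for \code{toHgvsG}) or a character HGVS
#'   string (for \code{parseHgvsG}).
#' @param ... unused.
#' @return \code{parseHgvsG}: a list with \code{refName}, \code{start},
#'   \code{end} (1-based inclusive), \code{statedLength} (NA when no
#'   suffix), \code{impliedLength}, and logical \code{consistent}.
#' @examples
#' parseHgvsG("NG_009252.1:g.36847_40771del3925")
#' @rdname toHgvsG
#' @export
setMethod("toHgvsG", "DeletionCall", function(x, ...) x@hgvsG)

#' @rdname toHgvsG
#' @export
parseHgvsG <- function(x) {
  m <- regmatches(x, regexec(
    "^\\s*([A-Za-z0-9_.-]+):g\\.([0-9]+)_([0-9]+)del([0-9]*)\\s*$", x))[[1]]
  if (!length(m))
    stop(sprintf("not a valid genomic HGVS deletion description: '%s'", x))
  s <- as.integer(m[3]); e <- as.integer(m[4])
  if (s > e) stop(sprintf("HGVS start (%d) > end (%d)", s, e))
  stated <- if (nzchar(m[5])) as.integer(m[5]) else NA_integer_
  implied <- e - s + 1L
  list(refName = m[2], start = s, end = e, statedLength = stated,
       impliedLength = implied,
       consistent = is.na(stated) || stated == implied)
}

#' Parse a cDNA-coordinate deletion description with intronic offsets
#'
#' Handles descriptions of the form
#' \code{"[REF:]c.<pos1>[+/-off1]_<pos2>[+/-off2]del[<n>]"}, e.g. a whole
#' exon deleted together with parts of its flanking introns. Offsets are
#' signed intronic distances from the nearest exonic position; an absent
#' offset means the endpoint is exonic.
#'
#' @param x character description.
#' @return list with \code{refName} (possibly NA), \code{startExonPos},
#'   \code{startOffset}, \code{endExonPos}, \code{endOffset},
#'   \code{statedLength} (NA if absent).
#' @examples
#' parseHgvsC("c.1370-2567_1539+1188del3925")
#' @export
parseHgvsC <- function(x) {
  m <- regmatches(x, regexec(paste0(
    "^\\s*(?:([A-Za-z0-9_.-]+):)?c\\.([0-9]+)([+-][0-9]+)?",
    "_([0-9]+)([+-][0-9]+)?del([0-9]*)\\s*$"), x))[[1]]
  if (!length(m))
    stop(sprintf("not a valid cDNA deletion description: '%s'", x))
  list(refName = if (nzchar(m[2])) m[2] else NA_character_,
       startExonPos = as.integer(m[3]),
       startOffset = if (nzchar(m[4])) as.integer(m[4]) else 0L,
       endExonPos = as.integer(m[5]),
       endOffset = if (nzchar(m[6])) as.integer(m[6]) else 0L,
       statedLength = if (nzchar(m[7])) as.integer(m[7]) else NA_integer_)
}

#' Construct an exon map
#'
#' @param exon integer exon labels.
#' @param cStart,cEnd cDNA coordinates per exon (1-based inclusive,
#'   contiguous across exons).
#' @param gStart,gEnd genomic coordinates per exon (1-based inclusive).
#' @return an \code{\linkS4class{ExonMap}}.
#' @seealso \code{\link{cDeletionLength}}, \code{\link{readExonMap}}
#' @export
exonMap <- function(exon, cStart, cEnd, gStart, gEnd) {
  df <- data.frame(exon = as.integer(exon), cStart = as.integer(cStart),
                   cEnd = as.integer(cEnd), gStart = as.integer(gStart),
                   gEnd = as.integer(gEnd))
  df <- df[order(df$cStart), , drop = FALSE]
  rownames(df) <- NULL
  new("ExonMap", exons = df)
}

#' Read an exon map from a TSV file
#'
#' Expects columns \code{exon}, \code{cStart}, \code{cEnd}, \code{gStart},
#' \code{gEnd} (1-based inclusive).
#'
#' @param file path.
#' @return an \code{\linkS4class{ExonMap}}.
#' @export
readExonMap <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  exonMap(df$exon, df$cStart, df$cEnd, df$gStart, df$gEnd)
}

## Resolve a cDNA position + intronic offset to a genomic coordinate.
.resolveC <- function(pos, offset, map) {
  e <- map@exons
  hit <- which(e$cStart <= pos & pos <= e$cEnd)
  if (!length(hit))
    stop(sprintf("cDNA position %d is outside the transcript (c.%d-c.%d)",
                 pos, min(e$cStart), max(e$cEnd)))
  i <- hit[1]
  g <- e$gStart[i] + (pos - e$cStart[i])
  gt <- g + offset
  if (offset > 0L && i < nrow(e) && gt >= e$gStart[i + 1L])
    stop(sprintf("offset +%d from c.%d crosses into the next exon", offset, pos))
  if (offset < 0L && i > 1L && gt <= e$gEnd[i - 1L])
    stop(sprintf("offset %d from c.%d crosses into the previous exon",
                 offset, pos))
  gt
}

#' Genomic length of a cDNA-coordinate deletion
#'
#' Resolves both endpoints of a cDNA deletion description (exonic position
#' plus signed intronic offset) against an exon map and returns the implied
#' genomic span length. For a single fully deleted exon spanning c.s to c.e
#' with upstream offset u and downstream offset v this equals
#' \code{u + (e - s + 1) + v}.
#'
#' @param x a parsed cDNA description (list from \code{\link{parseHgvsC}})
#'   or a character description.
#' @param map an \code{\linkS4class{ExonMap}}.
#' @return integer genomic length in bp.
#' @examples
#' em <- exonMap(exon = 9:11,
#'               cStart = c(1, 1370, 1540), cEnd = c(1369, 1539, 2200),
#'               gStart = c(1, 3937, 5295), gEnd = c(1369, 4106, 5955))
#' cDeletionLength("c.1370-2567_1539+1188del3925", em)  # 3925
#' @export
cDeletionLength <- function(x, map) {
  stopifnot(is(map, "ExonMap"))
  d <- if (is.character(x)) parseHgvsC(x) else x
  gs <- .resolveC(d$startExonPos, d$startOffset, map)
  ge <- .resolveC(d$endExonPos, d$endOffset, map)
  len <- ge - gs + 1L
  if (len <= 0L)
    stop("cDNA endpoints imply a non-positive genomic deletion length")
  as.integer(len)
}

## ---- writers ---------------------------------------------------------

#' Write a DeletionCall as JSON
#'
#' @param call a \code{\linkS4class{DeletionCall}}.
#' @param file path.
#' @export
writeDeletionJson <- function(call, file) {
  stopifnot(is(call, "DeletionCall"))
  jsonlite::write_json(list(
    refName = call@refName,
    start = start(call@del), end = end(call@del),
    length = width(call@del), mhLen = call@mhLen,
    ambiguityStart = start(call@ambiguity),
    ambiguityEnd = end(call@ambiguity),
    hgvsG = call@hgvsG), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Write a DeletionCall as a minimal VCF 4.2 symbolic-deletion record
#'
#' POS is the base before the deletion (VCF convention for symbolic
#' alleles); INFO carries \code{SVTYPE=DEL}, \code{END}, \code{SVLEN} and
#' \code{HOMLEN} (the microhomology length), bit-exact with the JSON
#' output.
#'
#' @param call a \code{\linkS4class{DeletionCall}}.
#' @param file path.
#' @param ref optional reference sequence used to fill the REF base at POS
#'   (otherwise \code{N}).
#' @export
writeDeletionVcf <- function(call, file, ref = NULL) {
  stopifnot(is(call, "DeletionCall"))
  pos <- start(call@del) - 1L
  refBase <- "N"
  if (!is.null(ref) && pos >= 1L) refBase <- .asBases(ref)[pos]
  hdr <- c("##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of the deleted interval\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=HOMLEN,Number=1,Type=Integer,Description=\"Breakpoint microhomology length\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rec <- sprintf("%s\t%d\t.\t%s\t<DEL>\t.\t.\tSVTYPE=DEL;END=%d;SVLEN=-%d;HOMLEN=%d",
                 call@refName, pos, refBase, end(call@del), width(call@del),
                 call@mhLen)
  writeLines(c(hdr, rec), file)
  invisible(file)
}
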