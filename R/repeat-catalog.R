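## Repeat catalogue: RepeatMasker .out dialect I/O, landscape summary and
## nomination of recombinogenic repeat pairs.

.stripParens <- function(x) sub("^\\((.*)\\)$", "\\1", x)
.hasParens <- function(x) grepl("^\\(.*\\)$", x)

.SIMPLE_CLASSES <- c("Simple_repeat", "Low_complexity")

#' Parse a RepeatMasker-style .out table
#'
#' Reads the whitespace-delimited repeat-annotation dialect produced by
#' RepeatMasker (score, divergence/deletion/insertion percentages, query id
#' and 1-based inclusive query coordinates with the remaining-bases column
#' in parentheses, orientation \code{+}/\code{C}, repeat name, class/family,
#' repeat coordinates, linkage id). Header and blank lines are skipped.
#' Orientation \code{C} is stored as strand \code{-}; for \code{C} rows the
#' repeat coordinates are read in the file's parenthesised order
#' (\code{(left) end begin}).
#'
#' The analysed window length is recovered from the invariant
#' \code{query end + query left = region length}, so no side channel is
#' needed to interpret window-relative coordinates.
#'
#' @param file path to a .out-dialect file, or a character vector of lines.
#' @param regionName optional name for the analysed window; defaults to the
#'   query id of the first data row.
#' @return a \code{\linkS4class{RepeatTable}}.
#' @examples
#' out <- system.file("extdata", "polh_exon9_11_repeats.out",
#'                    package = "aludel")
#' rt <- parseRepeatMaskerOut(out)
#' rt
#' @export
parseRepeatMaskerOut <- function(file, regionName = NULL) {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file)
           else as.character(file)
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    tok <- strsplit(ln, "[ \t]+")[[1]]
    ## header lines: first token is not a number
    if (is.na(suppressWarnings(as.numeric(tok[1])))) next
    if (length(tok) < 15L)
      stop(sprintf("line %d: expected >= 15 whitespace-delimited fields, got %d",
                   i, length(tok)))
    num <- suppressWarnings(as.numeric(tok[c(1:4, 6:7)]))
    if (anyNA(num))
      stop(sprintf("line %d: non-numeric score/divergence/position field", i))
    qb <- as.integer(tok[6]); qe <- as.integer(tok[7])
    if (qe < qb)
      stop(sprintf("line %d: query end (%d) < query begin (%d)", i, qe, qb))
    qleft <- suppressWarnings(as.integer(.stripParens(tok[8])))
    if (is.na(qleft))
      stop(sprintf("line %d: malformed query-left field '%s'", i, tok[8]))
    ori <- tok[9]
    if (!ori %in% c("+", "C"))
      stop(sprintf("line %d: unknown orientation token '%s'", i, ori))
    rcoord <- tok[12:14]
    if (ori == "+") {
      rb <- rcoord[1]; re <- rcoord[2]; rl <- rcoord[3]
    } else {
      rl <- rcoord[1]; re <- rcoord[2]; rb <- rcoord[3]
    }
    rb <- suppressWarnings(as.integer(.stripParens(rb)))
    re <- suppressWarnings(as.integer(.stripParens(re)))
    rl <- suppressWarnings(as.integer(.stripParens(rl)))
    if (anyNA(c(rb, re, rl)))
      stop(sprintf("line %d: malformed repeat-coordinate fields", i))
    id <- suppressWarnings(as.integer(tok[15]))
    if (is.na(id) || id < 1L)
      stop(sprintf("line %d: malformed linkage id '%s'", i, tok[15]))
    rows[[length(rows) + 1L]] <- list(
      swScore = as.integer(tok[1]), pctDiv = as.numeric(tok[2]),
      pctDel = as.numeric(tok[3]), pctIns = as.numeric(tok[4]),
      queryId = tok[5], qBegin = qb, qEnd = qe, qLeft = qleft,
      strand = if (ori == "+") "+" else "-", repeatName = tok[10],
      classFamily = tok[11], repeatBegin = rb, repeatEnd = re,
      repeatLeft = rl, elementID = id)
  }
  if (!length(rows)) {
    region <- GRanges(regionName %||% "region", IRanges(1, 1), strand = "*")
    fts <- GRanges()
    mcols(fts) <- DataFrame(
      swScore = integer(), pctDiv = numeric(), pctDel = numeric(),
      pctIns = numeric(), repeatName = character(),
      classFamily = character(), repeatBegin = integer(),
      repeatEnd = integer(), repeatLeft = integer(), elementID = integer())
    return(new("RepeatTable", region = region, features = fts))
  }
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  regionLength <- max(df$qEnd + df$qLeft)
  seqId <- regionName %||% df$queryId[1]
  region <- GRanges(seqId, IRanges(1L, regionLength), strand = "*")
  o <- order(df$qBegin, df$qEnd)
  df <- df[o, , drop = FALSE]
  fts <- GRanges(seqId, IRanges(df$qBegin, df$qEnd), strand = df$strand)
  mcols(fts) <- DataFrame(
    swScore = df$swScore, pctDiv = df$pctDiv, pctDel = df$pctDel,
    pctIns = df$pctIns, repeatName = df$repeatName,
    classFamily = df$classFamily, repeatBegin = df$repeatBegin,
    repeatEnd = df$repeatEnd, repeatLeft = df$repeatLeft,
    elementID = df$elementID)
  new("RepeatTable", region = region, features = fts)
}

#' Write a RepeatTable in the .out dialect
#'
#' Inverse of \code{\link{parseRepeatMaskerOut}} on the supported dialect:
#' a table written here and re-parsed reproduces the original feature list.
#'
#' @param x a \code{\linkS4class{RepeatTable}}.
#' @param file output path.
#' @export
writeRepeatMaskerOut <- function(x, file) {
  stopifnot(is(x, "RepeatTable"))
  fts <- x@features
  m <- mcols(fts)
  hdr <- paste("score", "div.", "del.", "ins.", "query", "begin", "end",
               "(left)", "C+", "repeat", "class/family", "begin", "end",
               "(left)", "id", sep = "\t")
  regionLength <- width(x@region)
  lines <- character(length(fts))
  for (i in seq_along(fts)) {
    ori <- if (as.character(strand(fts))[i] == "+") "+" else "C"
    rc <- if (ori == "+")
      c(m$repeatBegin[i], m$repeatEnd[i], sprintf("(%d)", m$repeatLeft[i]))
    else
      c(sprintf("(%d)", m$repeatLeft[i]), m$repeatEnd[i], m$repeatBegin[i])
    lines[i] <- paste(m$swScore[i], m$pctDiv[i], m$pctDel[i], m$pctIns[i],
                      as.character(seqnames(fts))[i], start(fts)[i],
                      end(fts)[i],
                      sprintf("(%d)", regionLength - end(fts)[i]),
                      ori, m$repeatName[i], m$classFamily[i],
                      rc[1], rc[2], rc[3], m$elementID[i], sep = "\t")
  }
  writeLines(c(hdr, lines), file)
  invisible(file)
}

#' Summarise the repeat landscape of a locus
#'
#' Computes per-family and per-class covered bp (overlapping annotations
#' merged before counting, so no base is counted twice), distinct element
#' counts (fragments sharing a linkage id collapse to one element), and the
#' interspersed-repeat total, which excludes \code{Simple_repeat} and
#' \code{Low_complexity}. Fractions are percentages of the analysed window,
#' rounded half-up to two decimals for reporting.
#'
#' @param x a \code{\linkS4class{RepeatTable}}.
#' @param ... unused.
#' @return a \code{\linkS4class{RepeatSummary}}.
#' @examples
#' out <- system.file("extdata", "polh_exon9_11_repeats.out",
#'                    package = "aludel")
#' summarizeRepeats(parseRepeatMaskerOut(out))
#' @rdname summarizeRepeats
#' @export
setMethod("summarizeRepeats", "RepeatTable", function(x, ...) {
  fts <- x@features
  regionLength <- width(x@region)
  if (regionLength <= 0L) stop("region length must be > 0")
  if (length(fts) &&
      (any(start(fts) < start(x@region)) || any(end(fts) > end(x@region))))
    stop("feature outside region")
  m <- mcols(fts)
  groupCov <- function(key) {
    keys <- sort(unique(key))
    do.call(rbind, lapply(keys, function(k) {
      sel <- key == k
      cov <- sum(width(reduce(ranges(fts)[sel])))
      data.frame(group = k, coveredBp = as.integer(cov),
                 elementCount = length(unique(m$elementID[sel])),
                 fraction = roundHalfUp(100 * cov / regionLength, 2))
    }))
  }
  if (length(fts)) {
    byFamily <- groupCov(m$classFamily)
    names(byFamily)[1] <- "classFamily"
    byClass <- groupCov(sub("/.*$", "", m$classFamily))
    names(byClass)[1] <- "class"
    inter <- !(m$classFamily %in% .SIMPLE_CLASSES)
    interBp <- as.integer(sum(width(reduce(ranges(fts)[inter]))))
  } else {
    byFamily <- data.frame(classFamily = character(), coveredBp = integer(),
                           elementCount = integer(), fraction = numeric())
    byClass <- data.frame(class = character(), coveredBp = integer(),
                          elementCount = integer(), fraction = numeric())
    interBp <- 0L
  }
  new("RepeatSummary", regionLength = as.integer(regionLength),
      byFamily = byFamily, byClass = byClass, interspersedBp = interBp,
      interspersedFraction = roundHalfUp(100 * interBp / regionLength, 2))
})

#' Accessors for RepeatSummary objects
#'
#' @param x a \code{\linkS4class{RepeatSummary}}.
#' @export
repeatCoverageByFamily <- function(x) {
  stopifnot(is(x, "RepeatSummary"))
  x@byFamily
}

#' @rdname repeatCoverageByFamily
#' @export
repeatCoverageByClass <- function(x) {
  stopifnot(is(x, "RepeatSummary"))
  x@byClass
}

#' @rdname repeatCoverageByFamily
#' @export
interspersedBp <- function(x) {
  stopifnot(is(x, "RepeatSummary"))
  x@interspersedBp
}

#' @rdname repeatCoverageByFamily
#' @export
interspersedFraction <- function(x) {
  stopifnot(is(x, "RepeatSummary"))
  x@interspersedFraction
}

#' Nominate same-family, same-orientation repeat pairs as deletion substrates
#'
#' Non-allelic homologous recombination between two interspersed repeats
#' requires the copies to be co-oriented and highly similar. This scans all
#' ordered repeat pairs of a table, keeps those with matching subfamily name
#' (or class/family when \code{sameFamilyOnly = FALSE}) and strand, computes
#' percent identity by global pairwise alignment of the two repeat
#' subsequences (identity = matches / alignment columns), and ranks
#' candidates by identity (descending), breaking ties by smaller
#' inter-repeat distance.
#'
#' The predicted deletion range brackets the sizes an equal crossover
#' between the two copies can produce: minimum \code{start(b) - end(a)},
#' maximum \code{end(b) - start(a)}.
#'
#' @param x a \code{\linkS4class{RepeatTable}}.
#' @param ref the region sequence (\code{DNAString} or character); its
#'   length must equal the region length of \code{x}.
#' @param minIdentity minimum percent identity to report (default 80).
#' @param sameFamilyOnly if TRUE (default), require exact subfamily-name
#'   match; otherwise match at the class/family level.
#' @param ... unused.
#' @return a \code{DataFrame} of ranked pairs with columns \code{nameA},
#'   \code{startA}, \code{endA}, \code{nameB}, \code{startB}, \code{endB},
#'   \code{strand}, \code{identity}, \code{interRepeatDistance},
#'   \code{delMin}, \code{delMax}.
#' @rdname findRecombinogenicPairs
#' @export
setMethod("findRecombinogenicPairs", "RepeatTable",
function(x, ref, minIdentity = 80, sameFamilyOnly = TRUE, ...) {
  fts <- x@features
  if (!length(fts)) stop("repeat table is empty")
  ref <- if (is(ref, "DNAString")) ref else DNAString(toupper(as.character(ref)))
  if (length(ref) != width(x@region))
    stop(sprintf("reference length (%d) does not match region length (%d)",
                 length(ref), width(x@region)))
  m <- mcols(fts)
  key <- if (sameFamilyOnly) m$repeatName else m$classFamily
  str <- as.character(strand(fts))
  res <- list()
  n <- length(fts)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      if (key[i] != key[j] || str[i] != str[j]) next
      sa <- Biostrings::subseq(ref, start(fts)[i], end(fts)[i])
      sb <- Biostrings::subseq(ref, start(fts)[j], end(fts)[j])
      aln <- Biostrings::pairwiseAlignment(sa, sb, type = "global")
      cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
      ident <- 100 * Biostrings::nmatch(aln) / cols
      if (ident < minIdentity) next
      res[[length(res) + 1L]] <- data.frame(
        nameA = m$repeatName[i], startA = start(fts)[i], endA = end(fts)[i],
        nameB = m$repeatName[j], startB = start(fts)[j], endB = end(fts)[j],
        strand = str[i], identity = ident,
        interRepeatDistance = start(fts)[j] - end(fts)[i] - 1L,
        delMin = start(fts)[j] - end(fts)[i],
        delMax = end(fts)[j] - start(fts)[i])
    }
  }
  if (!length(res))
    return(DataFrame(nameA = character(), startA = integer(),
                     endA = integer(), nameB = character(),
                     startB = integer(), endB = integer(),
                     strand = character(), identity = numeric(),
                     interRepeatDistance = integer(), delMin = integer(),
                     delMax = integer()))
  df <- do.call(rbind, res)
  df <- df[order(-df$identity, df$interRepeatDistance,
                 df$startA, df$startB), , drop = FALSE]
  rownames(df) <- NULL
  DataFrame(df)
})

#' Export repeat features as BED6
#'
#' BED uses 0-based half-open coordinates; the conversion happens here at
#' the boundary. Scores are capped at 1000 per the BED specification.
#'
#' @param x a \code{\linkS4class{RepeatTable}}.
#' @param file output path.
#' @export
exportRepeatsBed <- function(x, file) {
  stopifnot(is(x, "RepeatTable"))
  fts <- x@features
  m <- mcols(fts)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   as.character(seqnames(fts)), start(fts) - 1L, end(fts),
                   m$repeatName, pmin(m$swScore, 1000L),
                   as.character(strand(fts)))
  writeLines(lines, file)
  invisible(file)
}

#' Write a repeat summary as TSV and/or JSON
#'
#' @param x a \code{\linkS4class{RepeatSummary}}.
#' @param tsv,json output paths (either may be NULL).
#' @export
writeRepeatSummary <- function(x, tsv = NULL, json = NULL) {
  stopifnot(is(x, "RepeatSummary"))
  if (!is.null(tsv)) {
    df <- x@byFamily
    df$scope <- "family"
    dc <- x@byClass
    names(dc)[1] <- "classFamily"
    dc$scope <- "class"
    tot <- data.frame(classFamily = "Interspersed_total",
                      coveredBp = x@interspersedBp, elementCount = NA_integer_,
                      fraction = x@interspersedFraction, scope = "total")
    utils::write.table(rbind(df, dc, tot), tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(list(
      regionLength = x@regionLength,
      byFamily = x@byFamily, byClass = x@byClass,
      interspersedBp = x@interspersedBp,
      interspersedFraction = x@interspersedFraction),
      json, auto_unbox = TRUE, digits = NA)
  }
  invisible(x)
}

#' Write nominated repeat pairs as TSV (1-based inclusive coordinates)
#'
#' @param pairs result of \code{\link{findRecombinogenicPairs}}.
#' @param file output path.
#' @export
writeRepeatPairs <- function(pairs, file) {
  utils::write.table(as.data.frame(pairs), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
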