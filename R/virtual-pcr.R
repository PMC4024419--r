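## Virtual PCR: primer binding-site search, amplicon prediction and the
## two-reaction presence/absence diagnostic genotype call.

#' Construct a primer
#'
#' @param name primer name.
#' @param seq nucleotide sequence 5' to 3' (A/C/G/T/N; N matches any
#'   template base).
#' @param annealingTemp annealing temperature in degrees C (annotation
#'   only; no thermodynamic model is applied).
#' @return a \code{\linkS4class{Primer}}.
#' @export
primer <- function(name, seq, annealingTemp = NA_real_) {
  new("Primer", name = as.character(name),
      seq = DNAString(toupper(as.character(seq))),
      annealingTemp = as.numeric(annealingTemp))
}

#' Construct a primer pair
#'
#' @param forward,reverse \code{\linkS4class{Primer}} objects or sequences.
#' @param pairName label; defaults to "fwd/rev" names.
#' @param expectedWtSize,expectedMutSize annotated expected product sizes
#'   in bp (NA when unknown).
#' @return a \code{\linkS4class{PrimerPair}}.
#' @export
primerPair <- function(forward, reverse, pairName = NULL,
                       expectedWtSize = NA_real_,
                       expectedMutSize = NA_real_) {
  if (!is(forward, "Primer")) forward <- primer("fwd", forward)
  if (!is(reverse, "Primer")) reverse <- primer("rev", reverse)
  new("PrimerPair",
      pairName = pairName %||% paste0(forward@name, "/", reverse@name),
      forward = forward, reverse = reverse,
      expectedWtSize = as.numeric(expectedWtSize),
      expectedMutSize = as.numeric(expectedMutSize))
}

#' Read a primer panel from TSV
#'
#' Expects columns \code{pair}, \code{fwd_name}, \code{fwd_seq},
#' \code{rev_name}, \code{rev_seq}, \code{annealing_c},
#' \code{expected_wt_bp}, \code{expected_mut_bp} (the last two may be NA).
#' The packaged diagnostic panel for the polymerase-eta exon-10 deletion
#' ships at \code{system.file("extdata", "polh_primer_panel.tsv",
#' package = "aludel")}.
#'
#' @param file path.
#' @return named list of \code{\linkS4class{PrimerPair}} objects.
#' @export
readPrimerPanel <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  pairs <- lapply(seq_len(nrow(df)), function(i) {
    primerPair(
      primer(df$fwd_name[i], df$fwd_seq[i], df$annealing_c[i]),
      primer(df$rev_name[i], df$rev_seq[i], df$annealing_c[i]),
      pairName = df$pair[i],
      expectedWtSize = df$expected_wt_bp[i],
      expectedMutSize = df$expected_mut_bp[i])
  })
  names(pairs) <- df$pair
  pairs
}

## N-aware mismatch positions of a primer laid over a template window
## (both character vectors of equal length; N in the primer matches any).
.primerMismatches <- function(primerB, windowB) {
  which(primerB != windowB & primerB != "N")
}

#' Find primer binding sites on both strands of a template
#'
#' Scans the template for matches of the primer (plus strand) and of its
#' reverse complement (minus strand), allowing up to \code{maxMismatch}
#' mismatches overall but requiring the \code{exact3Prime} 3'-terminal
#' primer bases to match exactly (mispriming at the 3' end prevents
#' extension). \code{N} in the primer matches any template base.
#'
#' @param template template sequence (\code{DNAString} or character).
#' @param prm a \code{\linkS4class{Primer}} (or sequence).
#' @param maxMismatch mismatch budget (default 0).
#' @param exact3Prime number of 3'-terminal bases that must match exactly
#'   (default 5).
#' @param templateId label recorded in the output.
#' @return data.frame: \code{templateId}, \code{primer}, \code{start},
#'   \code{end} (plus-strand 1-based inclusive footprint), \code{strand},
#'   \code{mismatches}. A primer longer than the template yields zero rows.
#' @export
findBindingSites <- function(template, prm, maxMismatch = 0L,
                             exact3Prime = 5L, templateId = "template") {
  if (!is(prm, "Primer")) prm <- primer("primer", prm)
  tmplB <- seqChars(template)
  plen <- length(prm@seq)
  empty <- data.frame(templateId = character(), primer = character(),
                      start = integer(), end = integer(),
                      strand = character(), mismatches = integer())
  if (plen > length(tmplB)) return(empty)
  tmpl <- DNAString(paste(tmplB, collapse = ""))
  e3 <- min(exact3Prime, plen)
  scanStrand <- function(patt, strandChar) {
    hits <- Biostrings::matchPattern(patt, tmpl, max.mismatch = maxMismatch,
                                     fixed = "subject")
    if (!length(hits)) return(empty)
    pB <- seqChars(patt)
    out <- lapply(seq_along(hits), function(h) {
      s <- BiocGenerics::start(hits)[h]
      w <- tmplB[s:(s + plen - 1L)]
      mis <- .primerMismatches(pB, w)
      if (length(mis) > maxMismatch) return(NULL)
      ## primer 3' terminus: last bases on '+', first bases of the
      ## plus-strand footprint on '-'
      window3 <- if (strandChar == "+") (plen - e3 + 1L):plen else 1:e3
      if (any(mis %in% window3)) return(NULL)
      data.frame(templateId = templateId, primer = prm@name, start = s,
                 end = s + plen - 1L, strand = strandChar,
                 mismatches = length(mis))
    })
    out <- out[!vapply(out, is.null, logical(1))]
    if (!length(out)) empty else do.call(rbind, out)
  }
  plus <- scanStrand(prm@seq, "+")
  minus <- scanStrand(reverseComplement(prm@seq), "-")
  res <- rbind(plus, minus)
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Predict PCR products of a primer pair on a template
#'
#' Enumerates every combination of a plus-strand forward-primer site and a
#' minus-strand reverse-primer site in which the forward footprint lies
#' upstream of the reverse footprint (both edges ordered, so the rule is
#' invariant under strand mirroring), and reports the product
#' spanning the first base of the forward footprint through the last base
#' of the reverse footprint, inclusive of both primer footprints. The
#' \code{detectable} flag marks products no longer than
#' \code{maxProductLen}, modelling the reach of the polymerase/extension
#' protocol (about 2 kb for standard PCR; raise it, e.g. to 12000, for
#' long-range mode). Multiple products are reported, not errored.
#'
#' @param template template sequence.
#' @param pair a \code{\linkS4class{PrimerPair}}.
#' @param maxProductLen detectability threshold in bp (default 2000).
#' @param maxMismatch,exact3Prime passed to \code{\link{findBindingSites}}.
#' @param templateId label recorded in the output.
#' @return data.frame: \code{pair}, \code{templateId}, \code{start},
#'   \code{end}, \code{size}, \code{detectable}, \code{fwdMismatches},
#'   \code{revMismatches}. Zero rows when no compatible site pair exists.
#' @export
predictAmplicons <- function(template, pair, maxProductLen = 2000L,
                             maxMismatch = 0L, exact3Prime = 5L,
                             templateId = "template") {
  stopifnot(is(pair, "PrimerPair"))
  fwd <- findBindingSites(template, pair@forward, maxMismatch, exact3Prime,
                          templateId)
  rev <- findBindingSites(template, pair@reverse, maxMismatch, exact3Prime,
                          templateId)
  fwd <- fwd[fwd$strand == "+", , drop = FALSE]
  rev <- rev[rev$strand == "-", , drop = FALSE]
  empty <- data.frame(pair = character(), templateId = character(),
                      start = integer(), end = integer(), size = integer(),
                      detectable = logical(), fwdMismatches = integer(),
                      revMismatches = integer())
  if (!nrow(fwd) || !nrow(rev)) return(empty)
  out <- list()
  for (i in seq_len(nrow(fwd))) for (j in seq_len(nrow(rev))) {
    ## reverse site's 3' end is the left edge of its plus-strand footprint;
    ## requiring both edges ordered keeps the rule strand-symmetric
    if (fwd$start[i] > rev$start[j] || fwd$end[i] > rev$end[j]) next
    size <- rev$end[j] - fwd$start[i] + 1L
    out[[length(out) + 1L]] <- data.frame(
      pair = pair@pairName, templateId = templateId,
      start = fwd$start[i], end = rev$end[j], size = size,
      detectable = size <= maxProductLen,
      fwdMismatches = fwd$mismatches[i], revMismatches = rev$mismatches[j])
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$size, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Two-reaction diagnostic genotype call
#'
#' Combines the outcomes of two PCRs into a genotype: an internal-exon
#' reaction (product only when an intact allele is present) and a
#' junction reaction whose primers flank the deletion (short product only
#' when the deletion allele is present; on the wild-type allele the
#' product is too long for standard PCR). The truth table is
#' \code{(exon+, junction-) = WT}, \code{(exon+, junction+) = HET},
#' \code{(exon-, junction+) = HOM_DEL}, \code{(exon-, junction-) =
#' UNINFORMATIVE} (assay failure).
#'
#' @param exonDetectable logical, internal-exon reaction yielded a product.
#' @param junctionDetectable logical, junction reaction yielded a product.
#' @return list with \code{call} (one of \code{"WT"}, \code{"HET"},
#'   \code{"HOM_DEL"}, \code{"UNINFORMATIVE"}) and \code{evidence}.
#' @examples
#' callGenotype(TRUE, TRUE)$call   # "HET"
#' @export
callGenotype <- function(exonDetectable, junctionDetectable) {
  stopifnot(is.logical(exonDetectable), is.logical(junctionDetectable),
            length(exonDetectable) == 1L, length(junctionDetectable) == 1L,
            !is.na(exonDetectable), !is.na(junctionDetectable))
  call <- if (exonDetectable && !junctionDetectable) "WT"
          else if (exonDetectable && junctionDetectable) "HET"
          else if (!exonDetectable && junctionDetectable) "HOM_DEL"
          else "UNINFORMATIVE"
  list(call = call,
       evidence = c(exon = exonDetectable, junction = junctionDetectable))
}

#' Genotype a sample from its allele templates
#'
#' Runs the exon and junction reactions in silico on every allele template
#' of a sample (one for homozygotes, two for heterozygotes); a reaction is
#' positive when any allele yields a detectable product.
#'
#' @param alleles \code{DNAStringSet} (or character vector) of the
#'   sample's allele sequences.
#' @param exonPair,junctionPair \code{\linkS4class{PrimerPair}} objects for
#'   the internal-exon and across-deletion reactions.
#' @param maxProductLen standard-PCR detectability threshold (default
#'   2000).
#' @return list as from \code{\link{callGenotype}}.
#' @export
genotypeSample <- function(alleles, exonPair, junctionPair,
                           maxProductLen = 2000L) {
  alleles <- as.character(alleles)
  detectableOn <- function(pair) {
    any(vapply(alleles, function(a) {
      amp <- predictAmplicons(a, pair, maxProductLen = maxProductLen)
      any(amp$detectable)
    }, logical(1)))
  }
  callGenotype(detectableOn(exonPair), detectableOn(junctionPair))
}

#' Genotype a cohort of samples
#'
#' @param samples named list; each element a character vector or
#'   \code{DNAStringSet} of that sample's allele templates.
#' @inheritParams genotypeSample
#' @return data.frame: \code{sample}, \code{exonRxn}, \code{junctionRxn},
#'   \code{call}.
#' @export
genotypeCohort <- function(samples, exonPair, junctionPair,
                           maxProductLen = 2000L) {
  stopifnot(is.list(samples), !is.null(names(samples)))
  rows <- lapply(names(samples), function(id) {
    g <- genotypeSample(samples[[id]], exonPair, junctionPair, maxProductLen)
    data.frame(sample = id, exonRxn = unname(g$evidence["exon"]),
               junctionRxn = unname(g$evidence["junction"]), call = g$call)
  })
  do.call(rbind, rows)
}
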