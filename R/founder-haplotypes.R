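## Founder-haplotype analysis: homozygosity profiles over microsatellite
## panels and shared-haplotype detection across consanguineous families.
##
## Under consanguinity an affected individual homozygous by descent carries
## the founder haplotype on both chromosomes, so the homozygous genotype IS
## the phased haplotype; no general phasing algorithm is needed or
## implemented.

#' Read long-format microsatellite genotypes
#'
#' Expects TSV columns \code{family}, \code{individual}, \code{affected}
#' (logical or 0/1), \code{marker}, \code{allele_a}, \code{allele_b}
#' (integer fragment sizes in bp; NA for missing).
#'
#' @param file path.
#' @return data.frame.
#' @export
readGenotypes <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  df$affected <- as.logical(df$affected)
  df
}

#' Per-marker homozygosity profile of each individual
#'
#' An individual is homozygous at a marker iff both allele sizes are equal
#' and non-missing. Only markers in the panel are profiled; a panel marker
#' with no genotype row for an individual is reported as missing.
#'
#' @param genotypes data.frame with columns \code{family},
#'   \code{individual}, \code{affected}, \code{marker}, \code{allele_a},
#'   \code{allele_b}.
#' @param panel ordered character vector of marker names (or a data.frame
#'   with a \code{name} column).
#' @return data.frame: \code{family}, \code{individual}, \code{affected},
#'   \code{marker}, \code{status} (\code{"hom"}, \code{"het"},
#'   \code{"missing"}), \code{allele} (the homozygous allele size, NA
#'   otherwise).
#' @export
homozygosityProfile <- function(genotypes, panel) {
  if (is.data.frame(panel)) panel <- panel$name
  panel <- as.character(panel)
  need <- c("family", "individual", "affected", "marker",
            "allele_a", "allele_b")
  miss <- setdiff(need, names(genotypes))
  if (length(miss))
    stop("genotypes lack columns: ", paste(miss, collapse = ", "))
  g <- genotypes[genotypes$marker %in% panel, , drop = FALSE]
  dup <- duplicated(g[, c("individual", "marker")])
  if (any(dup))
    stop("duplicate genotype for individual/marker: ",
         paste(unique(paste(g$individual[dup], g$marker[dup], sep = "/")),
               collapse = ", "))
  inds <- unique(g[, c("family", "individual", "affected")])
  out <- list()
  for (i in seq_len(nrow(inds))) {
    gi <- g[g$individual == inds$individual[i], , drop = FALSE]
    for (mk in panel) {
      row <- gi[gi$marker == mk, , drop = FALSE]
      if (nrow(row) == 0L || is.na(row$allele_a) || is.na(row$allele_b)) {
        status <- "missing"; allele <- NA_integer_
      } else if (row$allele_a == row$allele_b) {
        status <- "hom"; allele <- as.integer(row$allele_a)
      } else {
        status <- "het"; allele <- NA_integer_
      }
      out[[length(out) + 1L]] <- data.frame(
        family = inds$family[i], individual = inds$individual[i],
        affected = inds$affected[i], marker = mk, status = status,
        allele = allele)
    }
  }
  res <- do.call(rbind, out)
  res$marker <- factor(res$marker, levels = panel)
  res <- res[order(res$family, res$individual, res$marker), , drop = FALSE]
  res$marker <- as.character(res$marker)
  rownames(res) <- NULL
  res
}

## Homozygous allele vector (ordered by panel) of one individual's
## profile; NULL unless homozygous at every typed marker and typed at >= 1.
.homVector <- function(prof, panel) {
  v <- integer(length(panel))
  names(v) <- panel
  for (k in seq_along(panel)) {
    row <- prof[prof$marker == panel[k], , drop = FALSE]
    st <- if (nrow(row)) row$status[1] else "missing"
    if (st == "het") return(NULL)
    v[k] <- if (st == "hom") row$allele[1] else NA_integer_
  }
  if (all(is.na(v))) return(NULL)
  v
}

.hapString <- function(v) paste(ifelse(is.na(v), "?", v), collapse = "-")

## Does individual vector v match candidate hap? Missing markers do not
## disqualify; with relax, one typed discordant marker is tolerated.
.matchesHap <- function(v, hap, relax) {
  typed <- !is.na(v)
  disc <- sum(v[typed] != hap[typed])
  disc == 0L || (relax && disc <= 1L)
}

#' Detect a shared homozygous (founder) haplotype across families
#'
#' Enumerates the homozygous allele vectors of affected individuals; a
#' candidate founder haplotype is any fully typed vector carried
#' homozygously by affecteds of at least two distinct families. For each
#' candidate, a family is counted as supporting when every one of its
#' typed affecteds matches the candidate at every typed marker
#' (\code{relax = TRUE} tolerates one discordant marker per affected,
#' accommodating one-step variant haplotypes of the founder allele).
#' Output is independent of the input order of families and individuals.
#'
#' @param profiles output of \code{\link{homozygosityProfile}} restricted
#'   to (or containing) affected individuals; only affecteds are used.
#' @param panel ordered character vector of marker names.
#' @param relax tolerate one discordant marker per affected (default
#'   FALSE).
#' @return a \code{\linkS4class{FounderReport}}.
#' @export
sharedHomozygousHaplotype <- function(profiles, panel, relax = FALSE) {
  if (is.data.frame(panel)) panel <- panel$name
  panel <- as.character(panel)
  aff <- profiles[profiles$affected, , drop = FALSE]
  if (!nrow(aff)) stop("no affected individuals in input")
  famTotal <- length(unique(aff$family))
  inds <- unique(aff[, c("family", "individual")])
  vecs <- list()
  for (i in seq_len(nrow(inds))) {
    prof <- aff[aff$individual == inds$individual[i], , drop = FALSE]
    v <- .homVector(prof, panel)
    if (!is.null(v))
      vecs[[length(vecs) + 1L]] <- list(family = inds$family[i], hap = v)
  }
  ## candidates: complete vectors seen in >= 2 distinct families
  complete <- Filter(function(x) !anyNA(x$hap), vecs)
  byHap <- split(vapply(complete, function(x) x$family, character(1)),
                 vapply(complete, function(x) .hapString(x$hap), character(1)))
  candStrings <- names(byHap)[vapply(byHap, function(f)
    length(unique(f)) >= 2L, logical(1))]
  candRows <- list()
  for (hs in sort(candStrings)) {
    hap <- as.integer(strsplit(hs, "-", fixed = TRUE)[[1]])
    names(hap) <- panel
    supp <- 0L
    for (fam in sort(unique(inds$family))) {
      famInds <- inds$individual[inds$family == fam]
      ok <- vapply(famInds, function(id) {
        prof <- aff[aff$individual == id, , drop = FALSE]
        v <- .homVector(prof, panel)
        !is.null(v) && .matchesHap(v, hap, relax)
      }, logical(1))
      if (all(ok)) supp <- supp + 1L
    }
    row <- as.data.frame(as.list(hap))
    names(row) <- panel
    row$haplotype <- hs
    row$familiesSupporting <- supp
    candRows[[length(candRows) + 1L]] <- row
  }
  if (length(candRows)) {
    cands <- do.call(rbind, candRows)
    cands <- cands[order(-cands$familiesSupporting, cands$haplotype), ,
                   drop = FALSE]
    rownames(cands) <- NULL
    best <- max(cands$familiesSupporting)
  } else {
    cands <- data.frame(haplotype = character(),
                        familiesSupporting = integer())
    best <- 0L
  }
  new("FounderReport", profiles = profiles, candidates = cands,
      familiesTotal = as.integer(famTotal),
      familiesSupporting = as.integer(best))
}

#' Accessors for FounderReport objects
#'
#' @param x a \code{\linkS4class{FounderReport}}.
#' @export
founderCandidates <- function(x) {
  stopifnot(is(x, "FounderReport"))
  x@candidates
}

#' @rdname founderCandidates
#' @export
familiesSupporting <- function(x) {
  stopifnot(is(x, "FounderReport"))
  x@familiesSupporting
}

#' @rdname founderCandidates
#' @export
familiesTotal <- function(x) {
  stopifnot(is(x, "FounderReport"))
  x@familiesTotal
}

#' Write a FounderReport as JSON and a per-family haplotype matrix as TSV
#'
#' @param x a \code{\linkS4class{FounderReport}}.
#' @param json,tsv output paths (either may be NULL).
#' @export
writeFounderReport <- function(x, json = NULL, tsv = NULL) {
  stopifnot(is(x, "FounderReport"))
  if (!is.null(json))
    jsonlite::write_json(list(
      familiesTotal = x@familiesTotal,
      familiesSupporting = x@familiesSupporting,
      candidates = x@candidates), json, auto_unbox = TRUE, digits = NA)
  if (!is.null(tsv)) {
    prof <- x@profiles
    wide <- stats::reshape(
      prof[, c("family", "individual", "marker", "status", "allele")],
      idvar = c("family", "individual"), timevar = "marker",
      v.names = c("status", "allele"), direction = "wide")
    utils::write.table(wide, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(x)
}
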