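## Synthetic-locus simulator: a repeat-laden reference with a planted
## equal-crossover deletion between two co-oriented repeat copies, junction
## fragments, and consanguineous pedigree genotypes -- everything carrying
## its ground truth so each analysis stage can be validated end to end.

.loadConsensus <- function() {
  fa <- system.file("extdata", "synthetic_repeat_consensus.fa",
                    package = "aludel")
  seqs <- Biostrings::readDNAStringSet(fa)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  lapply(as.list(as.character(seqs)), seqChars)
}

## Deterministic subfamily consensus: the base consensus mutated at 2%
## with a seed derived from the subfamily name, so distinct subfamilies
## differ reproducibly and independently of the user's simulation seed.
.subfamilyConsensus <- function(base, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 1000003L
  withSeed(h + 17L, .mutateBases(base, 2))
}

.mutateBases <- function(bases, divergencePct) {
  n <- length(bases)
  k <- round(n * divergencePct / 100)
  if (k == 0) return(bases)
  pos <- sample.int(n, k)
  for (p in pos) {
    alt <- setdiff(DNA_BASES4, bases[p])
    bases[p] <- alt[sample.int(3L, 1L)]
  }
  bases
}

.revcompBases <- function(bases) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[bases]))
}

#' Default repeat plan of the synthetic locus
#'
#' A 9358 bp window carrying 19 planted repeat copies whose layout emulates
#' the repeat landscape of an Alu-rich gene region: about 51 percent of the
#' window is interspersed repeats, with two same-orientation low-divergence
#' copies of one Alu-like subfamily (\code{AluSyn2}) 3910 bp apart serving
#' as the default crossover substrates, interrupted LINE-like fragments
#' sharing a linkage id, a simple repeat, and two adjacent DNA-transposon
#' fragments.
#'
#' @return data.frame with columns \code{start}, \code{length},
#'   \code{strand}, \code{repeatName}, \code{classFamily},
#'   \code{divergence}, \code{elementID}, \code{consensus},
#'   \code{consensusStart}.
#' @export
defaultRepeatPlan <- function() {
  data.frame(
    start = c(657L, 925L, 1267L, 1644L, 1958L, 2303L, 2610L, 3081L, 3391L,
              3744L, 3990L, 5271L, 5582L, 6162L, 6991L, 7564L, 8018L,
              8598L, 8684L),
    length = c(240L, 310L, 315L, 301L, 345L, 307L, 471L, 310L, 120L, 166L,
               520L, 310L, 34L, 72L, 310L, 300L, 296L, 86L, 31L),
    strand = c("-", "-", "-", "-", "-", "-", "-", "+", "-", "-", "+", "-",
               "+", "+", "+", "-", "-", "+", "+"),
    repeatName = c("AluSyn1", "AluSyn3", "L1Syn", "AluSyn4", "L1Syn",
                   "AluSyn5", "L1Syn", "AluSyn2", "L1Syn", "AluSyn6",
                   "L2Syn", "AluSyn4", "(TCTTTA)n", "AluSyn7", "AluSyn2",
                   "AluSyn3", "AluSyn8", "MERSyn", "MERSyn"),
    classFamily = c("SINE/Alu", "SINE/Alu", "LINE/L1", "SINE/Alu",
                    "LINE/L1", "SINE/Alu", "LINE/L1", "SINE/Alu",
                    "LINE/L1", "SINE/Alu", "LINE/L2", "SINE/Alu",
                    "Simple_repeat", "SINE/Alu", "SINE/Alu", "SINE/Alu",
                    "SINE/Alu", "DNA/hAT-Charlie", "DNA/hAT-Charlie"),
    divergence = c(13, 10, 26, 12, 15, 11, 16, 5, 18, 19, 30, 10, 10, 6,
                   5, 7, 8, 25, 16),
    elementID = c(1L, 2L, 3L, 4L, 5L, 6L, 5L, 7L, 5L, 8L, 9L, 10L, 11L,
                  12L, 13L, 14L, 15L, 16L, 17L),
    consensus = c("ALUSYN", "ALUSYN", "L1SYN", "ALUSYN", "L1SYN", "ALUSYN",
                  "L1SYN", "ALUSYN", "L1SYN", "ALUSYN", "L2SYN", "ALUSYN",
                  "SIMPLE", "ALUSYN", "ALUSYN", "ALUSYN", "ALUSYN",
                  "MERSYN", "MERSYN"),
    consensusStart = c(1L, 1L, 600L, 1L, 1L, 1L, 346L, 1L, 817L, 100L, 1L,
                       1L, 1L, 1L, 1L, 1L, 1L, 1L, 100L),
    stringsAsFactors = FALSE)
}

#' Default pedigree plan
#'
#' Ten consanguineous families, one affected each plus two carrier
#' parents, genotyped at a two-marker microsatellite panel flanking the
#' locus; the founder haplotype transmitted identically by descent is
#' (129, 188).
#'
#' @return list with \code{nFamilies}, \code{affectedPerFamily},
#'   \code{carriersPerFamily}, \code{panel}, \code{freqs} (per-marker
#'   named allele-frequency vectors summing to 1), \code{founder} (named
#'   allele-size vector, or NULL for the no-founder null model).
#' @export
defaultPedigreePlan <- function() {
  list(nFamilies = 10L, affectedPerFamily = 1L, carriersPerFamily = 2L,
       panel = c("D6S1582", "D6S271"),
       freqs = list(
         D6S1582 = c("129" = 0.3, "131" = 0.25, "133" = 0.25, "135" = 0.2),
         D6S271 = c("186" = 0.25, "188" = 0.3, "190" = 0.25, "192" = 0.2)),
       founder = c(D6S1582 = 129, D6S271 = 188))
}

#' Simulation configuration
#'
#' Bundles and validates all simulator knobs. The defaults ARE the study
#' conditions the package's tests exercise: a 9358 bp locus about half
#' covered by interspersed repeats, an equal crossover between two
#' co-oriented Alu-like copies 3910 bp apart with a 35 bp planted
#' microhomology block, error-free 500 bp junction flanks, and ten
#' consanguineous families homozygous for a (129, 188) founder haplotype.
#'
#' @param seed integer master seed; sequence, mutation, pedigree and
#'   junction-error draws use independent sub-streams derived from it, so
#'   changing one plan leaves the other outputs unchanged.
#' @param locusLength bp (default 9358).
#' @param repeatPlan data.frame as \code{\link{defaultRepeatPlan}}.
#' @param crossover list: \code{pairName} (repeat subfamily whose two
#'   copies recombine), \code{offset} (crossover offset within the copies,
#'   NULL to draw), \code{mhLen} (length of the identical block planted
#'   around the crossover, 0-60; NULL to leave the copies' natural
#'   identity structure).
#' @param junction list: \code{flank} bp of mutant flank per side of the
#'   junction in the emitted read, \code{errorRate} per-base substitution
#'   probability in [0, 0.1] (default 0, Sanger-consensus-like).
#' @param pedigree list as \code{\link{defaultPedigreePlan}}.
#' @return validated config list of class \code{aludel_sim_config}.
#' @export
simConfig <- function(seed = 1L, locusLength = 9358L,
                      repeatPlan = defaultRepeatPlan(),
                      crossover = list(pairName = "AluSyn2", offset = NULL,
                                       mhLen = 35L),
                      junction = list(flank = 500L, errorRate = 0),
                      pedigree = defaultPedigreePlan()) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  seed <- as.integer(seed %% 214748363L)
  if (any(repeatPlan$divergence < 0 | repeatPlan$divergence > 50))
    stop("repeat divergence must lie in [0, 50] percent")
  if (any(repeatPlan$start < 1L |
          repeatPlan$start + repeatPlan$length - 1L > locusLength))
    stop("planned repeat positions must lie within the locus")
  o <- order(repeatPlan$start)
  rp <- repeatPlan[o, , drop = FALSE]
  if (nrow(rp) > 1L &&
      any(rp$start[-1L] <= rp$start[-nrow(rp)] + rp$length[-nrow(rp)] - 1L))
    stop("overlapping planned insertions")
  er <- junction$errorRate %||% 0
  if (er < 0 || er > 0.1)
    stop("junction error rate must lie in [0, 0.1]")
  if (!is.null(crossover$mhLen) &&
      (crossover$mhLen < 0L || crossover$mhLen > 60L))
    stop("planted microhomology length must lie in [0, 60] bp")
  structure(list(seed = seed, locusLength = as.integer(locusLength),
                 repeatPlan = rp, crossover = crossover,
                 junction = junction, pedigree = pedigree),
            class = "aludel_sim_config")
}

## Build one repeat copy from its plan row (mutation stream must be
## active in the caller).
.buildCopy <- function(row, consensus) {
  if (row$consensus == "SIMPLE") {
    unit <- seqChars("TCTTTA")
    bases <- rep(unit, length.out = row$length)
  } else {
    cons <- consensus[[row$consensus]]
    cs <- row$consensusStart
    idx <- ((cs - 1L + seq_len(row$length) - 1L) %% length(cons)) + 1L
    bases <- cons[idx]
  }
  bases <- .mutateBases(bases, row$divergence)
  if (row$strand == "-") bases <- .revcompBases(bases)
  bases
}

.otherBase <- function(b) DNA_BASES4[(match(b, DNA_BASES4) %% 4L) + 1L]

#' Simulate a ground-truthed synthetic locus
#'
#' Draws an i.i.d. uniform A/C/G/T background of the configured length,
#' plants the planned repeat copies (each a seeded point-mutated window of
#' a packaged synthetic consensus, reverse-complemented on minus strand),
#' engineers the crossover pair's identical block when a target
#' microhomology is configured (with mismatch guards immediately outside
#' the block so the truth microhomology is exact), applies the equal
#' crossover to produce the deletion allele and junction read(s), and
#' simulates the pedigree genotypes. Byte-identical outputs for identical
#' (config, seed).
#'
#' @param config a \code{\link{simConfig}}.
#' @return a \code{\linkS4class{SimulatedLocus}}.
#' @examples
#' sim <- simulateLocus(simConfig(seed = 7))
#' sim
#' @export
simulateLocus <- function(config = simConfig()) {
  if (!inherits(config, "aludel_sim_config"))
    config <- do.call(simConfig, config)
  L <- config$locusLength
  rp <- config$repeatPlan
  consensus <- .loadConsensus()
  refB <- withSeed(config$seed * 10L + 1L,
                   sample(DNA_BASES4, L, replace = TRUE))

  xo <- config$crossover
  pairIdx <- which(rp$repeatName == xo$pairName &
                   rp$classFamily != "Simple_repeat")
  if (length(pairIdx) != 2L)
    stop("no eligible repeat pair for crossover plan: need exactly two '",
         xo$pairName, "' copies, found ", length(pairIdx))
  if (rp$strand[pairIdx[1]] != rp$strand[pairIdx[2]] ||
      rp$length[pairIdx[1]] != rp$length[pairIdx[2]])
    stop("no eligible repeat pair for crossover plan: copies must share ",
         "orientation and length")

  blockInfo <- withSeed(config$seed * 10L + 2L, {
    copies <- lapply(seq_len(nrow(rp)), function(i)
      .buildCopy(rp[i, ], consensus))
    cl <- rp$length[pairIdx[1]]
    a <- copies[[pairIdx[1]]]
    b <- copies[[pairIdx[2]]]
    if (!is.null(xo$mhLen)) {
      m <- as.integer(xo$mhLen)
      if (m > cl - 2L)
        stop("planted microhomology does not fit inside the repeat copies")
      if (m >= 1L) {
        bs <- sample.int(cl - m - 1L, 1L) + 1L   # bs in [2, cl - m]
        be <- bs + m - 1L
        b[bs:be] <- a[bs:be]
        b[bs - 1L] <- .otherBase(a[bs - 1L])
        if (be + 1L <= cl) b[be + 1L] <- .otherBase(a[be + 1L])
        off <- if (is.null(xo$offset)) bs + sample.int(m, 1L) - 1L
               else as.integer(xo$offset)
        if (off < bs || off > be)
          stop("crossover offset lies outside the planted identical block")
      } else {
        off <- if (is.null(xo$offset)) sample.int(cl - 3L, 1L) + 1L
               else as.integer(xo$offset)
        b[off] <- .otherBase(a[off])
        b[off + 1L] <- .otherBase(a[off + 1L])
      }
    } else {
      off <- xo$offset   # resolved against natural identity below
    }
    copies[[pairIdx[2]]] <- b
    list(copies = copies, off = off)
  })
  copies <- blockInfo$copies
  for (i in seq_len(nrow(rp)))
    refB[rp$start[i]:(rp$start[i] + rp$length[i] - 1L)] <- copies[[i]]
  refStr <- paste(refB, collapse = "")

  sA <- rp$start[pairIdx[1]]; sB <- rp$start[pairIdx[2]]
  cl <- rp$length[pairIdx[1]]
  off <- blockInfo$off
  if (is.null(off)) {
    ## no planted block: draw a crossover offset inside the longest
    ## natural identical block of the two copies
    off <- withSeed(config$seed * 10L + 2L + 7L, {
      eq <- refB[sA:(sA + cl - 1L)] == refB[sB:(sB + cl - 1L)]
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      runs <- which(r$values)
      if (!length(runs)) stop("no eligible repeat pair for crossover plan: ",
                              "copies share no identical block")
      best <- runs[which.max(r$lengths[runs])]
      bs <- ends[best] - r$lengths[best] + 1L
      min(bs + sample.int(r$lengths[best], 1L) - 1L, cl - 1L)
    })
  }
  cross <- simulateCrossoverDeletion(refStr, IRanges(sA, sA + cl - 1L),
                                     IRanges(sB, sB + cl - 1L),
                                     offset = off, minBlock = 0L,
                                     refname = "synthetic_locus")

  flank <- config$junction$flank %||% 500L
  p <- sA + off - 1L                  # last pre-junction base, mutant coords
  mutB <- seqChars(cross$deletedAllele)
  rs <- max(1L, p - flank + 1L); re <- min(length(mutB), p + flank)
  readB <- mutB[rs:re]
  er <- config$junction$errorRate %||% 0
  if (er > 0)
    readB <- withSeed(config$seed * 10L + 4L, {
      hit <- which(stats::runif(length(readB)) < er)
      for (h in hit) readB[h] <- .otherBase(readB[h])
      readB
    })
  reads <- DNAStringSet(paste(readB, collapse = ""))
  names(reads) <- "junction_read_1"

  consLen <- vapply(consensus, length, integer(1))
  fts <- GRanges("synthetic_locus",
                 IRanges(rp$start, rp$start + rp$length - 1L),
                 strand = rp$strand)
  cLen <- ifelse(rp$consensus == "SIMPLE", rp$length,
                 consLen[rp$consensus])
  rEnd <- pmin(rp$consensusStart + rp$length - 1L, cLen)
  mcols(fts) <- DataFrame(
    swScore = as.integer(round(2000 * (1 - rp$divergence / 100))),
    pctDiv = rp$divergence, pctDel = 0, pctIns = 0,
    repeatName = rp$repeatName, classFamily = rp$classFamily,
    repeatBegin = rp$consensusStart, repeatEnd = as.integer(rEnd),
    repeatLeft = as.integer(cLen - rEnd), elementID = rp$elementID)
  truthTable <- new("RepeatTable",
                    region = GRanges("synthetic_locus", IRanges(1L, L),
                                     strand = "*"),
                    features = fts)

  ped <- simulatePedigreeGenotypes(config$pedigree,
                                   seed = config$seed * 10L + 3L)

  manifest <- list(
    seed = config$seed, locusLength = L,
    plannedInterspersedBp = sum(rp$length[rp$classFamily !=
                                            "Simple_repeat"]),
    crossover = list(pairName = xo$pairName, startA = sA, startB = sB,
                     copyLength = cl, offset = off,
                     mhLen = cross$call@mhLen,
                     delStart = start(cross$call@del),
                     delEnd = end(cross$call@del),
                     delLength = width(cross$call@del),
                     hgvsG = cross$call@hgvsG),
    junction = list(flank = flank, errorRate = er,
                    readLength = length(readB)),
    pedigree = list(nFamilies = config$pedigree$nFamilies,
                    founder = as.list(config$pedigree$founder)))

  new("SimulatedLocus", config = unclass(config),
      reference = DNAString(refStr), repeats = truthTable,
      deletedAllele = cross$deletedAllele, truth = cross$call,
      junctionReads = reads, pedigree = ped, manifest = manifest)
}

#' Apply an equal crossover between two co-oriented repeat copies
#'
#' Joins copy A's 5' part to copy B's 3' part at an aligned offset,
#' deleting the intervening segment. The deletion length equals the
#' distance between equivalent aligned positions of the two copies
#' (\code{start(B) - start(A)} for equal-length copies, independent of the
#' offset). The truth microhomology is the maximal identical block of the
#' reference spanning the crossover point.
#'
#' @param ref reference sequence (character or \code{DNAString}).
#' @param repeatA,repeatB \code{IRanges} of the two copies (equal width;
#'   A upstream of B).
#' @param offset crossover offset within the copies (1-based, copy
#'   coordinates); NULL draws one uniformly from offsets inside identical
#'   blocks of length at least \code{minBlock}.
#' @param minBlock minimum identical-block length an eligible crossover
#'   offset must sit in (default 1; 0 permits any offset).
#' @param strandA,strandB orientations of the copies; must be equal.
#' @param refname reference name for the emitted call.
#' @return list: \code{deletedAllele} (\code{DNAString}), \code{call}
#'   (\code{\linkS4class{DeletionCall}}, 3'-normalised), \code{offset}.
#' @export
simulateCrossoverDeletion <- function(ref, repeatA, repeatB, offset = NULL,
                                      minBlock = 1L, strandA = "+",
                                      strandB = "+", refname = "ref") {
  refB <- seqChars(ref)
  if (strandA != strandB)
    stop("crossover copies must share orientation")
  wA <- BiocGenerics::width(repeatA); wB <- BiocGenerics::width(repeatB)
  if (wA != wB)
    stop("crossover copies must have equal length")
  sA <- BiocGenerics::start(repeatA); sB <- BiocGenerics::start(repeatB)
  if (sA >= sB) stop("repeatA must lie upstream of repeatB")
  cl <- wA
  a <- refB[sA:(sA + cl - 1L)]
  b <- refB[sB:(sB + cl - 1L)]
  eq <- a == b
  mhAt <- function(off) {
    r <- 0L
    while (off + 1L + r <= cl && eq[off + 1L + r]) r <- r + 1L
    l <- 0L
    while (off - l >= 1L && eq[off - l]) l <- l + 1L
    l + r
  }
  if (is.null(offset)) {
    elig <- which(vapply(seq_len(cl - 1L), mhAt, integer(1)) >= minBlock)
    if (!length(elig))
      stop("no crossover offset lies in an identical block of length >= ",
           minBlock)
    offset <- elig[sample.int(length(elig), 1L)]
  } else {
    offset <- as.integer(offset)
    if (offset < 1L || offset >= cl)
      stop("crossover offset must lie within the copies")
    if (mhAt(offset) < minBlock)
      stop("offset outside any identical block of the required length (",
           minBlock, " bp)")
  }
  delRaw <- IRanges(sA + offset, sB + offset - 1L)
  mutant <- paste(refB[-(BiocGenerics::start(delRaw):
                           BiocGenerics::end(delRaw))], collapse = "")
  delNorm <- normalize3Prime(refB, delRaw)
  mh <- microhomologyLength(refB, delNorm)
  s3 <- BiocGenerics::start(delNorm)
  call <- new("DeletionCall", refName = refname, del = delNorm,
              mhLen = mh, ambiguity = IRanges(s3 - mh, s3),
              hgvsG = sprintf("%s:g.%d_%ddel%d", refname, s3,
                              BiocGenerics::end(delNorm),
                              BiocGenerics::width(delNorm)),
              mechanismHint = DataFrame())
  list(deletedAllele = DNAString(mutant), call = call, offset = offset)
}

#' Simulate microsatellite genotypes for consanguineous pedigrees
#'
#' Affected individuals receive the founder haplotype identically by
#' descent on both chromosomes (homozygous at every panel marker); carrier
#' parents are heterozygous, with one founder allele and one drawn from
#' the population allele-frequency table. With \code{founder = NULL} all
#' alleles are independent population draws (the no-founder null model).
#'
#' @param plan list as \code{\link{defaultPedigreePlan}}.
#' @param seed integer seed for the pedigree stream.
#' @return long-format data.frame: \code{family}, \code{individual},
#'   \code{affected}, \code{marker}, \code{allele_a}, \code{allele_b}.
#' @export
simulatePedigreeGenotypes <- function(plan = defaultPedigreePlan(),
                                      seed = 1L) {
  panel <- plan$panel
  freqs <- plan$freqs
  for (mk in panel) {
    f <- freqs[[mk]]
    if (is.null(f) || abs(sum(f) - 1) > 1e-6)
      stop("invalid allele frequencies for marker ", mk,
           ": must be present and sum to 1")
  }
  emptyDf <- data.frame(family = character(), individual = character(),
                        affected = logical(), marker = character(),
                        allele_a = integer(), allele_b = integer())
  nf <- plan$nFamilies %||% 0L
  if (nf == 0L) return(emptyDf)
  founder <- plan$founder
  if (!is.null(founder) && !all(panel %in% names(founder)))
    stop("founder haplotype must name every panel marker")
  drawAllele <- function(mk) {
    f <- freqs[[mk]]
    as.integer(names(f)[sample.int(length(f), 1L, prob = f)])
  }
  withSeed(seed, {
    rows <- list()
    for (fam in seq_len(nf)) {
      famId <- sprintf("F%02d", fam)
      nAff <- plan$affectedPerFamily %||% 1L
      nCar <- plan$carriersPerFamily %||% 0L
      for (a in seq_len(nAff)) {
        id <- sprintf("%s_A%d", famId, a)
        for (mk in panel) {
          al <- if (is.null(founder)) c(drawAllele(mk), drawAllele(mk))
                else rep(as.integer(founder[[mk]]), 2L)
          rows[[length(rows) + 1L]] <- data.frame(
            family = famId, individual = id, affected = TRUE, marker = mk,
            allele_a = al[1], allele_b = al[2])
        }
      }
      for (p in seq_len(nCar)) {
        id <- sprintf("%s_C%d", famId, p)
        for (mk in panel) {
          al <- if (is.null(founder)) c(drawAllele(mk), drawAllele(mk))
                else c(as.integer(founder[[mk]]), drawAllele(mk))
          rows[[length(rows) + 1L]] <- data.frame(
            family = famId, individual = id, affected = FALSE, marker = mk,
            allele_a = al[1], allele_b = al[2])
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Write all artifacts of a simulated locus to a directory
#'
#' Emits FASTA (reference, deleted allele, junction reads), the truth
#' repeat annotation in the .out dialect and as BED6, the pedigree
#' genotype TSV, the truth manifest JSON, and an index of the written
#' files.
#'
#' @param sim a \code{\linkS4class{SimulatedLocus}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
writeSimulatedLocus <- function(sim, dir) {
  stopifnot(is(sim, "SimulatedLocus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    reference = file.path(dir, "reference.fa"),
    deleted = file.path(dir, "deleted_allele.fa"),
    junction = file.path(dir, "junction_reads.fa"),
    repeats_out = file.path(dir, "truth_repeats.out"),
    repeats_bed = file.path(dir, "truth_repeats.bed"),
    genotypes = file.path(dir, "genotypes.tsv"),
    manifest = file.path(dir, "truth_manifest.json"),
    index = file.path(dir, "manifest_index.json"))
  refSet <- DNAStringSet(sim@reference)
  names(refSet) <- "synthetic_locus"
  Biostrings::writeXStringSet(refSet, paths["reference"])
  mutSet <- DNAStringSet(sim@deletedAllele)
  names(mutSet) <- "synthetic_locus_del"
  Biostrings::writeXStringSet(mutSet, paths["deleted"])
  Biostrings::writeXStringSet(sim@junctionReads, paths["junction"])
  writeRepeatMaskerOut(sim@repeats, paths["repeats_out"])
  exportRepeatsBed(sim@repeats, paths["repeats_bed"])
  utils::write.table(sim@pedigree, paths["genotypes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim@manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(as.list(basename(paths[names(paths) != "index"])),
                       paths["index"], auto_unbox = TRUE)
  invisible(paths)
}
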