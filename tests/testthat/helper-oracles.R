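# Independent brute-force oracles and small generators used across the
# suite. These are deliberately naive O(n*m) implementations kept separate
# from the package's algorithms.

randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

deleteStr <- function(ref, s, e) {
  paste0(substr(ref, 1, s - 1), substr(ref, e + 1, nchar(ref)))
}

# Exhaustive slide oracle: number of deletion placements (same length)
# producing the identical mutant sequence, scanning every start position.
slidePlacements <- function(ref, s, e) {
  len <- e - s + 1
  mut0 <- deleteStr(ref, s, e)
  starts <- which(vapply(seq_len(nchar(ref) - len + 1), function(sp)
    deleteStr(ref, sp, sp + len - 1) == mut0, logical(1)))
  starts
}

# Brute-force primer binding-site scan at every offset on both strands,
# N-aware, with the same 3'-exactness rule the package documents.
revcompStr <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(toupper(x), "")[[1]]]), collapse = "")
}

bruteSites <- function(template, primerSeq, maxMismatch = 0, exact3 = 5) {
  tB <- strsplit(toupper(template), "")[[1]]
  scan <- function(pseq, strandChar) {
    pB <- strsplit(toupper(pseq), "")[[1]]
    plen <- length(pB)
    out <- list()
    if (plen > length(tB)) return(out)
    e3 <- min(exact3, plen)
    win3 <- if (strandChar == "+") (plen - e3 + 1):plen else 1:e3
    for (s in 1:(length(tB) - plen + 1)) {
      w <- tB[s:(s + plen - 1)]
      mis <- which(pB != w & pB != "N")
      if (length(mis) <= maxMismatch && !any(mis %in% win3))
        out[[length(out) + 1]] <- data.frame(
          start = s, end = s + plen - 1, strand = strandChar,
          mismatches = length(mis))
    }
    out
  }
  res <- c(scan(primerSeq, "+"), scan(revcompStr(primerSeq), "-"))
  if (!length(res))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer()))
  df <- do.call(rbind, res)
  df[order(df$start, df$strand), , drop = FALSE]
}

bruteAmplicons <- function(template, fwdSeq, revSeq, maxProductLen = 2000,
                           maxMismatch = 0, exact3 = 5) {
  f <- bruteSites(template, fwdSeq, maxMismatch, exact3)
  r <- bruteSites(template, revSeq, maxMismatch, exact3)
  f <- f[f$strand == "+", , drop = FALSE]
  r <- r[r$strand == "-", , drop = FALSE]
  out <- list()
  if (nrow(f) && nrow(r))
    for (i in seq_len(nrow(f))) for (j in seq_len(nrow(r))) {
      if (f$start[i] > r$start[j] || f$end[i] > r$end[j]) next
      size <- r$end[j] - f$start[i] + 1
      out[[length(out) + 1]] <- data.frame(
        start = f$start[i], end = r$end[j], size = size,
        detectable = size <= maxProductLen)
    }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(), size = integer(),
                      detectable = logical()))
  df <- do.call(rbind, out)
  df <- df[order(df$size, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Per-base occupancy oracle for interval coverage.
bitmapCoverage <- function(starts, ends, regionLength) {
  occ <- logical(regionLength)
  for (i in seq_along(starts)) occ[starts[i]:ends[i]] <- TRUE
  sum(occ)
}

# Build a RepeatTable directly from vectors (bypassing the parser).
makeTable <- function(starts, ends, strand, name, classFamily, elementID,
                      regionLength, seqId = "toy") {
  fts <- GenomicRanges::GRanges(seqId, IRanges::IRanges(starts, ends),
                                strand = strand)
  S4Vectors::mcols(fts) <- S4Vectors::DataFrame(
    swScore = rep(100L, length(starts)), pctDiv = rep(1, length(starts)),
    pctDel = rep(0, length(starts)), pctIns = rep(0, length(starts)),
    repeatName = name, classFamily = classFamily,
    repeatBegin = rep(1L, length(starts)),
    repeatEnd = as.integer(ends - starts + 1),
    repeatLeft = rep(0L, length(starts)),
    elementID = as.integer(elementID))
  new("RepeatTable",
      region = GenomicRanges::GRanges(seqId,
                                      IRanges::IRanges(1L, regionLength),
                                      strand = "*"),
      features = fts)
}

# Light simulation config for crossover-recovery sweeps: two co-oriented
# Alu-like copies delLen apart on a mostly background locus.
crossoverConfig <- function(seed, delLen, mhLen, flank = 400L) {
  sA <- 1200L
  sB <- sA + as.integer(delLen)
  plan <- data.frame(
    start = c(400L, sA, sB),
    length = c(200L, 310L, 310L),
    strand = c("-", "+", "+"),
    repeatName = c("L1Syn", "AluSyn2", "AluSyn2"),
    classFamily = c("LINE/L1", "SINE/Alu", "SINE/Alu"),
    divergence = c(15, 5, 5),
    elementID = 1:3,
    consensus = c("L1SYN", "ALUSYN", "ALUSYN"),
    consensusStart = c(1L, 1L, 1L),
    stringsAsFactors = FALSE)
  ped <- defaultPedigreePlan()
  ped$nFamilies <- 0L
  simConfig(seed = seed, locusLength = sB + 310L + 1500L,
            repeatPlan = plan,
            crossover = list(pairName = "AluSyn2", offset = NULL,
                             mhLen = as.integer(mhLen)),
            junction = list(flank = flank, errorRate = 0),
            pedigree = ped)
}
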