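test_that("a toy junction maps to the expected deletion", {
  call <- mapDeletionJunction("AAAATTTTCCCC", "AAAACCCC", anchorK = 4,
                              refname = "toy")
  expect_equal(deletionLength(call), 4L)
  expect_equal(as.integer(c(BiocGenerics::start(deletionRange(call)),
                            BiocGenerics::end(deletionRange(call)))),
               c(5L, 8L))
  expect_equal(microhomology(call), 0L)
  expect_equal(BiocGenerics::width(ambiguityWindow(call)), 1L)
  expect_equal(hgvsG(call), "toy:g.5_8del4")
})

test_that("a junction identical to the reference is not a deletion", {
  ref <- randSeq(200)
  expect_error(mapDeletionJunction(ref, ref, anchorK = 15),
               "no deletion detected")
})

test_that("microhomology length matches hand-checked cases and bounds", {
  expect_equal(microhomologyLength("AAGCTGCTTT", c(3, 5)), 3L)
  expect_equal(microhomologyLength("AAGCTGCTTT", c(6, 8)), 3L)
  # non-matching flanks
  expect_equal(microhomologyLength("AACGTTACGT", c(4, 6)), 0L)
  expect_error(microhomologyLength("ACGT", c(2, 9)), "out of bounds")
})

test_that("microhomology equals the exhaustive slide oracle on random deletions", {
  set.seed(71)
  for (rep in 1:30) {
    ref <- randSeq(sample(60:140, 1))
    len <- sample(5:20, 1)
    s <- sample(2:(nchar(ref) - len - 1), 1)
    e <- s + len - 1
    placements <- slidePlacements(ref, s, e)
    mh <- microhomologyLength(ref, c(s, e))
    expect_equal(mh, length(placements) - 1L)
    # the placements form one contiguous window containing the input
    expect_equal(placements, seq(min(placements), max(placements)))
  }
})

test_that("3' normalisation is idempotent and preserves the mutant sequence", {
  # shifting the first GCT lands on the second
  shifted <- normalize3Prime("AAGCTGCTTT", c(3, 5))
  expect_equal(c(BiocGenerics::start(shifted), BiocGenerics::end(shifted)),
               c(6L, 8L))
  # non-slidable deletion unchanged
  same <- normalize3Prime("AACGTTACGT", c(4, 6))
  expect_equal(c(BiocGenerics::start(same), BiocGenerics::end(same)),
               c(4L, 6L))
  set.seed(72)
  for (rep in 1:25) {
    ref <- randSeq(80)
    len <- sample(3:15, 1)
    s <- sample(2:(nchar(ref) - len - 1), 1)
    e <- s + len - 1
    norm <- normalize3Prime(ref, c(s, e))
    s2 <- BiocGenerics::start(norm); e2 <- BiocGenerics::end(norm)
    expect_equal(deleteStr(ref, s, e), deleteStr(ref, s2, e2))
    norm2 <- normalize3Prime(ref, c(s2, e2))
    expect_equal(BiocGenerics::start(norm2), s2)
    # the normalised placement is the rightmost equivalent one
    expect_equal(s2, max(slidePlacements(ref, s, e)))
  }
})

test_that("mapped calls reconstruct the mutant and bound all equivalent placements", {
  set.seed(73)
  for (rep in 1:10) {
    ref <- randSeq(400)
    len <- sample(40:120, 1)
    s <- sample(60:(nchar(ref) - len - 60), 1)
    e <- s + len - 1
    mutant <- deleteStr(ref, s, e)
    call <- mapDeletionJunction(ref, mutant, anchorK = 12)
    s3 <- BiocGenerics::start(deletionRange(call))
    e3 <- BiocGenerics::end(deletionRange(call))
    expect_equal(deleteStr(ref, s3, e3), mutant)
    placements <- slidePlacements(ref, s, e)
    expect_equal(BiocGenerics::start(ambiguityWindow(call)),
                 min(placements))
    expect_equal(BiocGenerics::end(ambiguityWindow(call)), max(placements))
    expect_equal(microhomology(call), length(placements) - 1L)
  }
})

test_that("junctions with an unexplained insertion are rejected", {
  ref <- randSeq(300)
  mutant <- paste0(substr(ref, 1, 100), "TTTTTTTTTT", substr(ref, 181, 300))
  expect_error(mapDeletionJunction(ref, mutant, anchorK = 12),
               "single contiguous deletion")
})

test_that("genomic HGVS strings format and parse as mutual inverses", {
  p <- parseHgvsG("NG_009252.1:g.36847_40771del3925")
  expect_equal(p$start, 36847L)
  expect_equal(p$end, 40771L)
  expect_equal(p$impliedLength, 3925L)
  expect_true(p$consistent)

  # the second printed coordinate pair is internally consistent too
  p2 <- parseHgvsG("NG_009252.1:g.32438_36363del3926")
  expect_equal(p2$impliedLength, 3926L)
  expect_true(p2$consistent)

  # a wrong suffix is flagged, never corrected
  p3 <- parseHgvsG("X:g.10_12del5")
  expect_false(p3$consistent)
  expect_equal(p3$statedLength, 5L)
  expect_equal(p3$impliedLength, 3L)

  expect_error(parseHgvsG("X:g.12_10del3"), "start.*end")
  expect_error(parseHgvsG("X:g.10-12del"), "not a valid")

  set.seed(74)
  for (rep in 1:10) {
    s <- sample(1:10000, 1); e <- s + sample(0:500, 1)
    str <- sprintf("REF_%d:g.%d_%ddel%d", rep, s, e, e - s + 1)
    q <- parseHgvsG(str)
    expect_equal(sprintf("%s:g.%d_%ddel%d", q$refName, q$start, q$end,
                         q$impliedLength), str)
  }
})

test_that("cDNA deletion descriptions resolve to the correct genomic length", {
  d <- parseHgvsC("c.1370-2567_1539+1188del3925")
  expect_equal(d$startExonPos, 1370L)
  expect_equal(d$startOffset, -2567L)
  expect_equal(d$endExonPos, 1539L)
  expect_equal(d$endOffset, 1188L)
  expect_equal(d$statedLength, 3925L)

  em <- exonMap(exon = 9:11,
                cStart = c(1, 1370, 1540), cEnd = c(1369, 1539, 2200),
                gStart = c(1, 3937, 5295), gEnd = c(1369, 4106, 5955))
  expect_equal(cDeletionLength(d, em), 3925L)
  # intron arithmetic: u + exon + v for a single fully deleted exon
  expect_equal(cDeletionLength(d, em), 2567L + 170L + 1188L)

  # zero offsets, a single exon of length L
  em1 <- exonMap(1, 1, 250, 501, 750)
  expect_equal(cDeletionLength("c.1_250del", em1), 250L)

  expect_error(cDeletionLength("c.9999_10000del", em), "outside")
  expect_error(cDeletionLength("c.1370-9999_1539del", em), "crosses")
})

test_that("cDNA lengths agree with direct genomic resolution on random exon maps", {
  set.seed(75)
  pick <- function(v) v[sample.int(length(v), 1)]
  for (rep in 1:15) {
    nEx <- sample(2:5, 1)
    exLen <- sample(50:200, nEx, replace = TRUE)
    intLen <- sample(100:2000, nEx - 1, replace = TRUE)
    cEnd <- cumsum(exLen); cStart <- cEnd - exLen + 1
    gStart <- integer(nEx); gEnd <- integer(nEx)
    g <- 1L
    for (i in seq_len(nEx)) {
      gStart[i] <- g; gEnd[i] <- g + exLen[i] - 1L
      g <- gEnd[i] + (if (i < nEx) intLen[i] else 0L) + 1L
    }
    em <- exonMap(seq_len(nEx), cStart, cEnd, gStart, gEnd)
    i <- pick(seq_len(nEx))
    pos1 <- pick(cStart[i]:cEnd[i])
    u <- if (i > 1) pick(0:(intLen[i - 1] - 1)) else 0L
    j <- pick(i:nEx)
    pos2 <- pick(max(pos1, cStart[j]):cEnd[j])
    v <- if (j < nEx) pick(0:(intLen[j] - 1)) else 0L
    str <- sprintf("c.%d%s_%d%sdel", pos1,
                   if (u > 0) sprintf("-%d", u) else "", pos2,
                   if (v > 0) sprintf("+%d", v) else "")
    gs <- gStart[i] + (pos1 - cStart[i]) - u
    ge <- gStart[j] + (pos2 - cStart[j]) + v
    if (ge < gs) next
    expect_equal(cDeletionLength(str, em), as.integer(ge - gs + 1))
  }
})

test_that("VCF and JSON outputs agree on HOMLEN and coordinates", {
  sim <- simulateLocus(simConfig(seed = 9))
  call <- sim@truth
  fj <- tempfile(fileext = ".json"); fv <- tempfile(fileext = ".vcf")
  writeDeletionJson(call, fj)
  writeDeletionVcf(call, fv, ref = sim@reference)
  js <- jsonlite::read_json(fj, simplifyVector = TRUE)
  rec <- strsplit(tail(readLines(fv), 1), "\t")[[1]]
  expect_equal(as.integer(rec[2]), js$start - 1L)  # POS = base before
  info <- rec[8]
  expect_match(info, sprintf("END=%d", js$end))
  expect_match(info, sprintf("HOMLEN=%d", js$mhLen))
  expect_match(info, sprintf("SVLEN=-%d", js$length))
})
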