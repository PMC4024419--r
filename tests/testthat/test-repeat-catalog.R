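fixtureOut <- system.file("extdata", "polh_exon9_11_repeats.out",
                          package = "aludel")

test_that("the packaged repeat table parses and its landscape arithmetic is exact", {
  rt <- parseRepeatMaskerOut(fixtureOut)
  fts <- repeatFeatures(rt)
  expect_length(fts, 19L)
  expect_equal(BiocGenerics::width(repeatRegion(rt)), 9358L)

  # the first co-oriented AluSq2 copy, converted from 1-based columns
  i <- which(S4Vectors::mcols(fts)$repeatName == "AluSq2")
  expect_length(i, 2L)
  expect_equal(BiocGenerics::start(fts)[i], c(3081L, 6991L))
  expect_equal(BiocGenerics::end(fts)[i], c(3372L, 7300L))
  expect_equal(as.character(BiocGenerics::strand(fts))[i], c("+", "+"))
  expect_equal(S4Vectors::mcols(fts)$elementID[i], c(7L, 13L))

  sm <- summarizeRepeats(rt)
  fam <- repeatCoverageByFamily(sm)
  cls <- repeatCoverageByClass(sm)
  expect_equal(fam$coveredBp[fam$classFamily == "SINE/Alu"], 2908L)
  expect_equal(fam$elementCount[fam$classFamily == "SINE/Alu"], 11L)
  expect_equal(fam$fraction[fam$classFamily == "SINE/Alu"], 31.08)
  expect_equal(cls$coveredBp[cls$class == "LINE"], 1789L)
  # three L1MB8 fragments share one linkage id -> 3 LINE elements, not 5
  expect_equal(cls$elementCount[cls$class == "LINE"], 3L)
  expect_equal(cls$fraction[cls$class == "LINE"], 19.12)
  expect_equal(interspersedBp(sm), 4814L)
  expect_equal(interspersedFraction(sm), 51.44)
})

test_that("write/parse round-trips the .out dialect and handles empty input", {
  sim <- simulateLocus(simConfig(seed = 3))
  f <- tempfile(fileext = ".out")
  writeRepeatMaskerOut(sim@repeats, f)
  back <- parseRepeatMaskerOut(f)
  expect_equal(as.data.frame(repeatFeatures(back)),
               as.data.frame(repeatFeatures(sim@repeats)))
  expect_equal(BiocGenerics::width(repeatRegion(back)),
               BiocGenerics::width(repeatRegion(sim@repeats)))

  empty <- parseRepeatMaskerOut(character(0))
  expect_length(repeatFeatures(empty), 0L)
  expect_s4_class(empty, "RepeatTable")
})

test_that("malformed rows are rejected with the offending line number", {
  good <- readLines(fixtureOut)
  bad <- good
  bad[3] <- gsub("925", "abc", bad[3])
  expect_error(parseRepeatMaskerOut(bad), "line 3")
  bad2 <- good
  bad2[4] <- sub("1267\\s+1581", "1581   1267", bad2[4])
  expect_error(parseRepeatMaskerOut(bad2), "line 4.*end.*begin")
  bad3 <- good
  bad3[5] <- sub(" C ", " Z ", bad3[5])
  expect_error(parseRepeatMaskerOut(bad3), "orientation")
})

test_that("merged coverage matches a per-base occupancy oracle on random tables", {
  set.seed(61)
  for (rep in 1:15) {
    n <- sample(3:12, 1)
    regionLength <- 500L
    starts <- sample(1:400, n)
    ends <- pmin(starts + sample(10:120, n, replace = TRUE), regionLength)
    cls <- sample(c("SINE/Alu", "LINE/L1", "Simple_repeat"), n,
                  replace = TRUE)
    o <- order(starts)
    tab <- makeTable(starts[o], ends[o], rep("+", n), cls[o], cls[o],
                     seq_len(n), regionLength)
    sm <- summarizeRepeats(tab)
    fam <- repeatCoverageByFamily(sm)
    # conservation: per-family merged bp sums to the per-family bitmaps,
    # and the interspersed total to the union of non-simple intervals
    for (k in unique(cls)) {
      sel <- cls[o] == k
      expect_equal(fam$coveredBp[fam$classFamily == k],
                   bitmapCoverage(starts[o][sel], ends[o][sel],
                                  regionLength))
    }
    sel <- cls[o] != "Simple_repeat"
    expected <- if (any(sel))
      bitmapCoverage(starts[o][sel], ends[o][sel], regionLength) else 0L
    expect_equal(interspersedBp(sm), expected)
  }
})

test_that("element counting is invariant under fragmenting a feature", {
  whole <- makeTable(c(100L, 300L), c(200L, 400L), c("+", "+"),
                     c("L1Syn", "L1Syn"), c("LINE/L1", "LINE/L1"),
                     c(1L, 2L), 1000L)
  split <- makeTable(c(100L, 140L, 300L), c(139L, 200L, 400L),
                     c("+", "+", "+"), rep("L1Syn", 3), rep("LINE/L1", 3),
                     c(1L, 1L, 2L), 1000L)
  sWhole <- summarizeRepeats(whole)
  sSplit <- summarizeRepeats(split)
  expect_equal(repeatCoverageByClass(sWhole)$elementCount,
               repeatCoverageByClass(sSplit)$elementCount)
  expect_equal(interspersedBp(sWhole), interspersedBp(sSplit))
})

test_that("the co-oriented same-subfamily Alu pair is nominated from the synthetic locus", {
  sim <- simulateLocus(simConfig(seed = 5))
  pairs <- findRecombinogenicPairs(sim@repeats, sim@reference,
                                   minIdentity = 80)
  expect_gt(nrow(pairs), 0L)
  top <- as.data.frame(pairs)[1, ]
  expect_equal(top$nameA, "AluSyn2")
  expect_equal(top$nameB, "AluSyn2")
  expect_equal(top$strand, "+")
  # the planted deletion length falls inside the predicted range
  expect_lte(top$delMin, deletionLength(sim@truth))
  expect_gte(top$delMax, deletionLength(sim@truth))

  # planting two identical copies yields a 100%-identity top pair
  ref <- randSeq(2000)
  copy <- randSeq(150)
  ref <- paste0(substr(ref, 1, 299), copy, substr(ref, 450, 1199), copy,
                substr(ref, 1350, 2000))
  tab <- makeTable(c(300L, 1200L), c(449L, 1349L), c("+", "+"),
                   c("AluX", "AluX"), c("SINE/Alu", "SINE/Alu"), 1:2,
                   nchar(ref))
  p2 <- findRecombinogenicPairs(tab, ref, minIdentity = 90)
  expect_equal(as.data.frame(p2)$identity[1], 100)
  expect_equal(as.data.frame(p2)$delMin[1], 1200L - 449L)
  expect_equal(as.data.frame(p2)$delMax[1], 1349L - 300L)

  # a single repeat cannot form a pair
  single <- makeTable(300L, 449L, "+", "AluX", "SINE/Alu", 1L, nchar(ref))
  expect_equal(nrow(findRecombinogenicPairs(single, ref)), 0L)

  # reference / region length mismatch is an error
  expect_error(findRecombinogenicPairs(tab, substr(ref, 1, 500)),
               "length")
})

test_that("relaxing the subfamily constraint admits cross-subfamily pairs", {
  ref <- randSeq(1500)
  copy <- randSeq(120)
  ref <- paste0(substr(ref, 1, 199), copy, substr(ref, 320, 899), copy,
                substr(ref, 1020, 1500))
  tab <- makeTable(c(200L, 900L), c(319L, 1019L), c("+", "+"),
                   c("AluY", "AluSx"), c("SINE/Alu", "SINE/Alu"), 1:2,
                   nchar(ref))
  expect_equal(nrow(findRecombinogenicPairs(tab, ref, minIdentity = 90)), 0L)
  relaxed <- findRecombinogenicPairs(tab, ref, minIdentity = 90,
                                     sameFamilyOnly = FALSE)
  expect_equal(nrow(relaxed), 1L)
})

test_that("BED export uses 0-based half-open coordinates", {
  tab <- makeTable(100L, 150L, "-", "AluX", "SINE/Alu", 1L, 500L)
  f <- tempfile(fileext = ".bed")
  exportRepeatsBed(tab, f)
  fields <- strsplit(readLines(f), "\t")[[1]]
  expect_equal(as.integer(fields[2]), 99L)
  expect_equal(as.integer(fields[3]), 150L)
  expect_equal(fields[6], "-")
})
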