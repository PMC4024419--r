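test_that("verbatim and reverse-complement primer occurrences are found", {
  tmpl <- paste0(randSeq(50), "ACGTACGTTGCA", randSeq(50))
  p <- primer("p1", "ACGTACGTTGCA")
  sites <- findBindingSites(tmpl, p)
  plus <- sites[sites$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$start, 51L)
  expect_equal(plus$mismatches, 0L)

  rcTmpl <- revcompStr(tmpl)
  rcSites <- findBindingSites(rcTmpl, p)
  expect_equal(nrow(rcSites[rcSites$strand == "-", ]), 1L)

  # primer longer than template: empty, not an error
  expect_equal(nrow(findBindingSites("ACGT", primer("p", "ACGTACGT"))), 0L)
})

test_that("binding sites equal an exhaustive both-strand scan on random templates", {
  set.seed(81)
  for (rep in 1:25) {
    tmpl <- randSeq(200)
    plen <- sample(8:12, 1)
    # half the time embed a (possibly mutated) copy so hits exist
    pseq <- if (rep %% 2 == 0) {
      s <- sample(1:(200 - plen), 1)
      x <- substr(tmpl, s, s + plen - 1)
      if (rep %% 4 == 0) substr(x, 2, 2) <- "N"
      x
    } else randSeq(plen)
    mm <- sample(0:2, 1)
    e3 <- sample(3:5, 1)
    got <- findBindingSites(tmpl, primer("p", pseq), maxMismatch = mm,
                            exact3Prime = e3)
    want <- bruteSites(tmpl, pseq, maxMismatch = mm, exact3 = e3)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got[, c("start", "end", "strand", "mismatches")],
                 want[, c("start", "end", "strand", "mismatches")])
  }
})

test_that("amplicon prediction equals brute-force site-pair enumeration", {
  set.seed(82)
  for (rep in 1:15) {
    tmpl <- randSeq(400)
    fs <- sample(1:150, 1); rs <- sample(200:380, 1)
    fwd <- substr(tmpl, fs, fs + 19)
    rev <- revcompStr(substr(tmpl, rs, rs + 19))
    pair <- primerPair(primer("F", fwd), primer("R", rev))
    got <- predictAmplicons(tmpl, pair, maxProductLen = 300)
    want <- bruteAmplicons(tmpl, fwd, rev, maxProductLen = 300)
    expect_equal(got[, c("start", "end", "size", "detectable")], want)
    expect_true(all(got$size == got$end - got$start + 1))
  }
})

test_that("a deletion strictly inside an amplicon shortens it by its exact length", {
  sim <- simulateLocus(simConfig(seed = 13))
  ref <- as.character(sim@reference)
  mut <- as.character(sim@deletedAllele)
  dS <- BiocGenerics::start(deletionRange(sim@truth))
  dE <- BiocGenerics::end(deletionRange(sim@truth))
  fwd <- substr(ref, dS - 400, dS - 400 + 21)
  rev <- revcompStr(substr(ref, dE + 380, dE + 380 + 21))
  pair <- primerPair(primer("F", fwd), primer("R", rev))
  wt <- predictAmplicons(ref, pair, maxProductLen = 20000)
  mu <- predictAmplicons(mut, pair, maxProductLen = 20000)
  expect_equal(nrow(wt), 1L)
  expect_equal(nrow(mu), 1L)
  expect_equal(mu$size, wt$size - deletionLength(sim@truth))
})

test_that("products mirror exactly under strand reversal", {
  set.seed(83)
  for (rep in 1:10) {
    tmpl <- randSeq(300)
    fs <- sample(1:100, 1); rs <- sample(150:270, 1)
    fwd <- substr(tmpl, fs, fs + 17)
    rev <- revcompStr(substr(tmpl, rs, rs + 17))
    a <- predictAmplicons(tmpl, primerPair(primer("F", fwd),
                                           primer("R", rev)))
    b <- predictAmplicons(revcompStr(tmpl),
                          primerPair(primer("F", rev), primer("R", fwd)))
    expect_equal(sort(a$size), sort(b$size))
    # mirrored coordinates: start' = n - end + 1
    expect_equal(sort(nchar(tmpl) - a$end + 1L), sort(b$start))
  }
})

test_that("nonspecific extra sites yield multiple reported products", {
  core <- randSeq(60)
  site <- "GATTACAGATTACAGGAATTC"
  tmpl <- paste0(site, core, site, randSeq(40),
                 revcompStr("CCTAGGCCTAGGCATCATCAT"), randSeq(30))
  pair <- primerPair(primer("F", site), primer("R", "CCTAGGCCTAGGCATCATCAT"))
  amp <- predictAmplicons(tmpl, pair, maxProductLen = 1000)
  expect_equal(nrow(amp), 2L)   # two forward sites, one reverse site
})

test_that("the two-reaction genotype call covers its whole truth table", {
  expect_equal(callGenotype(TRUE, FALSE)$call, "WT")
  expect_equal(callGenotype(TRUE, TRUE)$call, "HET")
  expect_equal(callGenotype(FALSE, TRUE)$call, "HOM_DEL")
  expect_equal(callGenotype(FALSE, FALSE)$call, "UNINFORMATIVE")
  expect_error(callGenotype(NA, TRUE))
})

test_that("the packaged primer panel loads with its annotated sizes", {
  panel <- readPrimerPanel(system.file("extdata", "polh_primer_panel.tsv",
                                       package = "aludel"))
  expect_length(panel, 6L)
  jn <- panel$POLHdel
  expect_equal(jn@forward@name, "POLHdelF")
  expect_equal(as.character(jn@forward@seq), "CATGTGCTTGTTGGACATTTG")
  expect_equal(jn@expectedWtSize, 4526)
  expect_equal(jn@expectedMutSize, 500)
  expect_equal(panel$XPV10@expectedWtSize, 459)
  expect_true(is.na(panel$XPV10@expectedMutSize))
})
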