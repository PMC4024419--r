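test_that("simulation is byte-identical under the same config and seed", {
  s1 <- simulateLocus(simConfig(seed = 21))
  s2 <- simulateLocus(simConfig(seed = 21))
  expect_identical(as.character(s1@reference), as.character(s2@reference))
  expect_identical(as.character(s1@deletedAllele),
                   as.character(s2@deletedAllele))
  expect_identical(as.character(s1@junctionReads),
                   as.character(s2@junctionReads))
  expect_identical(s1@pedigree, s2@pedigree)
  expect_identical(s1@manifest, s2@manifest)
  s3 <- simulateLocus(simConfig(seed = 22))
  expect_false(identical(as.character(s1@reference),
                         as.character(s3@reference)))
})

test_that("the sub-streams are independent: the pedigree plan does not alter the sequence", {
  ped <- defaultPedigreePlan()
  ped$nFamilies <- 3L
  s1 <- simulateLocus(simConfig(seed = 21))
  s2 <- simulateLocus(simConfig(seed = 21, pedigree = ped))
  expect_identical(as.character(s1@reference), as.character(s2@reference))
  expect_identical(s1@manifest$crossover, s2@manifest$crossover)
  expect_false(identical(nrow(s1@pedigree), nrow(s2@pedigree)))
})

test_that("the deleted allele conserves length and the truth call is self-consistent", {
  sim <- simulateLocus(simConfig(seed = 25))
  expect_equal(length(sim@deletedAllele),
               length(sim@reference) - deletionLength(sim@truth))
  # removing the truth interval from the reference gives the deleted allele
  dS <- BiocGenerics::start(deletionRange(sim@truth))
  dE <- BiocGenerics::end(deletionRange(sim@truth))
  expect_equal(deleteStr(as.character(sim@reference), dS, dE),
               as.character(sim@deletedAllele))
  # every placement in the ambiguity window is equivalent
  aS <- BiocGenerics::start(ambiguityWindow(sim@truth))
  aE <- BiocGenerics::end(ambiguityWindow(sim@truth))
  len <- deletionLength(sim@truth)
  for (sp in aS:aE)
    expect_equal(deleteStr(as.character(sim@reference), sp, sp + len - 1),
                 as.character(sim@deletedAllele))
  # default layout: deletion length is the distance between the copy starts
  expect_equal(deletionLength(sim@truth), 6991L - 3081L)
})

test_that("the truth repeat table reproduces the planned per-class coverage", {
  cfg <- simConfig(seed = 27)
  sim <- simulateLocus(cfg)
  sm <- summarizeRepeats(sim@repeats)
  plan <- cfg$repeatPlan
  fam <- repeatCoverageByFamily(sm)
  for (k in unique(plan$classFamily)) {
    expect_equal(fam$coveredBp[fam$classFamily == k],
                 sum(plan$length[plan$classFamily == k]))
  }
  expect_equal(interspersedBp(sm),
               sum(plan$length[plan$classFamily != "Simple_repeat"]))
  # about half the window is interspersed repeats
  expect_gt(interspersedFraction(sm), 45)
  expect_lt(interspersedFraction(sm), 58)
})

test_that("invalid plans are rejected", {
  plan <- defaultRepeatPlan()
  plan$start[2] <- plan$start[1] + 10L
  expect_error(simConfig(repeatPlan = plan), "overlapping")
  plan2 <- defaultRepeatPlan()
  plan2$divergence[1] <- 80
  expect_error(simConfig(repeatPlan = plan2), "divergence")
  expect_error(simConfig(junction = list(flank = 500, errorRate = 0.5)),
               "error rate")
  # only one copy of the crossover subfamily
  plan3 <- defaultRepeatPlan()
  plan3$repeatName[plan3$start == 6991] <- "AluSynX"
  expect_error(simulateLocus(simConfig(repeatPlan = plan3)),
               "no eligible repeat pair")
})

test_that("crossover between copies sharing no long identical block errs out", {
  set.seed(31)
  ref <- randSeq(2000)
  # two unrelated 100 bp windows: no 20 bp identical block exists
  expect_error(
    simulateCrossoverDeletion(ref, IRanges::IRanges(200, 299),
                              IRanges::IRanges(1200, 1299),
                              minBlock = 20),
    "identical block")
  expect_error(
    simulateCrossoverDeletion(ref, IRanges::IRanges(200, 299),
                              IRanges::IRanges(1200, 1299),
                              offset = 50, minBlock = 20),
    "identical block")
})

test_that("zero-divergence copies give microhomology equal to the full overlap", {
  plan <- defaultRepeatPlan()
  plan$divergence[plan$repeatName == "AluSyn2"] <- 0
  cfg <- simConfig(seed = 33, repeatPlan = plan,
                   crossover = list(pairName = "AluSyn2", offset = NULL,
                                    mhLen = NULL))
  sim <- simulateLocus(cfg)
  dS <- BiocGenerics::start(deletionRange(sim@truth))
  dE <- BiocGenerics::end(deletionRange(sim@truth))
  placements <- slidePlacements(as.character(sim@reference), dS, dE)
  expect_equal(microhomology(sim@truth), length(placements) - 1L)
  # identical 310 bp copies slide across (at least) the whole copy length
  expect_gte(microhomology(sim@truth), 309L)
})

test_that("equal crossover yields the positional deletion length for any offset", {
  set.seed(35)
  copy <- randSeq(300)
  ref <- paste0(randSeq(3080), copy, randSeq(6990 - 3080 - 300), copy,
                randSeq(500))
  for (off in c(1, 150, 299)) {
    cross <- simulateCrossoverDeletion(ref, IRanges::IRanges(3081, 3380),
                                       IRanges::IRanges(6991, 7290),
                                       offset = off)
    expect_equal(deletionLength(cross$call), 6991L - 3081L)
    expect_equal(nchar(ref) - 3910L, length(cross$deletedAllele))
  }
})

test_that("pedigree simulation transmits the founder haplotype identically by descent", {
  plan <- defaultPedigreePlan()
  gts <- simulatePedigreeGenotypes(plan, seed = 37)
  aff <- gts[gts$affected, ]
  expect_true(all(aff$allele_a == aff$allele_b))
  expect_true(all(aff$allele_a[aff$marker == "D6S1582"] == 129L))
  expect_true(all(aff$allele_a[aff$marker == "D6S271"] == 188L))
  car <- gts[!gts$affected, ]
  expect_true(all(car$allele_a[car$marker == "D6S1582"] == 129L))

  plan0 <- plan; plan0$nFamilies <- 0L
  expect_equal(nrow(simulatePedigreeGenotypes(plan0)), 0L)

  planBad <- plan
  planBad$freqs$D6S1582 <- c("129" = 0.7, "131" = 0.7)
  expect_error(simulatePedigreeGenotypes(planBad), "frequencies")
})

test_that("written artifacts round-trip through their standard formats", {
  sim <- simulateLocus(simConfig(seed = 39))
  dir <- file.path(tempdir(), "simout39")
  paths <- writeSimulatedLocus(sim, dir)
  expect_true(all(file.exists(paths)))
  ref <- Biostrings::readDNAStringSet(paths["reference"])[[1]]
  expect_equal(as.character(ref), as.character(sim@reference))
  back <- parseRepeatMaskerOut(paths["repeats_out"])
  expect_equal(as.data.frame(repeatFeatures(back)),
               as.data.frame(repeatFeatures(sim@repeats)))
  man <- jsonlite::read_json(paths["manifest"], simplifyVector = TRUE)
  expect_equal(man$crossover$delLength, deletionLength(sim@truth))
  gts <- readGenotypes(paths["genotypes"])
  expect_equal(nrow(gts), nrow(sim@pedigree))
})

test_that("junction mapping recovers the planted truth on error-free reads", {
  for (seed in 41:60) {
    sim <- simulateLocus(simConfig(seed = seed))
    call <- mapDeletionJunction(sim@reference, sim@junctionReads[[1]],
                                refname = "synthetic_locus")
    expect_identical(deletionRange(call), deletionRange(sim@truth))
    expect_identical(microhomology(call), microhomology(sim@truth))
    expect_identical(hgvsG(call), hgvsG(sim@truth))
  }
})
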