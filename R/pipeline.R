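## Pipeline orchestration: configuration, staged execution, report
## collation. Machine outputs are written under one output directory;
## logging goes to stderr only.

.defaultPipelineConfig <- function() {
  list(seed = 1L, out = "aludel_out", simulate = TRUE,
       inputs = list(reference = NULL, repeats = NULL, junction = NULL,
                     primers = NULL, genotypes = NULL,
                     panel = c("D6S1582", "D6S271")),
       thresholds = list(minIdentity = 80, maxMismatch = 0L,
                         maxProductLen = 2000L, anchorK = 25L,
                         relax = FALSE))
}

#' Read and normalise a pipeline configuration
#'
#' Accepts a YAML file path or a list; unspecified fields fall back to
#' defaults. Precedence of effective settings in \code{\link{runPipeline}}
#' is: explicit function arguments > config file > defaults.
#'
#' @param config path to a YAML file, a list, or NULL for defaults.
#' @return a config list.
#' @export
readPipelineConfig <- function(config = NULL) {
  base <- .defaultPipelineConfig()
  user <- if (is.null(config)) list()
          else if (is.character(config)) {
            if (!file.exists(config))
              stop("config file not found: ", config)
            yaml::read_yaml(config)
          } else if (is.list(config)) config
          else stop("config must be a YAML path or a list")
  mergeList <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        mergeList(a[[nm]], b[[nm]]) else b[[nm]]
    }
    a
  }
  cfg <- mergeList(base, user)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

.log <- function(fmt, ...) message(sprintf(paste0("[aludel] ", fmt), ...))

.stagePaths <- function(out) {
  list(
    simDir = file.path(out, "simulate"),
    reference = file.path(out, "simulate", "reference.fa"),
    deleted = file.path(out, "simulate", "deleted_allele.fa"),
    junction = file.path(out, "simulate", "junction_reads.fa"),
    repeats = file.path(out, "simulate", "truth_repeats.out"),
    genotypes = file.path(out, "simulate", "genotypes.tsv"),
    manifest = file.path(out, "simulate", "truth_manifest.json"),
    summaryTsv = file.path(out, "repeat_summary.tsv"),
    summaryJson = file.path(out, "repeat_summary.json"),
    pairsTsv = file.path(out, "repeat_pairs.tsv"),
    callJson = file.path(out, "deletion_call.json"),
    callVcf = file.path(out, "deletion_call.vcf"),
    ampliconsTsv = file.path(out, "amplicons.tsv"),
    cohortTsv = file.path(out, "genotype_calls.tsv"),
    founderJson = file.path(out, "founder_report.json"),
    founderTsv = file.path(out, "haplotype_matrix.tsv"),
    reportJson = file.path(out, "report.json"),
    reportMd = file.path(out, "report.md"))
}

.resolveInput <- function(cfg, p, key, stage) {
  path <- cfg$inputs[[key]]
  if (is.null(path)) {
    path <- switch(key, reference = p$reference, repeats = p$repeats,
                   junction = p$junction, genotypes = p$genotypes, NULL)
  }
  if (is.null(path) || !file.exists(path))
    stopStage(stage, "missing input '%s' (%s)", key,
              path %||% "no path configured and no simulate output")
  path
}

#' Design diagnostic primer pairs for a simulated deletion
#'
#' Builds the two reactions of the presence/absence assay on a synthetic
#' locus: an internal pair whose footprints lie inside the deleted
#' interval (product only from an intact allele) and a junction pair
#' flanking all equivalent breakpoint placements (short product only from
#' the deletion allele; the wild-type product exceeds the standard-PCR
#' reach). Candidate primer positions are scanned deterministically until
#' each primer has a unique binding site on the wild-type reference.
#'
#' @param sim a \code{\linkS4class{SimulatedLocus}}.
#' @param primerLen primer length (default 22).
#' @param junctionMargin bp between the ambiguity window and the nearest
#'   junction-primer footprint (default 120).
#' @return list with elements \code{exonPair} and \code{junctionPair}
#'   (\code{\linkS4class{PrimerPair}} objects).
#' @export
designDiagnosticPrimers <- function(sim, primerLen = 22L,
                                    junctionMargin = 120L) {
  refB <- seqChars(sim@reference)
  refStr <- paste(refB, collapse = "")
  delS <- start(sim@truth@del); delE <- end(sim@truth@del)
  ambS <- start(sim@truth@ambiguity)
  uniqueAt <- function(s, revcomp = FALSE) {
    if (s < 1L || s + primerLen - 1L > length(refB)) return(NULL)
    bases <- refB[s:(s + primerLen - 1L)]
    if (revcomp) bases <- .revcompBases(bases)
    seq <- paste(bases, collapse = "")
    sites <- findBindingSites(refStr, primer("cand", seq))
    if (nrow(sites) == 1L) seq else NULL
  }
  scan <- function(from, step, revcomp, limit = 400L) {
    for (k in 0:limit) {
      seq <- uniqueAt(from + k * step, revcomp)
      if (!is.null(seq)) return(list(seq = seq, start = from + k * step))
    }
    stop("could not place a unique primer near position ", from)
  }
  ## internal pair: centred in the deleted interval
  mid <- (delS + delE) %/% 2L
  exF <- scan(mid - 180L, 3L, FALSE)
  exR <- scan(mid + 180L - primerLen + 1L, -3L, TRUE)
  if (exR$start <= exF$start + primerLen)
    stop("deleted interval too short for the internal reaction")
  ## junction pair: outside the ambiguity window on both sides
  jnF <- scan(ambS - junctionMargin - primerLen, -3L, FALSE)
  jnR <- scan(delE + sim@truth@mhLen + junctionMargin, 3L, TRUE)
  list(
    exonPair = primerPair(primer("SIM_EX_F", exF$seq),
                          primer("SIM_EX_R", exR$seq),
                          pairName = "internal_exon"),
    junctionPair = primerPair(primer("SIM_JN_F", jnF$seq),
                              primer("SIM_JN_R", jnR$seq),
                              pairName = "junction"))
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages of the deletion-characterisation workflow:
#' \code{simulate} (synthetic ground-truthed locus), \code{annotate}
#' (repeat-landscape summary), \code{pairs} (recombinogenic repeat-pair
#' nomination), \code{map-junction} (breakpoint and microhomology mapping
#' with HGVS output), \code{pcr} (amplicon prediction for a primer panel),
#' \code{genotype} (two-reaction diagnostic calls on a cohort),
#' \code{founder} (shared-haplotype analysis), \code{report} (collation of
#' stage outputs into JSON + Markdown), and \code{all} (everything in
#' order). Stage outputs are written atomically; re-running with unchanged
#' inputs and seed reproduces them byte-identically.
#'
#' @param subcommand one of \code{"simulate"}, \code{"annotate"},
#'   \code{"pairs"}, \code{"map-junction"}, \code{"pcr"},
#'   \code{"genotype"}, \code{"founder"}, \code{"report"}, \code{"all"}.
#' @param config YAML path, list, or NULL (see
#'   \code{\link{readPipelineConfig}}).
#' @param out output directory override.
#' @param seed seed override.
#' @param maxProductLen,minIdentity,anchorK threshold overrides.
#' @return invisibly, a list of the artifacts the subcommand produced.
#' @export
runPipeline <- function(subcommand = "all", config = NULL, out = NULL,
                        seed = NULL, maxProductLen = NULL,
                        minIdentity = NULL, anchorK = NULL) {
  known <- c("simulate", "annotate", "pairs", "map-junction", "pcr",
             "genotype", "founder", "report", "all")
  if (!subcommand %in% known)
    stop("unknown subcommand '", subcommand, "'; expected one of: ",
         paste(known, collapse = ", "))
  cfg <- readPipelineConfig(config)
  if (!is.null(out)) cfg$out <- out
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(maxProductLen)) cfg$thresholds$maxProductLen <- maxProductLen
  if (!is.null(minIdentity)) cfg$thresholds$minIdentity <- minIdentity
  if (!is.null(anchorK)) cfg$thresholds$anchorK <- anchorK
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  p <- .stagePaths(cfg$out)
  th <- cfg$thresholds
  artifacts <- list()

  stages <- if (subcommand == "all") {
    c(if (isTRUE(cfg$simulate)) "simulate", "annotate", "pairs",
      "map-junction", "pcr", "genotype", "founder", "report")
  } else subcommand

  sim <- NULL
  getSim <- function() {
    if (is.null(sim)) sim <<- simulateLocus(simConfig(seed = cfg$seed))
    sim
  }

  for (stage in stages) {
    .log("stage %s", stage)
    if (stage == "simulate") {
      paths <- writeSimulatedLocus(getSim(), p$simDir)
      artifacts$simulate <- paths
    } else if (stage == "annotate") {
      rmOut <- .resolveInput(cfg, p, "repeats", "annotate")
      rt <- parseRepeatMaskerOut(rmOut)
      sm <- summarizeRepeats(rt)
      writeAtomic(function(f) writeRepeatSummary(sm, tsv = f), p$summaryTsv)
      writeAtomic(function(f) writeRepeatSummary(sm, json = f),
                  p$summaryJson)
      artifacts$annotate <- sm
    } else if (stage == "pairs") {
      rmOut <- .resolveInput(cfg, p, "repeats", "pairs")
      refFa <- .resolveInput(cfg, p, "reference", "pairs")
      rt <- parseRepeatMaskerOut(rmOut)
      ref <- Biostrings::readDNAStringSet(refFa)[[1]]
      pr <- findRecombinogenicPairs(rt, ref,
                                    minIdentity = th$minIdentity)
      writeAtomic(function(f) writeRepeatPairs(pr, f), p$pairsTsv)
      artifacts$pairs <- pr
    } else if (stage == "map-junction") {
      refFa <- .resolveInput(cfg, p, "reference", "map-junction")
      jnFa <- .resolveInput(cfg, p, "junction", "map-junction")
      refSet <- Biostrings::readDNAStringSet(refFa)
      jn <- Biostrings::readDNAStringSet(jnFa)[[1]]
      call <- mapDeletionJunction(refSet[[1]], jn,
                                  anchorK = th$anchorK,
                                  refname = names(refSet)[1])
      writeAtomic(function(f) writeDeletionJson(call, f), p$callJson)
      writeAtomic(function(f) writeDeletionVcf(call, f, ref = refSet[[1]]),
                  p$callVcf)
      artifacts$deletion <- call
    } else if (stage == "pcr") {
      refFa <- .resolveInput(cfg, p, "reference", "pcr")
      ref <- as.character(Biostrings::readDNAStringSet(refFa)[[1]])
      templates <- list(reference = ref)
      if (file.exists(p$deleted))
        templates$deleted <-
          as.character(Biostrings::readDNAStringSet(p$deleted)[[1]])
      pairs <- if (!is.null(cfg$inputs$primers))
        readPrimerPanel(cfg$inputs$primers)
      else {
        dp <- designDiagnosticPrimers(getSim())
        list(internal_exon = dp$exonPair, junction = dp$junctionPair)
      }
      preds <- list()
      for (pn in names(pairs)) for (tn in names(templates))
        preds[[length(preds) + 1L]] <- predictAmplicons(
          templates[[tn]], pairs[[pn]],
          maxProductLen = th$maxProductLen,
          maxMismatch = th$maxMismatch, templateId = tn)
      preds <- do.call(rbind, preds)
      writeAtomic(function(f) utils::write.table(preds, f, sep = "\t",
                  quote = FALSE, row.names = FALSE), p$ampliconsTsv)
      artifacts$pcr <- preds
    } else if (stage == "genotype") {
      s <- getSim()
      dp <- designDiagnosticPrimers(s)
      ref <- as.character(s@reference)
      mut <- as.character(s@deletedAllele)
      samples <- list(control_wt = c(ref, ref))
      for (fam in unique(s@pedigree$family)) {
        inds <- unique(s@pedigree$individual[s@pedigree$family == fam])
        for (id in inds) {
          aff <- s@pedigree$affected[s@pedigree$individual == id][1]
          samples[[id]] <- if (aff) c(mut, mut) else c(ref, mut)
        }
      }
      cohort <- genotypeCohort(samples, dp$exonPair, dp$junctionPair,
                               maxProductLen = th$maxProductLen)
      writeAtomic(function(f) utils::write.table(cohort, f, sep = "\t",
                  quote = FALSE, row.names = FALSE), p$cohortTsv)
      artifacts$genotype <- cohort
    } else if (stage == "founder") {
      gtPath <- .resolveInput(cfg, p, "genotypes", "founder")
      gts <- readGenotypes(gtPath)
      panel <- cfg$inputs$panel
      prof <- homozygosityProfile(gts, panel)
      rep <- sharedHomozygousHaplotype(prof, panel,
                                       relax = isTRUE(th$relax))
      writeAtomic(function(f) writeFounderReport(rep, json = f),
                  p$founderJson)
      writeAtomic(function(f) writeFounderReport(rep, tsv = f),
                  p$founderTsv)
      artifacts$founder <- rep
    } else if (stage == "report") {
      artifacts$report <- .buildReport(cfg, p)
    }
  }
  invisible(artifacts)
}

## Collate stage outputs into one JSON + Markdown report. Numbers are
## read back from the stage files so the report cannot drift from them.
.buildReport <- function(cfg, p) {
  need <- c(summaryJson = p$summaryJson, pairsTsv = p$pairsTsv,
            callJson = p$callJson, cohortTsv = p$cohortTsv,
            founderJson = p$founderJson)
  missing <- need[!file.exists(need)]
  if (length(missing))
    stopStage("report", "missing stage artifacts: %s",
              paste(basename(missing), collapse = ", "))
  summary <- jsonlite::read_json(p$summaryJson, simplifyVector = TRUE)
  pairs <- utils::read.table(p$pairsTsv, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  call <- jsonlite::read_json(p$callJson, simplifyVector = TRUE)
  cohort <- utils::read.table(p$cohortTsv, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  founder <- jsonlite::read_json(p$founderJson, simplifyVector = TRUE)
  cfgFile <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, cfgFile, auto_unbox = TRUE, force = TRUE)
  report <- list(
    provenance = list(
      tool = "aludel",
      version = as.character(utils::packageVersion("aludel")),
      seed = cfg$seed,
      configHash = unname(tools::md5sum(cfgFile))),
    repeatLandscape = summary,
    repeatPairs = pairs,
    deletionCall = call,
    genotypeCalls = cohort,
    founder = founder)
  unlink(cfgFile)
  writeAtomic(function(f) jsonlite::write_json(report, f,
              auto_unbox = TRUE, digits = NA), p$reportJson)
  md <- c(
    "# Deletion-characterisation run report", "",
    sprintf("Seed: %d; tool version %s.", cfg$seed,
            report$provenance$version), "",
    "## Repeat landscape",
    sprintf("Region %d bp; interspersed repeats %d bp (%.2f%%).",
            summary$regionLength, summary$interspersedBp,
            summary$interspersedFraction), "",
    "## Nominated repeat pairs",
    if (nrow(pairs)) sprintf("Top pair: %s (%d-%d) / %s (%d-%d), identity %.1f%%.",
        pairs$nameA[1], pairs$startA[1], pairs$endA[1], pairs$nameB[1],
        pairs$startB[1], pairs$endB[1], pairs$identity[1])
    else "No qualifying pair.", "",
    "## Deletion call",
    sprintf("%s (length %d bp, microhomology %d bp).", call$hgvsG,
            call$length, call$mhLen), "",
    "## Genotype calls",
    sprintf("%d samples: %s.", nrow(cohort),
            paste(sprintf("%s=%d", names(table(cohort$call)),
                          as.integer(table(cohort$call))),
                  collapse = ", ")), "",
    "## Founder analysis",
    sprintf("%d of %d families support the best shared haplotype.",
            founder$familiesSupporting, founder$familiesTotal))
  writeAtomic(function(f) writeLines(md, f), p$reportMd)
  report
}
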