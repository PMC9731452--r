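#' Write/read a 7-mer count table as TSV
#'
#' Tab-separated `sevenmer`/`count` with a commented header carrying the
#' package version, the configuration hash and the sample metadata
#' (including excluded-category tallies), so tables round-trip.
#'
#' @param table A [KmerCountTable-class].
#' @param path Output path.
#' @param configHash Optional hash stamped into the header.
#' @return `path` (write) or a [KmerCountTable-class] (read), invisibly.
#' @export
writeKmerCounts <- function(table, path, configHash = NULL) {
  meta <- c(outputHeader(configHash),
            sprintf("# sample=%s replicate=%d", sampleId(table),
                    replicateIndex(table)),
            sprintf("# condition %s=%s", names(conditionLabels(table)),
                    conditionLabels(table)),
            sprintf("# excluded %s=%g", names(excludedCounts(table)),
                    excludedCounts(table)))
  writeLines(meta, path)
  cnt <- kmerCounts(table)
  suppressWarnings(write.table(
    data.frame(sevenmer = names(cnt), count = cnt),
    path, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
  invisible(path)
}

#' @rdname writeKmerCounts
#' @export
readKmerCounts <- function(path) {
  hdr <- grep("^#", readLines(path, n = 50L), value = TRUE)
  d <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE)
  parseKv <- function(lines, prefix) {
    m <- regmatches(lines, regexec(paste0("^# ", prefix,
                                          " (\\S+)=(\\S+)$"), lines))
    m <- m[lengths(m) == 3L]
    setNames(vapply(m, `[`, "", 3L), vapply(m, `[`, "", 2L))
  }
  smp <- regmatches(hdr, regexec("^# sample=(\\S+) replicate=(\\d+)$", hdr))
  smp <- smp[lengths(smp) == 3L]
  cond <- parseKv(hdr, "condition")
  excl <- parseKv(hdr, "excluded")
  kmerCountTable(setNames(d$count, d$sevenmer),
                 sampleId = if (length(smp)) smp[[1L]][2L] else "sample",
                 condition = cond,
                 replicate = if (length(smp)) as.integer(smp[[1L]][3L]) else
                   1L,
                 excluded = setNames(as.numeric(excl), names(excl)))
}

writeTsv <- function(d, path, configHash = NULL) {
  writeLines(outputHeader(configHash), path)
  suppressWarnings(write.table(d, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Run the full synthetic end-to-end analysis
#'
#' Simulates every input at the configured study conditions and runs the
#' complete pipeline: plasmid library; reporter 5'-end reads (two
#' replicates) through spike-in removal, read classification, artifact-G
#' collapsing and 7-mer counting; normalized expression with +1-stratified
#' summaries and top-subset positional frequency matrices; polysome and
#' decay count tables through the log2-ratio estimators into the regulation
#' table; motif-class, pyrimidine-run, substitution-scan, 3-mer and hybrid
#' analyses; and the CAGE-style endogenous comparison on a toy genome.
#' Writes TSV outputs plus a markdown report when `outdir` is given; all
#' randomness derives from `config@rngSeed`.
#'
#' @param config A [SimulationConfig-class].
#' @param outdir Output directory, or `NULL` to skip writing.
#' @param nReplicates Reporter/fraction/decay replicates per condition.
#' @param actdHours ActD chase duration (hours).
#' @param plasmidDepth Plasmid library sequencing depth.
#' @param deepDepth Count-level depth of the expression libraries (the
#'   detection rule needs deep coverage; see the vignette).
#' @param fracDepth,decayDepth Count-level depths of the fraction and ActD
#'   chase samples.
#' @param cageGenes,cageGenomeLen Toy CAGE experiment size.
#' @param verbose Log per-stage read-conservation tallies.
#' @return A list with all intermediate and final objects (see the
#'   vignette for a tour).
#' @export
runPipeline <- function(config = simulationConfig(), outdir = NULL,
                        nReplicates = 2L, actdHours = 2,
                        plasmidDepth = 7.5e6,
                        deepDepth = 5.5e7, fracDepth = 4e7,
                        decayDepth = 4e7,
                        cageGenes = 400L, cageGenomeLen = 6e5,
                        verbose = interactive()) {
  template <- defaultTemplate()
  cfgHash <- objectHash(list(config@rngSeed, config@depth, nReplicates,
                             actdHours, cageGenes, cageGenomeLen))
  say <- function(...) if (verbose) message(sprintf(...))
  say("pipeline seed %d, config hash %s", config@rngSeed, cfgHash)

  ## ---- reporter quantification --------------------------------------
  plasmid <- simulatePlasmidLibrary(config, depth = plasmidDepth,
                                    seed = config@rngSeed + 11L)
  reporters <- list()
  truths <- list()
  tssDist <- NULL
  for (r in seq_len(nReplicates)) {
    sim <- simulateReporterReads(template, config,
                                 seed = config@rngSeed + 20L + r)
    sp <- countAndRemoveSpikein(sim$reads, template)
    calls <- classifyReads(sp$reads, template)
    tab <- collapseCalls(calls, sampleId = paste0("reporter_rep", r),
                         condition = c(library = "reporter"),
                         replicate = r, spikeinCount = sp$count)
    say("reporter rep %d: %d reads; assigned %d; %s", r, length(sim$reads),
        totalAssigned(tab),
        paste(names(excludedCounts(tab)), excludedCounts(tab), sep = "=",
              collapse = " "))
    if (r == 1L) tssDist <- tssPositionDistribution(calls)
    reporters[[r]] <- tab
    truths[[r]] <- sim$truth
  }

  ## ---- expression ----------------------------------------------------
  ## read-level expression (recovery diagnostics at sequencing depth)
  detectedRead <- detectionFilter(reporters, minReads = 50,
                                  plus1 = c("A", "C", "T"))
  normRead <- normalizeExpression(reporters, plasmid,
                                  detected = detectedRead)
  ## deep count-level expression library (detection-complete)
  deepReps <- lapply(seq_len(nReplicates), function(r) {
    simulateExpressionCounts(config, depth = deepDepth, replicate = r)
  })
  detected <- detectionFilter(deepReps, minReads = 50,
                              plus1 = c("A", "C", "T"))
  norm <- normalizeExpression(deepReps, plasmid, detected = detected)
  strata <- plus1StratifiedSummary(norm)
  foldRange <- expressionRange(norm)
  plasmidFreq <- positionalFrequencyMatrix(
    names(kmerCounts(plasmid)), weights = as.numeric(kmerCounts(plasmid)))
  logos <- lapply(c(A = "A", C = "C"), function(nuc) {
    positionalFrequencyMatrix(topStratum(norm, nuc), plasmidFreq = plasmidFreq)
  })
  say("expression: %d detected 7-mers (deep), %.0f-fold range; %d at read level",
      length(detected), foldRange, length(detectedRead))

  ## ---- translation and decay -----------------------------------------
  psp <- list()
  decay <- list()
  regTables <- list()
  for (cond in c("control", "torin")) {
    fr <- lapply(seq_len(nReplicates), function(r) {
      simulateFractionCounts(config, cond, depth = fracDepth, replicate = r,
                             seed = config@rngSeed + 40L + r +
                               100L * (cond == "torin"))
    })
    psp[[cond]] <- pspTranslation(lapply(fr, `[[`, "polysome"),
                                  lapply(fr, `[[`, "subpolysome"))
    t0 <- lapply(seq_len(nReplicates), function(r) {
      simulateDecayCounts(config, cond, 0, depth = decayDepth,
                          replicate = r,
                          seed = config@rngSeed + 60L + r +
                            100L * (cond == "torin"))
    })
    t1 <- lapply(seq_len(nReplicates), function(r) {
      simulateDecayCounts(config, cond, actdHours, depth = decayDepth,
                          replicate = r,
                          seed = config@rngSeed + 80L + r +
                            100L * (cond == "torin"))
    })
    decay[[cond]] <- log2Ratio(t1, t0, spikein = TRUE)
    regTables <- c(regTables, lapply(fr, `[[`, "polysome"),
                   lapply(fr, `[[`, "subpolysome"), t0, t1)
  }
  regDetected <- detectionFilter(regTables, minReads = 50,
                                 plus1 = c("A", "C", "T"))
  reg <- regulationTable(psp$control, psp$torin, decay$control, decay$torin,
                         detected = regDetected)
  deltaTest <- conditionDelta(reg, "psp")
  corCtrl <- translationStabilityCorrelation(reg, "control")
  corTorin <- translationStabilityCorrelation(reg, "torin")
  say("regulation: %d 7-mers; AG vs CT delta p = %.3g", nrow(reg),
      deltaTest$p.value)

  ## ---- motifs ---------------------------------------------------------
  normVals <- setNames(norm$normalized, norm$sevenmer)[detected]
  deltaVals <- setNames(reg$delta_psp, reg$sevenmer)
  classTests <- lapply(motifClasses()[c("Inr", "TCT", "AG", "CT")],
                       function(p) classValueTest(normVals, p))
  yrun <- yrunProfile(deltaVals)
  scanPsp <- substitutionScan(deltaVals)
  scanExpr <- substitutionScan(log2(normVals))
  expr3 <- aggregateToKmer(normVals, 3L)
  delta3 <- aggregateToKmer(deltaVals, 3L)
  hybrids <- hybridRanking(expr3, delta3)

  ## ---- CAGE comparison -------------------------------------------------
  cage <- simulateCage(toyGenomeLen = cageGenomeLen, nGenes = cageGenes,
                       config = config, seed = config@rngSeed + 7L)
  ptags <- extractPromoterTags(cage$tags, cage$annotation, unique = TRUE)
  cageFreq <- tagKmerFrequencies(ptags, cage$genome, k = 3L)
  cageCmp <- compareLibraryToCage(expr3, cageFreq)
  rpGenes <- cage$annotation$gene_id[cage$annotation$gene_class == "RP"]
  rpFreq <- geneSubsetFrequencies(cage$tags, cage$annotation, rpGenes,
                                  cage$genome, k = 3L)
  say("cage: %d promoter tags; library-vs-cage rho = %.3f (p = %.2g)",
      length(ptags), cageCmp$spearman, cageCmp$p)

  result <- list(
    config = config, template = template,
    plasmid = plasmid, reporters = reporters, truths = truths,
    tssDistribution = tssDist,
    detected = detected, detectedReadLevel = detectedRead,
    regDetected = regDetected,
    expression = norm, expressionReadLevel = normRead,
    foldRange = foldRange, strata = strata,
    logos = logos, psp = psp, decay = decay, regulation = reg,
    deltaTest = deltaTest,
    correlation = list(control = corCtrl, torin = corTorin),
    classTests = classTests, yrunProfile = yrun,
    substitutionScan = list(deltaPsp = scanPsp, expression = scanExpr),
    expr3 = expr3, delta3 = delta3, hybrids = hybrids,
    cage = cage, cageFreq = cageFreq, cageComparison = cageCmp,
    rpFreq = rpFreq)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeKmerCounts(plasmid, file.path(outdir, "plasmid_counts.tsv"), cfgHash)
    for (r in seq_len(nReplicates)) {
      writeKmerCounts(reporters[[r]],
                      file.path(outdir, sprintf("reporter_rep%d.tsv", r)),
                      cfgHash)
    }
    writeTsv(norm, file.path(outdir, "normalized_expression.tsv"), cfgHash)
    writeTsv(reg, file.path(outdir, "regulation_table.tsv"), cfgHash)
    writeTsv(yrun, file.path(outdir, "yrun_profile.tsv"), cfgHash)
    writeTsv(hybrids, file.path(outdir, "hybrid_ranking.tsv"), cfgHash)
    writeTsv(data.frame(offset = names(tssDist), fraction = tssDist),
             file.path(outdir, "tss_positions.tsv"), cfgHash)
    jsonlite::write_json(
      list(version = as.character(utils::packageVersion("capstart")),
           configHash = cfgHash, seed = config@rngSeed,
           excluded = lapply(reporters, excludedCounts),
           spikein = vapply(reporters,
                            function(t) excludedCounts(t)[["spikein"]],
                            numeric(1L)),
           tssDistribution = as.list(tssDist)),
      file.path(outdir, "qc_sidecar.json"), auto_unbox = TRUE, digits = NA)
    writePipelineReport(result, file.path(outdir, "report.md"), cfgHash)
  }
  invisible(result)
}

mdTable <- function(d, digits = 4) {
  num <- vapply(d, is.numeric, logical(1L))
  d[num] <- lapply(d[num], signif, digits)
  c(paste0("| ", paste(names(d), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(d)), collapse = "|"), "|"),
    vapply(seq_len(nrow(d)), function(i) {
      paste0("| ", paste(unlist(d[i, ]), collapse = " | "), " |")
    }, ""))
}

## markdown report with the analytic equivalents of the study's figures
writePipelineReport <- function(res, path, configHash = NULL) {
  L <- c(
    outputHeader(configHash),
    "",
    "# 5' terminal sequence analysis report",
    "",
    "## Start-position distribution (fraction of placed reads)",
    "",
    mdTable(data.frame(offset = names(res$tssDistribution),
                       fraction = as.numeric(res$tssDistribution))),
    "",
    sprintf("Detected 7-mers: %d; normalized expression fold range: %.0f.",
            length(res$detected), res$foldRange),
    "",
    "## Expression by +1 nucleotide",
    "",
    mdTable(res$strata$strata),
    "",
    sprintf("Bimodality coefficient of pooled log10 expression: %.3f.",
            res$strata$bimodality),
    "",
    "## Motif classes vs background (normalized expression)",
    "",
    mdTable(data.frame(
      class = names(res$classTests),
      classMean = vapply(res$classTests, `[[`, 0, "classMean"),
      backgroundMean = vapply(res$classTests, `[[`, 0, "backgroundMean"),
      p = vapply(res$classTests, `[[`, 0, "p.value"))),
    "",
    "## Translation delta by leading pyrimidine-run length",
    "",
    mdTable(res$yrunProfile),
    "",
    "## TOP substitution scan (delta P/SP, effect vs CYYYYNN mean)",
    "",
    mdTable(cbind(data.frame(position = rownames(res$substitutionScan$deltaPsp)),
                  as.data.frame(res$substitutionScan$deltaPsp))),
    "",
    "## Translation-stability correlation",
    "",
    mdTable(rbind(cbind(condition = "control", res$correlation$control),
                  cbind(condition = "torin", res$correlation$torin))),
    "",
    "## TCT/TOP hybrid ranking (top 10 3-mers)",
    "",
    mdTable(head(res$hybrids, 10L)),
    "",
    sprintf("Library vs CAGE 3-mer correlation: rho = %.3f (p = %.3g, n = %d).",
            res$cageComparison$spearman, res$cageComparison$p,
            res$cageComparison$n))
  writeLines(L, path)
  invisible(path)
}

#' Round-trippable run configuration
#'
#' Serializes the scalar run settings (seed, depth, thresholds, flags) to
#' YAML and back, losslessly.
#'
#' @param settings Named list of scalar settings.
#' @param path YAML path.
#' @return `path` (write) or the settings list (read).
#' @export
writeRunConfig <- function(settings, path) {
  yaml::write_yaml(settings, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  yaml::read_yaml(path)
}
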