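tpl <- defaultTemplate()

test_that("plasmid library sampling follows the composition model", {
  ## uniform bias: every 7-mer equally likely
  cfgU <- tinyConfig(seed = 1, plasmidBias = c(A = .25, C = .25, G = .25,
                                               T = .25))
  tab <- simulatePlasmidLibrary(cfgU, depth = 16384 * 60)
  gof <- suppressWarnings(stats::chisq.test(as.numeric(kmerCounts(tab))))
  expect_gt(gof$p.value, 0.001)
  ## T/G excess shows up in positional frequencies within 3 SE
  cfgB <- tinyConfig(seed = 2)
  tabB <- simulatePlasmidLibrary(cfgB, depth = 2e6)
  freq <- positionalFrequencyMatrix(names(kmerCounts(tabB)),
                                    weights = as.numeric(kmerCounts(tabB)))
  se <- sqrt(0.27 * 0.73 / 2e6)
  expect_true(all(abs(freq[, "T"] - 0.27) < 3 * se + 1e-3))
  expect_true(all(abs(freq[, "A"] - 0.23) < 3 * se + 1e-3))
  expect_error(simulatePlasmidLibrary(cfgU, depth = 0), "depth")
})

test_that("reporter reads encode the configured origins exactly", {
  ## degenerate artifact model: no read carries Gs
  cfg0 <- simulationConfig(rngSeed = 1, depth = 500,
                           gArtifactProbs = c("0" = 1),
                           spikeinFraction = 0)
  sim0 <- simulateReporterReads(tpl, cfg0)
  expect_true(all(sim0$truth$nArtifactG == 0L))
  ## fixed cassette, fixed start, one artifact G: reads are G + cassette...
  cfg1 <- simulationConfig(rngSeed = 2, depth = 300,
                           tssPositionProbs = c("0" = 1),
                           gArtifactProbs = c("1" = 1),
                           expressionModel = concentratedModel("AACCTTG"),
                           spikeinFraction = 0)
  sim1 <- simulateReporterReads(tpl, cfg1)
  expect_true(all(startsWith(sim1$reads, "GAACCTTG")))
  ## truth tables partition the reads exactly
  expect_identical(nrow(sim1$truth), length(sim1$reads))
  ## 10x rate difference recovers a 10x count ratio within 3 SE
  cfgR <- simulationConfig(rngSeed = 3, depth = 44000,
                           tssPositionProbs = c("0" = 1),
                           gArtifactProbs = c("0" = 1),
                           expressionModel = concentratedModel(
                             c("AACCTTG", "TACCTTG"), c(10, 1)),
                           plasmidBias = c(A = .25, C = .25, G = .25,
                                           T = .25),
                           spikeinFraction = 0)
  simR <- simulateReporterReads(tpl, cfgR)
  n <- table(simR$truth$sevenmer)
  p <- 10 / 11
  se <- sqrt(p * (1 - p) * cfgR@depth)
  expect_lt(abs(n[["AACCTTG"]] - p * cfgR@depth), 3 * se)
  ## generators are deterministic given the seed
  again <- simulateReporterReads(tpl, cfgR)
  expect_identical(simR$reads, again$reads)
  expect_identical(simR$truth, again$truth)
})

test_that("read length must cover the anchor seed", {
  cfg <- tinyConfig(readLength = 20L)
  expect_error(simulateReporterReads(tpl, cfg), "too short")
})

test_that("FASTQ round trip preserves simulated reads", {
  cfg <- tinyConfig(seed = 8, depth = 50)
  sim <- simulateReporterReads(tpl, cfg)
  fq <- tempfile(fileext = ".fastq")
  writeReadsFastq(sim$reads, fq)
  back <- readReadsFastq(fq)
  expect_identical(unname(back), sim$reads)
})

test_that("fraction counts split by the configured P/SP ratio", {
  ## r = 1 everywhere: 50/50 within sampling error
  tm1 <- cbind(control = rep(1, 16384), torin = rep(1, 16384))
  rownames(tm1) <- allSevenMers()
  cfg <- tinyConfig(seed = 4, translationModel = tm1)
  fr <- simulateFractionCounts(cfg, "control", depth = 4e5)
  pTot <- totalAssigned(fr$polysome)
  sTot <- totalAssigned(fr$subpolysome)
  expect_lt(abs(pTot / (pTot + sTot) - 0.5),
            3 * sqrt(0.25 / (pTot + sTot)))
  expect_error(simulateFractionCounts(cfg, "vehicle"), "arg")

  ## TOP-like switch: r 4 -> 0.25 gives a -4 recovered l2fc difference
  tm2 <- tm1
  tm2["CTCTTTT", ] <- c(4, 0.25)
  cfg2 <- tinyConfig(seed = 5, translationModel = tm2,
                     expressionModel = concentratedModel(
                       c("CTCTTTT", "AAAAAAA"), c(1, 1)))
  frC <- simulateFractionCounts(cfg2, "control", depth = 4e5)
  frT <- simulateFractionCounts(cfg2, "torin", depth = 4e5, seed = 99)
  l2c <- pspTranslation(frC$polysome, frC$subpolysome, pseudocount = 1e-9)
  l2t <- pspTranslation(frT$polysome, frT$subpolysome, pseudocount = 1e-9)
  d <- l2t$l2fc[l2t$sevenmer == "CTCTTTT"] -
    l2c$l2fc[l2c$sevenmer == "CTCTTTT"]
  expect_lt(abs(d - (-4)), 0.15)
  ## a 7-mer with zero depth is absent (zero) in both fractions
  expect_identical(unname(kmerCounts(frC$polysome)["TTTTTTT"] +
                            kmerCounts(frC$subpolysome)["TTTTTTT"]), 0L)
})

test_that("decay counts follow first-order loss of the true half-lives", {
  dm <- cbind(control = rep(2, 16384), torin = rep(2, 16384))
  rownames(dm) <- allSevenMers()
  mers <- c("AACCTTG", "CACCTTG", "TACCTTG")
  dm[mers, "control"] <- c(1, 2, 4)
  cfg <- tinyConfig(seed = 6, decayModel = dm,
                    expressionModel = concentratedModel(mers, c(1, 1, 1)))
  t0 <- simulateDecayCounts(cfg, "control", 0, depth = 6e5)
  t2 <- simulateDecayCounts(cfg, "control", 2, depth = 6e5, seed = 77)
  expect_error(simulateDecayCounts(cfg, "control", -1), "actdHours")
  ## t = 0 equals baseline composition within noise
  expect_lt(abs(totalAssigned(t0) - 6e5), 4 * sqrt(6e5))
  l2 <- log2Ratio(t2, t0, spikein = TRUE, pseudocount = 1e-9)
  got <- l2$l2fc[match(mers, l2$sevenmer)]
  ## half-life 2 h at t = 2 h: log2 ratio -1; ordering follows half-life
  expect_lt(abs(got[2] - (-1)), 0.1)
  expect_true(all(diff(got) > 0))
  expect_lt(max(abs(got - c(-2, -1, -0.5))), 0.15)
})

test_that("deep count-level expression library matches the pool composition", {
  cfg <- tinyConfig(seed = 12)
  tab <- simulateExpressionCounts(cfg, depth = 2e6)
  p <- capstart:::reporterProbs(cfg)
  expect_gt(cor(as.numeric(kmerCounts(tab)), p), 0.95)
  expect_error(simulateExpressionCounts(cfg, depth = -1), "depth")
})

test_that("toy CAGE data respect strand geometry and gene structure", {
  cfg <- tinyConfig(seed = 13)
  ## all tags at the annotated TSS
  cage <- simulateCage(toyGenomeLen = 1e5, nGenes = 20L,
                       perGeneTssModel = c("0" = 1), config = cfg,
                       rpFraction = 0.1)
  expect_identical(length(cage$genome), 1L)
  expect_setequal(unique(as.character(GenomicRanges::strand(
    cage$annotation))), c("+", "-"))
  ## tag positions coincide with annotated TSSs and counts equal gene depth
  expect_setequal(GenomicRanges::start(cage$tags),
                  GenomicRanges::start(cage$annotation))
  ord <- match(GenomicRanges::start(cage$annotation),
               GenomicRanges::start(cage$tags))
  expect_identical(as.integer(cage$tags$count[ord]),
                   as.integer(cage$truth$depth))
  ## planted start 3-mers read back from the genome in transcript sense
  ptags <- extractPromoterTags(cage$tags, cage$annotation, unique = TRUE)
  mers <- character(length(ptags))
  g <- as.character(cage$genome[[1]])
  pos <- GenomicRanges::start(ptags)
  minus <- as.character(GenomicRanges::strand(ptags)) == "-"
  mers[!minus] <- substring(g, pos[!minus], pos[!minus] + 2L)
  mers[minus] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(substring(g, pos[minus] - 2L, pos[minus]))))
  ord2 <- match(GenomicRanges::start(cage$annotation), pos)
  expect_identical(mers[ord2], cage$truth$start3mer)
  ## minus-strand genes: genomic tag positions decrease as offsets increase
  cage2 <- simulateCage(toyGenomeLen = 1e5, nGenes = 8L,
                        perGeneTssModel = c("0" = 0.5, "5" = 0.5),
                        config = cfg, rpFraction = 0)
  minusGenes <- cage2$annotation[
    as.character(GenomicRanges::strand(cage2$annotation)) == "-"]
  pt <- extractPromoterTags(cage2$tags, minusGenes, unique = FALSE)
  expect_true(all(GenomicRanges::start(pt)[pt$offset == 5] <
                    GenomicRanges::start(minusGenes[match(
                      pt$gene_id[pt$offset == 5], minusGenes$gene_id)])))
  ## too-dense gene placement warns rather than fails
  expect_warning(simulateCage(toyGenomeLen = 2e4, nGenes = 40L, config = cfg),
                 "window")
})
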