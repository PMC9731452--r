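tpl <- defaultTemplate()

test_that("findSeed locates the first exact seed occurrence", {
  expect_identical(findSeed("CCTTAAAGCCGCCGCCAAA", tpl), 6L)
  expect_identical(findSeed("CCTTAACCCCCCCCCCAAA", tpl), NA_integer_)
  ## seed present twice: first occurrence used (brute-force scan agrees)
  r2 <- paste0("TT", anchorSeed(tpl), "AA", anchorSeed(tpl))
  brute <- min(which(vapply(seq_len(nchar(r2) - 9L), function(i) {
    substr(r2, i, i + 9L) == anchorSeed(tpl)
  }, logical(1L)))) - 1L
  expect_identical(findSeed(r2, tpl), brute)
  ## occurrences beyond the scan window are not found
  expect_identical(findSeed(paste0(strrep("T", 70), anchorSeed(tpl)), tpl),
                   NA_integer_)
})

test_that("classifyRead reproduces the canonical worked examples", {
  ## definitive +1 start with a non-G base
  c1 <- classifyRead(buildRead("AACCTTG"), tpl)
  expect_identical(as.character(c1$category), "cassette_start")
  expect_identical(c1$sevenmer, "AACCTTG")
  expect_identical(c1$nStrippedG, 0L)
  ## 5'-GAACCTT: +1 G or +2 start with artifact G -- ambiguous
  c2 <- classifyRead(buildRead("GAACCTT"), tpl)
  expect_identical(as.character(c2$category), "ambiguous_plus1G")
  expect_true(is.na(c2$sevenmer))
  ## two artifact Gs over promoter T and C, retained base C at the +1
  c3 <- classifyRead(buildRead("CTCTTAA", g = 2L), tpl)
  expect_identical(as.character(c3$category), "cassette_start")
  expect_identical(c3$sevenmer, "CTCTTAA")
  expect_identical(c3$nStrippedG, 2L)
  expect_identical(c3$startOffset, 0L)
})

test_that("upstream, downstream, seedless and mismatching reads are binned", {
  up <- classifyRead(buildRead("AACCTTG", off = -2L), tpl)
  expect_identical(as.character(up$category), "upstream_start")
  expect_identical(up$startOffset, -2L)
  dn <- classifyRead(buildRead("AACCTTG", off = 2L), tpl)
  expect_identical(as.character(dn$category), "downstream_start")
  expect_identical(dn$startOffset, 2L)
  expect_identical(as.character(classifyRead(strrep("AT", 20), tpl)$category),
                   "no_seed")
  ## constant region mismatching the template is rejected, not miscounted
  bad <- buildRead("AACCTTG")
  substr(bad, 25, 25) <- "A"   # corrupt a constant base after the seed
  expect_identical(as.character(classifyRead(bad, tpl)$category), "truncated")
})

test_that("stripping is monotone: one template-mismatching G increments the
          stripped count and preserves the 7-mer", {
  set.seed(42)
  mers <- sample(grep("^[ACT]", allSevenMers(), value = TRUE), 200L)
  r0 <- buildRead(mers, g = 0L)
  r1 <- buildRead(mers, g = 1L)   # G over promoter 'C' at the -1 position
  c0 <- classifyReads(r0, tpl)
  c1 <- classifyReads(r1, tpl)
  i <- c0$category == "cassette_start"
  expect_identical(as.character(c1$category[i]),
                   rep("cassette_start", sum(i)))
  expect_identical(c1$sevenmer[i], c0$sevenmer[i])
  expect_identical(c1$nStrippedG[i], c0$nStrippedG[i] + 1L)
})

test_that("greedy classification agrees with the brute-force enumerator", {
  cfg <- tinyConfig(seed = 11, depth = 3e4)
  sim <- simulateReporterReads(tpl, cfg)
  sp <- countAndRemoveSpikein(sim$reads, tpl)
  greedy <- classifyReads(sp$reads, tpl)
  brute <- enumerateReadOrigins(sp$reads, tpl)
  expect_true(all(callsAgree(greedy, brute)))
  ## ambiguity coincides with multiple canonical consistent origins
  expect_identical(greedy$category == "ambiguous_plus1G", brute$nOrigins >= 2L)
})

test_that("read conservation: every read lands in exactly one category", {
  cfg <- tinyConfig(seed = 5, depth = 2e4)
  sim <- simulateReporterReads(tpl, cfg)
  sp <- countAndRemoveSpikein(sim$reads, tpl)
  calls <- classifyReads(sp$reads, tpl)
  expect_identical(sum(table(calls$category)), length(sp$reads))
  tab <- collapseCalls(calls, spikeinCount = sp$count)
  expect_equal(totalAssigned(tab) + sum(excludedCounts(tab)),
               length(sim$reads))
})

test_that("collapsing groups stripped-G variants and excludes +1 G 7-mers", {
  reads <- c(buildRead("AACCTTG", g = 0L), buildRead("AACCTTG", g = 1L),
             buildRead("AACCTTG", g = 2L))
  tab <- collapseCalls(classifyReads(reads, tpl))
  expect_identical(unname(kmerCounts(tab)["AACCTTG"]), 3L)
  expect_identical(totalAssigned(tab), 3L)
  ## no +1 G 7-mer is ever counted
  cfg <- tinyConfig(seed = 9, depth = 2e4)
  sim <- simulateReporterReads(tpl, cfg)
  sp <- countAndRemoveSpikein(sim$reads, tpl)
  tab2 <- collapseCalls(classifyReads(sp$reads, tpl))
  cnt <- kmerCounts(tab2)
  expect_identical(sum(cnt[startsWith(names(cnt), "G")]), 0L)
  ## counts equal the truth-table tallies for definitive +1 non-G origins
  tr <- sim$truth[!sp$isSpikein, ]
  truthTab <- table(tr$sevenmer[tr$offset == 0 &
                                  !startsWith(tr$sevenmer, "G")])
  seedClash <- grepl(substr(anchorSeed(tpl), 1L, 7L),
                     names(truthTab), fixed = TRUE)
  truthTab <- truthTab[!seedClash]  # cassettes recreating the anchor seed
  expect_identical(unname(cnt[names(truthTab)]),
                   as.integer(truthTab))
  ## empty input: totals preserved, no counts
  empty <- collapseCalls(classifyReads(strrep("AT", 20), tpl))
  expect_identical(totalAssigned(empty), 0L)
  expect_identical(sum(excludedCounts(empty)), 1)
})

test_that("collapseCalls refuses calls from mixed samples", {
  calls <- classifyReads(buildRead(c("AACCTTG", "CCCCCCC")), tpl)
  calls$sampleId <- c("a", "b")
  expect_error(collapseCalls(calls), "multiple samples")
})

test_that("spike-in reads are counted and removed, artifact Gs included", {
  sp0 <- countAndRemoveSpikein(buildRead(c("AACCTTG", "TTTTTTT")), tpl)
  expect_identical(sp0$count, 0L)
  expect_length(sp0$reads, 2L)
  spikeReads <- c(substr(spikeinSeq(tpl), 1L, 40L),
                  substr(paste0("G", spikeinSeq(tpl)), 1L, 40L))
  sp1 <- countAndRemoveSpikein(c(spikeReads, buildRead("AACCTTG")), tpl)
  expect_identical(sp1$count, 2L)
  expect_length(sp1$reads, 1L)
  cfg <- tinyConfig(seed = 2, depth = 2e4, spikeinFraction = 0.02)
  sim <- simulateReporterReads(tpl, cfg)
  sp <- countAndRemoveSpikein(sim$reads, tpl)
  expect_identical(sp$count, sum(sim$truth$spikein))
})

test_that("start-position distribution is recovered for an unambiguous
          model", {
  ## no artifact Gs and a G-free cassette universe: classification is exact
  probs <- c("-1" = 0.2, "0" = 0.48, "1" = 0.2, "2" = 0.12)
  gfree <- grep("G", allSevenMers(), value = TRUE, invert = TRUE)
  cfg <- simulationConfig(rngSeed = 3, depth = 4e4,
                          tssPositionProbs = probs,
                          gArtifactProbs = c("0" = 1),
                          expressionModel = concentratedModel(gfree),
                          spikeinFraction = 0)
  sim <- simulateReporterReads(tpl, cfg)
  calls <- classifyReads(sim$reads, tpl)
  expect_lt(sum(calls$category == "ambiguous_plus1G"), 5L)
  dist <- tssPositionDistribution(calls)
  expect_equal(sum(dist), 1)
  for (o in names(probs)) {
    se <- sqrt(probs[[o]] * (1 - probs[[o]]) / cfg@depth)
    expect_lt(abs(dist[[o]] - probs[[o]]), 3 * se + 1e-4)
  }
  ## degenerate single-position model
  cfg1 <- simulationConfig(rngSeed = 4, depth = 2e3,
                           tssPositionProbs = c("0" = 1),
                           gArtifactProbs = c("0" = 1),
                           expressionModel = concentratedModel(gfree),
                           spikeinFraction = 0)
  d1 <- tssPositionDistribution(
    classifyReads(simulateReporterReads(tpl, cfg1)$reads, tpl))
  expect_identical(names(d1), "0")
  expect_equal(unname(d1), 1)
})
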