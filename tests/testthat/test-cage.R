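## two-gene toy locus: a + strand gene at 1000 and a - strand gene at 3000
## (0-based TSS coordinates), genome engineered so the start 3-mers are CTT
## on both strands
toyLocus <- function() {
  set.seed(77)
  g <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
             collapse = "")
  substr(g, 1001, 1003) <- "CTT"             # + strand TSS at 0-based 1000
  substr(g, 2999, 3001) <- "AAG"             # - strand TSS at 0-based 3000
  genome <- Biostrings::DNAStringSet(setNames(g, "chr1"))
  ann <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = c(1001, 3001), width = 1),
    strand = c("+", "-"), gene_id = c("gplus", "gminus"),
    gene_class = c("other", "RP"))
  list(genome = genome, ann = ann)
}

tagsAt <- function(pos, strand, count) {
  GenomicRanges::GRanges("chr1",
                         IRanges::IRanges(start = pos + 1L, width = 1L),
                         strand = strand, count = as.integer(count))
}

test_that("CTSS text and BED round trips preserve tag sets", {
  tg <- tagsAt(c(10, 20, 30), c("+", "-", "+"), c(3, 1, 7))
  f <- tempfile(fileext = ".ctss")
  writeCtss(tg, f)
  back <- readCtss(f)
  expect_identical(GenomicRanges::start(back), GenomicRanges::start(tg))
  expect_identical(back$count, tg$count)
  expect_identical(as.character(GenomicRanges::strand(back)),
                   as.character(GenomicRanges::strand(tg)))
  fb <- tempfile(fileext = ".bed")
  bed <- tg
  bed$score <- bed$count
  bed$count <- NULL
  rtracklayer::export(bed, fb)
  back2 <- readCtss(fb)
  expect_identical(GenomicRanges::start(back2), GenomicRanges::start(tg))
  expect_identical(back2$count, tg$count)
})

test_that("promoter windows are strand-matched and half-open symmetric", {
  loc <- toyLocus()
  tg <- tagsAt(c(1000, 500, 501, 1499, 1500, 1000),
               c("+", "+", "+", "+", "+", "-"), rep(1, 6))
  kept <- extractPromoterTags(tg, loc$ann, window = 1000L)
  pos0 <- GenomicRanges::start(kept) - 1L
  ## the annotated TSS itself is retained; distance-500 tags are excluded
  ## on both sides; the wrong strand is excluded
  expect_setequal(pos0, c(1000, 501, 1499))
  expect_true(all(kept$gene_id == "gplus"))
  ## minus-strand offsets increase leftward in genomic coordinates
  tgM <- tagsAt(c(3000, 2900, 3100), rep("-", 3), rep(1, 3))
  keptM <- extractPromoterTags(tgM, loc$ann)
  expect_identical(keptM$offset[match(c(3001, 2901, 3101),
                                      GenomicRanges::start(keptM))],
                   c(0L, 100L, -100L))
  expect_error(extractPromoterTags(
    GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 1), strand = "+",
                           count = 1L), loc$ann), "chromosome")
})

test_that("overlapping windows assign tags to all genes but count once
          globally", {
  ann2 <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = c(1001, 1101), width = 1),
    strand = "+", gene_id = c("g1", "g2"))
  tg <- tagsAt(1050, "+", 4)
  both <- extractPromoterTags(tg, ann2)
  expect_identical(sort(both$gene_id), c("g1", "g2"))
  once <- extractPromoterTags(tg, ann2, unique = TRUE)
  expect_identical(length(once), 1L)
})

test_that("tag k-mer frequencies are strand-aware, weighted and +1 G
          filtered", {
  loc <- toyLocus()
  ## + strand tag reading CTT
  f1 <- tagKmerFrequencies(tagsAt(1000, "+", 5), loc$genome, k = 3)
  expect_equal(unname(f1["CTT"]), 1)
  expect_equal(sum(f1), 1)
  ## - strand tag over plus-strand AAG reads CTT in transcript sense
  f2 <- tagKmerFrequencies(tagsAt(3000, "-", 5), loc$genome, k = 3)
  expect_equal(unname(f2["CTT"]), 1)
  ## count weighting 3:1
  tg <- c(tagsAt(1000, "+", 3), tagsAt(3000, "-", 1))
  f3 <- tagKmerFrequencies(tg, loc$genome, k = 3, excludePlus1G = FALSE)
  expect_equal(unname(f3["CTT"]), 1)  # both read CTT
  g <- as.character(loc$genome[[1]])
  substr(g, 1001, 1003) <- "ACT"
  genome2 <- Biostrings::DNAStringSet(setNames(g, "chr1"))
  f4 <- tagKmerFrequencies(tg, genome2, k = 3, excludePlus1G = FALSE)
  expect_equal(unname(f4[c("ACT", "CTT")]), c(0.75, 0.25))
  ## +1 G exclusion renormalizes but preserves A/C/T ratios
  substr(g, 1001, 1003) <- "GCT"
  genome3 <- Biostrings::DNAStringSet(setNames(g, "chr1"))
  f5 <- tagKmerFrequencies(tg, genome3, k = 3)
  expect_equal(unname(f5["CTT"]), 1)
  expect_equal(sum(f5), 1)
  ## tags at contig edges are dropped with a warning
  expect_warning(
    fEdge <- tagKmerFrequencies(c(tagsAt(4999, "+", 1), tagsAt(1000, "+", 1)),
                                loc$genome, k = 3),
    "contig end")
  expect_equal(sum(fEdge), 1)
})

test_that("mirroring the genome leaves k-mer frequencies unchanged", {
  cfg <- tinyConfig(seed = 41)
  cage <- simulateCage(toyGenomeLen = 1e5, nGenes = 60L, config = cfg)
  freq <- tagKmerFrequencies(
    extractPromoterTags(cage$tags, cage$annotation, unique = TRUE),
    cage$genome, k = 3)
  len <- Biostrings::width(cage$genome)[1]
  mirrorGenome <- Biostrings::reverseComplement(cage$genome)
  names(mirrorGenome) <- names(cage$genome)
  flip <- function(gr) {
    out <- gr
    GenomicRanges::ranges(out) <- IRanges::IRanges(
      start = len - GenomicRanges::start(gr) + 1L, width = 1L)
    GenomicRanges::strand(out) <- ifelse(
      as.character(GenomicRanges::strand(gr)) == "+", "-", "+")
    out
  }
  freqM <- tagKmerFrequencies(
    extractPromoterTags(flip(cage$tags), flip(cage$annotation),
                        unique = TRUE),
    mirrorGenome, k = 3)
  expect_equal(freq, freqM)
})

test_that("library-CAGE comparison is significant for linked simulations and
          calibrated under permutation", {
  cfg <- tinyConfig(seed = 42)
  cage <- simulateCage(toyGenomeLen = 3e5, nGenes = 250L, config = cfg)
  freq <- tagKmerFrequencies(
    extractPromoterTags(cage$tags, cage$annotation, unique = TRUE),
    cage$genome, k = 3)
  expr3 <- aggregateToKmer(cfg@expressionModel, 3L)
  cmp <- compareLibraryToCage(expr3, freq)
  expect_identical(cmp$n, 48L)
  expect_gt(cmp$spearman, 0.4)
  expect_lt(cmp$p, 1e-5)
  expect_equal(compareLibraryToCage(freq, freq)$spearman, 1)
  ## permutation null: p-values roughly uniform
  set.seed(43)
  pv <- replicate(200, {
    compareLibraryToCage(setNames(sample(expr3), names(expr3)), freq)$p
  })
  expect_gt(mean(pv < 0.05), 0.005)
  expect_lt(mean(pv < 0.05), 0.15)
  expect_error(compareLibraryToCage(expr3[1:5], freq[1:5]), "10 shared")
})

test_that("gene-subset frequencies respect the subset and recover RP
          hybrids", {
  cfg <- tinyConfig(seed = 44)
  cage <- simulateCage(toyGenomeLen = 3e5, nGenes = 250L, config = cfg,
                       rpFraction = 0.1)
  allGenes <- cage$annotation$gene_id
  fAll <- geneSubsetFrequencies(cage$tags, cage$annotation, allGenes,
                                cage$genome, k = 3)
  fGlobal <- tagKmerFrequencies(
    extractPromoterTags(cage$tags, cage$annotation, unique = TRUE),
    cage$genome, k = 3)
  expect_equal(fAll, fGlobal)
  rp <- cage$annotation$gene_id[cage$annotation$gene_class == "RP"]
  fRP <- geneSubsetFrequencies(cage$tags, cage$annotation, rp, cage$genome,
                               k = 3)
  hyb <- c("CTC", "CCT", "CCC", "CTT")
  expect_gt(sum(fRP[hyb]), 0.5)
  expect_true(all(fRP[hyb] >= sort(fRP[setdiff(names(fRP), hyb)],
                                   decreasing = TRUE)[1] * 0.5))
  ## single-gene list and missing ids
  f1 <- geneSubsetFrequencies(cage$tags, cage$annotation, allGenes[1],
                              cage$genome, k = 3)
  expect_equal(sum(f1), 1)
  expect_warning(geneSubsetFrequencies(cage$tags, cage$annotation,
                                       c(allGenes[1], "nope"), cage$genome,
                                       k = 3), "not in the annotation")
})
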