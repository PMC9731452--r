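#' Simulate the plasmid 7-mer library
#'
#' Draws per-7-mer counts for the input plasmid library multinomially from
#' the composition-biased cassette probabilities (the randomized synthesis
#' carries a mild T/G excess by default). At the default depth nearly every
#' 7-mer is observed.
#'
#' @param config A [SimulationConfig-class].
#' @param depth Total plasmid reads (default `3 * config@depth`).
#' @param seed RNG seed (default the config's).
#' @return A [KmerCountTable-class] with sample id `"plasmid"`.
#' @export
simulatePlasmidLibrary <- function(config, depth = 3 * config@depth,
                                   seed = config@rngSeed) {
  if (depth <= 0) stop("depth must be > 0")
  set.seed(seed)
  p <- plasmidProbs(config)
  counts <- as.integer(rmultinom(1L, round(depth), p))
  kmerCountTable(setNames(counts, names(p)), sampleId = "plasmid",
                 condition = c(library = "plasmid"))
}

#' Simulate reporter 5'-end reads with ground truth
#'
#' Emits reads as sequenced from the reporter library: each read is a
#' sampled number of non-templated Gs followed by the mRNA 5' sequence from
#' a sampled start offset, with cassette 7-mers drawn in proportion to
#' plasmid frequency times transcription rate; a configured fraction of
#' reads is spike-in. The returned truth table annotates every read's true
#' origin (start offset, artifact G count, cassette 7-mer, spike-in flag)
#' and partitions the output exactly.
#'
#' @param template A [ConstructTemplate-class].
#' @param config A [SimulationConfig-class].
#' @param depth Number of reads (default `config@depth`).
#' @param seed RNG seed (default the config's).
#' @return A list with `reads` (character vector) and `truth` (data.frame
#'   with columns `offset`, `nArtifactG`, `sevenmer`, `spikein`).
#' @export
simulateReporterReads <- function(template, config, depth = config@depth,
                                  seed = config@rngSeed) {
  set.seed(seed)
  n <- round(depth)
  rl <- config@readLength
  L <- expectedTssIndex(template)
  minCover <- seedPosition(template) + nchar(anchorSeed(template)) - L + 3L
  if (rl < minCover) {
    stop("read length ", rl, " too short to cover the anchor seed")
  }

  offsets <- as.integer(names(config@tssPositionProbs))
  off <- offsets[sample.int(length(offsets), n, replace = TRUE,
                            prob = config@tssPositionProbs)]
  gs <- as.integer(names(config@gArtifactProbs))
  g <- gs[sample.int(length(gs), n, replace = TRUE,
                     prob = config@gArtifactProbs)]
  p <- reporterProbs(config)
  mer <- names(p)[sample.int(length(p), n, replace = TRUE, prob = p)]
  spike <- runif(n) < config@spikeinFraction

  prom <- promoterSeq(template)
  down <- substr(downstreamSeq(template), 1L, rl)
  t0 <- L + off
  gpre <- strrep("G", g)
  body <- paste0(gpre,
                 substr(rep(prom, n), pmin(t0, L) + 1L, L),
                 substr(mer, pmax(t0 - L, 0L) + 1L, 7L),
                 down)
  reads <- substr(body, 1L, rl)
  if (any(spike)) {
    sp <- spikeinSeq(template)
    if (is.na(sp)) stop("template has no spike-in sequence")
    reads[spike] <- substr(paste0(gpre[spike], sp), 1L, rl)
  }
  truth <- data.frame(offset = off, nArtifactG = g, sevenmer = mer,
                      spikein = spike, stringsAsFactors = FALSE)
  truth$offset[spike] <- NA_integer_
  truth$sevenmer[spike] <- NA_character_
  list(reads = reads, truth = truth)
}

#' Write/read simulated reads as FASTQ
#'
#' Phred-33 FASTQ with constant quality (the generator models no
#' sequencing errors).
#'
#' @param reads Character vector of read sequences.
#' @param path FASTQ path.
#' @return `path` (write) or a character vector of reads (read), invisibly
#'   named by record id.
#' @export
writeReadsFastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- paste0("read", seq_along(reads))
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(
                                strrep("I", nchar(reads))))
  invisible(path)
}

#' @rdname writeReadsFastq
#' @export
readReadsFastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}

#' Simulate a count-level reporter expression library
#'
#' Per-7-mer counts drawn directly from the reporter mRNA pool composition
#' (plasmid frequency times transcription rate), Poisson-sampled. This is
#' the count-table equivalent of sequencing the expressed library much more
#' deeply than the read-level simulator practically allows, and is used for
#' the expression analyses whose detection rule (> 50 reads in all
#' replicates) requires deep coverage of the poorly expressed strata.
#'
#' @param config A [SimulationConfig-class].
#' @param depth Expected total counts.
#' @param replicate Replicate index.
#' @param seed RNG seed.
#' @return A [KmerCountTable-class].
#' @export
simulateExpressionCounts <- function(config, depth = config@depth,
                                     replicate = 1L,
                                     seed = config@rngSeed + 300L +
                                       replicate) {
  if (depth <= 0) stop("depth must be > 0")
  set.seed(seed)
  p <- reporterProbs(config)
  kmerCountTable(setNames(rpois(length(p), depth * p), names(p)),
                 sampleId = sprintf("expression_rep%d", replicate),
                 condition = c(library = "reporter"),
                 replicate = replicate)
}

#' Simulate polysome / sub-polysome fraction counts
#'
#' Per-7-mer mRNA counts are drawn around the reporter pool composition and
#' split binomially between the polysome and sub-polysome fractions with
#' probability `r / (1 + r)`, where `r` is the condition's true P/SP ratio.
#' Spike-in counts are added to both fractions at the configured level
#' (equal spike-in amounts are added to each fraction in the protocol).
#'
#' @param config A [SimulationConfig-class].
#' @param condition `"control"` or `"torin"`.
#' @param depth Expected total mRNA counts per sample.
#' @param replicate Replicate index (also offsets the seed).
#' @param seed RNG seed.
#' @return List with `polysome` and `subpolysome` [KmerCountTable-class]
#'   objects; spike-in counts are stored in their excluded tallies.
#' @export
simulateFractionCounts <- function(config, condition = c("control", "torin"),
                                   depth = config@depth, replicate = 1L,
                                   seed = config@rngSeed + replicate) {
  condition <- match.arg(condition)
  set.seed(seed)
  p <- reporterProbs(config)
  r <- config@translationModel[, condition]
  n <- rpois(length(p), depth * p)
  poly <- rbinom(length(p), n, r / (1 + r))
  sub <- n - poly
  lam <- config@spikeinFraction * depth
  mk <- function(counts, fraction, spikeCount) {
    kmerCountTable(setNames(as.integer(counts), names(p)),
                   sampleId = sprintf("%s_%s_rep%d", condition, fraction,
                                      replicate),
                   condition = c(treatment = condition, fraction = fraction),
                   replicate = replicate,
                   excluded = c(spikein = spikeCount))
  }
  list(polysome = mk(poly, "polysome", rpois(1L, lam)),
       subpolysome = mk(sub, "subpolysome", rpois(1L, lam)))
}

#' Simulate transcription-shutoff (ActD chase) counts
#'
#' Expected per-7-mer counts at time `t` are the baseline counts times
#' `2^(-t / half-life)` under the condition's true half-lives,
#' Poisson-sampled. The spike-in level is constant across timepoints, so
#' spike-in scaling recovers absolute decay.
#'
#' @inheritParams simulateFractionCounts
#' @param actdHours Hours of Actinomycin D treatment (>= 0).
#' @return A [KmerCountTable-class]; spike-in count in the excluded tally.
#' @export
simulateDecayCounts <- function(config, condition = c("control", "torin"),
                                actdHours, depth = config@depth,
                                replicate = 1L,
                                seed = config@rngSeed + 100L * replicate +
                                  round(17 * actdHours)) {
  condition <- match.arg(condition)
  if (actdHours < 0) stop("actdHours must be >= 0")
  set.seed(seed)
  p <- reporterProbs(config)
  hl <- config@decayModel[, condition]
  lam <- depth * p * 2^(-actdHours / hl)
  counts <- rpois(length(p), lam)
  kmerCountTable(setNames(as.integer(counts), names(p)),
                 sampleId = sprintf("%s_actd%g_rep%d", condition, actdHours,
                                    replicate),
                 condition = c(treatment = condition,
                               actd = if (actdHours > 0) "plus" else "minus"),
                 replicate = replicate,
                 excluded = c(spikein = rpois(1L,
                                              config@spikeinFraction * depth)))
}

#' Simulate a CAGE-style experiment on a toy genome
#'
#' Generates a random genome, non-overlapping gene annotations on both
#' strands, and strand-aware 5' tag positions: each gene receives a start
#' 3-mer (planted into the genome at its annotated TSS in transcript
#' orientation) sampled in proportion to the library expression model, a
#' sequencing depth proportional to that 3-mer's expression, and tag
#' offsets drawn from a per-gene TSS position distribution. A configurable
#' fraction of genes is flagged as ribosomal-protein-like (`RP`): their
#' start 3-mers are drawn from the TCT/TOP hybrids (CTC, CCT, CCC, CTT) and
#' their depth is boosted.
#'
#' @param toyGenomeLen Genome length (nt, single contig).
#' @param nGenes Number of genes; a warning is issued if spacing falls
#'   below `window`.
#' @param perGeneTssModel Named numeric over transcript-orientation tag
#'   offsets relative to the annotated TSS; must sum to 1.
#' @param config A [SimulationConfig-class] (expression model and seed).
#' @param window Promoter window width used for the spacing check.
#' @param rpFraction Fraction of genes flagged `RP`.
#' @param seed RNG seed.
#' @return A list with `genome` (named [Biostrings::DNAStringSet]),
#'   `annotation` ([GenomicRanges::GRanges] of width-1 TSSs with `gene_id`,
#'   `gene_class`), `tags` (GRanges with a `count` column), and `truth`
#'   (data.frame of per-gene start 3-mers and depths).
#' @export
simulateCage <- function(toyGenomeLen = 6e5, nGenes = 400L,
                         perGeneTssModel = c("-2" = 0.05, "-1" = 0.10,
                                             "0" = 0.60, "1" = 0.10,
                                             "2" = 0.05, "5" = 0.05,
                                             "10" = 0.05),
                         config = simulationConfig(),
                         window = 1000L, rpFraction = 0.08,
                         seed = config@rngSeed) {
  stopifnot(abs(sum(perGeneTssModel) - 1) < 1e-9)
  set.seed(seed)
  genome <- paste(sample(NUCS, toyGenomeLen, replace = TRUE), collapse = "")

  spacing <- floor((toyGenomeLen - window) / nGenes)
  if (spacing < window) {
    warning("genes are closer than the promoter window width")
  }
  tss <- as.integer(window / 2 + spacing * (seq_len(nGenes) - 1L) +
                      sample.int(max(spacing - window, 1L), nGenes,
                                 replace = TRUE))
  strand <- rep(c("+", "-"), length.out = nGenes)

  expr3 <- aggregateToKmer(config@expressionModel, 3L)
  w3 <- expr3 / sum(expr3)
  mer3 <- names(w3)[sample.int(length(w3), nGenes, replace = TRUE,
                               prob = w3)]
  isRP <- seq_len(nGenes) %in% sample.int(nGenes, round(rpFraction * nGenes))
  mer3[isRP] <- sample(c("CTC", "CCT", "CCC", "CTT"), sum(isRP),
                       replace = TRUE)
  depth <- round(pmax(20, 40 * (expr3[mer3] / stats::median(expr3)) ^ 0.6 *
                        rlnorm(nGenes, 0, 0.4)))
  depth[isRP] <- depth[isRP] * 3

  ## plant each gene's start 3-mer at its TSS in transcript orientation
  for (i in seq_len(nGenes)) {
    if (strand[i] == "+") {
      substr(genome, tss[i] + 1L, tss[i] + 3L) <- mer3[i]
    } else {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(mer3[i])))
      substr(genome, tss[i] - 1L, tss[i] + 1L) <- rc
    }
  }

  offs <- as.integer(names(perGeneTssModel))
  tagList <- vector("list", nGenes)
  for (i in seq_len(nGenes)) {
    cnt <- as.integer(rmultinom(1L, depth[i], perGeneTssModel))
    pos <- if (strand[i] == "+") tss[i] + offs else tss[i] - offs
    keep <- cnt > 0L
    tagList[[i]] <- data.frame(pos = pos[keep], strand = strand[i],
                               count = cnt[keep])
  }
  tags <- do.call(rbind, tagList)
  tags <- stats::aggregate(count ~ pos + strand, tags, sum)

  genomeSet <- Biostrings::DNAStringSet(setNames(genome, "chr1"))
  annotation <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = tss + 1L, width = 1L),
    strand = strand,
    gene_id = sprintf("gene%03d", seq_len(nGenes)),
    gene_class = ifelse(isRP, "RP", "other"))
  tagSet <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = tags$pos + 1L, width = 1L),
    strand = tags$strand, count = tags$count)
  truth <- data.frame(gene_id = sprintf("gene%03d", seq_len(nGenes)),
                      tss = tss, strand = strand, start3mer = mer3,
                      depth = depth, gene_class = ifelse(isRP, "RP", "other"),
                      stringsAsFactors = FALSE)
  list(genome = genomeSet, annotation = annotation, tags = tagSet,
       truth = truth)
}
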