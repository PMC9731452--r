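## ---- Default ground-truth models -------------------------------------
##
## These encode the study conditions the pipeline is validated against:
## a bimodal ~200-fold expression distribution keyed to the +1/+2
## nucleotides, translation that is uniform under growth (~4-fold) but
## TOP-dependently repressed under mTOR inhibition (>= 16-fold), and decay
## that is narrow (~2-fold) under growth but pyrimidine-run-dependently
## stabilized under mTOR inhibition. All models are deterministic functions
## of the 7-mer (low-discrepancy jitter, no RNG state consumed) and are
## documented as synthetic: they mirror the reported regulatory rules
## qualitatively and are never a stand-in for measured values.

## repression magnitude (log2 units) of the TOP-like translation response:
## requires a +1 C; grows with the leading pyrimidine run up to 5 nt; the
## +3 pyrimidine contributes most, the +2 least.
topRepression <- function(mers) {
  runY <- leadingYRun(mers)
  p2Y <- substr(mers, 2L, 2L) %in% c("C", "T")
  p3Y <- substr(mers, 3L, 3L) %in% c("C", "T")
  ifelse(plus1(mers) == "C",
         0.3 + 0.35 * pmin(runY - 1L, 4L) + 1.1 * p3Y + 0.15 * p2Y,
         0)
}

#' Default synthetic ground-truth models
#'
#' `defaultExpressionModel()` returns relative transcription rates per
#' 7-mer: +1 A and +1 G well-expressed, +1 U poorly expressed, +1 C
#' spanning the range with a strong +2 U bonus, a mild penalty per A in
#' positions 2-7, and deterministic per-sequence spread; the two modes sit
#' about 200-fold apart. `defaultTranslationModel()` returns true
#' polysome/sub-polysome ratios under control and mTOR-inhibited (torin)
#' conditions: near-uniform in control, with TOP-motif-dependent repression
#' under torin (the repression rules are detailed in the vignette).
#' `defaultDecayModel()` returns true half-lives (hours): narrow and
#' +1-independent in control; under torin, +1 A mRNAs destabilized and
#' +1 C mRNAs stabilized in proportion to the same TOP repression quantity.
#'
#' @return Named numeric vector (expression) or a two-column matrix
#'   (`control`, `torin`) over all 16,384 7-mers.
#' @export
defaultExpressionModel <- function() {
  mers <- allSevenMers()
  idx <- kmerIndex(mers)
  u <- ldJitter(idx, 1L)
  p1 <- plus1(mers)
  p2T <- substr(mers, 2L, 2L) == "T"
  nA <- nchar(gsub("[^A]", "", substr(mers, 2L, 7L)))
  l2 <- ifelse(p1 == "A", 3 + 1.5 * (u - 0.5),
        ifelse(p1 == "G", 2.5 + 1.5 * (u - 0.5),
        ifelse(p1 == "C", -2 + 4.5 * p2T + 3 * (u - 0.5),
               -4.7 + 1.5 * (u - 0.5)))) - 0.2 * nA
  setNames(2^l2, mers)
}

#' @rdname defaultExpressionModel
#' @export
defaultTranslationModel <- function() {
  mers <- allSevenMers()
  idx <- kmerIndex(mers)
  u2 <- ldJitter(idx, 2L)
  u3 <- ldJitter(idx, 3L)
  p1 <- plus1(mers)
  runY <- leadingYRun(mers)
  l2ctrl <- ifelse(p1 == "A", 0.8,
            ifelse(p1 == "G", 0.6,
            ifelse(p1 == "C", -0.6, -0.3))) + 0.7 * (u2 - 0.5)
  delta <- ifelse(p1 == "A", 0.15,
           ifelse(p1 == "G", 0.1,
           ifelse(p1 == "T", -(0.35 + 0.1 * pmin(runY - 1L, 4L)),
                  -topRepression(mers)))) + 0.3 * (u3 - 0.5)
  m <- cbind(control = 2^l2ctrl, torin = 2^(l2ctrl + delta))
  rownames(m) <- mers
  m
}

#' @rdname defaultExpressionModel
#' @export
defaultDecayModel <- function() {
  mers <- allSevenMers()
  idx <- kmerIndex(mers)
  u4 <- ldJitter(idx, 4L)
  u5 <- ldJitter(idx, 5L)
  p1 <- plus1(mers)
  ctrl <- 4 * 2^(u4 - 0.5)
  torin <- ifelse(p1 == "A", 2.0,
           ifelse(p1 == "G", 2.2,
           ifelse(p1 == "T", 3.0, 2.6))) *
    2^(0.35 * topRepression(mers) + 0.5 * (u5 - 0.5))
  m <- cbind(control = ctrl, torin = torin)
  rownames(m) <- mers
  m
}

#' Build a simulation configuration
#'
#' Assembles a validated [SimulationConfig-class]. The defaults define the
#' study conditions used throughout the package's validation: preferential
#' initiation at the expected TSS (48% of reads) with minority starts at
#' neighboring positions, a reverse-transcription artifact appending 0-2
#' non-templated Gs per read, a mild T/G composition excess in the plasmid
#' cassette, and the ground-truth expression/translation/decay models of
#' [defaultExpressionModel()] and friends.
#'
#' @param rngSeed Integer seed for all stochastic draws.
#' @param depth Reads per reporter replicate.
#' @param tssPositionProbs Named numeric over start offsets relative to the
#'   expected TSS; must sum to 1.
#' @param gArtifactProbs Named numeric over appended non-templated G counts;
#'   must sum to 1.
#' @param plasmidBias Composition weights over A/C/G/T for cassette
#'   synthesis.
#' @param expressionModel,translationModel,decayModel Ground-truth models
#'   (see [defaultExpressionModel()]).
#' @param spikeinFraction Fraction of reads/counts that are spike-in.
#' @param readLength Simulated read length.
#' @return A [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(rngSeed = 1, depth = 1e4)
#' @export
simulationConfig <- function(rngSeed = 1L,
                             depth = 2.5e6,
                             tssPositionProbs = c(
                               "-3" = 0.02, "-2" = 0.05, "-1" = 0.15,
                               "0" = 0.48, "1" = 0.15, "2" = 0.10,
                               "3" = 0.05),
                             gArtifactProbs = c("0" = 0.4, "1" = 0.5,
                                                "2" = 0.1),
                             plasmidBias = c(A = 0.23, C = 0.23,
                                             G = 0.27, T = 0.27),
                             expressionModel = defaultExpressionModel(),
                             translationModel = defaultTranslationModel(),
                             decayModel = defaultDecayModel(),
                             spikeinFraction = 0.005,
                             readLength = 40L) {
  new("SimulationConfig",
      rngSeed = as.integer(rngSeed), depth = depth,
      tssPositionProbs = tssPositionProbs,
      gArtifactProbs = gArtifactProbs,
      plasmidBias = plasmidBias / sum(plasmidBias),
      expressionModel = expressionModel,
      translationModel = translationModel,
      decayModel = decayModel,
      spikeinFraction = spikeinFraction,
      readLength = as.integer(readLength))
}

## per-7-mer cassette probabilities implied by the composition bias
plasmidProbs <- function(config) {
  mers <- allSevenMers()
  w <- config@plasmidBias / sum(config@plasmidBias)
  p <- rep(1, length(mers))
  for (i in 1:7) p <- p * w[substr(mers, i, i)]
  setNames(p / sum(p), mers)
}

## reporter mRNA pool composition: plasmid frequency x transcription rate
reporterProbs <- function(config) {
  p <- plasmidProbs(config) * config@expressionModel
  p / sum(p)
}
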