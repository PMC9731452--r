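#' ConstructTemplate: coordinate model of the reporter construct
#'
#' Describes the reporter plasmid region against which 5'-end reads are
#' classified: the promoter sequence (template strand, mRNA sense, ending
#' immediately before the randomized cassette), the cassette length, the
#' constant downstream 5' UTR, the seed used to anchor reads, and the
#' optional spike-in sequence. Coordinates are 0-based and half-open
#' throughout; the "+1" nucleotide of the mRNA is construct coordinate
#' `expectedTssIndex`, which always equals `nchar(promoterSeq)`.
#'
#' @slot promoterSeq Promoter sequence, 5'->3', DNA alphabet.
#' @slot cassetteLen Length of the randomized cassette (7).
#' @slot downstreamSeq Constant sequence beginning immediately after the
#'   cassette.
#' @slot seed Anchor substring of `downstreamSeq` (constant-region seed,
#'   default `AGCCGCCGCC`); must occur exactly once in `downstreamSeq`.
#' @slot expectedTssIndex 0-based construct coordinate of the cassette's
#'   first nucleotide.
#' @slot spikeinSeq Spike-in mRNA sequence, or `NA_character_` when absent.
#'
#' @export
setClass("ConstructTemplate", representation(
  promoterSeq = "character",
  cassetteLen = "integer",
  downstreamSeq = "character",
  seed = "character",
  expectedTssIndex = "integer",
  spikeinSeq = "character"
))

setValidity("ConstructTemplate", function(object) {
  msgs <- character()
  for (s in c("promoterSeq", "downstreamSeq", "seed")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || !nzchar(v)) {
      msgs <- c(msgs, sprintf("'%s' must be a single non-empty string", s))
    } else if (grepl("[^ACGT]", v)) {
      msgs <- c(msgs, sprintf("'%s' contains non-ACGT characters", s))
    }
  }
  if (!length(msgs)) {
    if (object@cassetteLen < 1L) {
      msgs <- c(msgs, "cassetteLen must be >= 1")
    }
    nhit <- length(gregexpr(object@seed, object@downstreamSeq,
                            fixed = TRUE)[[1L]])
    if (regexpr(object@seed, object@downstreamSeq, fixed = TRUE) < 0L) {
      msgs <- c(msgs, "seed does not occur in downstreamSeq")
    } else if (nhit != 1L) {
      msgs <- c(msgs, "seed must occur exactly once in downstreamSeq")
    }
    if (object@expectedTssIndex != nchar(object@promoterSeq)) {
      msgs <- c(msgs, "expectedTssIndex must equal nchar(promoterSeq)")
    }
    if (!is.na(object@spikeinSeq) && grepl("[^ACGT]", object@spikeinSeq)) {
      msgs <- c(msgs, "spikeinSeq contains non-ACGT characters")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a ConstructTemplate
#'
#' @param promoterSeq,downstreamSeq,seed,spikeinSeq Sequences (U accepted,
#'   stored as T).
#' @param cassetteLen Cassette length (default 7).
#' @return A validated [ConstructTemplate-class] object.
#' @examples
#' tpl <- constructTemplate("GAACCGTC", "GCCGCAGCCGCCGCCATCG")
#' expectedTssIndex(tpl) # 8
#' @export
constructTemplate <- function(promoterSeq, downstreamSeq,
                              seed = "AGCCGCCGCC", cassetteLen = 7L,
                              spikeinSeq = NA_character_) {
  new("ConstructTemplate",
      promoterSeq = rnaToDna(promoterSeq),
      cassetteLen = as.integer(cassetteLen),
      downstreamSeq = rnaToDna(downstreamSeq),
      seed = rnaToDna(seed),
      expectedTssIndex = nchar(promoterSeq),
      spikeinSeq = if (is.na(spikeinSeq)) NA_character_ else
        rnaToDna(spikeinSeq))
}

#' KmerCountTable: per-sample counts keyed by 5' k-mer
#'
#' Holds the per-7-mer read counts for one sample together with its
#' condition labels, replicate index, and the tally of reads excluded from
#' counting by classification category (ambiguous +1 G, upstream and
#' downstream starts, spike-in, seedless and truncated reads). The
#' conservation invariant `totalAssigned(x) + sum(excludedCounts(x))` equals
#' the number of classified reads.
#'
#' @slot sampleId Sample identifier.
#' @slot condition Named character vector of condition labels (e.g.
#'   `c(treatment = "control", fraction = "polysome")`).
#' @slot replicate Replicate index.
#' @slot counts Named integer vector over the complete 7-mer universe.
#' @slot excluded Named numeric vector of excluded-read tallies.
#'
#' @export
setClass("KmerCountTable", representation(
  sampleId = "character",
  condition = "character",
  replicate = "integer",
  counts = "integer",
  excluded = "numeric"
))

setValidity("KmerCountTable", function(object) {
  msgs <- character()
  cn <- names(object@counts)
  if (is.null(cn) || anyNA(object@counts) || any(object@counts < 0L)) {
    msgs <- c(msgs, "counts must be a named non-negative integer vector")
  } else {
    k <- nchar(cn[1L])
    if (!identical(cn, allSevenMers(k))) {
      msgs <- c(msgs, "counts must be named by the complete k-mer universe")
    }
  }
  if (any(object@excluded < 0)) {
    msgs <- c(msgs, "excluded tallies must be non-negative")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a KmerCountTable
#'
#' @param counts Named integer vector (sparse allowed: missing universe
#'   members are filled with zero).
#' @param sampleId Sample identifier.
#' @param condition Named character vector of condition labels.
#' @param replicate Replicate index.
#' @param excluded Named numeric vector of excluded-read tallies.
#' @param k k-mer length of the universe (default 7).
#' @return A [KmerCountTable-class] object.
#' @export
kmerCountTable <- function(counts, sampleId = "sample",
                           condition = character(), replicate = 1L,
                           excluded = numeric(), k = 7L) {
  universe <- allSevenMers(k)
  full <- setNames(integer(length(universe)), universe)
  if (length(counts)) {
    if (is.null(names(counts))) stop("counts must be named by k-mer")
    nm <- rnaToDna(names(counts))
    bad <- setdiff(nm, universe)
    if (length(bad)) {
      stop("counts contain sequences outside the ", k, "-mer universe: ",
           paste(head(bad, 3L), collapse = ", "))
    }
    agg <- tapply(as.integer(counts), nm, sum)
    full[names(agg)] <- as.integer(agg)
  }
  new("KmerCountTable", sampleId = sampleId, condition = condition,
      replicate = as.integer(replicate), counts = full,
      excluded = excluded)
}

#' SimulationConfig: ground-truth parameters for the synthetic generator
#'
#' Bundles every parameter of the synthetic study: sequencing depth, the
#' start-position distribution around the expected TSS, the
#' reverse-transcription non-templated-G artifact model, the plasmid
#' cassette composition bias, and per-7-mer ground-truth models for
#' transcription rate, translation (polysome/sub-polysome ratios under
#' control and mTOR-inhibited conditions) and decay (half-lives in hours
#' under both conditions). Defaults encode the study conditions the
#' pipeline is validated against; see the package vignette.
#'
#' @slot rngSeed Integer seed controlling all stochastic draws.
#' @slot depth Reads per reporter replicate.
#' @slot tssPositionProbs Named numeric; names are start offsets relative to
#'   the expected TSS, values sum to 1.
#' @slot gArtifactProbs Named numeric over appended non-templated G counts
#'   ("0","1","2", ...), values sum to 1.
#' @slot plasmidBias Named numeric composition weights over A/C/G/T.
#' @slot expressionModel Relative transcription rate per 7-mer.
#' @slot translationModel Two-column matrix (control, torin) of true P/SP
#'   ratios per 7-mer.
#' @slot decayModel Two-column matrix (control, torin) of true half-lives
#'   (hours) per 7-mer.
#' @slot spikeinFraction Fraction of reads/counts that are spike-in.
#' @slot readLength Simulated read length (nt).
#'
#' @export
setClass("SimulationConfig", representation(
  rngSeed = "integer",
  depth = "numeric",
  tssPositionProbs = "numeric",
  gArtifactProbs = "numeric",
  plasmidBias = "numeric",
  expressionModel = "numeric",
  translationModel = "matrix",
  decayModel = "matrix",
  spikeinFraction = "numeric",
  readLength = "integer"
))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  if (object@depth <= 0) msgs <- c(msgs, "depth must be > 0")
  for (s in c("tssPositionProbs", "gArtifactProbs", "plasmidBias")) {
    p <- slot(object, s)
    if (is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      msgs <- c(msgs, sprintf("'%s' must be named, non-negative and sum to 1",
                              s))
    }
  }
  u <- allSevenMers()
  if (!identical(names(object@expressionModel), u) ||
      any(object@expressionModel <= 0)) {
    msgs <- c(msgs, "expressionModel must cover all 7-mers with rates > 0")
  }
  for (s in c("translationModel", "decayModel")) {
    m <- slot(object, s)
    if (!identical(rownames(m), u) ||
        !identical(colnames(m), c("control", "torin")) || any(m <= 0)) {
      msgs <- c(msgs, sprintf(
        "'%s' must be a strictly positive matrix over all 7-mers with columns control/torin", s))
    }
  }
  if (object@spikeinFraction < 0 || object@spikeinFraction >= 1) {
    msgs <- c(msgs, "spikeinFraction must be in [0, 1)")
  }
  if (length(msgs)) msgs else TRUE
})
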