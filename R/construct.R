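## Constant-region sequences of the reference reporter construct. The
## promoter fragment ends immediately before the randomized cassette; the
## downstream constant 5' UTR carries the anchor seed. The spike-in is a
## capped in-vitro transcript sharing the constant UTR.
REF_PROMOTER <- "CAGAGCTGGTTTAGTGAACCGTC"
REF_DOWNSTREAM <- "GCCGCAGCCGCCGCCATCGTCGACGCGCGCTTCCCTGTTCACC"
REF_SEED <- "AGCCGCCGCC"
REF_SPIKEIN <- paste0(
  "CTCTTCCCATGGCCGCAGCCGCCGCCATCGTCGACGCGCGCTTCCCTGTTCACCTCTGACTCTGAGAATCC",
  "GTCGCCATCCGCCACCGGCGCGCCGCTAGCCACCATGACTTCGAAAGTTTATG")

#' Reference reporter template
#'
#' The built-in [ConstructTemplate-class] for the randomized-7-mer reporter:
#' a 23-nt promoter fragment, the 7-nt cassette, and the constant
#' downstream 5' UTR containing the `AGCCGCCGCC` anchor seed, plus the
#' spike-in mRNA sequence.
#'
#' @return A [ConstructTemplate-class].
#' @examples
#' defaultTemplate()
#' @export
defaultTemplate <- function() {
  constructTemplate(REF_PROMOTER, REF_DOWNSTREAM, seed = REF_SEED,
                    spikeinSeq = REF_SPIKEIN)
}

#' Load a reporter template from FASTA plus a configuration
#'
#' Reads a single-record FASTA in which the randomized cassette is written
#' as a run of `N`s, and builds the [ConstructTemplate-class]. The cassette
#' is located by `cassetteStart`/`cassetteLen` from the configuration and
#' must be all-`N` in the FASTA (it is per-molecule unknown and never
#' compared against reads).
#'
#' @param fastaPath Path to a FASTA file with exactly one record.
#' @param config A list with elements `cassette_start` (0-based),
#'   `cassette_len` (default 7), `seed` (default `AGCCGCCGCC`) and
#'   optionally `spikein`; or a path to a YAML file with those keys.
#' @return A validated [ConstructTemplate-class].
#' @export
loadTemplate <- function(fastaPath, config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  recs <- Biostrings::readDNAStringSet(fastaPath)
  if (length(recs) != 1L) stop("template FASTA must contain exactly one record")
  full <- rnaToDna(as.character(recs[[1L]]))
  if (grepl("[^ACGTN]", full)) stop("template contains non-ACGTN characters")
  cs <- as.integer(config$cassette_start)
  cl <- as.integer(config$cassette_len %||% 7L)
  seed <- rnaToDna(config$seed %||% REF_SEED)
  cassette <- substr(full, cs + 1L, cs + cl)
  if (nchar(cassette) != cl || grepl("[^N]", cassette)) {
    stop("cassette region [", cs, ", ", cs + cl,
         ") must be exactly ", cl, " N characters")
  }
  downstream <- substr(full, cs + cl + 1L, nchar(full))
  if (regexpr(seed, downstream, fixed = TRUE) < 0L) {
    stop("seed '", seed, "' not found in the downstream constant region")
  }
  constructTemplate(substr(full, 1L, cs), downstream, seed = seed,
                    cassetteLen = cl,
                    spikeinSeq = config$spikein %||% NA_character_)
}

#' Write a reporter template to FASTA plus YAML configuration
#'
#' Inverse of [loadTemplate()]: writes the construct (cassette as `N`s) as a
#' one-record FASTA and the cassette coordinates, seed and spike-in as YAML.
#'
#' @param template A [ConstructTemplate-class].
#' @param fastaPath,configPath Output paths.
#' @return Invisibly, `fastaPath`.
#' @export
writeTemplate <- function(template, fastaPath, configPath) {
  seq <- Biostrings::DNAStringSet(constructSequence(template))
  names(seq) <- "construct"
  Biostrings::writeXStringSet(seq, fastaPath)
  cfg <- list(cassette_start = expectedTssIndex(template),
              cassette_len = cassetteLen(template),
              seed = anchorSeed(template))
  if (!is.na(spikeinSeq(template))) cfg$spikein <- spikeinSeq(template)
  yaml::write_yaml(cfg, configPath)
  invisible(fastaPath)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## full construct string with the cassette masked as N
constructSequence <- function(template) {
  paste0(template@promoterSeq, strrep("N", template@cassetteLen),
         template@downstreamSeq)
}

## 0-based construct coordinate of the seed's first base
seedPosition <- function(template) {
  template@expectedTssIndex + template@cassetteLen +
    as.integer(regexpr(template@seed, template@downstreamSeq,
                       fixed = TRUE)) - 1L
}

## template base at 0-based coordinates; NA for cassette (unknown) and
## out-of-range positions
templateBaseAt <- function(template, coords) {
  whole <- constructSequence(template)
  b <- substr(rep(whole, length(coords)), coords + 1L, coords + 1L)
  b[b == "" | b == "N"] <- NA_character_
  b
}
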