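#' @import methods
#' @importFrom stats rpois rbinom rmultinom rlnorm runif setNames quantile
#'   cor cor.test t.test sd var median
#' @importFrom utils write.table read.table head packageVersion
NULL

NUCS <- c("A", "C", "G", "T")

IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' All k-mers over the DNA alphabet
#'
#' Enumerates the full k-mer universe in lexicographic order. The default
#' k = 7 gives the 16,384-sequence universe of the randomized reporter
#' cassette.
#'
#' @param k k-mer length.
#' @return Character vector of length `4^k`.
#' @examples
#' length(allSevenMers()) # 16384
#' @export
allSevenMers <- function(k = 7L) {
  k <- as.integer(k)
  stopifnot(k >= 1L, k <= 10L)
  do.call(paste0, rev(lapply(seq_len(k), function(i) {
    rep(NUCS, each = 4^(i - 1L), times = 4^(k - i))
  })))
}

## RNA input (U) is accepted everywhere and stored in DNA space.
rnaToDna <- function(x) chartr("Uu", "Tt", toupper(x))

#' First nucleotide of a sequence
#'
#' @param x character vector of sequences (T/U equivalent).
#' @return Character vector of +1 nucleotides in DNA space.
#' @export
plus1 <- function(x) substr(rnaToDna(x), 1L, 1L)

## deterministic low-discrepancy "jitter" in [0, 1), used by the default
## synthetic ground-truth models so they are reproducible without consuming
## RNG state. idx is 0-based; salt selects an independent stream.
ldJitter <- function(idx, salt = 1) {
  x <- (idx + 1) * (sqrt(c(2, 3, 5, 7, 11, 13, 17, 19)[salt]) + salt / 97)
  x - floor(x)
}

## 0-based lexicographic index of each k-mer
kmerIndex <- function(kmers) {
  k <- nchar(kmers[1L])
  idx <- numeric(length(kmers))
  for (i in seq_len(k)) {
    idx <- idx * 4 + (match(substr(kmers, i, i), NUCS) - 1)
  }
  idx
}

## md5 of a deparsed R object (used to stamp output files)
objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

outputHeader <- function(configHash = NULL) {
  sprintf(
    "# capstart %s%s",
    as.character(utils::packageVersion("capstart")),
    if (is.null(configHash)) "" else paste0(" config=", configHash)
  )
}

## leading-G run length per read
leadingGRun <- function(reads) {
  m <- regexpr("^G*", reads)
  attr(m, "match.length")
}

## maximal leading pyrimidine (C/T) run length per sequence
leadingYRun <- function(x) {
  m <- regexpr("^[CT]*", rnaToDna(x))
  attr(m, "match.length")
}
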