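## construct a read from an explicit origin on a template: g artifact Gs +
## the mRNA from start offset `off` (relative to the expected TSS) with the
## cassette instantiated as `mer`
buildRead <- function(mer, off = 0L, g = 0L, template = defaultTemplate(),
                      len = 40L) {
  L <- expectedTssIndex(template)
  t0 <- L + off
  body <- paste0(strrep("G", g),
                 substr(promoterSeq(template), pmin(t0, L) + 1L, L),
                 substr(mer, pmax(t0 - L, 0L) + 1L, 7L),
                 downstreamSeq(template))
  substr(body, 1L, len)
}

## small simulation config for fast tests
tinyConfig <- function(seed = 1L, depth = 2e4, ...) {
  simulationConfig(rngSeed = seed, depth = depth, ...)
}

## expression model concentrated on a set of 7-mers (others negligible)
concentratedModel <- function(mers, rates = 1) {
  m <- setNames(rep(1e-12, 16384), allSevenMers())
  m[mers] <- rates
  m
}

## independent regex-based IUPAC matcher (test-side oracle)
regexMatch <- function(x, pattern) {
  sets <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
            S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
            D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  re <- paste0("^", paste(sets[strsplit(pattern, "")[[1L]]], collapse = ""))
  grepl(re, x)
}

## compare two classification data.frames field by field
callsAgree <- function(a, b) {
  same <- function(u, v) (is.na(u) & is.na(v)) | (!is.na(u) & !is.na(v) &
                                                    u == v)
  as.character(a$category) == as.character(b$category) &
    same(a$sevenmer, b$sevenmer) &
    same(a$startOffset, b$startOffset) &
    same(a$nStrippedG, b$nStrippedG)
}
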