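READ_CATEGORIES <- c("cassette_start", "upstream_start", "downstream_start",
                     "ambiguous_plus1G", "no_seed", "truncated", "spikein")

#' Locate the constant-region anchor seed in reads
#'
#' Finds the first exact occurrence of the template's seed among the first
#' `maxScan` start offsets of each read. Absence is a value (`NA`), not an
#' error: seedless reads are tallied as `no_seed` downstream.
#'
#' @param reads Character vector of read sequences (5'->3', T/U equivalent).
#' @param template A [ConstructTemplate-class].
#' @param maxScan Number of read start offsets scanned for the seed.
#' @return Integer vector of 0-based seed offsets, `NA` where absent.
#' @examples
#' tpl <- defaultTemplate()
#' findSeed("CCTTAAAGCCGCCGCCAAA", tpl) # 6
#' @export
findSeed <- function(reads, template, maxScan = 60L) {
  reads <- rnaToDna(reads)
  seed <- anchorSeed(template)
  window <- substr(reads, 1L, maxScan + nchar(seed) - 1L)
  m <- regexpr(seed, window, fixed = TRUE)
  ifelse(m > 0L, as.integer(m) - 1L, NA_integer_)
}

## read suffixes starting at read index `from` (0-based) must match the
## construct from coordinate `coord` at every known (non-cassette) position.
## Grouped by (coord, compared length) so each group is one anchored regex.
matchesTemplateFrom <- function(reads, readLen, template, from, coord) {
  whole <- constructSequence(template)
  totalLen <- nchar(whole)
  avail <- pmin(readLen - from, totalLen - coord)
  ok <- rep(NA, length(reads))
  ok[avail <= 0L] <- TRUE            # nothing left to compare
  todo <- which(is.na(ok))
  if (!length(todo)) return(ok)
  key <- paste(coord[todo], avail[todo])
  for (grp in split(todo, key)) {
    cc <- coord[grp[1L]]
    av <- avail[grp[1L]]
    expected <- substr(whole, cc + 1L, cc + av)
    pat <- paste0("^", gsub("N", ".", expected, fixed = TRUE), "$")
    obs <- substr(reads[grp], from[grp] + 1L, from[grp] + av)
    ok[grp] <- grepl(pat, obs)
  }
  ok
}

#' Classify 5'-end reads against the reporter template
#'
#' The core read-processing step. Each read is anchored on the construct by
#' the constant-region seed; leading G nucleotides are then stripped
#' greedily while each would align to a known template position whose base
#' is not G (a non-templated reverse-transcription artifact). Stripping
#' pauses where the template base is G: the G is retained as templated if
#' the rest of the read is consistent with starting there, and otherwise
#' stripped as an artifact that happens to sit over a templated G.
#' Stripping stops for good at a non-G read base or at the cassette
#' (template unknown). The first retained base determines the category:
#' \itemize{
#'   \item non-G at the expected TSS: `cassette_start`, with the following
#'     7 nt as the read's 7-mer;
#'   \item G anywhere within the cassette, or a retained templated-G start
#'     whose leading G run continues into the cassette:
#'     `ambiguous_plus1G` (an artifact interpretation with a different
#'     TSS/7-mer cannot be excluded);
#'   \item upstream of the cassette: `upstream_start` (a templated match is
#'     preferred over an artifact interpretation);
#'   \item past the expected TSS otherwise: `downstream_start`.
#' }
#' Reads without the seed are `no_seed`; reads that cannot be placed on the
#' template or that mismatch it at a known position are tallied separately
#' as `truncated`. The classification agrees exhaustively with the
#' brute-force [enumerateReadOrigins()].
#'
#' @inheritParams findSeed
#' @return A data.frame with one row per read: `readId`, `alignOffset`
#'   (0-based construct coordinate of the first templated base),
#'   `startOffset` (the same, relative to the expected TSS), `nStrippedG`,
#'   `base5` (first 30 templated nt), `category`, and `sevenmer` (non-`NA`
#'   iff `category == "cassette_start"`).
#' @seealso [enumerateReadOrigins()] for the exhaustive reference
#'   enumerator, [collapseCalls()] to reduce calls to counts.
#' @export
classifyReads <- function(reads, template, maxScan = 60L) {
  reads <- rnaToDna(reads)
  n <- length(reads)
  readId <- names(reads) %||% as.character(seq_len(n))
  rl <- nchar(reads)
  L <- expectedTssIndex(template)
  cl <- cassetteLen(template)
  sp <- seedPosition(template)
  totalLen <- nchar(constructSequence(template))

  s0 <- findSeed(reads, template, maxScan = maxScan)
  a0 <- sp - s0
  found <- !is.na(s0)
  placed <- found & a0 >= 0L

  category <- rep("no_seed", n)
  category[found & !placed] <- "truncated"

  k <- integer(n)
  nlead <- leadingGRun(reads)
  pending <- which(placed)
  while (length(pending)) {
    ## strip phase: artifact Gs over known non-G template positions
    active <- pending[k[pending] < nlead[pending]]
    while (length(active)) {
      b <- templateBaseAt(template, a0[active] + k[active])
      strip <- !is.na(b) & b != "G"
      active <- active[strip]
      k[active] <- k[active] + 1L
      active <- active[k[active] < nlead[active]]
    }

    cstar <- a0[pending] + k[pending]
    isG <- k[pending] < nlead[pending]
    tb <- templateBaseAt(template, cstar)
    inCas <- cstar >= L & cstar < L + cl
    offEnd <- cstar >= totalLen | k[pending] >= rl[pending]

    ## verify template consistency from the tentative start
    ok <- matchesTemplateFrom(reads[pending], rl[pending], template,
                              from = k[pending], coord = cstar)

    done <- rep(TRUE, length(pending))
    cat0 <- rep(NA_character_, length(pending))

    cat0[offEnd] <- "truncated"
    todo <- !offEnd
    ## non-G first base: unique origin
    sel <- todo & !isG
    cat0[sel & !ok] <- "truncated"
    cat0[sel & ok & cstar < L] <- "upstream_start"
    cat0[sel & ok & cstar == L] <- "cassette_start"
    cat0[sel & ok & cstar > L] <- "downstream_start"
    ## G over the cassette: the artifact interpretation cannot be excluded
    sel <- todo & isG & inCas
    cat0[sel & ok] <- "ambiguous_plus1G"
    cat0[sel & !ok] <- "truncated"
    ## G over a known templated G: retain if consistent, else it is an
    ## artifact over a templated G -- strip it and re-enter the loop
    sel <- todo & isG & !inCas
    resume <- sel & !ok
    keepG <- sel & ok
    ## a retained upstream templated-G start whose G run reaches into the
    ## cassette admits a second canonical origin inside the cassette
    intoCas <- keepG & cstar < L & (a0[pending] + nlead[pending]) > L
    cat0[keepG & cstar < L & !intoCas] <- "upstream_start"
    cat0[intoCas] <- "ambiguous_plus1G"
    cat0[keepG & cstar >= L + cl] <- "downstream_start"
    done[resume] <- FALSE
    k[pending[resume]] <- k[pending[resume]] + 1L

    category[pending[done]] <- cat0[done]
    pending <- pending[!done]
  }
  cstar <- a0 + k

  sevenmer <- rep(NA_character_, n)
  isCas <- category == "cassette_start"
  sevenmer[isCas] <- substr(reads[isCas], k[isCas] + 1L, k[isCas] + cl)

  usable <- !(category %in% c("no_seed", "truncated", "ambiguous_plus1G"))
  data.frame(
    readId = readId,
    alignOffset = ifelse(usable, cstar, NA_integer_),
    startOffset = ifelse(usable, cstar - L, NA_integer_),
    nStrippedG = ifelse(usable, k, NA_integer_),
    base5 = ifelse(usable, substr(reads, k + 1L, k + 30L), NA_character_),
    category = factor(category, levels = READ_CATEGORIES),
    sevenmer = sevenmer,
    stringsAsFactors = FALSE
  )
}

#' @rdname classifyReads
#' @param read A single read sequence.
#' @export
classifyRead <- function(read, template, maxScan = 60L) {
  stopifnot(length(read) == 1L)
  classifyReads(read, template, maxScan = maxScan)
}

#' Brute-force origin enumeration for 5'-end reads
#'
#' Reference implementation used to validate [classifyReads()]: for each
#' read it tries every physically possible origin -- a true start position
#' (fixed by the seed anchor up to the artifact count) combined with `g`
#' appended non-templated Gs, `g` ranging over the read's whole leading-G
#' run -- and keeps the origins whose remaining bases match the template at
#' all known positions. Origins are reduced to canonical form by absorbing
#' purported artifact Gs that align to templated Gs (the two interpretations
#' produce indistinguishable molecules, and a template match is preferred).
#' A read is ambiguous if two or more canonical origins remain, which
#' happens exactly when a leading G sits over a cassette position.
#'
#' @inheritParams findSeed
#' @param gMax Upper bound on enumerated artifact-G counts (default: each
#'   read's full leading-G run).
#' @return A data.frame like [classifyReads()] with an extra `nOrigins`
#'   column (count of canonical consistent origins).
#' @export
enumerateReadOrigins <- function(reads, template, maxScan = 60L,
                                 gMax = Inf) {
  reads <- rnaToDna(reads)
  n <- length(reads)
  readId <- names(reads) %||% as.character(seq_len(n))
  rl <- nchar(reads)
  L <- expectedTssIndex(template)
  cl <- cassetteLen(template)
  sp <- seedPosition(template)

  s0 <- findSeed(reads, template, maxScan = maxScan)
  a0 <- sp - s0
  nlead <- leadingGRun(reads)
  gCap <- pmin(nlead, s0, gMax)

  nOrigins <- integer(n)
  bestG <- rep(NA_integer_, n)
  maxG <- suppressWarnings(max(gCap[!is.na(gCap)], 0L))
  for (g in 0L:maxG) {
    sel <- which(!is.na(s0) & gCap >= g & a0 + g >= 0L)
    if (!length(sel)) next
    ok <- matchesTemplateFrom(reads[sel], rl[sel], template,
                              from = rep(g, length(sel)),
                              coord = a0[sel] + g)
    ## canonical: g = 0, or the G at the previous coordinate cannot be a
    ## templated G
    if (g > 0L) {
      prev <- templateBaseAt(template, a0[sel] + g - 1L)
      ok <- ok & (is.na(prev) | prev != "G")
    }
    hit <- sel[ok]
    nOrigins[hit] <- nOrigins[hit] + 1L
    bestG[hit[is.na(bestG[hit])]] <- g
  }

  category <- rep("no_seed", n)
  category[!is.na(s0) & nOrigins == 0L] <- "truncated"
  one <- nOrigins >= 1L
  t0 <- a0 + bestG
  firstBase <- substr(reads, bestG + 1L, bestG + 1L)
  category[one & nOrigins >= 2L] <- "ambiguous_plus1G"
  uniq <- one & nOrigins == 1L
  category[uniq & t0 < L] <- "upstream_start"
  category[uniq & t0 > L] <- "downstream_start"
  category[uniq & t0 == L & firstBase != "G"] <- "cassette_start"
  category[uniq & t0 == L & firstBase == "G"] <- "ambiguous_plus1G"

  sevenmer <- rep(NA_character_, n)
  isCas <- category == "cassette_start"
  sevenmer[isCas] <- substr(reads[isCas], bestG[isCas] + 1L, bestG[isCas] + cl)
  usable <- uniq
  data.frame(
    readId = readId,
    alignOffset = ifelse(usable, t0, NA_integer_),
    startOffset = ifelse(usable, t0 - L, NA_integer_),
    nStrippedG = ifelse(usable, bestG, NA_integer_),
    base5 = ifelse(usable, substr(reads, bestG + 1L, bestG + 30L),
                   NA_character_),
    category = factor(category, levels = READ_CATEGORIES),
    sevenmer = sevenmer,
    nOrigins = nOrigins,
    stringsAsFactors = FALSE
  )
}

#' Count and remove spike-in reads
#'
#' Reads whose 5' end (after stripping any leading Gs) matches the first
#' `matchLen` nucleotides of the spike-in sequence are counted and removed
#' before classification.
#'
#' @param reads Character vector of read sequences.
#' @param spikein Spike-in sequence (or a [ConstructTemplate-class] whose
#'   spike-in slot is used).
#' @param matchLen Prefix length compared.
#' @return A list with `count`, the logical vector `isSpikein`, and
#'   `reads` (the remaining reads).
#' @export
countAndRemoveSpikein <- function(reads, spikein, matchLen = 15L) {
  if (is(spikein, "ConstructTemplate")) spikein <- spikeinSeq(spikein)
  if (is.na(spikein) || nchar(spikein) < matchLen) {
    stop("spike-in sequence must be at least matchLen nucleotides")
  }
  reads <- rnaToDna(reads)
  prefix <- substr(rnaToDna(spikein), 1L, matchLen)
  stripped <- sub("^G+", "", reads)
  isSpikein <- substr(stripped, 1L, matchLen) == prefix
  list(count = sum(isSpikein), isSpikein = isSpikein,
       reads = reads[!isSpikein])
}

#' Collapse read classifications to a per-sample 7-mer count table
#'
#' Groups `cassette_start` calls by their base 7-mer (reads differing only
#' in the number of stripped non-templated Gs share a group) and sums the
#' counts; every other category is tallied as excluded. Read conservation
#' holds: assigned counts plus excluded tallies equal the number of
#' classified reads plus the spike-in count.
#'
#' @param calls A data.frame from [classifyReads()] (one sample).
#' @param sampleId,condition,replicate Sample metadata stored on the result.
#' @param spikeinCount Number of spike-in reads removed before
#'   classification.
#' @return A [KmerCountTable-class].
#' @export
collapseCalls <- function(calls, sampleId = "sample",
                          condition = character(), replicate = 1L,
                          spikeinCount = 0) {
  if ("sampleId" %in% names(calls) &&
      length(unique(calls$sampleId)) > 1L) {
    stop("calls from multiple samples cannot be collapsed together")
  }
  cas <- calls$sevenmer[calls$category == "cassette_start"]
  counts <- if (length(cas)) table(cas) else integer()
  lev <- setdiff(READ_CATEGORIES, "cassette_start")
  tab <- table(factor(calls$category, levels = lev))
  excl <- setNames(as.numeric(tab), lev)
  excl["spikein"] <- excl["spikein"] + spikeinCount
  kmerCountTable(setNames(as.integer(counts), names(counts)),
                 sampleId = sampleId, condition = condition,
                 replicate = replicate, excluded = excl)
}

#' Distribution of inferred transcription start positions
#'
#' Fractions of reads by start offset relative to the expected TSS,
#' computed over unambiguously placed calls (cassette, upstream and
#' downstream starts; ambiguous +1 G reads are excluded, as are seedless
#' and truncated reads). In the reporter data the modal position is the
#' expected TSS itself.
#'
#' @param calls A data.frame from [classifyReads()].
#' @return Named numeric vector of fractions (names are offsets), summing
#'   to 1.
#' @export
tssPositionDistribution <- function(calls) {
  use <- calls$category %in% c("cassette_start", "upstream_start",
                               "downstream_start")
  if (!any(use)) stop("no unambiguously placed calls")
  tab <- table(calls$startOffset[use])
  frac <- as.numeric(tab) / sum(tab)
  setNames(frac, names(tab))
}
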