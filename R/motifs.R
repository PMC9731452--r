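#' Built-in 5' motif classes
#'
#' The degenerate patterns used throughout the analysis, anchored at the
#' mRNA +1 position and written with IUPAC codes (Y = C/T, R = A/G,
#' B = C/G/T, W = A/T, N = any): the Initiator-derived class `Inr` (ABW),
#' the `TCT` class (CTYTYY), the key dinucleotides `AG` and `CT`, the
#' canonical `TOP` pattern (CYYYYNN) and the purine baseline `R1`.
#'
#' @return Named list of pattern strings.
#' @export
motifClasses <- function() {
  list(Inr = "ABW", TCT = "CTYTYY", AG = "AG", CT = "CT",
       TOP = "CYYYYNN", R1 = "R")
}

#' Match sequences against a positional IUPAC pattern
#'
#' Positional matching anchored at the first nucleotide: position `i` of
#' the sequence must belong to the nucleotide set of pattern position `i`.
#' Patterns shorter than the sequences constrain only their own length.
#'
#' @param sevenmers Character vector of sequences (T/U equivalent).
#' @param pattern IUPAC pattern (length <= sequence length), or a name from
#'   [motifClasses()].
#' @return Logical vector.
#' @examples
#' matchClass("CTCTCCA", "CTYTYY") # TRUE
#' sum(matchClass(allSevenMers(), "ABW")) # 1536
#' @export
matchClass <- function(sevenmers, pattern) {
  sevenmers <- rnaToDna(sevenmers)
  if (pattern %in% names(motifClasses())) {
    pattern <- motifClasses()[[pattern]]
  }
  pattern <- rnaToDna(toupper(pattern))
  codes <- strsplit(pattern, "")[[1L]]
  bad <- setdiff(codes, names(IUPAC_CODES))
  if (length(bad)) stop("unknown IUPAC code: ", paste(bad, collapse = ", "))
  if (nchar(pattern) > nchar(sevenmers[1L])) {
    stop("pattern longer than the sequences")
  }
  ok <- rep(TRUE, length(sevenmers))
  for (i in seq_along(codes)) {
    ok <- ok & substr(sevenmers, i, i) %in% IUPAC_CODES[[codes[i]]]
  }
  ok
}

#' Motif class versus background value test
#'
#' Welch t-test of the values of class members against the all-sequence
#' background (the comparison used for the class-level expression panels),
#' or against non-members.
#'
#' @param values Named numeric vector (names are 7-mers or k-mers).
#' @param motifClass IUPAC pattern or built-in class name.
#' @param background `"all"` (default) or `"complement"`.
#' @return A list with `classMean`, `backgroundMean`, `n`, `statistic`,
#'   `p.value`.
#' @export
classValueTest <- function(values, motifClass, background = c("all",
                                                              "complement")) {
  background <- match.arg(background)
  member <- matchClass(names(values), motifClass)
  if (sum(member) < 2L || sum(!member) < 2L) {
    stop("degenerate class: need >= 2 members and >= 2 non-members")
  }
  x <- values[member]
  y <- if (background == "all") values else values[!member]
  tt <- tryCatch(t.test(x, y), error = function(e) NULL)
  list(classMean = mean(x), backgroundMean = mean(y), n = sum(member),
       statistic = if (is.null(tt)) 0 else unname(tt$statistic),
       p.value = if (is.null(tt)) 1 else tt$p.value)
}

#' Effect of leading pyrimidine-run length
#'
#' Groups 7-mers by their maximal leading C/T run (the run is terminated by
#' a purine, so groups are disjoint: `Y^k R ...` for k < 7 and `Y^7`), and
#' summarizes a per-7-mer value (typically the mTOR-dependent translation
#' delta) per run length. Group `k = 0` is the purine-+1 baseline. With
#' `requirePlus1C = TRUE` the pyrimidine groups are restricted to +1 C
#' (strict TOP semantics). With `inclusive = TRUE` groups are nested
#' (`run >= k`) instead of disjoint.
#'
#' @param values Named numeric vector over 7-mers.
#' @param requirePlus1C Restrict Y-run groups to +1 C sequences.
#' @param inclusive Use nested groups instead of disjoint run lengths.
#' @return A data.frame with `k`, `n`, `mean`, `sd`.
#' @export
yrunProfile <- function(values, requirePlus1C = FALSE, inclusive = FALSE) {
  mers <- names(values)
  run <- leadingYRun(mers)
  keep <- run == 0L | !requirePlus1C | plus1(mers) == "C"
  out <- lapply(0:7, function(k) {
    g <- if (k == 0L) run == 0L
         else if (inclusive) run >= k & keep
         else run == k & keep
    v <- values[g]
    data.frame(k = k, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1L) sd(v) else NA_real_)
  })
  do.call(rbind, out)
}

#' Single-position substitution scan over a degenerate pattern
#'
#' For each position of `basePattern` and each nucleotide, the effect of
#' forcing that position to that nucleotide: mean value over 7-mers
#' matching the modified pattern minus mean value over 7-mers matching the
#' unmodified pattern. Forcing a position to a set equal to its own code
#' gives exactly 0. Cells whose modified pattern matches nothing are `NA`.
#'
#' @param values Named numeric vector over 7-mers.
#' @param basePattern IUPAC pattern (default the canonical TOP `CYYYYNN`).
#' @return A positions x nucleotides matrix of effects, with the base-set
#'   mean as attribute `baseMean`.
#' @export
substitutionScan <- function(values, basePattern = "CYYYYNN") {
  basePattern <- rnaToDna(toupper(basePattern))
  mers <- names(values)
  base <- matchClass(mers, basePattern)
  if (!any(base)) stop("base pattern matches no sequence")
  baseMean <- mean(values[base])
  kp <- nchar(basePattern)
  eff <- matrix(NA_real_, nrow = kp, ncol = 4L,
                dimnames = list(paste0("pos", seq_len(kp)), NUCS))
  for (p in seq_len(kp)) {
    for (nuc in NUCS) {
      mod <- basePattern
      substr(mod, p, p) <- nuc
      hit <- matchClass(mers, mod)
      if (any(hit)) eff[p, nuc] <- mean(values[hit]) - baseMean
    }
  }
  attr(eff, "baseMean") <- baseMean
  eff
}

#' Aggregate per-7-mer values to shorter 5' k-mers
#'
#' Groups 7-mers by their first `k` nucleotides and averages the values
#' (unweighted by default, or weighted e.g. by plasmid frequency). The 5'
#' 3-mers account for most of the expression variation, making `k = 3` the
#' usual comparison unit against endogenous TSS data.
#'
#' @param values Named numeric vector over 7-mers.
#' @param k Prefix length (1-7).
#' @param weights Optional named weights over the same 7-mers.
#' @return Named numeric vector over k-mers (lexicographic order).
#' @export
aggregateToKmer <- function(values, k, weights = NULL) {
  stopifnot(k >= 1L, k <= 7L)
  pre <- factor(substr(names(values), 1L, k), levels = allSevenMers(k))
  if (is.null(weights)) {
    out <- tapply(values, pre, mean, default = NA_real_)
  } else {
    num <- tapply(values * weights, pre, sum, default = NA_real_)
    den <- tapply(weights, pre, sum, default = NA_real_)
    out <- num / den
  }
  setNames(as.numeric(out), levels(pre))
}

#' Rank 3-mers jointly on expression and regulated translation
#'
#' Identifies 5' 3-mers that are simultaneously well-transcribed and
#' strongly mTOR-regulated: Pareto optimality for (high expression, strong
#' repression = negative translation delta) plus a rank-product score. The
#' +1 C subset contains the TCT/TOP hybrids.
#'
#' @param expression Named numeric over 3-mers (normalized expression).
#' @param deltaPsp Named numeric over the same 3-mers (torin-minus-control
#'   translation delta; more negative = more repressed).
#' @return A data.frame sorted by rank product with columns `kmer`,
#'   `plus1`, `expression`, `repression`, `pareto`, `rankProduct`.
#' @export
hybridRanking <- function(expression, deltaPsp) {
  shared <- intersect(names(expression), names(deltaPsp))
  shared <- shared[is.finite(expression[shared]) &
                     is.finite(deltaPsp[shared])]
  e <- expression[shared]
  r <- -deltaPsp[shared]   # repression strength
  pareto <- vapply(seq_along(shared), function(i) {
    !any(e >= e[i] & r >= r[i] & (e > e[i] | r > r[i]))
  }, logical(1L))
  rp <- rank(-e) * rank(-r)
  out <- data.frame(kmer = shared, plus1 = plus1(shared),
                    expression = unname(e), repression = unname(r),
                    pareto = pareto, rankProduct = unname(rp),
                    stringsAsFactors = FALSE)
  out[order(out$rankProduct), , drop = FALSE]
}
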