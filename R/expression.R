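#' Reads per million
#'
#' Converts assigned 7-mer counts to reads per million: count x 1e6 /
#' total assigned reads. RPM values of a sample sum to 1e6.
#'
#' @param x A [KmerCountTable-class], or a named count vector.
#' @return Named numeric vector of RPM values.
#' @export
toRPM <- function(x) {
  counts <- if (is(x, "KmerCountTable")) kmerCounts(x) else x
  tot <- sum(counts)
  if (tot <= 0) stop("empty count table: total assigned reads is 0")
  counts * 1e6 / tot
}

#' Detection filter over 7-mer count tables
#'
#' Returns the 7-mers whose raw count exceeds `minReads` in every table
#' (or, with `requireAll = FALSE`, in at least one), optionally restricted
#' to a set of +1 nucleotides. The reporter-side rule is > 50 reads in all
#' replicates over the +1 A/C/U sub-universe; the plasmid-side rule is
#' > 20 reads over the full universe.
#'
#' @param tables A [KmerCountTable-class] or list of them.
#' @param minReads Detection threshold (strict inequality).
#' @param requireAll Require the threshold in all tables (`TRUE`) or any
#'   (`FALSE`).
#' @param plus1 Optional +1 nucleotide restriction, e.g. `c("A","C","T")`.
#' @return Character vector of detected 7-mers.
#' @export
detectionFilter <- function(tables, minReads = 50, requireAll = TRUE,
                            plus1 = NULL) {
  if (is(tables, "KmerCountTable")) tables <- list(tables)
  if (!length(tables)) stop("at least one count table is required")
  universe <- names(kmerCounts(tables[[1L]]))
  mat <- vapply(tables, function(t) as.numeric(kmerCounts(t)),
                numeric(length(universe)))
  rownames(mat) <- universe
  hits <- mat > minReads
  det <- if (requireAll) rowSums(hits) == ncol(hits) else rowSums(hits) > 0L
  mers <- rownames(mat)
  if (!is.null(plus1)) det <- det & substr(mers, 1L, 1L) %in% rnaToDna(plus1)
  mers[det]
}

#' Normalized per-7-mer expression
#'
#' Mean reporter RPM divided by plasmid RPM per 7-mer. Detection (by
#' default the reporter rule: > `minReads` in all replicates, +1 A/C/U) is
#' recorded as a flag; undetected entries are kept. Detected 7-mers with a
#' zero plasmid count are excluded with a warning.
#'
#' @param reporterTables List of reporter [KmerCountTable-class] replicates.
#' @param plasmidTable Plasmid [KmerCountTable-class].
#' @param detected Character vector of detected 7-mers, or `NULL` to apply
#'   [detectionFilter()] with `minReads`/`plus1`.
#' @param minReads,plus1 Detection rule used when `detected` is `NULL`.
#' @param aggregate `"mean"` (arithmetic, the default) or `"geometric"`
#'   replicate aggregation of RPM.
#' @return A data.frame with columns `sevenmer`, `reporterRPM`,
#'   `plasmidRPM`, `normalized`, `detected`.
#' @export
normalizeExpression <- function(reporterTables, plasmidTable,
                                detected = NULL, minReads = 50,
                                plus1 = c("A", "C", "T"),
                                aggregate = c("mean", "geometric")) {
  aggregate <- match.arg(aggregate)
  if (is(reporterTables, "KmerCountTable")) {
    reporterTables <- list(reporterTables)
  }
  rpm <- vapply(reporterTables, toRPM,
                numeric(length(kmerCounts(plasmidTable))))
  repRPM <- if (aggregate == "mean") rowMeans(rpm) else
    exp(rowMeans(log(rpm)))
  plaRPM <- toRPM(plasmidTable)
  if (is.null(detected)) {
    detected <- detectionFilter(reporterTables, minReads = minReads,
                                plus1 = plus1)
  }
  mers <- names(plaRPM)
  det <- mers %in% detected
  zero <- det & plaRPM == 0
  if (any(zero)) {
    warning(sum(zero), " detected 7-mer(s) with zero plasmid count excluded")
    det[zero] <- FALSE
  }
  norm <- ifelse(plaRPM > 0, repRPM / plaRPM, NA_real_)
  data.frame(sevenmer = mers, reporterRPM = repRPM, plasmidRPM = plaRPM,
             normalized = norm, detected = det, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Fold range of normalized expression
#'
#' Ratio of the `hiQ` to the `loQ` quantile of normalized expression over
#' detected entries; the defaults (0, 1) give the full min-to-max span.
#'
#' @param x A data.frame from [normalizeExpression()] (detected entries are
#'   used), or a numeric vector of values.
#' @param loQ,hiQ Quantiles in `[0, 1]`, `loQ < hiQ`.
#' @return The fold range (a single number).
#' @export
expressionRange <- function(x, loQ = 0, hiQ = 1) {
  stopifnot(loQ >= 0, hiQ <= 1, loQ < hiQ)
  v <- if (is.data.frame(x)) x$normalized[x$detected] else x
  v <- v[is.finite(v) & v > 0]
  if (length(v) < 2L) stop("need at least two detected entries")
  q <- quantile(v, c(loQ, hiQ), names = FALSE)
  q[2L] / q[1L]
}

## sample moments bimodality coefficient: (skewness^2 + 1) / (kurtosis +
## small-sample correction); > ~0.555 suggests bimodality
bimodalityCoefficient <- function(v) {
  v <- v[is.finite(v)]
  n <- length(v)
  if (n < 4L) return(NA_real_)
  z <- (v - mean(v)) / sd(v)
  g1 <- mean(z^3) * sqrt(n * (n - 1)) / (n - 2)
  g2 <- ((n + 1) * mean(z^4) - 3 * (n - 1)) * (n - 1) / ((n - 2) * (n - 3))
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

#' Expression distribution stratified by +1 nucleotide
#'
#' Summaries of (log10) normalized expression per +1 nucleotide stratum:
#' counts, means, quantiles and histogram bins, plus the bimodality
#' coefficient of the pooled distribution.
#'
#' @param norm A data.frame from [normalizeExpression()].
#' @param nbins Number of histogram bins (log10 scale).
#' @return A list with `strata` (data.frame of per-stratum summaries),
#'   `histogram` (data.frame of pooled log10 bins and per-stratum counts)
#'   and `bimodality` (coefficient of the pooled log10 values).
#' @export
plus1StratifiedSummary <- function(norm, nbins = 40L) {
  d <- norm[norm$detected & is.finite(norm$normalized) &
              norm$normalized > 0, ]
  if (!nrow(d)) stop("no detected entries")
  d$p1 <- plus1(d$sevenmer)
  lg <- log10(d$normalized)
  strata <- do.call(rbind, lapply(split(seq_len(nrow(d)), d$p1), function(i) {
    v <- d$normalized[i]
    data.frame(plus1 = d$p1[i[1L]], n = length(v), mean = mean(v),
               median = median(v),
               q10 = quantile(v, 0.1, names = FALSE),
               q90 = quantile(v, 0.9, names = FALSE),
               meanLog10 = mean(log10(v)))
  }))
  rownames(strata) <- NULL
  breaks <- seq(min(lg), max(lg), length.out = nbins + 1L)
  bin <- cut(lg, breaks, include.lowest = TRUE)
  hist <- as.data.frame.matrix(table(bin, d$p1))
  hist <- cbind(data.frame(binMid = (head(breaks, -1L) + breaks[-1L]) / 2),
                hist)
  rownames(hist) <- NULL
  list(strata = strata, histogram = hist,
       bimodality = bimodalityCoefficient(lg))
}

#' Positional nucleotide-frequency matrix
#'
#' Per-position nucleotide frequencies of a 7-mer subset (the analytic
#' equivalent of a sequence logo), optionally weighted, and optionally
#' corrected by dividing by plasmid positional frequencies and
#' renormalizing each position. Every row sums to 1.
#'
#' @param sevenmers Character vector of 7-mers.
#' @param weights Optional per-sequence weights.
#' @param plasmidFreq Optional 7 x 4 plasmid positional-frequency matrix
#'   used for bias correction.
#' @return A 7 x 4 matrix (rows = positions 1-7, columns = A/C/G/T).
#' @export
positionalFrequencyMatrix <- function(sevenmers, weights = NULL,
                                      plasmidFreq = NULL) {
  sevenmers <- rnaToDna(sevenmers)
  if (!length(sevenmers)) stop("empty 7-mer subset")
  if (is.null(weights)) weights <- rep(1, length(sevenmers))
  k <- nchar(sevenmers[1L])
  m <- matrix(0, nrow = k, ncol = 4L,
              dimnames = list(paste0("pos", seq_len(k)), NUCS))
  for (i in seq_len(k)) {
    tab <- tapply(weights, factor(substr(sevenmers, i, i), levels = NUCS),
                  sum, default = 0)
    m[i, ] <- tab / sum(tab)
  }
  if (!is.null(plasmidFreq)) {
    m <- m / plasmidFreq
    m <- m / rowSums(m)
  }
  m
}

#' Top-expressed subset of a stratum
#'
#' Convenience selector: detected 7-mers with the given +1 nucleotide whose
#' normalized expression lies in the top `topFraction`.
#'
#' @param norm A data.frame from [normalizeExpression()].
#' @param plus1Nuc +1 nucleotide of the stratum.
#' @param topFraction Fraction retained (default 0.05; the companion
#'   figure text also quotes 0.10 -- both are reasonable).
#' @return Character vector of 7-mers.
#' @export
topStratum <- function(norm, plus1Nuc, topFraction = 0.05) {
  d <- norm[norm$detected & plus1(norm$sevenmer) == rnaToDna(plus1Nuc), ]
  if (!nrow(d)) stop("empty stratum")
  cut <- quantile(d$normalized, 1 - topFraction, names = FALSE)
  d$sevenmer[d$normalized >= cut]
}
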