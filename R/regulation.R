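## normalized abundance per 7-mer: RPM, or counts scaled to the spike-in
## when spike-in scaling is requested (x 1e6 to keep the pseudocount scale
## comparable)
normalizedAbundance <- function(table, spikein = FALSE) {
  if (!spikein) return(toRPM(table))
  s <- excludedCounts(table)["spikein"]
  if (is.na(s) || s <= 0) {
    stop("spike-in scaling requested but sample '", sampleId(table),
         "' has no spike-in count")
  }
  kmerCounts(table) * 1e6 / as.numeric(s)
}

#' Per-7-mer log2 ratio between two sets of count tables
#'
#' The package's ratio estimator: for each replicate pair,
#' `log2((num + a) / (den + a))` on normalized abundances (RPM, or
#' spike-in-scaled counts when `spikein = TRUE`), averaged over replicates.
#' The pseudocount `a` (default 0.5 normalized units) regularizes
#' low-count entries; at `a = 0` the estimator is antisymmetric under
#' swapping numerator and denominator.
#'
#' @param numTables,denTables [KmerCountTable-class] objects or lists of
#'   them, paired by position (replicates).
#' @param spikein Scale counts to each sample's spike-in count instead of
#'   RPM.
#' @param pseudocount Pseudocount `a` in normalized units.
#' @return A data.frame with `sevenmer`, per-replicate `l2fc_rep*` columns
#'   and their mean `l2fc`.
#' @export
log2Ratio <- function(numTables, denTables, spikein = FALSE,
                      pseudocount = 0.5) {
  if (is(numTables, "KmerCountTable")) numTables <- list(numTables)
  if (is(denTables, "KmerCountTable")) denTables <- list(denTables)
  if (length(numTables) != length(denTables)) {
    stop("numerator and denominator replicate lists differ in length")
  }
  u <- names(kmerCounts(numTables[[1L]]))
  reps <- lapply(seq_along(numTables), function(i) {
    nn <- normalizedAbundance(numTables[[i]], spikein)
    dd <- normalizedAbundance(denTables[[i]], spikein)
    if (!identical(names(nn), names(dd)) || !identical(names(nn), u)) {
      stop("count tables are over different 7-mer universes")
    }
    log2((nn + pseudocount) / (dd + pseudocount))
  })
  out <- data.frame(sevenmer = u, stringsAsFactors = FALSE)
  for (i in seq_along(reps)) out[[paste0("l2fc_rep", i)]] <- reps[[i]]
  out$l2fc <- rowMeans(do.call(cbind, reps))
  out
}

#' Polysome/sub-polysome translation ratio
#'
#' Estimates per-7-mer translation as `log2(P/SP)` from paired polysome and
#' sub-polysome count tables of one condition, spike-in-scaled by default
#' (equal spike-in is added to each fraction in the protocol, making
#' fractions comparable in absolute terms).
#'
#' @param polysome,subpolysome [KmerCountTable-class] objects or replicate
#'   lists.
#' @param spikein Use spike-in scaling (default `TRUE`).
#' @param pseudocount Pseudocount in normalized units.
#' @return As [log2Ratio()].
#' @export
pspTranslation <- function(polysome, subpolysome, spikein = TRUE,
                           pseudocount = 0.5) {
  log2Ratio(polysome, subpolysome, spikein = spikein,
            pseudocount = pseudocount)
}

#' Assemble the per-7-mer regulation table
#'
#' Joins translation (P/SP) and decay (ActD+/ActD-) log2 ratios under
#' control and mTOR-inhibited (torin) conditions into one table with the
#' torin-minus-control deltas, restricted to 7-mers passing detection in
#' all contributing samples.
#'
#' @param pspControl,pspTorin,decayControl,decayTorin Data.frames from
#'   [log2Ratio()]/[pspTranslation()].
#' @param detected Character vector of detected 7-mers (rows kept).
#' @return A data.frame with columns `sevenmer`, `l2_psp_control`,
#'   `l2_psp_torin`, `l2_decay_control`, `l2_decay_torin`, `delta_psp`,
#'   `delta_decay`.
#' @export
regulationTable <- function(pspControl, pspTorin, decayControl, decayTorin,
                            detected = NULL) {
  u <- pspControl$sevenmer
  stopifnot(identical(u, pspTorin$sevenmer),
            identical(u, decayControl$sevenmer),
            identical(u, decayTorin$sevenmer))
  out <- data.frame(
    sevenmer = u,
    l2_psp_control = pspControl$l2fc,
    l2_psp_torin = pspTorin$l2fc,
    l2_decay_control = decayControl$l2fc,
    l2_decay_torin = decayTorin$l2fc,
    stringsAsFactors = FALSE)
  out$delta_psp <- out$l2_psp_torin - out$l2_psp_control
  out$delta_decay <- out$l2_decay_torin - out$l2_decay_control
  if (!is.null(detected)) out <- out[out$sevenmer %in% detected, ]
  rownames(out) <- NULL
  out
}

#' Condition delta with a stratum contrast
#'
#' Returns the per-7-mer torin-minus-control delta for the chosen metric
#' together with a Welch two-sample t-test comparing two motif-defined
#' strata (by default the well-transcribed AG- versus CU-initiated
#' sequences) on that delta.
#'
#' @param reg A data.frame from [regulationTable()].
#' @param metric `"psp"` (translation) or `"decay"`.
#' @param strataA,strataB IUPAC patterns (anchored at +1) defining the two
#'   strata.
#' @return A list with `delta` (named numeric per 7-mer), `meanA`, `meanB`,
#'   `statistic` and `p.value`.
#' @export
conditionDelta <- function(reg, metric = c("psp", "decay"),
                           strataA = "AG", strataB = "CT") {
  metric <- match.arg(metric)
  delta <- setNames(reg[[paste0("delta_", metric)]], reg$sevenmer)
  a <- delta[matchClass(reg$sevenmer, strataA)]
  b <- delta[matchClass(reg$sevenmer, strataB)]
  if (!length(a) || !length(b)) stop("empty stratum")
  tt <- tryCatch(t.test(a, b), error = function(e) NULL)
  stat <- if (is.null(tt) || is.na(tt$statistic)) 0 else
    unname(tt$statistic)
  p <- if (is.null(tt) || is.na(tt$p.value)) 1 else tt$p.value
  list(delta = delta, meanA = mean(a), meanB = mean(b),
       statistic = stat, p.value = p)
}

#' Correlation between translation and stability
#'
#' Pearson and Spearman correlations between `log2(P/SP)` and
#' `log2(ActD+/ActD-)` for one condition, overall and per +1 nucleotide
#' stratum. In the reporter data these are uncorrelated under growth and
#' strongly correlated under mTOR inhibition.
#'
#' @param reg A data.frame from [regulationTable()].
#' @param condition `"control"` or `"torin"`.
#' @return A data.frame with one row per stratum (`all`, then +1 A/C/G/T
#'   as present): `n`, `pearson`, `spearman`, `p` (Spearman test).
#' @export
translationStabilityCorrelation <- function(reg,
                                            condition = c("control",
                                                          "torin")) {
  condition <- match.arg(condition)
  x <- reg[[paste0("l2_psp_", condition)]]
  y <- reg[[paste0("l2_decay_", condition)]]
  if (sum(is.finite(x) & is.finite(y)) < 10L) {
    stop("need at least 10 paired entries")
  }
  strat <- c(list(all = seq_along(x)),
             split(seq_along(x), plus1(reg$sevenmer)))
  do.call(rbind, lapply(names(strat), function(s) {
    i <- strat[[s]]
    if (length(i) < 3L || sd(x[i]) == 0 || sd(y[i]) == 0) {
      return(data.frame(stratum = s, n = length(i), pearson = NA_real_,
                        spearman = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(cor.test(x[i], y[i], method = "spearman",
                                    exact = FALSE))
    data.frame(stratum = s, n = length(i), pearson = cor(x[i], y[i]),
               spearman = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  }))
}
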