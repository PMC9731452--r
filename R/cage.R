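#' Read and write CTSS-style 5' tag tables
#'
#' CTSS text is 4 columns (chrom, 0-based position of the tag 5' end,
#' strand, count); BED6 (via [rtracklayer::import]) is also accepted, with
#' the score column as count. Tags are returned as a width-1
#' [GenomicRanges::GRanges] with a `count` metadata column (the in-memory
#' CageTagSet representation).
#'
#' @param path Input path (`.bed` extension switches to BED6 parsing).
#' @return A GRanges of 5' tag positions with counts.
#' @export
readCtss <- function(path) {
  if (grepl("\\.bed(\\.gz)?$", path)) {
    g <- rtracklayer::import(path)
    gr <- GenomicRanges::resize(g, width = 1L, fix = "start")
    gr$count <- as.integer(g$score)
    gr$name <- NULL
    gr$score <- NULL
    return(gr)
  }
  d <- read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                  col.names = c("chrom", "pos", "strand", "count"),
                  stringsAsFactors = FALSE)
  GenomicRanges::GRanges(d$chrom,
                         IRanges::IRanges(start = d$pos + 1L, width = 1L),
                         strand = d$strand, count = as.integer(d$count))
}

#' @rdname readCtss
#' @param tags GRanges with a `count` column.
#' @export
writeCtss <- function(tags, path) {
  d <- data.frame(chrom = as.character(GenomicRanges::seqnames(tags)),
                  pos = GenomicRanges::start(tags) - 1L,
                  strand = as.character(GenomicRanges::strand(tags)),
                  count = tags$count)
  writeLines(outputHeader(), path)
  suppressWarnings(write.table(d, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = FALSE,
                               append = TRUE))
  invisible(path)
}

#' Extract 5' tags within promoter windows
#'
#' Keeps tags lying on a gene's strand within the promoter window -- the
#' `window`-nt region surrounding the annotated TSS, implemented as
#' absolute distance `< window/2`. Tags falling in several genes' windows
#' are assigned to every containing gene (rows are duplicated, with the
#' gene id recorded), so global frequency computations should deduplicate
#' via `unique = TRUE`.
#'
#' @param tags GRanges of 5' tags with a `count` column.
#' @param annotation GRanges of width-1 annotated TSSs with `gene_id` (and
#'   optionally `gene_class`).
#' @param window Window width (nt, default 1000).
#' @param unique Drop duplicate tag records arising from overlapping
#'   windows (keeps each genomic tag once, for global frequencies).
#' @return GRanges of retained tags with `count`, `gene_id`, `gene_class`
#'   and `offset` (transcript-orientation distance from the annotated TSS)
#'   columns.
#' @export
extractPromoterTags <- function(tags, annotation, window = 1000L,
                                unique = FALSE) {
  stopifnot(window > 0L, window %% 2L == 0L)
  if (!length(intersect(GenomicRanges::seqnames(tags),
                        GenomicRanges::seqnames(annotation)))) {
    stop("tags and annotation share no chromosome")
  }
  half <- window %/% 2L
  win <- GenomicRanges::resize(annotation, width = 2L * half - 1L,
                               fix = "center")
  hits <- GenomicRanges::findOverlaps(tags, win, ignore.strand = FALSE)
  out <- tags[S4Vectors::queryHits(hits)]
  genes <- annotation[S4Vectors::subjectHits(hits)]
  out$gene_id <- genes$gene_id
  out$gene_class <- if (!is.null(genes$gene_class)) genes$gene_class else
    NA_character_
  sgn <- ifelse(as.character(GenomicRanges::strand(genes)) == "-", -1L, 1L)
  out$offset <- sgn * (GenomicRanges::start(out) -
                         GenomicRanges::start(genes))
  if (unique) {
    key <- paste(GenomicRanges::seqnames(out), GenomicRanges::start(out),
                 GenomicRanges::strand(out))
    out <- out[!duplicated(key)]
  }
  out
}

#' k-mer frequencies at tag 5' ends
#'
#' For each tag, reads the genomic `k`-mer beginning at its 5' end in
#' transcript orientation (reverse-complemented on the minus strand). Tags
#' whose +1 base is G are dropped when `excludePlus1G` (mirroring the
#' reporter-side exclusion; this never changes relative ratios among the
#' retained +1 A/C/T k-mers). Frequencies are count-weighted and sum to 1
#' over retained tags; tags within `k` of a contig end are dropped with a
#' warning.
#'
#' @param tags GRanges of 5' tags with a `count` column.
#' @param genome Named [Biostrings::DNAStringSet].
#' @param k k-mer length (default 3).
#' @param excludePlus1G Drop tags whose first transcribed base is G.
#' @param positionCollapsed Weight each distinct tag position once instead
#'   of by count.
#' @return Named numeric vector of frequencies over the `4^k` k-mer
#'   universe (zeros included), summing to 1.
#' @export
tagKmerFrequencies <- function(tags, genome, k = 3L, excludePlus1G = TRUE,
                               positionCollapsed = FALSE) {
  chrom <- as.character(GenomicRanges::seqnames(tags))
  if (!all(chrom %in% names(genome))) {
    stop("genome does not cover all tag chromosomes")
  }
  pos <- GenomicRanges::start(tags)            # 1-based
  minus <- as.character(GenomicRanges::strand(tags)) == "-"
  lens <- setNames(Biostrings::width(genome), names(genome))[chrom]
  startG <- ifelse(minus, pos - k + 1L, pos)
  endG <- startG + k - 1L
  inRange <- startG >= 1L & endG <= lens
  if (!all(inRange)) {
    warning(sum(!inRange), " tag(s) within ", k,
            " nt of a contig end dropped")
  }
  t2 <- tags[inRange]
  chrom <- chrom[inRange]
  minus <- minus[inRange]
  sG <- startG[inRange]
  eG <- endG[inRange]
  mer <- character(length(t2))
  for (ch in unique(chrom)) {
    i <- chrom == ch
    mer[i] <- substring(as.character(genome[[ch]]), sG[i], eG[i])
  }
  if (any(minus)) {
    mer[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(mer[minus])))
  }
  w <- if (positionCollapsed) rep(1, length(t2)) else as.numeric(t2$count)
  if (excludePlus1G) {
    keep <- substr(mer, 1L, 1L) != "G"
    mer <- mer[keep]
    w <- w[keep]
  }
  if (!length(mer)) stop("no tags retained")
  tot <- tapply(w, factor(mer, levels = allSevenMers(k)), sum, default = 0)
  freq <- as.numeric(tot) / sum(tot)
  setNames(freq, allSevenMers(k))
}

#' Compare library and endogenous 3-mer values
#'
#' Pearson and Spearman correlation between library-derived per-3-mer
#' values (e.g. normalized expression) and CAGE tag 3-mer frequencies, on
#' log10 scale with a floor at the smallest positive observation, over the
#' shared +1 A/C/T universe.
#'
#' @param libraryValues Named numeric over 3-mers.
#' @param cageFreq Named numeric over 3-mers.
#' @return A list with `n`, `pearson`, `spearman`, `p` (Spearman test).
#' @export
compareLibraryToCage <- function(libraryValues, cageFreq) {
  shared <- intersect(names(libraryValues), names(cageFreq))
  shared <- shared[substr(shared, 1L, 1L) %in% c("A", "C", "T")]
  x <- libraryValues[shared]
  y <- cageFreq[shared]
  ok <- is.finite(x) & is.finite(y)
  shared <- shared[ok]
  if (length(shared) < 10L) stop("fewer than 10 shared 3-mers")
  x <- x[ok]
  y <- y[ok]
  flog <- function(v) log10(pmax(v, min(v[v > 0])))
  lx <- flog(x)
  ly <- flog(y)
  ct <- suppressWarnings(cor.test(lx, ly, method = "spearman",
                                  exact = FALSE))
  list(n = length(shared), pearson = cor(lx, ly),
       spearman = unname(ct$estimate), p = ct$p.value)
}

#' k-mer frequencies for a gene subset
#'
#' [tagKmerFrequencies()] restricted to tags assigned (by
#' [extractPromoterTags()]) to a list of genes, e.g. ribosomal-protein
#' genes. Tags shared by several listed genes are counted once.
#'
#' @param tags GRanges of 5' tags with a `count` column.
#' @param annotation GRanges of annotated TSSs with `gene_id`.
#' @param geneList Character vector of gene ids (missing ids warned).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param k k-mer length.
#' @param window Promoter window width.
#' @param ... Passed to [tagKmerFrequencies()].
#' @return Named numeric frequency vector as [tagKmerFrequencies()].
#' @export
geneSubsetFrequencies <- function(tags, annotation, geneList, genome,
                                  k = 3L, window = 1000L, ...) {
  missing <- setdiff(geneList, annotation$gene_id)
  if (length(missing)) {
    warning(length(missing), " gene id(s) not in the annotation")
  }
  sub <- annotation[annotation$gene_id %in% geneList]
  if (!length(sub)) stop("no listed gene found in the annotation")
  ptags <- extractPromoterTags(tags, sub, window = window, unique = TRUE)
  if (!length(ptags)) stop("no tags in the listed genes' windows")
  tagKmerFrequencies(ptags, genome, k = k, ...)
}
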