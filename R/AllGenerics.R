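#' @name capstart-accessors
#' @title Accessors for capstart classes
#' @description Slot accessors for [ConstructTemplate-class],
#'   [KmerCountTable-class] and [SimulationConfig-class] objects.
#' @param x An object.
#' @return The corresponding slot value; `totalAssigned()` returns the sum
#'   of assigned 7-mer counts.
NULL

#' @rdname capstart-accessors
#' @export
setGeneric("kmerCounts", function(x) standardGeneric("kmerCounts"))
#' @rdname capstart-accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname capstart-accessors
#' @export
setGeneric("conditionLabels", function(x) standardGeneric("conditionLabels"))
#' @rdname capstart-accessors
#' @export
setGeneric("replicateIndex", function(x) standardGeneric("replicateIndex"))
#' @rdname capstart-accessors
#' @export
setGeneric("excludedCounts", function(x) standardGeneric("excludedCounts"))
#' @rdname capstart-accessors
#' @export
setGeneric("totalAssigned", function(x) standardGeneric("totalAssigned"))
#' @rdname capstart-accessors
#' @export
setGeneric("promoterSeq", function(x) standardGeneric("promoterSeq"))
#' @rdname capstart-accessors
#' @export
setGeneric("downstreamSeq", function(x) standardGeneric("downstreamSeq"))
#' @rdname capstart-accessors
#' @export
setGeneric("anchorSeed", function(x) standardGeneric("anchorSeed"))
#' @rdname capstart-accessors
#' @export
setGeneric("cassetteLen", function(x) standardGeneric("cassetteLen"))
#' @rdname capstart-accessors
#' @export
setGeneric("expectedTssIndex", function(x) standardGeneric("expectedTssIndex"))
#' @rdname capstart-accessors
#' @export
setGeneric("spikeinSeq", function(x) standardGeneric("spikeinSeq"))

#' @rdname capstart-accessors
#' @export
setMethod("kmerCounts", "KmerCountTable", function(x) x@counts)
#' @rdname capstart-accessors
#' @export
setMethod("sampleId", "KmerCountTable", function(x) x@sampleId)
#' @rdname capstart-accessors
#' @export
setMethod("conditionLabels", "KmerCountTable", function(x) x@condition)
#' @rdname capstart-accessors
#' @export
setMethod("replicateIndex", "KmerCountTable", function(x) x@replicate)
#' @rdname capstart-accessors
#' @export
setMethod("excludedCounts", "KmerCountTable", function(x) x@excluded)
#' @rdname capstart-accessors
#' @export
setMethod("totalAssigned", "KmerCountTable", function(x) sum(x@counts))

#' @rdname capstart-accessors
#' @export
setMethod("promoterSeq", "ConstructTemplate", function(x) x@promoterSeq)
#' @rdname capstart-accessors
#' @export
setMethod("downstreamSeq", "ConstructTemplate", function(x) x@downstreamSeq)
#' @rdname capstart-accessors
#' @export
setMethod("anchorSeed", "ConstructTemplate", function(x) x@seed)
#' @rdname capstart-accessors
#' @export
setMethod("cassetteLen", "ConstructTemplate", function(x) x@cassetteLen)
#' @rdname capstart-accessors
#' @export
setMethod("expectedTssIndex", "ConstructTemplate",
          function(x) x@expectedTssIndex)
#' @rdname capstart-accessors
#' @export
setMethod("spikeinSeq", "ConstructTemplate", function(x) x@spikeinSeq)

setMethod("show", "ConstructTemplate", function(object) {
  cat("ConstructTemplate\n")
  cat(sprintf("  promoter:   %d nt (+1 at construct coordinate %d)\n",
              nchar(object@promoterSeq), object@expectedTssIndex))
  cat(sprintf("  cassette:   N x %d (randomized, per-molecule unknown)\n",
              object@cassetteLen))
  cat(sprintf("  downstream: %d nt, seed %s at offset %d\n",
              nchar(object@downstreamSeq), object@seed,
              regexpr(object@seed, object@downstreamSeq, fixed = TRUE) - 1L))
  cat(sprintf("  spike-in:   %s\n",
              if (is.na(object@spikeinSeq)) "absent" else
                sprintf("%d nt", nchar(object@spikeinSeq))))
})

setMethod("show", "KmerCountTable", function(object) {
  cond <- if (length(object@condition)) {
    paste(names(object@condition), object@condition, sep = "=",
          collapse = ", ")
  } else "none"
  cat(sprintf("KmerCountTable '%s' (replicate %d)\n", object@sampleId,
              object@replicate))
  cat(sprintf("  conditions: %s\n", cond))
  cat(sprintf("  %d-mers with counts > 0: %d of %d; assigned reads: %d\n",
              nchar(names(object@counts)[1L]), sum(object@counts > 0L),
              length(object@counts), sum(object@counts)))
  if (length(object@excluded)) {
    cat(sprintf("  excluded: %s\n",
                paste(names(object@excluded), object@excluded, sep = "=",
                      collapse = ", ")))
  }
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  seed %d, depth %g reads, read length %d nt\n",
              object@rngSeed, object@depth, object@readLength))
  cat(sprintf("  start offsets: %s\n",
              paste(names(object@tssPositionProbs),
                    signif(object@tssPositionProbs, 3), sep = ":",
                    collapse = " ")))
  cat(sprintf("  artifact Gs:   %s\n",
              paste(names(object@gArtifactProbs),
                    signif(object@gArtifactProbs, 3), sep = ":",
                    collapse = " ")))
  cat(sprintf("  spike-in fraction: %g\n", object@spikeinFraction))
})
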