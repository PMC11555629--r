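#' @include AllClasses.R
NULL

#' Accessors for IOscore classes
#'
#' Small accessor generics: \code{speciesName} returns the species
#' identifier(s) an object refers to; \code{pairInfo} the curated pair
#' table; \code{ioRatios} / \code{ioScores} the long ratio table and the
#' per-transcript score summary; \code{rbhPairs} the 1:1 ortholog pairs;
#' \code{orthologGroups} the consolidated group table;
#' \code{commonOrthologs} the hub ids common to all species;
#' \code{totalScores} the total-score record table; \code{degCalls} the
#' up/down/unchanged partition; \code{scoreThreshold} the calling threshold.
#'
#' @param x An IOscore object.
#' @param ... Passed to methods.
#' @return A vector or \linkS4class{DataFrame}; see each method.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("speciesName", function(x, ...) standardGeneric("speciesName"))
#' @rdname accessors
#' @export
setGeneric("pairInfo", function(x, ...) standardGeneric("pairInfo"))
#' @rdname accessors
#' @export
setGeneric("ioRatios", function(x, ...) standardGeneric("ioRatios"))
#' @rdname accessors
#' @export
setGeneric("ioScores", function(x, ...) standardGeneric("ioScores"))
#' @rdname accessors
#' @export
setGeneric("rbhPairs", function(x, ...) standardGeneric("rbhPairs"))
#' @rdname accessors
#' @export
setGeneric("orthologGroups", function(x, ...)
    standardGeneric("orthologGroups"))
#' @rdname accessors
#' @export
setGeneric("commonOrthologs", function(x, ...)
    standardGeneric("commonOrthologs"))
#' @rdname accessors
#' @export
setGeneric("totalScores", function(x, ...) standardGeneric("totalScores"))
#' @rdname accessors
#' @export
setGeneric("degCalls", function(x, ...) standardGeneric("degCalls"))
#' @rdname accessors
#' @export
setGeneric("scoreThreshold", function(x, ...)
    standardGeneric("scoreThreshold"))

#' @rdname accessors
setMethod("speciesName", "IOPairSet", function(x, ...) x@species)
#' @rdname accessors
setMethod("speciesName", "IOScoreTable", function(x, ...) x@species)
#' @rdname accessors
setMethod("speciesName", "RBHMap", function(x, ...) x@species)
#' @rdname accessors
setMethod("speciesName", "OrthologSet", function(x, ...) x@species)
#' @rdname accessors
setMethod("speciesName", "TotalScoreResult", function(x, ...) x@species)

#' @rdname accessors
setMethod("pairInfo", "IOPairSet", function(x, ...) x@pairs)
#' @rdname accessors
setMethod("ioRatios", "IOScoreTable", function(x, ...) x@ratios)
#' @rdname accessors
setMethod("ioScores", "IOScoreTable", function(x, ...) x@scores)
#' @rdname accessors
setMethod("rbhPairs", "RBHMap", function(x, ...) x@pairs)
#' @rdname accessors
setMethod("orthologGroups", "OrthologSet", function(x, ...) x@groups)
#' @rdname accessors
setMethod("commonOrthologs", "OrthologSet", function(x, ...)
    x@groups$hub_id[x@groups$is_common])
#' @rdname accessors
setMethod("totalScores", "TotalScoreResult", function(x, ...) x@records)
#' @rdname accessors
setMethod("scoreThreshold", "TotalScoreResult", function(x, ...)
    x@threshold)

#' @rdname accessors
setMethod("degCalls", "TotalScoreResult", function(x, ...) {
    if (is.na(x@threshold))
        stop("calls not yet made; run callDEGs() first")
    rec <- x@records
    ord <- order(-abs(rec$total), rec$hub_id)
    rec <- rec[ord, , drop = FALSE]
    list(up = rec[rec$call == "up", , drop = FALSE],
         down = rec[rec$call == "down", , drop = FALSE],
         unchanged = rec[rec$call == "unchanged", , drop = FALSE])
})

setMethod("show", "ScoringParams", function(object) {
    cat(sprintf(
        "ScoringParams: pseudocount %g TPM, %g-fold cutoff (|IO-ratio| > %.4f)\n",
        object@pseudocount, object@foldThreshold, log2(object@foldThreshold)))
})

setMethod("show", "SimParams", function(object) {
    cat(sprintf(
        "SimParams: %d species (hub %s), %d orthologs, %d pairs, seed %d\n",
        object@nSpecies, object@speciesNames[object@hubIndex],
        object@nOrthologs, sum(object@pairsPerSpecies), object@seed))
    cat(sprintf(
        "  planted: %.1f%% up / %.1f%% down at %g-fold; noise SD %g, dropout %g\n",
        100 * object@fracUp, 100 * object@fracDown, object@effectFold,
        object@noiseSd, object@dropoutProb))
})

setMethod("show", "IOPairSet", function(object) {
    cat(sprintf("IOPairSet for species '%s': %d transcripts, %d samples, %d pairs\n",
                object@species, nrow(object), ncol(object),
                nrow(object@pairs)))
})

setMethod("show", "IOScoreTable", function(object) {
    sc <- object@scores
    cat(sprintf(
        "IOScoreTable for '%s': %d transcripts over %d pairs; IO-score range [%d, %d]\n",
        object@species, nrow(sc), object@nPairs,
        if (nrow(sc)) min(sc$io_score) else 0L,
        if (nrow(sc)) max(sc$io_score) else 0L))
})

setMethod("show", "RBHMap", function(object) {
    cat(sprintf("RBHMap '%s' vs hub: %d reciprocal best hits\n",
                object@species, nrow(object@pairs)))
})

setMethod("show", "OrthologSet", function(object) {
    cat(sprintf(
        "OrthologSet on hub '%s': %d groups over %d non-hub species; %d common\n",
        object@hubSpecies, nrow(object@groups), length(object@species),
        sum(object@groups$is_common)))
})

setMethod("show", "TotalScoreResult", function(object) {
    rec <- object@records
    cat(sprintf("TotalScoreResult: %d common orthologs, %d species, %d pairs\n",
                nrow(rec), length(object@species),
                sum(object@pairsPerSpecies)))
    if (!is.na(object@threshold))
        cat(sprintf("  threshold +/-%d: %d up, %d down, %d unchanged\n",
                    object@threshold, sum(rec$call == "up"),
                    sum(rec$call == "down"), sum(rec$call == "unchanged")))
    else cat("  calls not yet made (see callDEGs)\n")
})
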