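#' @include AllClasses.R expression.R
NULL

#' Compute the IO-ratio of a sample pair
#'
#' The IO-ratio of a transcript in one curated pair is
#' \deqn{\log_2(TPM_{intersexual} + c) - \log_2(TPM_{ovary} + c)}
#' with pseudocount \eqn{c} (default 0.01 TPM) keeping the ratio finite at
#' zero expression. Vectorised over its TPM arguments.
#'
#' @param tpmIntersexual,tpmOvary Non-negative TPM values (recycled).
#' @param params \linkS4class{ScoringParams}.
#' @return Numeric log2-ratio(s).
#' @examples
#' computeIORatio(0.99, 0.19)   # log2(5)
#' computeIORatio(0.01, 0.03)   # -1
#' computeIORatio(0, 0)         # 0
#' @export
computeIORatio <- function(tpmIntersexual, tpmOvary,
                           params = scoringParams()) {
    stopifnot(is(params, "ScoringParams"))
    if (any(!is.finite(tpmIntersexual)) || any(!is.finite(tpmOvary)))
        stop("TPM values must be finite")
    if (any(tpmIntersexual < 0) || any(tpmOvary < 0))
        stop("TPM values must be >= 0")
    log2(tpmIntersexual + params@pseudocount) -
        log2(tpmOvary + params@pseudocount)
}

#' Classify an IO-ratio against the fold-change cutoff
#'
#' A pair is \code{"upregulated"} iff its IO-ratio is strictly greater than
#' \code{log2(foldThreshold)}, \code{"downregulated"} iff strictly less than
#' \code{-log2(foldThreshold)}, and \code{"unchanged"} otherwise. Ratios
#' exactly at the boundary are unchanged (the inequalities are strict).
#'
#' @param ioRatio Numeric log2-ratio(s); must be finite.
#' @param params \linkS4class{ScoringParams}.
#' @return Character vector of labels.
#' @examples
#' classifyRatio(c(2.40, log2(5), -2.33))
#' @export
classifyRatio <- function(ioRatio, params = scoringParams()) {
    stopifnot(is(params, "ScoringParams"))
    if (any(!is.finite(ioRatio))) stop("IO-ratios must be finite")
    cut <- log2(params@foldThreshold)
    ifelse(ioRatio > cut, "upregulated",
           ifelse(ioRatio < -cut, "downregulated", "unchanged"))
}

#' Score one species: IO-ratios per pair, IO-score per transcript
#'
#' Computes the IO-ratio for every (transcript, pair) in an
#' \linkS4class{IOPairSet}, classifies each against the fold cutoff, and
#' summarises per transcript as the integer IO-score: the count of
#' upregulated pairs minus the count of downregulated pairs (unchanged pairs
#' contribute zero). Ratios are taken pair by pair exactly as curated; no
#' replicate averaging takes place before ratioing.
#'
#' @param x An \linkS4class{IOPairSet}.
#' @param params \linkS4class{ScoringParams}.
#' @return An \linkS4class{IOScoreTable}.
#' @examples
#' tpm <- matrix(c(50, 1, 2, 1.1), 2, 2,
#'               dimnames = list(c("t1", "t2"), c("I1", "O1")))
#' x <- IOPairSet(tpm, data.frame(pair_id = "p1", intersexual = "I1",
#'                                ovary = "O1"), species = "spA")
#' ioScores(scoreSpecies(x))
#' @export
scoreSpecies <- function(x, params = scoringParams()) {
    stopifnot(is(x, "IOPairSet"))
    tpm <- SummarizedExperiment::assay(x, "TPM")
    pr <- as.data.frame(pairInfo(x))
    if (!nrow(pr)) stop("no curated pairs for species '", x@species, "'")
    ratio <- computeIORatio(tpm[, pr$intersexual, drop = FALSE],
                            tpm[, pr$ovary, drop = FALSE], params)
    colnames(ratio) <- pr$pair_id
    cut <- log2(params@foldThreshold)
    up <- ratio > cut
    down <- ratio < -cut
    n_up <- as.integer(rowSums(up))
    n_down <- as.integer(rowSums(down))
    labels <- matrix("unchanged", nrow(ratio), ncol(ratio))
    labels[up] <- "upregulated"
    labels[down] <- "downregulated"
    long <- S4Vectors::DataFrame(
        transcript_id = rep(rownames(tpm), times = nrow(pr)),
        pair_id = rep(pr$pair_id, each = nrow(tpm)),
        io_ratio = as.vector(ratio),
        label = as.vector(labels))
    scores <- S4Vectors::DataFrame(
        transcript_id = rownames(tpm),
        io_score = n_up - n_down,
        n_up = n_up, n_down = n_down,
        n_unchanged = as.integer(nrow(pr)) - n_up - n_down)
    new("IOScoreTable", species = x@species, params = params,
        ratios = long, scores = scores, nPairs = nrow(pr))
}

#' Pooled IO-ratio dispersion diagnostic for one species
#'
#' Pools the IO-ratios of all transcripts and pairs of a species and reports
#' their mean, standard deviation, and \code{fold_at_2sd = 2^(2 * sd)} —
#' the fold change sitting at the +2 SD boundary of the empirical ratio
#' distribution. Comparing \code{fold_at_2sd} with the classification
#' cutoff shows whether the fold threshold clears the bulk of biological and
#' technical ratio noise in that species.
#'
#' @param x An \linkS4class{IOScoreTable}.
#' @param expressedOnly If TRUE, transcripts whose every ratio is exactly
#'   zero (typically all-zero TPM in both members of every pair) are
#'   excluded from the pool. Default FALSE: all ratios are pooled.
#' @return Named list: \code{species}, \code{n}, \code{mean}, \code{sd},
#'   \code{fold_at_2sd}.
#' @export
ratioSdDiagnostic <- function(x, expressedOnly = FALSE) {
    stopifnot(is(x, "IOScoreTable"))
    r <- ioRatios(x)
    ratios <- r$io_ratio
    if (expressedOnly) {
        allzero <- tapply(ratios == 0, r$transcript_id, all)
        keep <- !(r$transcript_id %in% names(allzero)[allzero])
        ratios <- ratios[keep]
    }
    if (length(ratios) < 2L)
        stop("need at least 2 IO-ratios to compute a dispersion diagnostic")
    s <- stats::sd(ratios)
    list(species = x@species, n = length(ratios),
         mean = mean(ratios), sd = s, fold_at_2sd = 2^(2 * s))
}
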