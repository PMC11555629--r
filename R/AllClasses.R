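#' @import methods
#' @importFrom data.table as.data.table fread fwrite setorderv
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Scoring parameters for IO-ratio classification
#'
#' Holds the pseudocount added to TPM values before taking log2 ratios and
#' the fold-change cutoff used to classify a pair as up- or downregulated.
#' The defaults (0.01 TPM and 5-fold) are the values used throughout the
#' package; a 5-fold cutoff corresponds to calling pairs with IO-ratio
#' strictly above log2(5) "upregulated" and strictly below -log2(5)
#' "downregulated" (a 0.2-fold change).
#'
#' @slot pseudocount numeric(1), TPM units, added to both numerator and
#'   denominator so ratios stay finite at zero expression. Must be > 0.
#' @slot foldThreshold numeric(1), dimensionless fold-change cutoff, > 1.
#' @export
setClass("ScoringParams",
    representation(pseudocount = "numeric", foldThreshold = "numeric"),
    prototype(pseudocount = 0.01, foldThreshold = 5))

setValidity("ScoringParams", function(object) {
    msg <- NULL
    if (length(object@pseudocount) != 1L || !is.finite(object@pseudocount) ||
        object@pseudocount <= 0)
        msg <- c(msg, "'pseudocount' must be a single positive number")
    if (length(object@foldThreshold) != 1L ||
        !is.finite(object@foldThreshold) || object@foldThreshold <= 1)
        msg <- c(msg, "'foldThreshold' must be a single number > 1")
    if (is.null(msg)) TRUE else msg
})

#' Construct scoring parameters
#'
#' @param pseudocount Positive TPM offset (default 0.01).
#' @param foldThreshold Fold-change cutoff, > 1 (default 5).
#' @return A \linkS4class{ScoringParams} object.
#' @examples
#' scoringParams()
#' scoringParams(pseudocount = 0.5, foldThreshold = 2)
#' @export
scoringParams <- function(pseudocount = 0.01, foldThreshold = 5) {
    new("ScoringParams", pseudocount = as.numeric(pseudocount),
        foldThreshold = as.numeric(foldThreshold))
}

#' Simulation parameters for the synthetic fixture generator
#'
#' Describes a synthetic cross-species study: an ortholog universe over
#' \code{nSpecies} species anchored on a hub species, per-species
#' intersexual/ovary sample pairs, planted up/down expression effects, and
#' nuisance structure (paralog decoys, dropout, reciprocity-breaking hits).
#'
#' The defaults reproduce the shape of a seven-species protogynous-fish
#' study: pairs (4, 2, 2, 6, 2, 12, 3) summing to 31, 5000 orthologs, 50
#' planted up and 50 planted down at 25-fold, log-normal baselines and 0.25
#' log2 noise SD.
#'
#' @slot nSpecies integer, number of species (>= 2).
#' @slot hubIndex integer, which species anchors ortholog consolidation.
#' @slot nOrthologs integer, size of the ortholog universe (> 0).
#' @slot presenceProb probability a non-hub species retains an ortholog.
#' @slot pairsPerSpecies integer vector, intersexual/ovary pair count per
#'   species (length \code{nSpecies}).
#' @slot fracUp,fracDown fractions of orthologs planted as up/down.
#' @slot effectFold multiplicative TPM effect in intersexual samples (> 1).
#' @slot baselineLog2Mean,baselineLog2Sd log2-TPM baseline distribution.
#' @slot noiseSd per-sample log2 noise SD applied to intersexual samples.
#' @slot dropoutProb probability a true TPM is zeroed in one sample.
#' @slot nParalogs decoy proteins per non-hub species.
#' @slot fracBreakReciprocity fraction of decoys made best-in-one-direction
#'   only, which silently removes their target group from the RBH set.
#' @slot speciesNames character, species identifiers.
#' @slot seed integer master RNG seed; all substreams derive from it.
#' @export
setClass("SimParams",
    representation(
        nSpecies = "integer", hubIndex = "integer", nOrthologs = "integer",
        presenceProb = "numeric", pairsPerSpecies = "integer",
        fracUp = "numeric", fracDown = "numeric", effectFold = "numeric",
        baselineLog2Mean = "numeric", baselineLog2Sd = "numeric",
        noiseSd = "numeric", dropoutProb = "numeric", nParalogs = "integer",
        fracBreakReciprocity = "numeric", speciesNames = "character",
        seed = "integer"))

setValidity("SimParams", function(object) {
    msg <- NULL
    p1 <- function(x) length(x) == 1L && is.finite(x)
    if (!p1(object@nSpecies) || object@nSpecies < 2L)
        msg <- c(msg, "'nSpecies' must be >= 2")
    if (!p1(object@hubIndex) || object@hubIndex < 1L ||
        object@hubIndex > object@nSpecies)
        msg <- c(msg, "'hubIndex' must be in 1..nSpecies")
    if (!p1(object@nOrthologs) || object@nOrthologs < 1L)
        msg <- c(msg, "'nOrthologs' must be a positive integer")
    probs <- c(presenceProb = object@presenceProb,
               dropoutProb = object@dropoutProb,
               fracBreakReciprocity = object@fracBreakReciprocity,
               fracUp = object@fracUp, fracDown = object@fracDown)
    bad <- names(probs)[!is.finite(probs) | probs < 0 | probs > 1]
    if (length(bad))
        msg <- c(msg, sprintf("probabilities out of [0,1]: %s",
                              paste(bad, collapse = ", ")))
    if (is.finite(object@fracUp) && is.finite(object@fracDown) &&
        object@fracUp + object@fracDown > 1)
        msg <- c(msg, "'fracUp' + 'fracDown' must be <= 1")
    if (!p1(object@effectFold) || object@effectFold <= 1)
        msg <- c(msg, "'effectFold' must be > 1")
    if (length(object@pairsPerSpecies) != object@nSpecies)
        msg <- c(msg, "'pairsPerSpecies' must have one entry per species")
    else if (any(object@pairsPerSpecies < 1L))
        msg <- c(msg, "'pairsPerSpecies' entries must be >= 1")
    if (length(object@speciesNames) != object@nSpecies ||
        anyDuplicated(object@speciesNames))
        msg <- c(msg, "'speciesNames' must be nSpecies unique names")
    if (!p1(object@noiseSd) || object@noiseSd < 0)
        msg <- c(msg, "'noiseSd' must be >= 0")
    if (!p1(object@baselineLog2Sd) || object@baselineLog2Sd < 0)
        msg <- c(msg, "'baselineLog2Sd' must be >= 0")
    if (!p1(object@nParalogs) || object@nParalogs < 0L)
        msg <- c(msg, "'nParalogs' must be >= 0")
    if (!p1(object@seed))
        msg <- c(msg, "'seed' must be a single integer")
    if (is.null(msg)) TRUE else msg
})

#' Construct simulation parameters
#'
#' @param nSpecies,hubIndex,nOrthologs,presenceProb,pairsPerSpecies
#'   Universe shape; see \linkS4class{SimParams}.
#' @param fracUp,fracDown,effectFold Planted-effect design.
#' @param baselineLog2Mean,baselineLog2Sd,noiseSd,dropoutProb Expression
#'   model parameters (log2-TPM units for the first three).
#' @param nParalogs,fracBreakReciprocity Homology-search confounders.
#' @param speciesNames Species identifiers; defaults to sp01..spNN.
#' @param seed Master RNG seed.
#' @return A validated \linkS4class{SimParams} object.
#' @examples
#' simParams(nOrthologs = 100, seed = 7)
#' @export
simParams <- function(nSpecies = 7, hubIndex = 1, nOrthologs = 5000,
                      presenceProb = 0.9,
                      pairsPerSpecies = c(4, 2, 2, 6, 2, 12, 3),
                      fracUp = 0.01, fracDown = 0.01, effectFold = 25,
                      baselineLog2Mean = 5, baselineLog2Sd = 2,
                      noiseSd = 0.25, dropoutProb = 0.02, nParalogs = 200,
                      fracBreakReciprocity = 0, speciesNames = NULL,
                      seed = 1) {
    nSpecies <- as.integer(nSpecies)
    if (is.null(speciesNames))
        speciesNames <- sprintf("sp%02d", seq_len(max(nSpecies, 0L)))
    new("SimParams",
        nSpecies = nSpecies, hubIndex = as.integer(hubIndex),
        nOrthologs = as.integer(nOrthologs),
        presenceProb = as.numeric(presenceProb),
        pairsPerSpecies = as.integer(pairsPerSpecies),
        fracUp = as.numeric(fracUp), fracDown = as.numeric(fracDown),
        effectFold = as.numeric(effectFold),
        baselineLog2Mean = as.numeric(baselineLog2Mean),
        baselineLog2Sd = as.numeric(baselineLog2Sd),
        noiseSd = as.numeric(noiseSd),
        dropoutProb = as.numeric(dropoutProb),
        nParalogs = as.integer(nParalogs),
        fracBreakReciprocity = as.numeric(fracBreakReciprocity),
        speciesNames = as.character(speciesNames), seed = as.integer(seed))
}

#' Paired intersexual/ovary expression set for one species
#'
#' A \linkS4class{SummarizedExperiment} carrying one \code{"TPM"} assay
#' (transcripts x samples) together with the curated sample pairing: each
#' pair names one intersexual-gonad sample and one ovary sample. The pairing
#' is the unit at which IO-ratios are computed; a sample may serve in more
#' than one pair but a pair's two samples must differ.
#'
#' @slot pairs \linkS4class{DataFrame} with columns \code{pair_id},
#'   \code{intersexual}, \code{ovary} referencing assay columns.
#' @slot species character(1) species identifier.
#' @export
setClass("IOPairSet",
    contains = "SummarizedExperiment",
    representation(pairs = "DataFrame", species = "character"))

setValidity("IOPairSet", function(object) {
    msg <- NULL
    if (length(object@species) != 1L || !nzchar(object@species))
        msg <- c(msg, "'species' must be a single non-empty identifier")
    if (!"TPM" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'TPM' is required")
    else {
        tpm <- SummarizedExperiment::assay(object, "TPM")
        if (any(!is.finite(tpm)) || any(tpm < 0))
            msg <- c(msg, "TPM values must be finite and >= 0")
        if (anyDuplicated(rownames(tpm)))
            msg <- c(msg, "duplicate transcript ids")
        if (anyDuplicated(colnames(tpm)))
            msg <- c(msg, "duplicate sample ids")
    }
    pr <- object@pairs
    need <- c("pair_id", "intersexual", "ovary")
    if (!all(need %in% colnames(pr)))
        msg <- c(msg, "'pairs' needs columns pair_id, intersexual, ovary")
    else {
        if (anyDuplicated(pr$pair_id))
            msg <- c(msg, "pair_id values must be unique within a species")
        if (any(pr$intersexual == pr$ovary))
            msg <- c(msg, "a pair's intersexual and ovary samples must differ")
        missing <- setdiff(c(pr$intersexual, pr$ovary), colnames(object))
        if (length(missing))
            msg <- c(msg, sprintf("pair samples not in assay: %s",
                                  paste(missing, collapse = ", ")))
    }
    if (is.null(msg)) TRUE else msg
})

#' Per-species IO-ratio and IO-score table
#'
#' Result of scoring one species: a long table of per-(transcript, pair)
#' IO-ratios with their up/down/unchanged labels, and a per-transcript
#' summary with the integer IO-score (upregulated pairs minus downregulated
#' pairs).
#'
#' @slot species character(1).
#' @slot params the \linkS4class{ScoringParams} used.
#' @slot ratios \linkS4class{DataFrame}: transcript_id, pair_id, io_ratio,
#'   label.
#' @slot scores \linkS4class{DataFrame}: transcript_id, io_score, n_up,
#'   n_down, n_unchanged.
#' @slot nPairs integer(1), number of curated pairs for the species.
#' @export
setClass("IOScoreTable",
    representation(species = "character", params = "ScoringParams",
                   ratios = "DataFrame", scores = "DataFrame",
                   nPairs = "integer"))

setValidity("IOScoreTable", function(object) {
    msg <- NULL
    sc <- object@scores
    if (!all(c("transcript_id", "io_score", "n_up", "n_down",
               "n_unchanged") %in% colnames(sc)))
        msg <- c(msg, "malformed 'scores' table")
    else {
        if (any(sc$io_score != sc$n_up - sc$n_down))
            msg <- c(msg, "io_score must equal n_up - n_down")
        if (any(abs(sc$io_score) > object@nPairs))
            msg <- c(msg, "|io_score| cannot exceed the pair count")
    }
    if (!all(c("transcript_id", "pair_id", "io_ratio", "label") %in%
             colnames(object@ratios)))
        msg <- c(msg, "malformed 'ratios' table")
    if (is.null(msg)) TRUE else msg
})

#' Reciprocal-best-hit map between a species and the hub
#'
#' One-to-one ortholog pairs: (hub protein, species protein) such that each
#' is the other's best homology-search hit. Validity enforces the 1:1
#' property on both sides.
#'
#' @slot species character(1), the non-hub species.
#' @slot pairs \linkS4class{DataFrame}: hub_id, member_id.
#' @export
setClass("RBHMap",
    representation(species = "character", pairs = "DataFrame"))

setValidity("RBHMap", function(object) {
    msg <- NULL
    pr <- object@pairs
    if (!all(c("hub_id", "member_id") %in% colnames(pr)))
        msg <- c(msg, "'pairs' needs columns hub_id, member_id")
    else {
        if (anyDuplicated(pr$hub_id))
            msg <- c(msg, "a hub id appears more than once (RBH must be 1:1)")
        if (anyDuplicated(pr$member_id))
            msg <- c(msg, "a member id appears more than once (RBH must be 1:1)")
    }
    if (is.null(msg)) TRUE else msg
})

#' Consolidated ortholog groups anchored on hub protein IDs
#'
#' One group per hub protein seen in any RBH map (or supplied in the hub
#' universe), with the RBH partner per non-hub species (NA when absent) and
#' a flag marking groups common to all species — the candidate gene universe
#' passed to total-score aggregation.
#'
#' @slot hubSpecies character(1).
#' @slot species character, the non-hub species represented.
#' @slot groups \linkS4class{DataFrame}: hub_id, one member column per
#'   non-hub species, is_common.
#' @export
setClass("OrthologSet",
    representation(hubSpecies = "character", species = "character",
                   groups = "DataFrame"))

setValidity("OrthologSet", function(object) {
    msg <- NULL
    gr <- object@groups
    if (!all(c("hub_id", "is_common", object@species) %in% colnames(gr)))
        msg <- c(msg, "'groups' must carry hub_id, is_common and one column per species")
    else {
        if (anyDuplicated(gr$hub_id))
            msg <- c(msg, "hub ids must be unique")
        memb <- as.matrix(as.data.frame(gr)[, object@species, drop = FALSE])
        if (!identical(as.logical(gr$is_common),
                       as.logical(rowSums(!is.na(memb)) == length(object@species))))
            msg <- c(msg, "is_common must mean presence in every non-hub species")
    }
    if (is.null(msg)) TRUE else msg
})

#' Total IO-score records over common orthologs
#'
#' One record per common ortholog group: the signed per-species IO-score
#' contributions, their sum (the total IO-score), the DEG call at the
#' derived threshold, a flag for totals derived from a single species, and
#' the 1-based rank in descending-total order.
#'
#' @slot records \linkS4class{DataFrame}: hub_id, one contribution column
#'   per species, total, call, single_species, rank (and, after
#'   \code{annotateRecords}, reference_symbol).
#' @slot species character, species in contribution-column order.
#' @slot threshold integer(1), the calling threshold (NA before calling).
#' @slot pairsPerSpecies named integer, curated pair count per species.
#' @export
setClass("TotalScoreResult",
    representation(records = "DataFrame", species = "character",
                   threshold = "integer", pairsPerSpecies = "integer"))

setValidity("TotalScoreResult", function(object) {
    msg <- NULL
    rec <- object@records
    need <- c("hub_id", object@species, "total", "call", "single_species",
              "rank")
    if (!all(need %in% colnames(rec)))
        msg <- c(msg, "malformed 'records' table")
    else if (nrow(rec)) {
        contrib <- as.matrix(as.data.frame(rec)[, object@species,
                                                drop = FALSE])
        if (any(rec$total != rowSums(contrib)))
            msg <- c(msg, "total must equal the sum of contributions")
        if (sum(object@pairsPerSpecies) > 0 &&
            any(abs(rec$total) > sum(object@pairsPerSpecies)))
            msg <- c(msg, "|total| cannot exceed the study-wide pair count")
    }
    if (is.null(msg)) TRUE else msg
})
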