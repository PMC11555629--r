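#' @include AllClasses.R orthology.R scoring.R
NULL

#' Sum per-species IO-scores over common orthologs
#'
#' For every common ortholog group, gathers the IO-score of its member
#' transcript in each species and sums them into the total IO-score. Species
#' whose member has an IO-score of zero contribute 0 explicitly. A member
#' absent from its species score table (e.g. a hub protein with no
#' transcript in the expression data) contributes 0 and flags the record
#' when \code{strict = FALSE} (default; the affected-group count is
#' reported), or raises an error when \code{strict = TRUE}.
#'
#' Records carry a 1-based \code{rank} in descending-total order (ties by
#' hub id); the DEG \code{call} column is filled by \code{\link{callDEGs}}.
#'
#' @param orthologs An \linkS4class{OrthologSet}.
#' @param scoreTables Named list of \linkS4class{IOScoreTable}, one per
#'   species in the ortholog set, plus one for the hub species.
#' @param strict Error on unresolvable members instead of flagging.
#' @return A \linkS4class{TotalScoreResult} (calls not yet made).
#' @export
totalIOScore <- function(orthologs, scoreTables, strict = FALSE) {
    stopifnot(is(orthologs, "OrthologSet"),
              all(vapply(scoreTables, is, logical(1), "IOScoreTable")))
    tab_sp <- vapply(scoreTables, speciesName, character(1))
    names(scoreTables) <- tab_sp
    species <- c(orthologs@hubSpecies, speciesName(orthologs))
    missing_sp <- setdiff(species, tab_sp)
    if (length(missing_sp))
        stop("no IOScoreTable for species: ",
             paste(missing_sp, collapse = ", "))
    gr <- as.data.frame(orthologGroups(orthologs))
    gr <- gr[gr$is_common, , drop = FALSE]
    n <- nrow(gr)
    contrib <- matrix(0L, nrow = n, ncol = length(species),
                      dimnames = list(NULL, species))
    flagged <- rep(FALSE, n)
    for (sp in species) {
        member <- if (sp == orthologs@hubSpecies) gr$hub_id else gr[[sp]]
        sc <- ioScores(scoreTables[[sp]])
        idx <- match(member, sc$transcript_id)
        if (anyNA(idx)) {
            if (strict)
                stop("species '", sp, "': ", sum(is.na(idx)),
                     " ortholog member(s) absent from its score table, ",
                     "e.g. '", member[is.na(idx)][1L], "'")
            flagged <- flagged | is.na(idx)
        }
        contrib[, sp] <- ifelse(is.na(idx), 0L, sc$io_score[idx])
    }
    if (any(flagged))
        message(sum(flagged), " ortholog group(s) have members without ",
                "expression data; their missing contributions count as 0")
    total <- as.integer(rowSums(contrib))
    nonzero <- rowSums(contrib != 0L)
    ord <- order(-total, gr$hub_id)
    rank <- integer(n)
    rank[ord] <- seq_len(n)
    rec <- S4Vectors::DataFrame(hub_id = gr$hub_id)
    for (sp in species) rec[[sp]] <- as.integer(contrib[, sp])
    rec$total <- total
    rec$call <- rep(NA_character_, n)
    rec$single_species <- nonzero == 1L
    rec$no_expression_member <- flagged
    rec$rank <- rank
    pps <- vapply(scoreTables[species], function(t) t@nPairs, integer(1))
    new("TotalScoreResult", records = rec, species = species,
        threshold = NA_integer_, pairsPerSpecies = pps)
}

#' Derive the total IO-score calling threshold
#'
#' The threshold is a fixed fraction of the attainable maximum total
#' IO-score — the study-wide number of curated pairs — rounded up to the
#' next integer; the downregulation threshold is its negation. With 31
#' pairs and the default fraction 0.2 this gives ceiling(6.2) = 7, i.e.
#' calling at total IO-scores of at least +7 or at most -7.
#'
#' @param nPairsTotal Total curated pair count across species (>= 1).
#' @param fraction Fraction of the maximum (0 < fraction <= 1).
#' @return Positive integer threshold.
#' @examples
#' deriveTotalThreshold(31)        # 7
#' deriveTotalThreshold(10, 0.2)   # 2
#' @export
deriveTotalThreshold <- function(nPairsTotal, fraction = 0.2) {
    stopifnot(length(nPairsTotal) == 1L, nPairsTotal >= 1,
              length(fraction) == 1L, fraction > 0, fraction <= 1)
    as.integer(ceiling(fraction * nPairsTotal))
}

#' Call differentially expressed genes at a total-score threshold
#'
#' Partitions the records: \code{up} iff total >= +threshold, \code{down}
#' iff total <= -threshold, otherwise \code{unchanged} (the boundary is
#' inclusive: totals exactly at the threshold are called). The returned
#' object carries the filled \code{call} column and the threshold; use
#' \code{\link{degCalls}} to extract the three lists, each sorted by
#' descending absolute total then hub id.
#'
#' @param x A \linkS4class{TotalScoreResult}.
#' @param threshold Positive integer; defaults to
#'   \code{deriveTotalThreshold(sum(pairsPerSpecies))}.
#' @return \code{x} with calls made.
#' @export
callDEGs <- function(x, threshold = NULL) {
    stopifnot(is(x, "TotalScoreResult"))
    if (is.null(threshold))
        threshold <- deriveTotalThreshold(sum(x@pairsPerSpecies))
    threshold <- as.integer(threshold)
    stopifnot(length(threshold) == 1L, threshold >= 1L)
    rec <- x@records
    rec$call <- ifelse(rec$total >= threshold, "up",
                       ifelse(rec$total <= -threshold, "down", "unchanged"))
    x@records <- rec
    x@threshold <- threshold
    validObject(x)
    x
}

#' Long-format per-species composition of called totals
#'
#' Expands each called (up or down) record into its nonzero signed
#' per-species contributions — the data behind a stacked-bar rendering of
#' total IO-score composition. Records whose total derives from a single
#' species keep their \code{single_species} mark (the asterisk convention).
#'
#' @param x A called \linkS4class{TotalScoreResult}.
#' @return data.frame: hub_id, call, species, contribution,
#'   single_species, total.
#' @export
compositionTable <- function(x) {
    stopifnot(is(x, "TotalScoreResult"))
    if (is.na(x@threshold))
        stop("calls not yet made; run callDEGs() first")
    rec <- as.data.frame(x@records)
    rec <- rec[rec$call %in% c("up", "down"), , drop = FALSE]
    if (!nrow(rec))
        return(data.frame(hub_id = character(0), call = character(0),
                          species = character(0),
                          contribution = integer(0),
                          single_species = logical(0), total = integer(0)))
    out <- do.call(rbind, lapply(x@species, function(sp)
        data.frame(hub_id = rec$hub_id, call = rec$call, species = sp,
                   contribution = rec[[sp]],
                   single_species = rec$single_species, total = rec$total,
                   stringsAsFactors = FALSE)))
    out <- out[out$contribution != 0L, , drop = FALSE]
    out <- out[order(-abs(out$total), out$hub_id, out$species), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Attach reference-annotation symbols to total-score records
#'
#' Joins a best-hit table mapping hub protein ids to reference gene
#' ids/symbols (e.g. global-alignment hits against a model-organism
#' proteome). Per hub id the maximum-score reference is kept; score ties go
#' to the lexicographically smallest reference id (logged); duplicate
#' (hub_id, reference_id) rows keep their maximum score. Records without
#' any table row are reported unmapped.
#'
#' @param x A \linkS4class{TotalScoreResult}.
#' @param bestHitTable data.frame with columns \code{hub_id},
#'   \code{reference_id}, \code{score}.
#' @return \code{x} with a \code{reference_symbol} column (NA when
#'   unmapped); the unmapped count is stored in
#'   \code{metadata(totalScores(x))$n_unmapped}.
#' @export
annotateRecords <- function(x, bestHitTable) {
    stopifnot(is(x, "TotalScoreResult"), is.data.frame(bestHitTable),
              all(c("hub_id", "reference_id", "score") %in%
                  colnames(bestHitTable)))
    bh <- data.table::as.data.table(
        bestHitTable[, c("hub_id", "reference_id", "score")])
    # duplicate (hub, reference) rows: keep the maximum score
    bh <- bh[order(bh$hub_id, bh$reference_id, -bh$score)]
    ndup <- sum(duplicated(bh, by = c("hub_id", "reference_id")))
    if (ndup) message(ndup, " duplicate (hub_id, reference_id) row(s); ",
                      "keeping the maximum score")
    bh <- bh[!duplicated(bh, by = c("hub_id", "reference_id"))]
    data.table::setorderv(bh, c("hub_id", "score", "reference_id"),
                          order = c(1, -1, 1))
    top <- bh[!duplicated(bh, by = "hub_id")]
    # hub ids whose top score is shared by more than one reference
    tied <- if (nrow(bh))
        bh[, list(tie = sum(score == max(score)) > 1L), by = "hub_id"]
    else data.frame(tie = logical(0))
    if (any(tied$tie))
        message(sum(tied$tie), " hub id(s) with tied top scores; ",
                "lexicographically smallest reference kept")
    rec <- x@records
    idx <- match(rec$hub_id, top$hub_id)
    rec$reference_symbol <- top$reference_id[idx]
    n_unmapped <- sum(is.na(idx))
    md <- S4Vectors::metadata(rec)
    md$n_unmapped <- n_unmapped
    S4Vectors::metadata(rec) <- md
    x@records <- rec
    x
}
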