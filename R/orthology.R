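#' @include AllClasses.R
NULL

.OUTFMT6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                   "gapopen", "qstart", "qend", "sstart", "send",
                   "evalue", "bitscore")

#' Parse a 12-column tabular homology-search hit file
#'
#' Reads the standard 12-column tab-separated hit format (BLAST/Diamond
#' "outfmt 6": qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore; no header). Records failing the e-value
#' cutoff are dropped at parse time so the same filtered universe feeds both
#' search directions; the default cutoff 1e-3 matches passing \code{-e 1e-3}
#' to the search tool itself.
#'
#' @param path Hit file path.
#' @param evalueMax E-value cutoff; records with \code{evalue >} this are
#'   dropped.
#' @return data.frame of typed hit records (possibly zero rows).
#' @export
readHits <- function(path, evalueMax = 1e-3) {
    if (file.size(path) == 0L) {
        warning("empty hit file: '", path, "'")
        out <- as.data.frame(
            stats::setNames(rep(list(numeric(0)), 12L), .OUTFMT6_COLS))
        out$qseqid <- character(0)
        out$sseqid <- character(0)
        return(out[, .OUTFMT6_COLS])
    }
    dt <- data.table::fread(path, sep = "\t", header = FALSE,
                            data.table = FALSE, showProgress = FALSE)
    if (ncol(dt) != 12L)
        stop("'", path, "' has ", ncol(dt),
             " columns; 12-column tabular hits expected")
    colnames(dt) <- .OUTFMT6_COLS
    numcols <- .OUTFMT6_COLS[-(1:2)]
    for (cc in numcols) {
        dt[[cc]] <- suppressWarnings(as.numeric(dt[[cc]]))
        if (anyNA(dt[[cc]]))
            stop("unparseable numeric values in column '", cc, "' of '",
                 path, "'")
    }
    dt$qseqid <- as.character(dt$qseqid)
    dt$sseqid <- as.character(dt$sseqid)
    if (any(dt$evalue < 0)) stop("negative e-values in '", path, "'")
    dt[dt$evalue <= evalueMax, , drop = FALSE]
}

#' Resolve the best hit per query
#'
#' For each query the subject with the maximum bitscore is chosen. Multiple
#' HSPs for the same (query, subject) are first collapsed to their
#' max-bitscore record. Ties are broken deterministically: lower e-value,
#' then longer alignment, then lexicographically smallest subject id.
#' Self-hits (query equal to subject) are excluded defensively; they cannot
#' arise between distinct proteomes.
#'
#' @param hits data.frame of hit records from one search direction
#'   (see \code{\link{readHits}}).
#' @return Named character vector mapping query id to best subject id.
#' @examples
#' h <- data.frame(qseqid = "q", sseqid = c("a", "b"), pident = 90,
#'                 length = c(100, 100), mismatch = 0, gapopen = 0,
#'                 qstart = 1, qend = 100, sstart = 1, send = 100,
#'                 evalue = 1e-30, bitscore = c(250, 310))
#' bestHits(h)  # q -> b
#' @export
bestHits <- function(hits) {
    stopifnot(is.data.frame(hits))
    if (!nrow(hits)) return(stats::setNames(character(0), character(0)))
    dt <- data.table::as.data.table(
        hits[hits$qseqid != hits$sseqid,
             c("qseqid", "sseqid", "evalue", "bitscore", "length")])
    if (!nrow(dt)) return(stats::setNames(character(0), character(0)))
    # collapse HSPs per (query, subject) to the strongest record
    data.table::setorderv(dt, c("qseqid", "sseqid", "bitscore", "evalue",
                                "length"), order = c(1, 1, -1, 1, -1))
    dt <- dt[!duplicated(dt, by = c("qseqid", "sseqid"))]
    # then pick the best subject per query under the tie hierarchy
    data.table::setorderv(dt, c("qseqid", "bitscore", "evalue", "length",
                                "sseqid"), order = c(1, -1, 1, -1, 1))
    best <- dt[!duplicated(dt, by = "qseqid")]
    stats::setNames(best$sseqid, best$qseqid)
}

#' Reciprocal best hits between the hub and one species
#'
#' A pair (h, s) is a reciprocal best hit iff s is the best hit of h in the
#' hub-to-species direction and h is the best hit of s in the
#' species-to-hub direction. RBH pairs are taken as 1:1 orthologs.
#'
#' @param hitsHubToSp,hitsSpToHub Parsed hit tables for the two directions.
#' @param species Species identifier for the resulting map.
#' @return An \linkS4class{RBHMap}.
#' @export
reciprocalBestHits <- function(hitsHubToSp, hitsSpToHub, species) {
    fwd <- bestHits(hitsHubToSp)   # hub id -> species id
    rev <- bestHits(hitsSpToHub)   # species id -> hub id
    h <- names(fwd)
    s <- unname(fwd)
    keep <- !is.na(rev[s]) & rev[s] == h
    keep[is.na(keep)] <- FALSE
    ord <- order(h[keep])
    new("RBHMap", species = as.character(species),
        pairs = S4Vectors::DataFrame(hub_id = h[keep][ord],
                                     member_id = s[keep][ord]))
}

#' Consolidate per-species RBH maps into ortholog groups on the hub
#'
#' Joins the RBH maps of every non-hub species on hub protein ids: one group
#' per hub id appearing in any map (or supplied in \code{hubIds}), with the
#' species member or NA per species. A group is \emph{common} iff a member
#' exists for every non-hub species; the common subset is the candidate gene
#' universe passed to total-score aggregation.
#'
#' @param rbhMaps Named list of \linkS4class{RBHMap}, one per non-hub
#'   species (names are ignored; species are taken from the maps).
#' @param hubIds Optional character vector of hub protein ids to seed groups
#'   for (e.g. the full hub proteome); ids absent from every map yield
#'   all-NA, non-common groups.
#' @param hubSpecies Hub species identifier (default \code{"hub"}).
#' @return An \linkS4class{OrthologSet}.
#' @export
consolidateOrthologs <- function(rbhMaps, hubIds = NULL,
                                 hubSpecies = "hub") {
    stopifnot(length(rbhMaps) >= 1L,
              all(vapply(rbhMaps, is, logical(1), "RBHMap")))
    sp <- vapply(rbhMaps, speciesName, character(1))
    if (anyDuplicated(sp))
        stop("multiple RBH maps for one species: ",
             paste(unique(sp[duplicated(sp)]), collapse = ", "))
    all_hub <- sort(unique(c(unlist(lapply(rbhMaps, function(m)
        rbhPairs(m)$hub_id)), hubIds)))
    groups <- data.frame(hub_id = all_hub, stringsAsFactors = FALSE)
    for (i in seq_along(rbhMaps)) {
        pr <- rbhPairs(rbhMaps[[i]])
        if (anyDuplicated(pr$member_id))
            stop("species '", sp[i],
                 "': a member id maps to two hub ids (violates RBH 1:1)")
        groups[[sp[i]]] <- pr$member_id[match(all_hub, pr$hub_id)]
    }
    memb <- as.matrix(groups[, sp, drop = FALSE])
    groups$is_common <- rowSums(!is.na(memb)) == length(sp)
    new("OrthologSet", hubSpecies = as.character(hubSpecies),
        species = unname(sp), groups = S4Vectors::DataFrame(groups))
}
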