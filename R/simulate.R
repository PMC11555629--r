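#' @include AllClasses.R expression.R orthology.R
NULL

# Deterministic substream seed from the master seed; stays below 2^31.
.subSeed <- function(seed, k) {
    as.integer((abs(as.numeric(seed)) + 1000003 * k) %% 2147483646 + 1)
}

.memberId <- function(sp, i) sprintf("%s_p%05d", sp, i)
.decoyId <- function(sp, j) sprintf("%s_d%04d", sp, j)

.hit_rows <- function(q, s, bitscore, evalue = NULL, len = NULL) {
    n <- length(q)
    if (is.null(len)) len <- rep(250, n)
    pident <- rep(80, n)
    if (is.null(evalue)) evalue <- 2^(-bitscore / 2)
    data.frame(qseqid = q, sseqid = s,
               pident = pident, length = len,
               mismatch = round(len * (1 - pident / 100)),
               gapopen = rep(0L, n), qstart = rep(1L, n), qend = len,
               sstart = rep(1L, n), send = len,
               evalue = evalue, bitscore = bitscore,
               stringsAsFactors = FALSE)
}

#' Simulate an ortholog universe with reciprocal hit tables
#'
#' Generates a universe of \code{nOrthologs} ortholog groups over
#' \code{nSpecies} species anchored on the hub: the hub retains every
#' ortholog, each non-hub species retains each ortholog independently with
#' probability \code{presenceProb}. A fraction of groups is planted as up-
#' or downregulated (the planted class is shared across species). For every
#' retained ortholog, reciprocal hub/species hit-table records are emitted
#' whose bitscore is the highest in both directions; \code{nParalogs} decoy
#' proteins per species receive strictly lower bitscores (below 0.9 of the
#' true pair), except for a \code{fracBreakReciprocity} fraction of decoys
#' that outscore the true partner in the hub-to-species direction only,
#' silently removing their target group from the reciprocal-best-hit set.
#' A few sub-threshold junk records (e-value above 1e-3) exercise the parse
#' filter.
#'
#' @param params A \linkS4class{SimParams}.
#' @return List with \code{truth} (long data.frame: ortholog_id,
#'   planted_class, species, member_id, present), \code{hits} (per non-hub
#'   species, a list with \code{hub_to_sp} and \code{sp_to_hub} hit
#'   data.frames), \code{hubIds} (the hub protein universe), and
#'   \code{hubSpecies}.
#' @examples
#' u <- simulateUniverse(simParams(nSpecies = 3, nOrthologs = 20,
#'                                 pairsPerSpecies = c(2, 2, 2),
#'                                 nParalogs = 5, seed = 1))
#' head(u$truth)
#' @export
simulateUniverse <- function(params) {
    stopifnot(is(params, "SimParams"))
    validObject(params)
    n <- params@nOrthologs
    if (n == 0L) stop("empty universe: 'nOrthologs' must be positive")
    sp <- params@speciesNames
    hub <- sp[params@hubIndex]
    others <- sp[-params@hubIndex]

    set.seed(.subSeed(params@seed, 1))
    og <- sprintf("OG%05d", seq_len(n))
    n_up <- round(params@fracUp * n)
    n_down <- round(params@fracDown * n)
    idx <- sample.int(n)
    class <- rep("null", n)
    class[idx[seq_len(n_up)]] <- "up"
    if (n_down > 0) class[idx[n_up + seq_len(n_down)]] <- "down"

    present <- matrix(TRUE, nrow = n, ncol = length(sp),
                      dimnames = list(og, sp))
    for (s in others)
        present[, s] <- stats::runif(n) < params@presenceProb

    truth <- do.call(rbind, lapply(sp, function(s) data.frame(
        ortholog_id = og, planted_class = class, species = s,
        member_id = ifelse(present[, s], .memberId(s, seq_len(n)), ""),
        present = present[, s], stringsAsFactors = FALSE)))
    rownames(truth) <- NULL

    hits <- list()
    for (si in seq_along(others)) {
        s <- others[si]
        set.seed(.subSeed(params@seed, 10 + si))
        P <- which(present[, s])
        if (!length(P)) {
            empty <- .hit_rows(character(0), character(0), numeric(0))
            hits[[s]] <- list(hub_to_sp = empty, sp_to_hub = empty)
            next
        }
        bit_true <- round(stats::runif(length(P), 200, 1000), 1)
        hub_ids <- .memberId(hub, P)
        sp_ids <- .memberId(s, P)
        fwd <- .hit_rows(hub_ids, sp_ids, bit_true)
        rev <- .hit_rows(sp_ids, hub_ids, bit_true)

        npar <- params@nParalogs
        if (npar > 0L) {
            target <- sample(seq_along(P), npar, replace = TRUE)
            d_ids <- .decoyId(s, seq_len(npar))
            bit_decoy <- round(bit_true[target] *
                               stats::runif(npar, 0.4, 0.85), 1)
            n_break <- round(params@fracBreakReciprocity * npar)
            is_break <- seq_len(npar) <= n_break & length(P) >= 2L
            # honest decoys: reciprocal rows strictly below the true pair
            hb <- which(!is_break)
            if (length(hb)) {
                fwd <- rbind(fwd, .hit_rows(hub_ids[target[hb]], d_ids[hb],
                                            bit_decoy[hb]))
                rev <- rbind(rev, .hit_rows(d_ids[hb], hub_ids[target[hb]],
                                            bit_decoy[hb]))
            }
            # reciprocity breakers: beat the true partner hub->species,
            # but point at a different hub protein species->hub
            bk <- which(is_break)
            if (length(bk)) {
                bit_hi <- round(bit_true[target[bk]] * 1.1, 1)
                fwd <- rbind(fwd, .hit_rows(hub_ids[target[bk]], d_ids[bk],
                                            bit_hi))
                other_g <- vapply(target[bk], function(g)
                    sample(setdiff(seq_along(P), g), 1L), integer(1))
                rev <- rbind(rev, .hit_rows(d_ids[bk], hub_ids[other_g],
                                            round(bit_true[other_g] * 0.5,
                                                  1)))
            }
        }
        # sub-threshold junk rows, dropped by the parse-time e-value cutoff
        njunk <- max(1L, round(0.01 * length(P)))
        jq <- sample(hub_ids, njunk, replace = TRUE)
        js <- sample(sp_ids, njunk, replace = TRUE)
        junk_bit <- round(stats::runif(njunk, 20, 30), 1)
        junk_ev <- signif(stats::runif(njunk, 0.01, 0.9), 3)
        fwd <- rbind(fwd, .hit_rows(jq, js, junk_bit, evalue = junk_ev))
        rev <- rbind(rev, .hit_rows(js, jq, junk_bit, evalue = junk_ev))
        rownames(fwd) <- rownames(rev) <- NULL
        hits[[s]] <- list(hub_to_sp = fwd, sp_to_hub = rev)
    }
    list(truth = truth, hits = hits,
         hubIds = .memberId(hub, seq_len(n)), hubSpecies = hub)
}

#' Simulate paired intersexual/ovary expression from a universe
#'
#' For each species, every present ortholog member (and every decoy
#' paralog, as a null transcript) receives, per curated pair, a baseline
#' drawn as \code{2^Normal(baselineLog2Mean, baselineLog2Sd)} log2-TPM. The
#' ovary sample carries the baseline; the intersexual sample multiplies it
#' by \code{effectFold} (planted up) or divides by it (planted down) and
#' then applies multiplicative noise \code{2^Normal(0, noiseSd)}. Dropout
#' zeroes individual entries independently with probability
#' \code{dropoutProb}. TPMs are deliberately not renormalised to sum to 1e6
#' per sample: scoring uses within-transcript ratios only, and
#' renormalisation would couple transcripts.
#'
#' @param params A \linkS4class{SimParams}.
#' @param universe Output of \code{\link{simulateUniverse}} generated from
#'   the same params.
#' @return List with \code{tpm} (named list of transcripts x samples
#'   matrices), \code{manifest} (species, pair_id, intersexual_sample,
#'   ovary_sample), and \code{lengths} (named list of per-transcript
#'   nominal lengths, used when writing quant.sf files).
#' @export
simulateExpression <- function(params, universe) {
    stopifnot(is(params, "SimParams"))
    validObject(params)
    truth <- universe$truth
    sp <- params@speciesNames
    if (!setequal(unique(truth$species), sp))
        stop("universe is inconsistent with params: species differ")
    hub <- sp[params@hubIndex]
    l2eff <- log2(params@effectFold)

    tpm <- list()
    lengths <- list()
    manifest <- list()
    for (si in seq_along(sp)) {
        s <- sp[si]
        set.seed(.subSeed(params@seed, 100 + si))
        tr <- truth[truth$species == s & truth$present, , drop = FALSE]
        tx <- tr$member_id
        dir <- ifelse(tr$planted_class == "up", 1,
                      ifelse(tr$planted_class == "down", -1, 0))
        if (params@nParalogs > 0L) {
            extra <- if (s == hub)
                sprintf("%s_x%04d", s, seq_len(params@nParalogs))
            else .decoyId(s, seq_len(params@nParalogs))
            tx <- c(tx, extra)
            dir <- c(dir, rep(0, params@nParalogs))
        }
        nt <- length(tx)
        np <- params@pairsPerSpecies[si]
        base <- matrix(stats::rnorm(nt * np, params@baselineLog2Mean,
                                    params@baselineLog2Sd), nt, np)
        noise <- matrix(stats::rnorm(nt * np, 0, params@noiseSd), nt, np)
        ov <- 2^base
        ix <- 2^(base + dir * l2eff + noise)
        if (params@dropoutProb > 0) {
            ov[matrix(stats::runif(nt * np), nt, np) <
               params@dropoutProb] <- 0
            ix[matrix(stats::runif(nt * np), nt, np) <
               params@dropoutProb] <- 0
        }
        ix_names <- sprintf("%s_p%02d_I", s, seq_len(np))
        ov_names <- sprintf("%s_p%02d_O", s, seq_len(np))
        m <- matrix(0, nt, 2 * np,
                    dimnames = list(tx, as.vector(rbind(ix_names,
                                                        ov_names))))
        m[, ix_names] <- ix
        m[, ov_names] <- ov
        tpm[[s]] <- m
        lengths[[s]] <- stats::setNames(
            sample(300:5000, nt, replace = TRUE), tx)
        manifest[[s]] <- data.frame(
            species = s, pair_id = sprintf("%s_p%02d", s, seq_len(np)),
            intersexual_sample = ix_names, ovary_sample = ov_names,
            stringsAsFactors = FALSE)
    }
    list(tpm = tpm, manifest = do.call(rbind, c(manifest,
                                                make.row.names = FALSE)),
         lengths = lengths)
}

#' Assemble IOPairSet objects from simulated (or re-loaded) matrices
#'
#' @param tpm Named list of TPM matrices, one per species.
#' @param manifest Pair manifest data.frame covering those species.
#' @return Named list of \linkS4class{IOPairSet}.
#' @export
bundleToPairSets <- function(tpm, manifest) {
    stopifnot(is.list(tpm), !is.null(names(tpm)))
    out <- lapply(names(tpm), function(s) {
        pr <- manifest[manifest$species == s, , drop = FALSE]
        if (!nrow(pr)) stop("manifest has no pairs for species '", s, "'")
        IOPairSet(tpm[[s]], pr, species = s)
    })
    stats::setNames(out, names(tpm))
}

#' Write a self-describing fixture bundle to disk
#'
#' Lays out the generated study under \code{dir}: \code{config.yaml} (the
#' generating parameters), \code{truth.tsv}, \code{manifest.tsv},
#' \code{hits/<sp>__to__hub.tsv} and \code{hits/hub__to__<sp>.tsv}
#' (12-column tabular, no header), and one \code{quant.sf}-dialect file per
#' sample under \code{expr/<species>/}. Writing is pure formatting of the
#' supplied objects, so identical inputs give byte-identical bundles.
#'
#' @param dir Destination directory (created if needed).
#' @param params,universe,expression The generating
#'   \linkS4class{SimParams} and the outputs of
#'   \code{\link{simulateUniverse}} and \code{\link{simulateExpression}}.
#' @return \code{dir}, invisibly.
#' @export
writeFixtureBundle <- function(dir, params, universe, expression) {
    stopifnot(is(params, "SimParams"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(dir) || file.access(dir, 2L) != 0L)
        stop("destination '", dir, "' is not writable")
    yaml::write_yaml(simParamsToList(params), file.path(dir, "config.yaml"))
    data.table::fwrite(universe$truth, file.path(dir, "truth.tsv"),
                       sep = "\t")
    data.table::fwrite(expression$manifest, file.path(dir, "manifest.tsv"),
                       sep = "\t")
    hitdir <- file.path(dir, "hits")
    dir.create(hitdir, showWarnings = FALSE)
    for (s in names(universe$hits)) {
        data.table::fwrite(universe$hits[[s]]$hub_to_sp,
                           file.path(hitdir, sprintf("hub__to__%s.tsv", s)),
                           sep = "\t", col.names = FALSE)
        data.table::fwrite(universe$hits[[s]]$sp_to_hub,
                           file.path(hitdir, sprintf("%s__to__hub.tsv", s)),
                           sep = "\t", col.names = FALSE)
    }
    for (s in names(expression$tpm)) {
        sdir <- file.path(dir, "expr", s)
        dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
        m <- expression$tpm[[s]]
        len <- expression$lengths[[s]][rownames(m)]
        efflen <- pmax(len - 150, 10)
        for (smp in colnames(m)) {
            qt <- data.frame(Name = rownames(m), Length = unname(len),
                             EffectiveLength = unname(efflen),
                             TPM = m[, smp],
                             NumReads = round(m[, smp] * efflen / 100, 2))
            data.table::fwrite(qt, file.path(sdir,
                                             paste0(smp, ".quant.sf")),
                               sep = "\t")
        }
    }
    invisible(dir)
}

#' Serialise simulation parameters to a plain list (for YAML round trips)
#' @param params A \linkS4class{SimParams}.
#' @return Named list of the parameter values.
#' @export
simParamsToList <- function(params) {
    list(nSpecies = params@nSpecies, hubIndex = params@hubIndex,
         nOrthologs = params@nOrthologs,
         presenceProb = params@presenceProb,
         pairsPerSpecies = params@pairsPerSpecies,
         fracUp = params@fracUp, fracDown = params@fracDown,
         effectFold = params@effectFold,
         baselineLog2Mean = params@baselineLog2Mean,
         baselineLog2Sd = params@baselineLog2Sd,
         noiseSd = params@noiseSd, dropoutProb = params@dropoutProb,
         nParalogs = params@nParalogs,
         fracBreakReciprocity = params@fracBreakReciprocity,
         speciesNames = params@speciesNames, seed = params@seed)
}

#' Re-load a fixture bundle written by writeFixtureBundle
#'
#' @param dir Bundle directory.
#' @return List with \code{params}, \code{truth}, \code{manifest},
#'   \code{hits} (parsed at the default e-value cutoff), \code{tpm}
#'   (named list of matrices rebuilt from the quant.sf files), and
#'   \code{hubSpecies}.
#' @export
readFixtureBundle <- function(dir) {
    cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
    params <- do.call(simParams, cfg)
    truth <- data.table::fread(file.path(dir, "truth.tsv"), sep = "\t",
                               data.table = FALSE, showProgress = FALSE,
                               colClasses = list(character = "member_id"))
    truth$member_id[is.na(truth$member_id)] <- ""
    manifest <- readPairManifest(file.path(dir, "manifest.tsv"))
    hub <- params@speciesNames[params@hubIndex]
    others <- setdiff(params@speciesNames, hub)
    hits <- lapply(stats::setNames(others, others), function(s) list(
        hub_to_sp = readHits(file.path(dir, "hits",
                                       sprintf("hub__to__%s.tsv", s))),
        sp_to_hub = readHits(file.path(dir, "hits",
                                       sprintf("%s__to__hub.tsv", s)))))
    tpm <- lapply(stats::setNames(params@speciesNames,
                                  params@speciesNames), function(s) {
        files <- list.files(file.path(dir, "expr", s),
                            pattern = "\\.quant\\.sf$", full.names = TRUE)
        names(files) <- sub("\\.quant\\.sf$", "", basename(files))
        readExpression(files, format = "quant_sf")
    })
    list(params = params, truth = truth, manifest = manifest, hits = hits,
         tpm = tpm, hubSpecies = hub)
}

#' Simulate a complete fixture bundle in one call
#'
#' Convenience wrapper: \code{\link{simulateUniverse}} +
#' \code{\link{simulateExpression}}, optionally written to disk with
#' \code{\link{writeFixtureBundle}}.
#'
#' @param params A \linkS4class{SimParams}.
#' @param dir Optional destination directory.
#' @return List with \code{params}, \code{universe}, \code{expression}
#'   (and \code{dir} when written).
#' @export
simulateBundle <- function(params = simParams(), dir = NULL) {
    universe <- simulateUniverse(params)
    expression <- simulateExpression(params, universe)
    out <- list(params = params, universe = universe,
                expression = expression)
    if (!is.null(dir)) {
        writeFixtureBundle(dir, params, universe, expression)
        out$dir <- dir
    }
    out
}
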