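# Shared fixture builders and independent oracles for the test suite.

# Small, fast simulation setups
tinyParams <- function(seed = 1, ...) {
    defaults <- list(nSpecies = 3, hubIndex = 1, nOrthologs = 40,
                     presenceProb = 1, pairsPerSpecies = c(2, 2, 2),
                     fracUp = 0.1, fracDown = 0.1, nParalogs = 5,
                     noiseSd = 0.1, dropoutProb = 0, seed = seed)
    args <- utils::modifyList(defaults, list(...))
    do.call(simParams, args)
}

# In-memory end-to-end study: simulate, score, RBH, consolidate, total,
# call. Returns everything a test needs to compare against the truth.
runStudy <- function(params, threshold = NULL) {
    u <- simulateUniverse(params)
    e <- simulateExpression(params, u)
    tabs <- lapply(bundleToPairSets(e$tpm, e$manifest), scoreSpecies)
    hub <- u$hubSpecies
    maps <- lapply(setdiff(names(u$hits), hub), function(s)
        reciprocalBestHits(u$hits[[s]]$hub_to_sp, u$hits[[s]]$sp_to_hub,
                           s))
    orthologs <- consolidateOrthologs(maps, hubSpecies = hub)
    result <- callDEGs(totalIOScore(orthologs, tabs), threshold)
    list(universe = u, expression = e, scoreTables = tabs,
         rbhMaps = maps, orthologs = orthologs, result = result)
}

# Hub member ids of planted up/down orthologs present in all species
truthSets <- function(truth, hubSpecies) {
    pres <- tapply(truth$present, truth$ortholog_id, all)
    cls <- unique(truth[, c("ortholog_id", "planted_class")])
    hub <- truth[truth$species == hubSpecies, , drop = FALSE]
    hm <- stats::setNames(hub$member_id, hub$ortholog_id)
    common <- cls$ortholog_id[pres[cls$ortholog_id]]
    list(up = unname(hm[intersect(
             common, cls$ortholog_id[cls$planted_class == "up"])]),
         down = unname(hm[intersect(
             common, cls$ortholog_id[cls$planted_class == "down"])]),
         n_common = length(common))
}

# Independent brute-force best-hit oracle: exhaustive scan with the
# documented tie hierarchy, written without data.table.
bruteBestHits <- function(hits) {
    hits <- hits[hits$qseqid != hits$sseqid, , drop = FALSE]
    out <- character(0)
    for (q in sort(unique(hits$qseqid))) {
        h <- hits[hits$qseqid == q, , drop = FALSE]
        # collapse HSPs per subject to the strongest record
        coll <- NULL
        for (s in unique(h$sseqid)) {
            hs <- h[h$sseqid == s, , drop = FALSE]
            hs <- hs[order(-hs$bitscore, hs$evalue, -hs$length), ,
                     drop = FALSE]
            coll <- rbind(coll, hs[1L, , drop = FALSE])
        }
        coll <- coll[order(-coll$bitscore, coll$evalue, -coll$length,
                           coll$sseqid), , drop = FALSE]
        out[q] <- coll$sseqid[1L]
    }
    out
}

# Independent brute-force RBH oracle built on bruteBestHits
bruteRBH <- function(fwd, rev) {
    bf <- bruteBestHits(fwd)
    br <- bruteBestHits(rev)
    pairs <- data.frame(hub_id = character(0), member_id = character(0))
    for (h in names(bf)) {
        s <- bf[[h]]
        if (!is.na(br[s]) && identical(unname(br[s]), h))
            pairs <- rbind(pairs, data.frame(hub_id = h, member_id = s))
    }
    pairs[order(pairs$hub_id), , drop = FALSE]
}

# Random outfmt-6-shaped hit table for oracle-equivalence tests
randomHitTable <- function(nq, ns, nrows, qprefix = "q", sprefix = "s") {
    q <- sprintf("%s%03d", qprefix, sample.int(nq, nrows, replace = TRUE))
    s <- sprintf("%s%03d", sprefix, sample.int(ns, nrows, replace = TRUE))
    len <- sample(50:400, nrows, replace = TRUE)
    # coarse rounding provokes frequent bitscore/evalue ties
    bits <- round(stats::runif(nrows, 50, 70))
    data.frame(qseqid = q, sseqid = s, pident = 80, length = len,
               mismatch = round(len * 0.2), gapopen = 0L, qstart = 1L,
               qend = len, sstart = 1L, send = len,
               evalue = signif(10^(-sample(5:8, nrows, replace = TRUE)),
                               1),
               bitscore = bits, stringsAsFactors = FALSE)
}

# One-line quant.sf writer for parser tests
writeQuantSf <- function(path, ids, tpm,
                         len = rep(500L, length(ids))) {
    df <- data.frame(Name = ids, Length = len, EffectiveLength = len - 150,
                     TPM = tpm, NumReads = round(tpm * (len - 150) / 100))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}
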