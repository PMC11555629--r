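# Synthetic universe and expression generator: planted structure,
# determinism, and the fixture-bundle round trip.

test_that("presence extremes give all-common or zero-common universes", {
    # every species retains every ortholog, no confounders
    p1 <- tinyParams(seed = 2, presenceProb = 1, nParalogs = 0)
    st1 <- runStudy(p1)
    expect_identical(length(commonOrthologs(st1$orthologs)),
                     p1@nOrthologs)

    # one species retains nothing: the intersection is empty
    p0 <- tinyParams(seed = 2, presenceProb = 0, nParalogs = 0)
    u0 <- simulateUniverse(p0)
    tr <- u0$truth
    expect_true(all(!tr$present[tr$species == "sp02"]))
    maps0 <- lapply(setdiff(names(u0$hits), "sp01"), function(s)
        reciprocalBestHits(u0$hits[[s]]$hub_to_sp,
                           u0$hits[[s]]$sp_to_hub, s))
    os0 <- consolidateOrthologs(maps0, hubIds = u0$hubIds,
                                hubSpecies = "sp01")
    expect_identical(length(commonOrthologs(os0)), 0L)
})

test_that("common-ortholog count follows the binomial retention model", {
    # 500 orthologs, 7 species, presence 0.9: common ~ Binomial(500, 0.9^6)
    p <- 0.9^6
    lo <- stats::qbinom(0.005, 500, p)
    hi <- stats::qbinom(0.995, 500, p)
    counts <- vapply(1:50, function(seed) {
        u <- simulateUniverse(simParams(
            nSpecies = 7, nOrthologs = 500, presenceProb = 0.9,
            pairsPerSpecies = rep(2, 7), nParalogs = 0, seed = seed))
        pres <- tapply(u$truth$present, u$truth$ortholog_id, all)
        sum(pres)
    }, numeric(1))
    expect_equal(mean(counts), 500 * p, tolerance = 0.05)
    # each draw inside the 99% binomial band (allow the nominal 1% misses)
    expect_gte(mean(counts >= lo & counts <= hi), 0.94)
})

test_that("an empty universe is rejected", {
    expect_error(simParams(nOrthologs = 0), "positive")
})

test_that("generated hit tables are sound: brute-force RBH recovers the planted pairs", {
    for (seed in 1:3) {
        p <- tinyParams(seed = seed, nOrthologs = 25, presenceProb = 0.8,
                        nParalogs = 8)
        u <- simulateUniverse(p)
        for (s in names(u$hits)) {
            fwd <- u$hits[[s]]$hub_to_sp
            rev <- u$hits[[s]]$sp_to_hub
            # parse-time cutoff drops the junk rows the generator plants
            keep <- fwd$evalue <= 1e-3
            expect_true(any(!keep))
            oracle <- bruteRBH(fwd[keep, ], rev[rev$evalue <= 1e-3, ])
            tr <- u$truth[u$truth$species == s & u$truth$present, ]
            hub_tr <- u$truth[u$truth$species == "sp01", ]
            planted <- data.frame(
                hub_id = hub_tr$member_id[match(tr$ortholog_id,
                                                hub_tr$ortholog_id)],
                member_id = tr$member_id)
            planted <- planted[order(planted$hub_id), ]
            rownames(planted) <- rownames(oracle) <- NULL
            expect_identical(oracle, planted)
        }
    }
})

test_that("reciprocity-breaking decoys remove exactly their target groups", {
    p <- tinyParams(seed = 9, nOrthologs = 60, nParalogs = 20,
                    fracBreakReciprocity = 0.5)
    u <- simulateUniverse(p)
    for (s in names(u$hits)) {
        map <- reciprocalBestHits(u$hits[[s]]$hub_to_sp,
                                  u$hits[[s]]$sp_to_hub, s)
        n_present <- sum(u$truth$present[u$truth$species == s])
        expect_lt(nrow(rbhPairs(map)), n_present)
        # surviving pairs are still planted pairs, never decoys
        expect_false(any(grepl("_d\\d+$", rbhPairs(map)$member_id)))
    }
})

test_that("noiseless planted effects yield exact IO-ratios", {
    p <- tinyParams(seed = 4, nOrthologs = 30, noiseSd = 0,
                    effectFold = 25, fracUp = 0.2, fracDown = 0,
                    baselineLog2Mean = 8, baselineLog2Sd = 1,
                    nParalogs = 0)
    u <- simulateUniverse(p)
    e <- simulateExpression(p, u)
    tabs <- lapply(bundleToPairSets(e$tpm, e$manifest),
                   function(x) scoreSpecies(x))
    up_ids <- u$truth$member_id[u$truth$planted_class == "up" &
                                u$truth$present]
    null_ids <- u$truth$member_id[u$truth$planted_class == "null" &
                                  u$truth$present]
    for (tab in tabs) {
        r <- as.data.frame(ioRatios(tab))
        r_up <- r$io_ratio[r$transcript_id %in% up_ids]
        expect_equal(r_up, rep(log2(25), length(r_up)), tolerance = 1e-3)
        r_null <- r$io_ratio[r$transcript_id %in% null_ids]
        expect_equal(r_null, rep(0, length(r_null)), tolerance = 1e-9)
    }
})

test_that("planted-up pairs clear the 5-fold cutoff almost surely", {
    # P(N(log2 25, 0.25) > log2 5) = pnorm(log2 5 / 0.25) ~ 1 - 6e-21
    frac <- vapply(1:10, function(seed) {
        p <- tinyParams(seed = seed, nOrthologs = 60, noiseSd = 0.25,
                        effectFold = 25, fracUp = 0.5, fracDown = 0,
                        baselineLog2Mean = 8, baselineLog2Sd = 1,
                        nParalogs = 0)
        u <- simulateUniverse(p)
        e <- simulateExpression(p, u)
        up_ids <- u$truth$member_id[u$truth$planted_class == "up" &
                                    u$truth$present]
        ratios <- unlist(lapply(
            lapply(bundleToPairSets(e$tpm, e$manifest), scoreSpecies),
            function(tab) {
                r <- as.data.frame(ioRatios(tab))
                r$io_ratio[r$transcript_id %in% up_ids]
            }))
        mean(ratios > log2(5))
    }, numeric(1))
    expect_gte(mean(frac), 0.999)
})

test_that("identical seed and parameters give byte-identical bundles", {
    p <- tinyParams(seed = 17, nOrthologs = 15, nParalogs = 3)
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    simulateBundle(p, dir = d1)
    simulateBundle(p, dir = d2)
    f1 <- list.files(d1, recursive = TRUE)
    f2 <- list.files(d2, recursive = TRUE)
    expect_identical(f1, f2)
    for (f in f1)
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))
})

test_that("a written bundle round-trips to the generated objects", {
    p <- tinyParams(seed = 23, nOrthologs = 20, presenceProb = 0.85,
                    nParalogs = 4, dropoutProb = 0.05)
    d <- withr::local_tempdir()
    b <- simulateBundle(p, dir = d)
    back <- readFixtureBundle(d)
    expect_equal(simParamsToList(back$params), simParamsToList(p))
    expect_identical(back$truth, b$universe$truth)
    expect_identical(back$manifest, b$expression$manifest)
    for (s in names(back$tpm)) {
        orig <- b$expression$tpm[[s]]
        got <- back$tpm[[s]][rownames(orig), colnames(orig)]
        expect_equal(got, orig, tolerance = 1e-12)
    }
    # hit tables come back already filtered at the default cutoff
    for (s in names(back$hits)) {
        raw <- b$universe$hits[[s]]$hub_to_sp
        expect_identical(nrow(back$hits[[s]]$hub_to_sp),
                         sum(raw$evalue <= 1e-3))
    }
})

test_that("the default study design curates 31 pairs over 7 species", {
    p <- simParams(nOrthologs = 10, nParalogs = 0, seed = 1)
    e <- simulateExpression(p, simulateUniverse(p))
    expect_identical(nrow(e$manifest), 31L)
    counts <- table(e$manifest$species)
    expect_identical(as.integer(counts[p@speciesNames]),
                     p@pairsPerSpecies)
    # a bespoke split is honoured row for row
    p2 <- simParams(nSpecies = 7, nOrthologs = 5,
                    pairsPerSpecies = c(4, 2, 2, 6, 2, 12, 3),
                    nParalogs = 0, seed = 1)
    e2 <- simulateExpression(p2, simulateUniverse(p2))
    expect_identical(nrow(e2$manifest), 31L)
})

test_that("simulation parameter invariants are enforced", {
    expect_error(simParams(fracUp = 0.7, fracDown = 0.6), "<= 1")
    expect_error(simParams(presenceProb = 1.5), "out of \\[0,1\\]")
    expect_error(simParams(effectFold = 1), "> 1")
    expect_error(simParams(pairsPerSpecies = c(2, 2)), "one entry per")
    p <- tinyParams(seed = 1)
    u <- simulateUniverse(p)
    p2 <- tinyParams(seed = 1, nSpecies = 4, nOrthologs = 40,
                     pairsPerSpecies = c(2, 2, 2, 2))
    expect_error(simulateExpression(p2, u), "inconsistent")
})
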