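# Total IO-score aggregation, threshold derivation, DEG calling,
# composition tables and reference annotation.

# Build a TotalScoreResult directly from a contribution matrix
mkResult <- function(contrib, pairs = rep(5L, ncol(contrib))) {
    sp <- colnames(contrib)
    ids <- rownames(contrib)
    rec <- S4Vectors::DataFrame(
        hub_id = if (is.null(ids)) character(0) else ids)
    for (s in sp) rec[[s]] <- as.integer(contrib[, s])
    rec$total <- as.integer(rowSums(contrib))
    rec$call <- rep(NA_character_, nrow(contrib))
    rec$single_species <- rowSums(contrib != 0) == 1L
    rec$no_expression_member <- rep(FALSE, nrow(contrib))
    ord <- order(-rec$total, rec$hub_id)
    rec$rank <- integer(nrow(contrib))
    rec$rank[ord] <- seq_len(nrow(contrib))
    new("TotalScoreResult", records = rec, species = sp,
        threshold = NA_integer_,
        pairsPerSpecies = stats::setNames(as.integer(pairs), sp))
}

scoreTableFor <- function(species, ids, scores, nPairs = 12L) {
    n_up <- pmax(scores, 0L)
    n_down <- pmax(-scores, 0L)
    new("IOScoreTable", species = species, params = scoringParams(),
        ratios = S4Vectors::DataFrame(
            transcript_id = character(0), pair_id = character(0),
            io_ratio = numeric(0), label = character(0)),
        scores = S4Vectors::DataFrame(
            transcript_id = ids, io_score = as.integer(scores),
            n_up = as.integer(n_up), n_down = as.integer(n_down),
            n_unchanged = as.integer(nPairs - n_up - n_down)),
        nPairs = nPairs)
}

test_that("totals are sums of per-species contributions", {
    m1 <- new("RBHMap", species = "spB",
              pairs = S4Vectors::DataFrame(hub_id = c("h1", "h2"),
                                           member_id = c("b1", "b2")))
    m2 <- new("RBHMap", species = "spC",
              pairs = S4Vectors::DataFrame(hub_id = c("h1", "h2"),
                                           member_id = c("c1", "c2")))
    os <- consolidateOrthologs(list(m1, m2), hubSpecies = "spA")
    tabs <- list(scoreTableFor("spA", c("h1", "h2"), c(3L, 0L)),
                 scoreTableFor("spB", c("b1", "b2"), c(2L, 0L)),
                 scoreTableFor("spC", c("c1", "c2"), c(2L, 7L)))
    res <- totalIOScore(os, tabs)
    rec <- as.data.frame(totalScores(res))
    expect_identical(rec$total[rec$hub_id == "h1"], 7L)
    expect_identical(rec$total[rec$hub_id == "h2"], 7L)
    expect_false(rec$single_species[rec$hub_id == "h1"])
    # h2's total comes from spC alone
    expect_true(rec$single_species[rec$hub_id == "h2"])
    # ranks are 1-based in descending-total order, ties by hub id
    expect_identical(rec$rank, c(1L, 2L))
})

test_that("members without expression data contribute 0 and are flagged", {
    m1 <- new("RBHMap", species = "spB",
              pairs = S4Vectors::DataFrame(hub_id = "h1",
                                           member_id = "b1"))
    os <- consolidateOrthologs(list(m1), hubSpecies = "spA")
    tabs <- list(scoreTableFor("spA", "hX", 5L),     # h1 missing
                 scoreTableFor("spB", "b1", 4L))
    expect_error(totalIOScore(os, tabs, strict = TRUE), "absent from")
    expect_message(res <- totalIOScore(os, tabs), "count as 0")
    rec <- as.data.frame(totalScores(res))
    expect_identical(rec$total, 4L)
    expect_true(rec$no_expression_member)
})

test_that("threshold derivation is ceiling(fraction x pair total)", {
    expect_identical(deriveTotalThreshold(31, 0.2), 7L)
    expect_identical(deriveTotalThreshold(10, 0.2), 2L)
    expect_identical(deriveTotalThreshold(1, 0.2), 1L)
    expect_identical(deriveTotalThreshold(31, 0.5), 16L)
    expect_error(deriveTotalThreshold(0))
    expect_error(deriveTotalThreshold(31, 0))
})

test_that("DEG calling is boundary-inclusive and partitions the records", {
    contrib <- matrix(c(8L, 7L, 6L, -7L, -6L), ncol = 1,
                      dimnames = list(paste0("h", 1:5), "spA"))
    res <- callDEGs(mkResult(contrib, pairs = 31L), threshold = 7)
    calls <- degCalls(res)
    expect_identical(calls$up$total, c(8L, 7L))
    expect_identical(calls$down$total, -7L)
    expect_identical(sort(calls$unchanged$total), c(-6L, 6L))
    expect_identical(nrow(calls$up) + nrow(calls$down) +
                     nrow(calls$unchanged), 5L)
    expect_identical(scoreThreshold(res), 7L)

    # empty record set gives three empty lists
    empty <- callDEGs(mkResult(matrix(integer(0), 0, 1,
                                      dimnames = list(NULL, "spA"))),
                      threshold = 7)
    expect_identical(vapply(degCalls(empty), nrow, integer(1)),
                     c(up = 0L, down = 0L, unchanged = 0L))
})

test_that("raising the threshold never increases the called set", {
    set.seed(13)
    contrib <- matrix(sample(-6:6, 300, replace = TRUE), ncol = 3,
                      dimnames = list(sprintf("h%03d", 1:100),
                                      c("spA", "spB", "spC")))
    base <- mkResult(contrib, pairs = c(6L, 6L, 6L))
    n_called <- vapply(1:12, function(th) {
        calls <- degCalls(callDEGs(base, threshold = th))
        nrow(calls$up) + nrow(calls$down)
    }, integer(1))
    expect_true(all(diff(n_called) <= 0))
})

test_that("composition rows conserve totals and mark single-species genes", {
    contrib <- matrix(c(3L, 7L, 0L, 7L, 0L, 0L, 0L, 0L, -8L),
                      ncol = 3, byrow = TRUE,
                      dimnames = list(c("h1", "h2", "h3"),
                                      c("spA", "spB", "spC")))
    res <- callDEGs(mkResult(contrib, pairs = c(8L, 8L, 8L)),
                    threshold = 7)
    comp <- compositionTable(res)
    # only called records appear; nonzero contributions only
    expect_setequal(unique(comp$hub_id), c("h1", "h2", "h3"))
    expect_true(all(comp$contribution != 0L))
    for (h in unique(comp$hub_id))
        expect_identical(sum(comp$contribution[comp$hub_id == h]),
                         comp$total[comp$hub_id == h][1L])
    expect_true(all(comp$single_species[comp$hub_id == "h2"]))
    expect_true(all(comp$single_species[comp$hub_id == "h3"]))
    expect_false(any(comp$single_species[comp$hub_id == "h1"]))
})

test_that("annotation keeps the max-score reference and counts unmapped", {
    # 99 records, 90 of which have reference rows: 9 unmapped
    ids <- sprintf("h%03d", 1:99)
    contrib <- matrix(8L, 99, 1, dimnames = list(ids, "spA"))
    res <- callDEGs(mkResult(contrib, pairs = 31L), threshold = 7)
    bh <- data.frame(hub_id = rep(ids[1:90], each = 2),
                     reference_id = paste0("z",
                                           rep(1:90, each = 2),
                                           c("a", "b")),
                     score = rep(c(50, 99), times = 90))
    ann <- annotateRecords(res, bh)
    rec <- totalScores(ann)
    expect_identical(S4Vectors::metadata(rec)$n_unmapped, 9L)
    expect_identical(sum(is.na(rec$reference_symbol)), 9L)
    # per hub id, the higher-scoring reference won
    expect_identical(rec$reference_symbol[rec$hub_id == "h001"], "z1b")

    # empty table: everything unmapped
    ann0 <- annotateRecords(res, bh[0, ])
    expect_identical(
        S4Vectors::metadata(totalScores(ann0))$n_unmapped, 99L)
})

test_that("annotation ties go to the smallest reference id, like the oracle", {
    ids <- c("h1", "h2")
    contrib <- matrix(8L, 2, 1, dimnames = list(ids, "spA"))
    res <- callDEGs(mkResult(contrib, pairs = 31L), threshold = 7)
    set.seed(3)
    bh <- data.frame(hub_id = sample(rep(ids, each = 4)),
                     reference_id = sample(paste0("z", 1:8)),
                     score = sample(c(10, 20, 20, 30), 8, replace = TRUE))
    expect_message(ann <- annotateRecords(res, bh), regexp = NULL)
    rec <- totalScores(ann)
    # exhaustive-scan oracle with the stated tie rule
    oracle <- vapply(ids, function(h) {
        rows <- bh[bh$hub_id == h, ]
        rows <- rows[rows$score == max(rows$score), ]
        min(rows$reference_id)
    }, character(1))
    expect_identical(stats::setNames(rec$reference_symbol, rec$hub_id),
                     oracle[rec$hub_id])

    # duplicate (hub, reference) rows with conflicting scores keep the max
    dup <- data.frame(hub_id = c("h1", "h1", "h2"),
                      reference_id = c("zz", "zz", "zz"),
                      score = c(10, 80, 5))
    expect_message(ann2 <- annotateRecords(res, dup), "duplicate")
    expect_identical(totalScores(ann2)$reference_symbol, c("zz", "zz"))
})
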