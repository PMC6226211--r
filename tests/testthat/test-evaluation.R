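test_that("simulated profiles are noisy parent copies with inherited terms", {
    net <- generateGeneticNetwork(nStrains = 30, nQueries = 12, nModules = 3,
                                  seed = 51)
    ## multiplier 0: exact copies
    sim0 <- simulateProfiles(net$gi, net$ann, replicates = 2,
                             varianceMultiplier = 0, seed = 52)
    expect_identical(ncol(profiles(sim0)), 24L)
    pq <- parentQuery(sim0)
    for (k in c(1, 13, 24))
        expect_equal(unname(cgScores(profiles(sim0))[, k]),
                     unname(giScores(net$gi)[, pq[k]]))

    ## inherited terms equal the parent query's annotation row
    it <- inheritedTerms(sim0)
    B <- membership(net$ann)
    for (k in c(2, 20))
        expect_identical(it[[k]], colnames(B)[B[pq[k], ] > 0])

    ## noise variance scales with the strain variance and the multiplier
    net2 <- generateGeneticNetwork(nStrains = 6, nQueries = 40, nModules = 4,
                                   seed = 53)
    sim2 <- simulateProfiles(net2$gi, net2$ann, replicates = 5,
                             varianceMultiplier = 2, seed = 54)
    G <- giScores(net2$gi)
    delta <- cgScores(profiles(sim2)) -
        G[, parentQuery(sim2), drop = FALSE]
    n <- ncol(delta)
    for (i in c(1, 4)) {
        target <- 2 * var(G[i, ])
        sv <- var(delta[i, ])
        se <- target * sqrt(2 / (n - 1))    # chi-square sd of a sample var
        expect_lt(abs(sv - target), 3 * se)
    }
})

test_that("top-prediction precision-recall accumulates correctly", {
    top <- data.frame(condition_id = c("p1", "p2"),
                      term_id = c("T1", "T2"),
                      p = c(0.01, 0.02), z = c(3, 2))
    gold <- list(p1 = "T1", p2 = "T9")
    pr <- topPredictionPR(top, gold)
    expect_identical(pr$precision, c(1, 0.5))
    expect_equal(pr$recall, c(1, 1))
    expect_identical(attr(pr, "topAccuracy"), 0.5)

    ## all true positives: precision constant 1
    goldAll <- list(p1 = "T1", p2 = "T2")
    prAll <- topPredictionPR(top, goldAll)
    expect_true(all(prAll$precision == 1))

    ## final accuracy equals a direct recount on a random instance
    set.seed(55)
    n <- 40
    top2 <- data.frame(condition_id = sprintf("p%02d", 1:n),
                       term_id = sample(paste0("T", 1:5), n, TRUE),
                       p = runif(n), z = rnorm(n))
    gold2 <- setNames(lapply(1:n, function(i) sample(paste0("T", 1:5), 2)),
                      top2$condition_id)
    pr2 <- topPredictionPR(top2, gold2)
    recount <- sum(vapply(seq_len(n), function(i)
        top2$term_id[i] %in% gold2[[top2$condition_id[i]]], TRUE))
    expect_equal(max(pr2$recall), recount)
    expect_equal(attr(pr2, "topAccuracy"), recount / n)

    expect_warning(topPredictionPR(top2, gold2[-1]), "excluded")
})

test_that("gold rank shuffling approaches the analytic r/n law", {
    np <- 20
    p <- setNames(seq(0.01, 0.2, length.out = np), paste0("T", 1:np))
    z <- setNames(rep(1, np), names(p))
    ## unique smallest p -> rank 1
    g1 <- goldRankSignificance(p, z, "T1", nShuffles = 200, seed = 61)
    expect_identical(g1$rank, 1L)

    ## analytic law: P(shuffled rank <= r) = r / n_p
    g5 <- goldRankSignificance(p, z, "T5", nShuffles = 4000, seed = 62)
    expect_identical(g5$rank, 5L)
    expect_lt(abs(g5$pValue - 5 / np),
              3 * sqrt((5 / np) * (1 - 5 / np) / 4000))

    ## identical (p, z) everywhere: deterministic term-id tie order, p ~ 1
    ids <- sprintf("T%02d", 1:np)
    pT <- setNames(rep(0.5, np), ids)
    zT <- setNames(rep(1, np), ids)
    gT <- goldRankSignificance(pT, zT, "T09", nShuffles = 500, seed = 63)
    expect_identical(gT$rank, 9L)   # lexicographic tie-break on padded ids
    expect_gt(gT$pValue, 0.4)
})

test_that("effective rank takes the best sufficiently-overlapping term", {
    ann <- tinyAnn(genes = paste0("g", 1:10),
                   terms = list(gold = paste0("g", 1:4),
                                near = paste0("g", c(1, 2, 9, 10)),
                                far = paste0("g", 7:10)))
    ranked <- c("far", "near", "x", "y", "gold")
    expect_identical(effectiveRank(ranked, "gold", ann, 0.4), 2L)
    ## no related term above threshold: effective rank = gold rank
    expect_identical(effectiveRank(ranked, "gold", ann, 0.9), 5L)
    ## threshold 1 with non-nested terms: only the gold term qualifies
    expect_identical(effectiveRank(ranked, "gold", ann, 1), 5L)
})

test_that("per-term normalized AUPR matches hand and brute-force values", {
    ## perfect ranking of 2 positives among 4: AUPR 1, random 0.5
    p <- setNames(c(0.01, 0.02, 0.5, 0.6), paste0("c", 1:4))
    z <- setNames(rep(0, 4), names(p))
    res <- perTermAupr(p, z, positives = c("c1", "c2"))
    expect_identical(res$aupr, 1)
    expect_identical(res$normalized, 2)

    ## positives ranked last: AP = (1/3 + 2/4)/2 = 5/12, normalized 5/6
    res2 <- perTermAupr(p, z, positives = c("c3", "c4"))
    expect_equal(res2$aupr, 5 / 12)
    expect_equal(res2$normalized, 5 / 6)

    ## exhaustive check against the oracle on all length-6 label patterns
    p6 <- setNames(seq(0.1, 0.6, by = 0.1), paste0("c", 1:6))
    z6 <- setNames(rep(0, 6), names(p6))
    for (bits in 1:63) {
        lab <- as.logical(bitwAnd(bits, 2^(0:5)))
        pos <- names(p6)[lab]
        got <- perTermAupr(p6, z6, pos)
        expect_equal(got$aupr, oracleAveragePrecision(lab), tolerance = 1e-12)
    }

    ## random scores average out to ~1 after normalization (the bias of a
    ## random ranking's average precision vanishes as lists grow, so use a
    ## reasonably long list with many positives)
    set.seed(64)
    ids <- sprintf("c%03d", 1:400)
    norms <- replicate(100, {
        pr <- setNames(runif(400), ids)
        perTermAupr(pr, z = setNames(rep(0, 400), ids),
                    positives = ids[1:200])$normalized
    })
    expect_lt(abs(mean(norms) - 1), 0.05)
})

test_that("Braun-Blanquet similarity divides by the larger set", {
    expect_identical(braunBlanquet(c(1, 2, 3), c(2, 3, 4, 5)), 0.5)
    expect_identical(braunBlanquet(letters[1:3], letters[1:3]), 1)
    expect_identical(braunBlanquet("a", "b"), 0)
    expect_error(braunBlanquet(character(), "a"), "empty")

    tmp <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("cpdA\tf1\tf2\tf3", "cpdB\tf2\tf3\tf4\tf5"), tmp)
    fp <- readFingerprints(tmp)
    expect_identical(braunBlanquet(fp$cpdA, fp$cpdB), 0.5)
})

test_that("the prediction sort order is total and deterministic", {
    p <- c(A = 0.5, B = 0.1, C = 0.1, D = 0.1)
    z <- c(A = 9, B = 2, C = 5, D = 2)
    ## p asc, then z desc, then id asc
    expect_identical(names(p)[orderPredictions(p, z)],
                     c("C", "B", "D", "A"))
})
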