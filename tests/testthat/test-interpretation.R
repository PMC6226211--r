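test_that("importance profiles are the mean qualifying profile times the cg profile", {
    ## one annotated query at [1,0], cg [2,0]: inner product 2 qualifies
    Gp <- matrix(c(1, 0), 2, dimnames = list(c("s1", "s2"), "q1"))
    gn <- GeneticInteractionMatrix(Gp, normalized = TRUE)
    ann <- tinyAnn(genes = "q1", terms = list(T1 = "q1"))
    cgp <- c(s1 = 2, s2 = 0)
    ip <- importanceProfile(cgp, gn, ann, "T1")
    expect_identical(ip$mean_gi, c(1, 0))
    expect_identical(ip$importance, c(2, 0))
    expect_identical(attr(ip, "contributingQueries"), "q1")

    ## two qualifying queries average elementwise
    Gp2 <- matrix(c(1, 0, 0, 1), 2,
                  dimnames = list(c("s1", "s2"), c("q1", "q2")))
    gn2 <- GeneticInteractionMatrix(Gp2, normalized = TRUE)
    ann2 <- tinyAnn(genes = c("q1", "q2"), terms = list(T1 = c("q1", "q2")))
    ip2 <- importanceProfile(c(s1 = 2, s2 = 2), gn2, ann2, "T1")
    expect_identical(ip2$mean_gi, c(0.5, 0.5))
    expect_identical(ip2$importance, c(1, 1))

    ## below-threshold queries leave an empty, flagged result
    ip3 <- importanceProfile(c(s1 = 0.5, s2 = 0.5), gn2, ann2, "T1")
    expect_true(attr(ip3, "empty"))
    expect_identical(nrow(ip3), 0L)

    expect_error(importanceProfile(cgp, gn, ann, "nope"), "unknown term")
})

test_that("importance is positive exactly when the two interactions agree in sign", {
    set.seed(71)
    for (rep in 1:5) {
        g <- randomMatrix(12, 4, prefix = c("s", "q"))
        gn <- l2NormalizeQueries(GeneticInteractionMatrix(g))
        ann <- tinyAnn(genes = paste0("q", 1:4),
                       terms = list(T1 = paste0("q", 1:4)))
        cgp <- setNames(rnorm(12, sd = 4), rownames(g))
        ip <- importanceProfile(cgp, gn, ann, "T1", threshold = -Inf)
        agree <- sign(ip$cg_score) == sign(ip$mean_gi)
        nonzero <- ip$importance != 0
        expect_identical(ip$importance[nonzero] > 0, agree[nonzero])
        expect_equal(ip$importance, ip$cg_score * ip$mean_gi,
                     tolerance = 1e-12)
    }
})

test_that("contribution summaries count interactions and sign splits", {
    d <- data.frame(strain_id = c("s1", "s2", "s3"),
                    cg_score = c(-6, 3, 0.5),
                    importance = c(0.5, -0.2, 0.9))
    cs <- contributionSummary(list(cmpdA = d), cgCutoff = 2.5,
                              impCutoff = 0.1)
    per <- cs$perCompound
    expect_identical(per$n_interactions, 2L)      # s1, s2
    expect_identical(per$n_contributing, 1L)      # s1 only
    expect_identical(per$fraction, 0.5)
    expect_identical(per$fraction_neg, 1)         # 1/1 negative
    expect_identical(per$fraction_pos, 0)         # 0/1 positive

    ## all importance below cutoff: fraction 0
    d0 <- data.frame(strain_id = "s1", cg_score = -9, importance = 0.01)
    expect_identical(
        contributionSummary(list(x = d0))$perCompound$fraction, 0)

    ## pooled counts are the sums of per-compound counts
    d2 <- data.frame(strain_id = c("s1", "s2"),
                     cg_score = c(-7, -8), importance = c(1, 0.05))
    cs2 <- contributionSummary(list(a = d, b = d2))
    expect_identical(cs2$pooled$n_interactions,
                     sum(cs2$perCompound$n_interactions))
    expect_identical(cs2$pooled$n_contributing,
                     sum(cs2$perCompound$n_contributing))

    ## compounds without interactions at the cutoff leave the mean unaffected
    dEmpty <- data.frame(strain_id = "s1", cg_score = 0.1, importance = 1)
    cs3 <- contributionSummary(list(a = d, none = dEmpty))
    expect_identical(cs3$meanFraction, 0.5)
})

test_that("strain overrepresentation matches the exact hypergeometric oracle", {
    ## 4 strains, 20 strong-negative observations; strain s1 sits mostly in
    ## the non-contributing region
    rec <- data.frame(
        strain_id = rep(c("s1", "s2", "s3", "s4"), each = 5),
        cg_score = rep(-8, 20),
        importance = c(rep(0.0, 4), 0.9,          # s1: 4 in region
                       rep(0.9, 4), 0.05,         # s2: 1 in region
                       rep(1.2, 5),               # s3: 0
                       0.02, rep(0.8, 4)))        # s4: 1
    out <- strainOverrepresentation(rec, zCutoff = -5, band = 0.1)
    K <- 6; N <- 20
    for (i in seq_len(nrow(out))) {
        expect_equal(out$p[i],
                     oracleHyperP(N, K, out$n_background[i],
                                  out$n_in_region[i]),
                     tolerance = 1e-12)
    }
    expect_identical(out$strain_id[1], "s1")      # most enriched first
    expect_identical(out$p[out$strain_id == "s3"], 1)  # zero in-region
    expect_equal(out$p_adjusted, oracleBH(out$p), tolerance = 1e-12)

    ## observations above the z cutoff are not background
    recNone <- data.frame(strain_id = "s1", cg_score = -1, importance = 0)
    expect_error(strainOverrepresentation(recNone), "empty background")
})

test_that("strong contributions on the negative-signal fixture are negative interactions", {
    ## planted screen whose signal lives in sensitivity (negative) scores:
    ## strains contributing strongly to the planted term's prediction should
    ## be overwhelmingly negative interactions
    net <- generateGeneticNetwork(seed = 81)
    scr <- generateScreen(net$gi, net$ann, nActive = 12, nInactive = 0,
                          nControls = 0, signal = "negative", seed = 82)
    gn <- l2NormalizeQueries(net$gi)
    truth <- scr$truth
    profs <- list()
    for (id in truth$condition_id) {
        cgp <- cgScores(scr$cg)[, id]
        ip <- importanceProfile(cgp, gn, net$ann, plantedTermOf(truth, id))
        if (!attr(ip, "empty")) profs[[id]] <- ip
    }
    cs <- contributionSummary(profs, cgCutoff = 5, impCutoff = 0.5)
    expect_gt(cs$pooled$negative_share_of_contributing, 0.9)
})
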