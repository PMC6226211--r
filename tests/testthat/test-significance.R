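test_that("control-derived z and empirical p match hand calculations", {
    Xb <- matrix(c(1, 3), 2, dimnames = list(c("b1", "b2"), "T1"))
    Xa <- matrix(c(2, 5, 3), 3, dimnames = list(c("a1", "a2", "a3"), "T1"))
    st <- controlStatistics(Xa, Xb)
    expect_equal(st$z["a1", "T1"], 0)                 # at the control mean
    expect_equal(st$z["a2", "T1"], 3 / sqrt(2))       # sd with n-1 = sqrt(2)
    expect_identical(st$p["a2", "T1"], 0)             # beats both controls
    ## tie with the largest control counts: p >= 1/n_b
    expect_identical(st$p["a3", "T1"], 1 / 2)

    expect_error(controlStatistics(Xa, Xb[1, , drop = FALSE]), "at least 2")
})

test_that("control statistics match the naive loop oracle on random instances", {
    set.seed(21)
    for (rep in 1:3) {
        Xa <- randomMatrix(5, 4, prefix = c("a", "T"))
        Xb <- randomMatrix(9, 4, prefix = c("b", "T"))
        colnames(Xb) <- colnames(Xa)
        st <- controlStatistics(Xa, Xb)
        or <- oracleControlStats(Xa, Xb)
        expect_equal(st$z, or$z, tolerance = 1e-12)
        expect_equal(st$p, or$p, tolerance = 1e-15)
    }
})

test_that("zero-variance terms get the sentinel z but a valid empirical p", {
    Xb <- matrix(c(2, 2, 2), 3, dimnames = list(paste0("b", 1:3), "T1"))
    Xa <- matrix(c(2, 7), 2, dimnames = list(c("a1", "a2"), "T1"))
    st <- controlStatistics(Xa, Xb)
    expect_identical(st$z["a1", "T1"], 0)         # numerator 0
    expect_identical(st$z["a2", "T1"], 1e30)      # positive sentinel
    expect_identical(st$zeroVarTerms, "T1")
    expect_identical(st$p["a1", "T1"], 1)         # tied with all controls
    expect_identical(st$p["a2", "T1"], 0)
})

test_that("within-profile z matches hand and oracle calculations", {
    ann <- tinyAnn()
    ## S row [1,2,3], term {g1,g3}: term mean equals profile mean -> z = 0
    S <- matrix(1:3, 1, dimnames = list("c1", c("g1", "g2", "g3")))
    st <- withinStatistics(S, ann, nPerm = 50, seed = 1)
    expect_equal(st$z["c1", "T1"], 0)

    ## S row [0,0,4], singleton term {g3}: z = 2/sqrt(3)
    ann1 <- tinyAnn(terms = list(T1 = "g3"))
    S2 <- matrix(c(0, 0, 4), 1, dimnames = list("c1", c("g1", "g2", "g3")))
    st2 <- withinStatistics(S2, ann1, nPerm = 50, seed = 1)
    expect_equal(st2$z["c1", "T1"], 2 / sqrt(3))

    set.seed(22)
    S3 <- randomMatrix(5, 8, prefix = c("c", "g"))
    ann3 <- tinyAnn(genes = paste0("g", 1:8),
                    terms = list(T1 = paste0("g", 1:3),
                                 T2 = paste0("g", c(2, 5, 7, 8)),
                                 T3 = paste0("g", 4:8),
                                 T4 = "g6"))
    st3 <- withinStatistics(S3, ann3, nPerm = 10, seed = 2)
    expect_equal(st3$z, oracleWithinZ(S3, membership(ann3)),
                 tolerance = 1e-12)
})

test_that("constant similarity rows give permutation p of exactly 1", {
    S <- matrix(2, 2, 4, dimnames = list(c("c1", "c2"), paste0("g", 1:4)))
    ann <- tinyAnn(genes = paste0("g", 1:4),
                   terms = list(T1 = c("g1", "g2")))
    st <- withinStatistics(S, ann, nPerm = 100, seed = 3)
    expect_true(all(st$p == 1))
    expect_true(all(st$z == 0))
    expect_identical(st$zeroVarConditions, c("c1", "c2"))
})

test_that("within permutation p is an exact tail count and seed-stable", {
    set.seed(23)
    S <- randomMatrix(3, 10, prefix = c("c", "g"))
    ann <- tinyAnn(genes = paste0("g", 1:10),
                   terms = list(T1 = paste0("g", 1:4),
                                T2 = paste0("g", 6:10)))
    st <- withinStatistics(S, ann, nPerm = 400, seed = 4)
    expect_true(all(st$p >= 0 & st$p <= 1))
    expect_true(all(abs(st$p * 400 - round(st$p * 400)) < 1e-9))

    ## identical seed reproduces; chunking does not change the result
    st2 <- withinStatistics(S, ann, nPerm = 400, seed = 4)
    expect_identical(st$p, st2$p)

    ## two seeds agree within Monte-Carlo error at n_l = 10000
    stA <- withinStatistics(S, ann, nPerm = 10000, seed = 5)
    stB <- withinStatistics(S, ann, nPerm = 10000, seed = 6)
    for (idx in list(c(1, 1), c(2, 2), c(3, 1))) {
        p <- stA$p[idx[1], idx[2]]
        tol <- 3 * sqrt(max(p * (1 - p), 1e-4) / 10000)
        expect_lt(abs(p - stB$p[idx[1], idx[2]]), max(tol, 0.02))
    }
})

test_that("empirical control p is uniform-or-conservative under the null", {
    ## treatments generated exactly like controls: rank statistic property
    ## P(p <= q) <= q + 1/n_b for every q
    set.seed(24)
    nb <- 40
    ps <- replicate(300, {
        Xb <- matrix(rnorm(nb), nb, dimnames = list(NULL, "T1"))
        Xa <- matrix(rnorm(1), 1, dimnames = list("a1", "T1"))
        controlStatistics(Xa, Xb)$p[1, 1]
    })
    for (q in c(0.05, 0.1, 0.25, 0.5, 0.9)) {
        ## allow 3 binomial standard errors on top of the exact bound
        bound <- q + 1 / nb + 3 * sqrt(q * (1 - q) / 300)
        expect_lte(mean(ps <= q), bound)
    }
})

test_that("the combination picks the largest p, breaking ties by smallest z", {
    mk <- function(v) matrix(v, 1, dimnames = list("c1", "T1"))
    zL <- list(control = mk(3), resampled = mk(2), within = mk(4))
    pL <- list(control = mk(0.02), resampled = mk(0.05), within = mk(0.01))
    cb <- combineStatistics(zL, pL,
                            denominators = c(control = 50, resampled = 100,
                                             within = 200))
    expect_identical(cb$p[1, 1], 0.05)
    expect_identical(cb$z[1, 1], 2)
    expect_identical(cb$source[1, 1], "resampled")
    expect_identical(cb$pDen[1, 1], 100)
    expect_identical(cb$pNum[1, 1], 5)

    ## tie on p: smallest associated z wins
    zL2 <- list(control = mk(2.5), resampled = mk(2.0), within = mk(4))
    pL2 <- list(control = mk(0.05), resampled = mk(0.05), within = mk(0.01))
    cb2 <- combineStatistics(zL2, pL2)
    expect_identical(cb2$z[1, 1], 2.0)
    expect_identical(cb2$source[1, 1], "resampled")

    ## full tie: any source, but z and p are invariant to the choice
    zL3 <- list(control = mk(1), resampled = mk(1), within = mk(1))
    pL3 <- list(control = mk(0.3), resampled = mk(0.3), within = mk(0.3))
    cb3 <- combineStatistics(zL3, pL3)
    expect_identical(cb3$z[1, 1], 1)
    expect_identical(cb3$p[1, 1], 0.3)
})

test_that("combination satisfies its invariants on random tie-rich instances", {
    set.seed(25)
    for (rep in 1:5) {
        dims <- c(6, 4)
        ## coarse grids force plenty of ties
        pGrid <- c(0, 0.25, 0.5, 1)
        mkp <- function() matrix(sample(pGrid, prod(dims), TRUE), dims[1],
                                 dimnames = list(paste0("c", 1:6),
                                                 paste0("T", 1:4)))
        mkz <- function() matrix(sample(-2:2, prod(dims), TRUE), dims[1],
                                 dimnames = dimnames(mkp()))
        pL <- list(control = mkp(), resampled = mkp(), within = mkp())
        zL <- list(control = mkz(), resampled = mkz(), within = mkz())
        cb <- combineStatistics(zL, pL)
        for (i in 1:6) for (j in 1:4) {
            ps <- vapply(pL, function(m) m[i, j], 0)
            zs <- vapply(zL, function(m) m[i, j], 0)
            expect_identical(cb$p[i, j], max(ps))
            tied <- names(ps)[ps == max(ps)]
            expect_identical(cb$z[i, j], min(zs[tied]))
            expect_true(cb$source[i, j] %in% tied)
            expect_identical(zs[[cb$source[i, j]]], cb$z[i, j])
        }
    }
})
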