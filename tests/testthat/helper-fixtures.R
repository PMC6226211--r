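## Shared fixture builders and independent brute-force oracles. Oracles are
## deliberately naive (explicit loops, integer arithmetic) and never call the
## implementation under test.

tinyCg <- function(values = matrix(c(1, 3, 2, 4), 2,
                                   dimnames = list(c("s1", "s2"),
                                                   c("c1", "c2"))),
                   types = c("treatment", "control")) {
    ChemGenProfileSet(values, types)
}

tinyGi <- function(values = matrix(c(3, 4, 1, 0), 2,
                                   dimnames = list(c("s1", "s2"),
                                                   c("q1", "q2")))) {
    GeneticInteractionMatrix(values)
}

tinyAnn <- function(genes = c("g1", "g2", "g3"),
                    terms = list(T1 = c("g1", "g3"), T2 = c("g2", "g3"))) {
    m <- matrix(0, length(genes), length(terms),
                dimnames = list(genes, names(terms)))
    for (t in names(terms)) m[terms[[t]], t] <- 1
    AnnotationMatrix(m)
}

randomMatrix <- function(nr, nc, prefix = c("r", "c"), seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    matrix(rnorm(nr * nc), nr, nc,
           dimnames = list(sprintf("%s%d", prefix[1], seq_len(nr)),
                           sprintf("%s%d", prefix[2], seq_len(nc))))
}

## oracle: similarity by triple loop
oracleSimilarity <- function(C, Gn) {
    S <- matrix(0, ncol(C), ncol(Gn),
                dimnames = list(colnames(C), colnames(Gn)))
    for (c in seq_len(ncol(C)))
        for (q in seq_len(ncol(Gn)))
            for (i in seq_len(nrow(C)))
                S[c, q] <- S[c, q] + C[i, c] * Gn[i, q]
    S
}

## oracle: process scores by per-term loop
oracleProcessScores <- function(S, B) {
    X <- matrix(0, nrow(S), ncol(B),
                dimnames = list(rownames(S), colnames(B)))
    for (c in seq_len(nrow(S)))
        for (t in seq_len(ncol(B)))
            for (q in seq_len(nrow(B)))
                if (B[q, t] > 0) X[c, t] <- X[c, t] + S[c, rownames(B)[q]]
    X
}

## oracle: control z / empirical p by explicit counting
oracleControlStats <- function(Xa, Xb) {
    z <- Xa; p <- Xa
    for (t in seq_len(ncol(Xa))) {
        u <- mean(Xb[, t]); v <- sd(Xb[, t])
        for (c in seq_len(nrow(Xa))) {
            z[c, t] <- (Xa[c, t] - u) / v
            p[c, t] <- sum(Xa[c, t] <= Xb[, t]) / nrow(Xb)
        }
    }
    list(z = z, p = p)
}

## oracle: within z by explicit per-entry formula
oracleWithinZ <- function(S, B) {
    X <- oracleProcessScores(S, B)
    z <- X
    for (c in seq_len(nrow(S))) {
        w <- mean(S[c, ]); y <- sd(S[c, ])
        for (t in seq_len(ncol(B))) {
            d <- sum(B[, t])
            z[c, t] <- (X[c, t] / d - w) / (y / sqrt(d))
        }
    }
    z
}

## oracle: upper-tail hypergeometric by integer binomial arithmetic
oracleHyperP <- function(N, K, n, k) {
    tot <- choose(N, n)
    num <- 0
    for (i in max(k, 0):min(K, n))
        num <- num + choose(K, i) * choose(N - K, n - i)
    num / tot
}

## oracle: BH step-up by hand
oracleBH <- function(p) {
    n <- length(p)
    ord <- order(p)
    adj <- p[ord] * n / seq_len(n)
    if (n > 1L)
        for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
    out <- numeric(n)
    out[ord] <- pmin(adj, 1)
    out
}

## oracle: suffix minimum by explicit loop
oracleSuffixMin <- function(x) {
    out <- x
    for (i in seq_along(x)) out[i] <- min(x[i:length(x)])
    out
}

## oracle: average precision by definition
oracleAveragePrecision <- function(labels) {
    tp <- 0; s <- 0
    for (i in seq_along(labels)) {
        if (labels[i]) {
            tp <- tp + 1
            s <- s + tp / i
        }
    }
    s / sum(labels)
}

## default planted-signal study conditions used by the recovery checks
plantedRun <- function(seed, signal = "full", nActive = 50L,
                       nInactive = 50L, nControls = 50L) {
    net <- generateGeneticNetwork(nStrains = 100L, nQueries = 60L,
                                  nModules = 10L, withinModuleCorr = 0.7,
                                  seed = seed)
    scr <- generateScreen(net$gi, net$ann, nActive = nActive,
                          nInactive = nInactive, nControls = nControls,
                          noiseSd = 0.5, signal = signal, seed = seed + 1L)
    res <- predictBioprocesses(scr$cg, net$gi, net$ann, nGamma = 5000L,
                               nPerm = 2000L, seed = seed + 2L)
    list(net = net, scr = scr, res = res)
}

plantedTermOf <- function(truth, id) {
    strsplit(truth$terms[truth$condition_id == id], ",", fixed = TRUE)[[1]]
}
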