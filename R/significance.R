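## z-scores and empirical p-values from three nulls, combined conservatively.
## Empirical p-values are exact counts over the null set (rational with
## denominator n_b or the permutation count); a p of exactly 0 is preserved
## and reported as "< 1/denominator" only at the presentation layer.

## sentinel for infinite z at zero null variance (kept finite so matrices
## stay dense and comparable)
.Z_SENTINEL <- 1e30

## per-column count of null scores >= each observed score (ties count)
.countGe <- function(obs, nullScores) {
    s <- sort(nullScores)
    length(s) - findInterval(obs, s, left.open = TRUE)
}

.zeroVarZ <- function(num, denom) {
    z <- num / denom
    zv <- denom == 0
    if (any(zv)) {
        n0 <- num[zv]
        z[zv] <- ifelse(n0 == 0, 0, sign(n0) * .Z_SENTINEL)
    }
    z
}

#' Control-derived z-scores and empirical p-values
#'
#' Compares each compound-process score against the distribution of that
#' process' scores over a set of control profiles (solvent controls or
#' resampled profiles). The z-score standardizes by the control mean and
#' sample standard deviation (n-1 denominator); the empirical p-value is the
#' fraction of control scores greater than or equal to the observed score
#' (ties count, so a control scored against its own cohort has p >= 1/n).
#'
#' Terms with zero control variance get z = 0 where the observed score equals
#' the control mean and a large finite sentinel (+-1e30) otherwise; the
#' affected terms are reported in `zeroVarTerms` and the empirical p-value
#' remains well defined.
#'
#' @param Xa conditions x terms process-score matrix to be scored (any
#'   condition type).
#' @param Xb controls x terms process-score matrix of one control type
#'   (needs at least 2 rows).
#' @return A list with `z`, `p` (matrices like `Xa`), `u`, `v` (per-term
#'   control mean and sd), `n` (control count), and `zeroVarTerms`.
#' @export
controlStatistics <- function(Xa, Xb) {
    if (!identical(colnames(Xa), colnames(Xb)))
        stop("term columns of the two score matrices do not match")
    nb <- nrow(Xb)
    if (nb < 2L)
        stop("need at least 2 control profiles to estimate a standard deviation")
    u <- colMeans(Xb)
    v <- sqrt(colSums(sweep(Xb, 2L, u)^2) / (nb - 1))
    z <- Xa
    p <- Xa
    for (j in seq_len(ncol(Xa))) {
        z[, j] <- .zeroVarZ(Xa[, j] - u[j], v[j])
        p[, j] <- .countGe(Xa[, j], Xb[, j]) / nb
    }
    list(z = z, p = p, u = u, v = v, n = nb,
         zeroVarTerms = colnames(Xa)[v == 0])
}

#' Within-profile z-scores and permutation p-values
#'
#' Compares the mean of a compound's gene similarity scores within a process
#' against the mean and sample standard deviation of the compound's entire
#' gene similarity score vector: `z = (X/d - w) / (y / sqrt(d))` with `d` the
#' term size. The p-value is a Monte-Carlo permutation tail: gene labels of
#' the similarity scores are permuted `nPerm` times, process scores are
#' recomputed, and p is the fraction of permuted scores greater than or equal
#' to the observed one.
#'
#' Each permutation draws one relabeling applied across all conditions
#' (realized as a row permutation of the membership matrix, which is
#' algebraically identical and lets the whole null be computed as `nPerm`
#' matrix products); per-(condition, term) counts are distributionally
#' identical to permuting each condition's scores independently.
#' Permutations are sampled with replacement from the permutation group.
#'
#' @param S conditions x queries similarity matrix.
#' @param ann an [AnnotationMatrix-class] over (a subset of) the query genes.
#' @param nPerm number of random permutations (default 10000).
#' @param seed optional integer seed.
#' @param chunkSize permutations per matrix-product block (memory/speed
#'   trade-off; results are identical for any value).
#' @return A list with `z`, `p` (conditions x terms), `w`, `y` (per-condition
#'   moments), `n` (= `nPerm`), and `zeroVarConditions` (conditions with a
#'   constant similarity row, where every permutation reproduces the observed
#'   score and p = 1).
#' @export
withinStatistics <- function(S, ann, nPerm = 10000L, seed = NULL,
                             chunkSize = 200L) {
    stopifnot(nPerm >= 1L)
    B <- membership(ann)
    missing <- setdiff(rownames(B), colnames(S))
    if (length(missing))
        stop("annotation gene(s) absent from the similarity matrix: ",
             paste(utils::head(missing, 5L), collapse = ", "))
    S <- S[, rownames(B), drop = FALSE]
    nq <- ncol(S)
    d <- colSums(B)
    X <- S %*% B
    w <- rowMeans(S)
    y <- sqrt(rowSums(sweep(S, 1L, w)^2) / (nq - 1))

    z <- X
    for (j in seq_len(ncol(X)))
        z[, j] <- .zeroVarZ(X[, j] / d[j] - w, y / sqrt(d[j]))

    if (!is.null(seed)) set.seed(seed)
    count <- matrix(0, nrow(X), ncol(X), dimnames = dimnames(X))
    done <- 0L
    while (done < nPerm) {
        k <- min(chunkSize, nPerm - done)
        ## k permuted copies of B, column-bound: one product scores them all
        Bperm <- matrix(0, nq, ncol(B) * k)
        for (i in seq_len(k))
            Bperm[, (i - 1L) * ncol(B) + seq_len(ncol(B))] <-
                B[sample.int(nq), , drop = FALSE]
        Xk <- S %*% Bperm
        cmp <- X[, rep(seq_len(ncol(B)), k), drop = FALSE] <= Xk
        dim(cmp) <- c(nrow(X), ncol(B), k)
        count <- count + rowSums(cmp, dims = 2L)
        done <- done + k
    }
    list(z = z, p = count / nPerm, w = w, y = y, n = as.integer(nPerm),
         zeroVarConditions = rownames(S)[y == 0])
}

#' Combine statistics from the three nulls conservatively
#'
#' For each (condition, term) pair, the final p-value is the largest (least
#' significant) of the available p-values and the final z-score is the one
#' paired with it. When several p-values tie for the largest, the source with
#' the smallest associated z-score wins (remaining ties break by the order of
#' the input lists). The result is the most conservative estimate of the
#' strength and significance of each prediction.
#'
#' @param zList,pList named lists of z / p matrices of identical dimensions,
#'   in matching order; conventionally named `control`, `resampled`,
#'   `within`.
#' @param denominators optional named integer vector (per source) of the
#'   counts underlying each empirical p, used to report exact rational
#'   p-value counts.
#' @return A list with matrices `z`, `p`, `source` (winning source name per
#'   entry), and — when `denominators` is given — `pNum` and `pDen` (integer
#'   numerator and denominator of each final p).
#' @export
combineStatistics <- function(zList, pList, denominators = NULL) {
    stopifnot(length(zList) == length(pList), length(pList) >= 1L,
              !is.null(names(pList)), identical(names(zList), names(pList)))
    dims <- dim(pList[[1L]])
    for (m in c(zList, pList))
        if (!identical(dim(m), dims))
            stop("all z/p matrices must share the same dimensions")

    pFinal <- Reduce(pmax, pList)
    srcIdx <- matrix(1L, dims[1L], dims[2L])
    bestZ <- matrix(Inf, dims[1L], dims[2L])
    for (s in seq_along(pList)) {
        tied <- pList[[s]] == pFinal
        zMask <- ifelse(tied, zList[[s]], Inf)
        take <- zMask < bestZ        # strict: earlier source wins exact ties
        srcIdx[take] <- s
        bestZ[take] <- zMask[take]
    }
    zFinal <- matrix(0, dims[1L], dims[2L], dimnames = dimnames(pList[[1L]]))
    for (s in seq_along(zList))
        zFinal[srcIdx == s] <- zList[[s]][srcIdx == s]
    src <- matrix(names(pList)[srcIdx], dims[1L], dims[2L],
                  dimnames = dimnames(pList[[1L]]))
    dimnames(pFinal) <- dimnames(pList[[1L]])
    out <- list(z = zFinal, p = pFinal, source = src)
    if (!is.null(denominators)) {
        if (!all(names(pList) %in% names(denominators)))
            stop("denominators must be named after every source")
        den <- matrix(as.numeric(denominators[names(pList)[srcIdx]]),
                      dims[1L], dims[2L], dimnames = dimnames(pFinal))
        out$pDen <- den
        out$pNum <- round(pFinal * den)
    }
    out
}
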