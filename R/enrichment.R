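## Enrichment-based baseline predictors: hypergeometric enrichment on each
## compound's top-n gene similarity scores ("gene-target enrichment") or on
## its most negative chemical-genetic interactions ("direct enrichment").

#' Top-n selection mask per condition
#'
#' For each row, marks the entries whose score reaches the n-th largest value
#' (direction `"largest"`) or the n-th smallest (direction
#' `"most-negative"`). Ties at the threshold are all included, so a row can
#' select more than `nTop` entries; set `strictTies = TRUE` to break
#' threshold ties at random down to exactly `nTop`.
#'
#' @param scores conditions x genes numeric matrix.
#' @param nTop nominal selection size, `1 <= nTop <= ncol(scores)`.
#' @param direction `"largest"` or `"most-negative"`.
#' @param strictTies logical; resolve threshold ties randomly to exactly
#'   `nTop` selections per row.
#' @param seed optional seed used only when `strictTies = TRUE`.
#' @return A binary matrix of the same shape as `scores`.
#' @export
topNMask <- function(scores, nTop, direction = c("largest", "most-negative"),
                     strictTies = FALSE, seed = NULL) {
    direction <- match.arg(direction)
    if (nTop < 1L) stop("nTop must be at least 1")
    if (nTop > ncol(scores)) stop("nTop exceeds the number of genes")
    if (!is.null(seed)) set.seed(seed)
    mask <- scores
    for (i in seq_len(nrow(scores))) {
        r <- scores[i, ]
        if (direction == "largest") {
            thr <- sort(r, decreasing = TRUE)[nTop]
            sel <- r >= thr
        } else {
            thr <- sort(r)[nTop]
            sel <- r <= thr
        }
        if (strictTies && sum(sel) > nTop) {
            atThr <- which(sel & r == thr)
            keepN <- nTop - (sum(sel) - length(atThr))
            drop <- atThr[!seq_along(atThr) %in%
                              sample.int(length(atThr), keepN)]
            sel[drop] <- FALSE
        }
        mask[i, ] <- as.numeric(sel)
    }
    mask
}

#' Hypergeometric enrichment of selected genes in each term
#'
#' With `N` genes in the universe, a term of size `K`, a nominal selection of
#' `n` genes and `k` selected genes in the term, the enrichment factor is
#' `E = k * N / (K * n)` and the p-value is the upper hypergeometric tail
#' `P(X >= k)` for `n` draws from a population of `N` with `K` successes. The
#' nominal `n` is used even when ties expanded the selection.
#'
#' @param mask binary conditions x genes selection matrix from [topNMask()];
#'   its gene columns must equal the annotation's gene universe.
#' @param ann an [AnnotationMatrix-class] over the same gene universe.
#' @param nTop the nominal selection size used to build `mask`.
#' @return A list of class `"EnrichmentResult"` with `nTop`, `mask`, `E`
#'   (enrichment factors) and `P` (hypergeometric p-values), the score
#'   matrices being conditions x terms.
#' @export
enrichmentScores <- function(mask, ann, nTop) {
    B <- membership(ann)
    if (!setequal(colnames(mask), rownames(B)))
        stop("selection mask genes must equal the annotation gene universe")
    B <- B[colnames(mask), , drop = FALSE]
    N <- ncol(mask)
    K <- colSums(B)
    if (any(K == 0))
        stop("terms of size 0 must be removed (filterTermSizes) before enrichment")
    k <- mask %*% B
    E <- sweep(k * N / nTop, 2L, K, "/")
    P <- k
    for (j in seq_len(ncol(k)))
        P[, j] <- stats::phyper(k[, j] - 1, K[j], N - K[j], nTop,
                                lower.tail = FALSE)
    structure(list(nTop = nTop, mask = mask, E = E, P = P),
              class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
    cat(sprintf("EnrichmentResult: top-%d selection, %d conditions x %d terms\n",
                x$nTop, nrow(x$E), ncol(x$E)))
    invisible(x)
}

#' Direct enrichment on the strongest negative chemical-genetic interactions
#'
#' Baseline predictor that scores each compound by hypergeometric enrichment
#' of bioprocess terms among its `nTop` most negative chemical-genetic
#' interaction strains, against a strain-level annotation matrix.
#'
#' @param cg a [ChemGenProfileSet-class].
#' @param strainAnn an [AnnotationMatrix-class] whose gene universe is the
#'   strains of `cg`.
#' @param nTop selection size (default 20).
#' @param ... passed to [topNMask()] (e.g. `strictTies`).
#' @return An `"EnrichmentResult"` (see [enrichmentScores()]).
#' @export
directEnrichment <- function(cg, strainAnn, nTop = 20L, ...) {
    scores <- t(cgScores(cg))                # conditions x strains
    mask <- topNMask(scores, nTop, "most-negative", ...)
    enrichmentScores(mask, strainAnn, nTop)
}

#' Gene-target enrichment on the top compound-gene similarity scores
#'
#' Baseline predictor that selects each compound's `nTop` highest compound-gene
#' similarity scores and tests bioprocess terms for hypergeometric enrichment
#' within the selected genes. Several selection sizes can be swept at once.
#'
#' @param sim conditions x queries similarity matrix from
#'   [similarityScores()].
#' @param ann an [AnnotationMatrix-class] over the query genes of `sim`.
#' @param nTop integer vector of selection sizes (default the standard sweep
#'   10..800).
#' @param ... passed to [topNMask()].
#' @return A named list of `"EnrichmentResult"` objects, one per `nTop`.
#' @export
geneTargetEnrichment <- function(sim, ann,
                                 nTop = c(10L, 20L, 50L, 100L, 200L, 300L,
                                          400L, 600L, 800L),
                                 ...) {
    sim <- sim[, geneIds(ann), drop = FALSE]
    nTop <- nTop[nTop <= ncol(sim)]
    if (!length(nTop))
        stop("all requested selection sizes exceed the number of queries")
    res <- lapply(nTop, function(n)
        enrichmentScores(topNMask(sim, n, "largest", ...), ann, n))
    names(res) <- paste0("top", nTop)
    res
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjusted p-values (monotone, capped at 1); a thin wrapper
#' over [stats::p.adjust()] kept as the package's named surface for
#' multiple-testing correction.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values of the same length.
#' @export
bhAdjust <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}
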