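## Benchmarking machinery: simulated profiles inheriting gold-standard
## annotations from their parent query genes, precision-recall of top
## predictions, rank significance of gold-standard terms, effective rank,
## per-term normalized AUPR, and a structural similarity coefficient.

#' Deterministic prediction ordering
#'
#' The total order used everywhere predictions are ranked: p-value ascending,
#' then z-score (or enrichment factor) descending, then term identifier
#' ascending so that ranks are reproducible across runs.
#'
#' @param p,z numeric vectors of equal length.
#' @param ids character identifiers used as the final tie-break (defaults to
#'   `names(p)`).
#' @return An integer permutation (as from [order()]).
#' @export
orderPredictions <- function(p, z, ids = names(p)) {
    if (is.null(ids)) ids <- as.character(seq_along(p))
    order(p, -z, ids)
}

#' Simulate chemical-genetic profiles from genetic interaction profiles
#'
#' Each simulated profile is a query genetic interaction profile plus
#' independent Gaussian noise with mean 0 and per-strain variance equal to
#' `varianceMultiplier` times that strain's sample variance across the
#' genetic interaction matrix. `replicates` profiles are generated per query;
#' each inherits its parent query's bioprocess annotations as the gold
#' standard.
#'
#' @param gi a raw [GeneticInteractionMatrix-class].
#' @param ann an [AnnotationMatrix-class] over the query genes (source of the
#'   inherited gold-standard terms).
#' @param replicates simulated profiles per query (default 3).
#' @param varianceMultiplier noise variance as a multiple of each strain's
#'   observed variance (default 2; 0 reproduces the parent profiles exactly).
#' @param seed optional integer seed.
#' @return A [SimulatedProfileSet-class] with `replicates * n_q` treatment
#'   profiles named `sim_<query>_<replicate>`.
#' @export
simulateProfiles <- function(gi, ann, replicates = 3L,
                             varianceMultiplier = 2, seed = NULL) {
    stopifnot(is(gi, "GeneticInteractionMatrix"), replicates >= 1L,
              varianceMultiplier >= 0)
    if (!is.null(seed)) set.seed(seed)
    G <- giScores(gi)
    nm <- nrow(G)
    rowVar <- rowSums((G - rowMeans(G))^2) / (ncol(G) - 1)
    sdNoise <- sqrt(varianceMultiplier * rowVar)
    nq <- ncol(G)
    out <- matrix(0, nm, nq * replicates)
    parent <- character(nq * replicates)
    cn <- character(nq * replicates)
    k <- 0L
    for (q in seq_len(nq)) {
        for (r in seq_len(replicates)) {
            k <- k + 1L
            out[, k] <- G[, q] + stats::rnorm(nm, 0, sdNoise)
            parent[k] <- colnames(G)[q]
            cn[k] <- sprintf("sim_%s_%d", colnames(G)[q], r)
        }
    }
    dimnames(out) <- list(rownames(G), cn)
    B <- membership(ann)
    gold <- lapply(parent, function(q)
        if (q %in% rownames(B)) colnames(B)[B[q, ] > 0] else character())
    new("SimulatedProfileSet",
        profiles = ChemGenProfileSet(out, "treatment"),
        parentQuery = parent, inheritedTerms = gold)
}

#' Top prediction per profile
#'
#' @param p,z conditions x terms matrices of combined p-values and z-scores
#'   (or enrichment p-values and factors).
#' @return A data frame with one row per condition: `condition_id`,
#'   `term_id`, `p`, `z`, using the deterministic prediction order.
#' @export
topPredictions <- function(p, z) {
    stopifnot(identical(dim(p), dim(z)))
    rows <- lapply(seq_len(nrow(p)), function(i) {
        ord <- orderPredictions(p[i, ], z[i, ], colnames(p))
        j <- ord[1L]
        data.frame(condition_id = rownames(p)[i], term_id = colnames(p)[j],
                   p = p[i, j], z = z[i, j], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Precision-recall over sorted top predictions
#'
#' Keeps each profile's single top prediction, sorts those predictions by
#' (p ascending, z descending), and accumulates precision (true positives
#' over predictions made so far) and recall (true positive count) down the
#' list. A top prediction is a true positive when it belongs to the profile's
#' gold-standard term set.
#'
#' @param top data frame from [topPredictions()].
#' @param gold named list of gold-standard term-id vectors per profile
#'   (profiles with an empty set are excluded with a warning).
#' @return A data frame sorted in evaluation order with columns
#'   `condition_id`, `term_id`, `p`, `z`, `tp`, `precision`, `recall`, plus
#'   attribute `topAccuracy`: final TP count over the number of evaluated
#'   profiles.
#' @export
topPredictionPR <- function(top, gold) {
    has <- top$condition_id %in% names(gold)[lengths(gold) > 0L]
    if (any(!has)) {
        warning(sum(!has), " profile(s) without gold annotations excluded")
        top <- top[has, , drop = FALSE]
    }
    tp <- mapply(function(cond, term) term %in% gold[[cond]],
                 top$condition_id, top$term_id)
    ord <- orderPredictions(top$p, top$z, top$condition_id)
    out <- top[ord, , drop = FALSE]
    out$tp <- tp[ord]
    out$precision <- cumsum(out$tp) / seq_len(nrow(out))
    out$recall <- cumsum(out$tp)
    rownames(out) <- NULL
    attr(out, "topAccuracy") <- sum(out$tp) / nrow(out)
    out
}

#' Rank of the gold-standard term and its shuffle significance
#'
#' Ranks one compound's predictions deterministically and records the 1-based
#' rank of its gold-standard term. Significance is assessed by randomly
#' reassigning the (p, z) pairs to terms (a permutation, without
#' replacement), re-ranking, and counting how often the shuffled gold rank is
#' at least as good (<=) as the observed one.
#'
#' @param p,z named numeric vectors over terms for one compound.
#' @param goldTerm the gold-standard term identifier.
#' @param nShuffles number of random reassignments (default 10000).
#' @param seed optional integer seed.
#' @return A list with `rank` (observed) and `pValue` (empirical shuffle p).
#' @export
goldRankSignificance <- function(p, z, goldTerm, nShuffles = 10000L,
                                 seed = NULL) {
    stopifnot(length(p) == length(z), nShuffles >= 1L)
    ids <- names(p)
    if (is.null(ids) || !goldTerm %in% ids)
        stop("goldTerm must be one of the named terms")
    if (!is.null(seed)) set.seed(seed)
    gi <- match(goldTerm, ids)
    obsRank <- which(orderPredictions(p, z, ids) == gi)
    n <- length(p)
    hits <- 0L
    for (k in seq_len(nShuffles)) {
        idx <- sample.int(n)          # term t receives pair idx[t]
        shufRank <- which(orderPredictions(p[idx], z[idx], ids) == gi)
        if (shufRank <= obsRank) hits <- hits + 1L
    }
    list(rank = obsRank, pValue = hits / nShuffles)
}

#' Effective rank of a gold-standard term
#'
#' The best rank achieved by any term whose gene membership overlaps the
#' gold-standard term's membership at or above `threshold` (overlap index:
#' intersection over the smaller set). The gold term itself always qualifies
#' at overlap 1, so the effective rank never exceeds the gold rank.
#'
#' @param rankedTerms character vector of term ids in rank order (rank 1
#'   first).
#' @param goldTerm the gold-standard term id.
#' @param ann an [AnnotationMatrix-class] giving term memberships.
#' @param threshold overlap-index threshold in `(0, 1]` (default 0.4).
#' @return The effective rank (integer).
#' @export
effectiveRank <- function(rankedTerms, goldTerm, ann, threshold = 0.4) {
    stopifnot(threshold > 0, threshold <= 1)
    goldGenes <- termMembers(ann, goldTerm)
    ranks <- integer()
    for (r in seq_along(rankedTerms)) {
        t <- rankedTerms[r]
        if (!t %in% termIds(ann)) next
        if (overlapIndex(termMembers(ann, t), goldGenes) >= threshold)
            return(r)
    }
    stop("gold term not present in the ranked list")
}

#' Normalized area under the precision-recall curve for one term
#'
#' Sorts all profiles' predictions to one term by (p ascending, z
#' descending, profile id) and computes the average precision (the mean of
#' the precision at each positive — the step-function AUPR). The result is
#' divided by the AUPR of a random classifier, i.e. the positive fraction,
#' so 1 means chance performance.
#'
#' @param p,z named numeric vectors over profiles: each profile's p-value and
#'   z-score for the term under evaluation.
#' @param positives character vector of profile ids annotated to the term
#'   (at least one).
#' @return A list with `aupr` (average precision) and `normalized` (average
#'   precision over the random baseline).
#' @export
perTermAupr <- function(p, z, positives) {
    ids <- names(p)
    stopifnot(!is.null(ids), length(p) == length(z))
    isPos <- ids %in% positives
    if (!any(isPos)) stop("term has no positive profiles; skip it upstream")
    ord <- orderPredictions(p, z, ids)
    lab <- isPos[ord]
    prec <- cumsum(lab) / seq_along(lab)
    ap <- sum(prec[lab]) / sum(lab)
    list(aupr = ap, normalized = ap / (sum(lab) / length(lab)))
}

#' Braun-Blanquet similarity of two binary fingerprints
#'
#' Size of the intersection divided by the size of the larger set; used to
#' compare compounds' binary structural fingerprints.
#'
#' @param fpA,fpB nonempty vectors of feature identifiers.
#' @return A similarity in `[0, 1]`.
#' @examples
#' braunBlanquet(c(1, 2, 3), c(2, 3, 4, 5))  # 0.5
#' @export
braunBlanquet <- function(fpA, fpB) {
    fpA <- unique(fpA); fpB <- unique(fpB)
    if (length(fpA) == 0L || length(fpB) == 0L)
        stop("braunBlanquet is undefined for empty feature sets")
    length(intersect(fpA, fpB)) / max(length(fpA), length(fpB))
}

#' Read binary fingerprints from TSV
#'
#' One compound per line: `compound_id<TAB>feature1<TAB>feature2...`.
#'
#' @param path file path.
#' @return Named list of feature-id character vectors.
#' @export
readFingerprints <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ids <- vapply(fields, `[[`, "", 1L)
    if (anyDuplicated(ids))
        stop("duplicated compound id in ", path)
    setNames(lapply(fields, function(f) unique(f[-1L])), ids)
}
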