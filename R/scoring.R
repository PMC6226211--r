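## Compound-gene similarity and compound-process aggregation. Only the
## genetic side is normalized: gene scores then scale with the overall
## strength of each chemical-genetic profile, so strong profiles keep strong
## scores.

#' L2-normalize the query columns of a genetic interaction matrix
#'
#' Divides each query gene's profile by its Euclidean norm so that the inner
#' product with a chemical-genetic profile measures directional similarity.
#' Queries with an all-zero profile cannot be normalized and are dropped with
#' a warning.
#'
#' @param gi a raw [GeneticInteractionMatrix-class].
#' @return A [GeneticInteractionMatrix-class] with `isNormalized(x) == TRUE`.
#' @export
l2NormalizeQueries <- function(gi) {
    stopifnot(is(gi, "GeneticInteractionMatrix"))
    m <- giScores(gi)
    nrm <- sqrt(colSums(m^2))
    zero <- nrm == 0
    if (any(zero)) {
        warning("dropped ", sum(zero), " zero-norm query column(s): ",
                paste(utils::head(colnames(m)[zero], 5L), collapse = ", "))
        m <- m[, !zero, drop = FALSE]
        nrm <- nrm[!zero]
    }
    GeneticInteractionMatrix(sweep(m, 2L, nrm, "/"), normalized = TRUE)
}

#' Compound-gene similarity scores
#'
#' Computes `S = t(C) %*% G'`, the inner product between every
#' chemical-genetic profile (any condition type) and every L2-normalized
#' genetic interaction profile. Inputs must be strain-aligned (see
#' [alignStrains()]). S is linear in the chemical-genetic profiles: scaling a
#' condition's profile by k scales its similarity row by k.
#'
#' @param cg a [ChemGenProfileSet-class].
#' @param giNorm a normalized [GeneticInteractionMatrix-class].
#' @return A conditions x queries numeric matrix with dimnames.
#' @export
similarityScores <- function(cg, giNorm) {
    stopifnot(is(cg, "ChemGenProfileSet"),
              is(giNorm, "GeneticInteractionMatrix"))
    if (!isNormalized(giNorm))
        stop("genetic interaction matrix must be L2-normalized first")
    if (!identical(strainIds(cg), strainIds(giNorm)))
        stop("strain ids are misaligned; run alignStrains() first")
    crossprod(cgScores(cg), giScores(giNorm))
}

#' Aggregate gene similarity scores into process scores
#'
#' Computes `X = S %*% B`: each compound-process score is the sum of the
#' compound's gene similarity scores over the genes annotated to that
#' process.
#'
#' @param sim conditions x queries similarity matrix from
#'   [similarityScores()].
#' @param ann an [AnnotationMatrix-class] whose gene universe is a subset of
#'   the similarity matrix's query columns.
#' @return A conditions x terms numeric matrix.
#' @export
processScores <- function(sim, ann) {
    B <- membership(ann)
    missing <- setdiff(rownames(B), colnames(sim))
    if (length(missing))
        stop("annotation gene(s) absent from the similarity matrix: ",
             paste(utils::head(missing, 5L), collapse = ", "),
             " (annotation built on the wrong universe?)")
    sim[, rownames(B), drop = FALSE] %*% B
}
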