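## Which strains drive a prediction: importance-score profiles (elementwise
## product of the compound's chemical-genetic profile with the mean qualifying
## genetic interaction profile of the predicted term), contribution summaries,
## and overrepresentation of non-contributing strains.

#' Importance-score profile for one compound-term prediction
#'
#' Averages the L2-normalized genetic interaction profiles of the term's
#' annotated query genes whose inner product with the compound's
#' chemical-genetic profile reaches `threshold` (default 2), then takes the
#' Hadamard (elementwise) product of this mean profile with the
#' chemical-genetic profile. A strain's importance is positive exactly when
#' its chemical-genetic and mean genetic interactions agree in sign, and its
#' magnitude reflects how much the strain contributes to the prediction.
#'
#' @param cgProfile named per-strain chemical-genetic score vector for one
#'   compound.
#' @param giNorm a normalized [GeneticInteractionMatrix-class], strain-aligned
#'   with `cgProfile`.
#' @param ann an [AnnotationMatrix-class] over the query genes.
#' @param termId the predicted term.
#' @param threshold inner-product cutoff for a query profile to qualify
#'   (default 2).
#' @return A data frame with columns `strain_id`, `cg_score`, `mean_gi`,
#'   `importance`, plus attributes `contributingQueries` (qualifying query
#'   ids) and `empty` (`TRUE` with zero rows when no query qualifies).
#' @export
importanceProfile <- function(cgProfile, giNorm, ann, termId, threshold = 2) {
    stopifnot(is(giNorm, "GeneticInteractionMatrix"), isNormalized(giNorm))
    members <- termMembers(ann, termId)     # errors on unknown term
    members <- intersect(members, queryIds(giNorm))
    Gp <- giScores(giNorm)
    if (!identical(names(cgProfile), rownames(Gp)))
        stop("cgProfile strains must match the genetic matrix rows")
    ip <- as.vector(crossprod(Gp[, members, drop = FALSE], cgProfile))
    qual <- members[ip >= threshold]
    if (length(qual) == 0L) {
        out <- data.frame(strain_id = character(), cg_score = numeric(),
                          mean_gi = numeric(), importance = numeric())
        attr(out, "contributingQueries") <- character()
        attr(out, "empty") <- TRUE
        return(out)
    }
    meanGi <- rowMeans(Gp[, qual, drop = FALSE])
    out <- data.frame(strain_id = names(cgProfile),
                      cg_score = unname(cgProfile),
                      mean_gi = unname(meanGi),
                      importance = unname(meanGi * cgProfile),
                      stringsAsFactors = FALSE)
    attr(out, "contributingQueries") <- qual
    attr(out, "empty") <- FALSE
    out
}

#' Summarize how many interactions contribute to predictions
#'
#' For each compound, counts its chemical-genetic interactions (strains with
#' `|cg| >= cgCutoff`) and the subset that contribute to its prediction
#' (importance `>= impCutoff`, one-sided), overall and split by interaction
#' sign; pooled counts across compounds are also returned. Compounds with no
#' interaction at the cutoff are excluded from the per-compound mean but
#' counted in the pooled denominators.
#'
#' @param profileList named list (by compound) of data frames from
#'   [importanceProfile()] (columns `cg_score` and `importance`).
#' @param cgCutoff absolute chemical-genetic interaction cutoff (default
#'   2.5; the "strong" convention is 5).
#' @param impCutoff positive importance cutoff (default 0.1; "strong" 0.5).
#' @return A list with `perCompound` (data frame: compound, interaction and
#'   contribution counts, fractions overall / negative / positive),
#'   `meanFraction` (mean contributing fraction over compounds with
#'   interactions), and `pooled` (summed counts with the pooled fractions).
#' @export
contributionSummary <- function(profileList, cgCutoff = 2.5,
                                impCutoff = 0.1) {
    stopifnot(cgCutoff > 0, impCutoff > 0)
    rows <- lapply(names(profileList), function(id) {
        d <- profileList[[id]]
        inter <- abs(d$cg_score) >= cgCutoff
        contrib <- inter & d$importance >= impCutoff
        neg <- inter & d$cg_score < 0
        pos <- inter & d$cg_score > 0
        data.frame(
            compound_id = id,
            n_interactions = sum(inter),
            n_contributing = sum(contrib),
            n_neg = sum(neg), n_neg_contributing = sum(contrib & neg),
            n_pos = sum(pos), n_pos_contributing = sum(contrib & pos),
            stringsAsFactors = FALSE)
    })
    per <- do.call(rbind, rows)
    per$fraction <- ifelse(per$n_interactions > 0,
                           per$n_contributing / per$n_interactions, NA_real_)
    per$fraction_neg <- ifelse(per$n_neg > 0,
                               per$n_neg_contributing / per$n_neg, NA_real_)
    per$fraction_pos <- ifelse(per$n_pos > 0,
                               per$n_pos_contributing / per$n_pos, NA_real_)
    pooled <- list(
        n_interactions = sum(per$n_interactions),
        n_contributing = sum(per$n_contributing),
        n_neg = sum(per$n_neg),
        n_neg_contributing = sum(per$n_neg_contributing),
        n_pos = sum(per$n_pos),
        n_pos_contributing = sum(per$n_pos_contributing))
    pooled$fraction <- if (pooled$n_interactions > 0)
        pooled$n_contributing / pooled$n_interactions else NA_real_
    pooled$negative_share_of_contributing <- if (pooled$n_contributing > 0)
        pooled$n_neg_contributing / pooled$n_contributing else NA_real_
    list(perCompound = per,
         meanFraction = mean(per$fraction, na.rm = TRUE),
         pooled = pooled)
}

#' Overrepresentation of strains among strong non-contributing interactions
#'
#' Restricting attention to strains with strong negative chemical-genetic
#' interactions (`cg_score < zCutoff`), tests each strain for
#' overrepresentation inside the non-contributing region (importance within
#' `+-band`) using an upper-tail hypergeometric test: the strain's in-region
#' count is compared against its total count in the background, the region
#' size, and the background size. P-values are Benjamini-Hochberg adjusted
#' across strains.
#'
#' @param records data frame with one row per (compound, strain) observation
#'   at each compound's top prediction, columns `strain_id`, `cg_score`,
#'   `importance` (e.g. stacked [importanceProfile()] outputs).
#' @param zCutoff negative threshold defining strong interactions (default
#'   -5).
#' @param band importance half-width of the non-contributing region (default
#'   0.1).
#' @param alpha adjusted-p significance flag threshold (default 0.05).
#' @return A data frame per strain: `strain_id`, `n_background`,
#'   `n_in_region`, `p`, `p_adjusted`, `significant`, sorted by p.
#' @export
strainOverrepresentation <- function(records, zCutoff = -5, band = 0.1,
                                     alpha = 0.05) {
    stopifnot(zCutoff < 0, band > 0)
    bg <- records[records$cg_score < zCutoff, , drop = FALSE]
    if (nrow(bg) == 0L)
        stop("empty background: no observations with cg_score < ", zCutoff)
    inRegion <- abs(bg$importance) <= band
    N <- nrow(bg)
    K <- sum(inRegion)
    strains <- sort(unique(bg$strain_id))
    nTot <- vapply(strains, function(s) sum(bg$strain_id == s), 0L)
    nIn <- vapply(strains, function(s) sum(inRegion & bg$strain_id == s), 0L)
    p <- stats::phyper(nIn - 1, K, N - K, nTot, lower.tail = FALSE)
    out <- data.frame(strain_id = strains, n_background = nTot,
                      n_in_region = nIn, p = p,
                      p_adjusted = bhAdjust(p), stringsAsFactors = FALSE)
    out$significant <- out$p_adjusted <= alpha
    out <- out[order(out$p, out$strain_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}
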