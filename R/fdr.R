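## Per-profile false discovery rate estimation: the rate at which control
## profiles (solvent controls, or resampled profiles) acquire predictions is
## compared with the rate for treatments over the full grid of observed
## p-values.

#' Best (smallest) p-value per profile
#'
#' @param P conditions x terms p-value matrix with at least one column.
#' @return Named numeric vector of per-row minima.
#' @export
bestPPerProfile <- function(P) {
    if (is.null(dim(P)) || ncol(P) == 0L)
        stop("P must be a matrix with at least one term column")
    apply(P, 1L, min)
}

#' Build a p-value-to-FDR map against one control profile type
#'
#' For every threshold in `pAll`, the raw FDR is the fraction of control
#' profiles whose best prediction passes the threshold divided by the same
#' fraction for treatment profiles. Because this ratio need not increase with
#' p, it is adjusted to its suffix running minimum (the smallest value at any
#' equal-or-larger threshold), yielding a nondecreasing step function.
#' Conventions: 0/0 is 0, a positive fraction over 0 is capped, and all
#' values are capped at `cap` (ratios exceed 1 when controls outpace
#' treatments).
#'
#' @param ptopTreat,ptopCtrl per-profile best p-values (see
#'   [bestPPerProfile()]) for treatments and for one control type.
#' @param pAll vector containing every observed p-value (the union over all
#'   entries of the combined p matrices of all profile types); deduplicated
#'   and sorted internally.
#' @param controlType `"control"` or `"resampled"` (metadata only).
#' @param cap upper bound for reported FDR values (default 1).
#' @return An [FdrMap-class].
#' @export
buildFdrMap <- function(ptopTreat, ptopCtrl, pAll,
                        controlType = c("control", "resampled"), cap = 1) {
    controlType <- match.arg(controlType)
    if (length(ptopTreat) == 0L || length(ptopCtrl) == 0L)
        stop("need at least one treatment and one control profile")
    pAll <- sort(unique(pAll))
    fracT <- findInterval(pAll, sort(ptopTreat)) / length(ptopTreat)
    fracC <- findInterval(pAll, sort(ptopCtrl)) / length(ptopCtrl)
    rStar <- ifelse(fracT == 0, ifelse(fracC == 0, 0, cap), fracC / fracT)
    rStar <- pmin(rStar, cap)
    r <- rev(cummin(rev(rStar)))
    new("FdrMap", controlType = controlType, pAll = pAll, rStar = rStar,
        r = r, nTreat = length(ptopTreat), nCtrl = length(ptopCtrl))
}

#' Look p-values up through an FDR map
#'
#' Elementwise lookup through the monotone step function: each p maps to the
#' FDR at the largest observed threshold `<= p`. Every queried p occurs in
#' the map by construction when the map was built on the full p universe; a
#' smaller p (only reachable if the map was built on a subset) falls back to
#' the first threshold with a message.
#'
#' @param map an [FdrMap-class].
#' @param P numeric vector or matrix of p-values.
#' @return FDR estimates with the shape and dimnames of `P`.
#' @export
applyFdr <- function(map, P) {
    idx <- findInterval(as.vector(P), map@pAll)
    if (any(idx == 0L)) {
        message("applyFdr: ", sum(idx == 0L),
                " p-value(s) below the mapped range; using the first threshold")
        idx[idx == 0L] <- 1L
    }
    out <- map@r[idx]
    if (!is.null(dim(P)))
        out <- array(out, dim = dim(P), dimnames = dimnames(P))
    else
        names(out) <- names(P)
    out
}

#' Threshold-by-threshold FDR summary table
#'
#' Machine-readable discovery summary: for each observed p-value threshold,
#' the number of treatment, experimental-control and resampled profiles whose
#' best prediction passes it, and the two monotone FDR estimates.
#'
#' @param mapCtrl,mapRes [FdrMap-class] objects built against experimental
#'   controls and resampled profiles (on the same `pAll`).
#' @param ptopTreat,ptopCtrl,ptopRes per-profile best p-values by type.
#' @return A data frame with columns `p`, `n_treat_discovered`,
#'   `n_ctrl_discovered`, `n_resampled_discovered`, `fdr_ctrl`,
#'   `fdr_resampled`.
#' @export
fdrSummary <- function(mapCtrl, mapRes, ptopTreat, ptopCtrl, ptopRes) {
    p <- mapCtrl@pAll
    data.frame(
        p = p,
        n_treat_discovered = findInterval(p, sort(ptopTreat)),
        n_ctrl_discovered = findInterval(p, sort(ptopCtrl)),
        n_resampled_discovered = findInterval(p, sort(ptopRes)),
        fdr_ctrl = mapCtrl@r,
        fdr_resampled = mapRes@r)
}

#' Count profiles discovered at an FDR cutoff
#'
#' A profile is discovered when the FDR mapped from its best prediction
#' p-value is at or below the cutoff.
#'
#' @param map an [FdrMap-class].
#' @param ptop per-profile best p-values.
#' @param cutoff FDR cutoff (the high-confidence convention is 0.25).
#' @return Named logical vector: discovered or not, per profile.
#' @export
discoveredAtFdr <- function(map, ptop, cutoff = 0.25) {
    applyFdr(map, ptop) <= cutoff
}
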