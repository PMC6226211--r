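## The resampled-profile null: treatment-specific variance that solvent
## controls cannot capture.

#' Generate resampled chemical-genetic profiles
#'
#' Builds a null profile set in which each strain's score in each resampled
#' profile is drawn independently, uniformly with replacement, from that
#' strain's scores across the *treatment* (not control) conditions. Because
#' strains are sampled independently, resampled profiles retain each mutant's
#' treatment-derived marginal score distribution while destroying the
#' cross-strain coherence that encodes biological signal — a stringent null
#' for profile-similarity scoring.
#'
#' Sampling uses a single seeded generator filling the matrix in row-major
#' order (strain by strain), so results are reproducible for a fixed seed.
#'
#' @param cg a [ChemGenProfileSet-class]; only its treatment columns are
#'   resampled from (an error is thrown if there are none).
#' @param nGamma number of resampled profiles to generate (the study-scale
#'   default is 50000; tests use far fewer).
#' @param seed optional integer seed.
#' @return A [ChemGenProfileSet-class] of type `resampled` with conditions
#'   named `resampled_00001, ...`.
#' @export
resampleProfiles <- function(cg, nGamma = 50000L, seed = NULL) {
    stopifnot(is(cg, "ChemGenProfileSet"), nGamma >= 1L)
    tr <- cgScores(cg)[, conditionType(cg) == "treatment", drop = FALSE]
    if (ncol(tr) == 0L)
        stop("no treatment columns to resample from")
    if (!is.null(seed)) set.seed(seed)
    nm <- nrow(tr)
    out <- matrix(0, nm, nGamma)
    for (i in seq_len(nm))
        out[i, ] <- tr[i, sample.int(ncol(tr), nGamma, replace = TRUE)]
    dimnames(out) <- list(rownames(tr),
                          sprintf("resampled_%05d", seq_len(nGamma)))
    ChemGenProfileSet(out, "resampled")
}
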