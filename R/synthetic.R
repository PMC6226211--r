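## Fully synthetic screens: a modular genetic interaction network with one
## bioprocess term per module, and chemical-genetic screens with planted
## compound-to-process signal. Everything downstream of these generators is
## testable without any external data.

#' Generate a modular synthetic genetic interaction network
#'
#' Queries are partitioned into modules (functional groups); each module has
#' a latent per-strain signature and every member query profile is
#' `sqrt(corr) * signature + sqrt(1 - corr) * noise`, so the expected
#' correlation between two profiles of the same module is `corr` and between
#' modules is 0. Each module defines one bioprocess term annotated with
#' exactly its member queries.
#'
#' @param nStrains,nQueries matrix dimensions (defaults 100 x 60).
#' @param nModules number of modules/terms (default 10); remainders are
#'   spread so module sizes differ by at most one.
#' @param withinModuleCorr shared-signature fraction in `[0, 1)` (default
#'   0.7).
#' @param seed optional integer seed.
#' @param minTermSize smallest acceptable module (default 4); smaller modules
#'   are an error since the resulting terms would be filtered out.
#' @return A list with `gi` (raw [GeneticInteractionMatrix-class]) and `ann`
#'   (an [AnnotationMatrix-class] with one term per module).
#' @export
generateGeneticNetwork <- function(nStrains = 100L, nQueries = 60L,
                                   nModules = 10L, withinModuleCorr = 0.7,
                                   seed = NULL, minTermSize = 4L) {
    stopifnot(withinModuleCorr >= 0, withinModuleCorr < 1, nModules >= 1L)
    if (!is.null(seed)) set.seed(seed)
    module <- sort(rep_len(seq_len(nModules), nQueries))
    if (min(table(module)) < minTermSize)
        stop("module size below the minimum term size; ",
             "use fewer modules or more queries")
    sig <- matrix(stats::rnorm(nStrains * nModules), nStrains, nModules)
    G <- sqrt(withinModuleCorr) * sig[, module, drop = FALSE] +
        sqrt(1 - withinModuleCorr) *
            matrix(stats::rnorm(nStrains * nQueries), nStrains, nQueries)
    dimnames(G) <- list(sprintf("strain_%03d", seq_len(nStrains)),
                        sprintf("Q%04d", seq_len(nQueries)))
    B <- matrix(0, nQueries, nModules,
                dimnames = list(colnames(G),
                                sprintf("M%02d", seq_len(nModules))))
    B[cbind(seq_len(nQueries), module)] <- 1
    list(gi = GeneticInteractionMatrix(G),
         ann = AnnotationMatrix(B, sprintf("module %d process",
                                           seq_len(nModules))))
}

#' Generate a synthetic chemical-genetic screen with planted signal
#'
#' Active compounds are scaled, noisy copies of randomly chosen query
#' columns: `profile = s * base + N(0, (noiseSd * s * sd(base))^2)` per
#' strain, where `base` is the parent query profile (or its negative part
#' when `signal = "negative"`, emulating screens where the biology lives in
#' sensitivity interactions) and `s = signalStrength`. Inactive compounds and
#' solvent controls are unit-variance Gaussian noise — the natural null for
#' z-score profiles. The truth table records each active compound's parent
#' query and its planted terms.
#'
#' @param gi,ann network and annotations from [generateGeneticNetwork()].
#' @param nActive,nInactive,nControls compound/control counts (defaults 50
#'   each).
#' @param noiseSd noise standard deviation as a fraction of the signal
#'   standard deviation (default 0.5; 0 makes actives exact scaled copies).
#' @param signalStrength multiplicative scale applied to the parent profile
#'   (default 4, placing strong planted interactions beyond |z| = 5 as in
#'   real screens).
#' @param signal `"full"` (both interaction signs, the raw query copy) or
#'   `"negative"` (signal carried only by negative scores).
#' @param seed optional integer seed.
#' @return A list with `cg` (a [ChemGenProfileSet-class]: actives and
#'   inactives as `treatment`, solvent profiles as `control`) and `truth`
#'   (data frame: `condition_id`, `status`, `parent_query`, `terms`
#'   comma-separated; inactive rows have empty fields).
#' @export
generateScreen <- function(gi, ann, nActive = 50L, nInactive = 50L,
                           nControls = 50L, noiseSd = 0.5,
                           signalStrength = 4, signal = c("full", "negative"),
                           seed = NULL) {
    signal <- match.arg(signal)
    stopifnot(nActive >= 0L, nInactive >= 0L, nControls >= 0L, noiseSd >= 0)
    if (!is.null(seed)) set.seed(seed)
    G <- giScores(gi)
    nm <- nrow(G)
    B <- membership(ann)

    cols <- list(); types <- character(); truthRows <- list()
    if (nActive > 0L) {
        parents <- sample(colnames(G), nActive, replace = TRUE)
        for (i in seq_len(nActive)) {
            base <- G[, parents[i]]
            if (signal == "negative") base <- pmin(base, 0)
            sdSig <- stats::sd(base)
            prof <- signalStrength * base +
                stats::rnorm(nm, 0, noiseSd * signalStrength * sdSig)
            id <- sprintf("cmpd_active_%03d", i)
            cols[[id]] <- prof; types <- c(types, "treatment")
            terms <- colnames(B)[B[parents[i], ] > 0]
            truthRows[[id]] <- data.frame(
                condition_id = id, status = "active",
                parent_query = parents[i],
                terms = paste(terms, collapse = ","),
                stringsAsFactors = FALSE)
        }
    }
    if (nInactive > 0L) {
        for (i in seq_len(nInactive)) {
            id <- sprintf("cmpd_inactive_%03d", i)
            cols[[id]] <- stats::rnorm(nm)
            types <- c(types, "treatment")
            truthRows[[id]] <- data.frame(
                condition_id = id, status = "inactive", parent_query = "",
                terms = "", stringsAsFactors = FALSE)
        }
    }
    if (nControls > 0L) {
        for (i in seq_len(nControls)) {
            id <- sprintf("ctrl_%03d", i)
            cols[[id]] <- stats::rnorm(nm)
            types <- c(types, "control")
        }
    }
    m <- do.call(cbind, cols)
    rownames(m) <- rownames(G)
    truth <- do.call(rbind, truthRows)
    if (!is.null(truth)) rownames(truth) <- NULL
    list(cg = ChemGenProfileSet(m, types), truth = truth)
}

#' Write a complete synthetic screen to a directory
#'
#' Emits the three pipeline inputs plus the truth table as plain TSV/GMT
#' files: `chemgen.tsv`, `condition_types.tsv`, `genetic.tsv`,
#' `gene_sets.gmt`, `truth.tsv`.
#'
#' @param dir output directory (created if needed).
#' @param network output of [generateGeneticNetwork()].
#' @param screen output of [generateScreen()].
#' @return `dir`, invisibly.
#' @export
writeSyntheticScreen <- function(dir, network, screen) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeLabeledMatrix(screen$cg, file.path(dir, "chemgen.tsv"))
    writeConditionTypes(screen$cg, file.path(dir, "condition_types.tsv"))
    writeLabeledMatrix(network$gi, file.path(dir, "genetic.tsv"))
    writeGeneSets(network$ann, file.path(dir, "gene_sets.gmt"))
    if (!is.null(screen$truth))
        utils::write.table(screen$truth, file.path(dir, "truth.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(dir)
}
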