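## End-to-end orchestration: align -> normalize -> resample -> similarity ->
## process scores -> three nulls -> conservative combination -> two FDR maps
## -> tables.

.deriveSeed <- function(seed, k) {
    if (is.null(seed)) NULL else (as.integer(seed) + k) %% 2147483647L
}

#' Predict perturbed bioprocesses for a chemical-genetic screen
#'
#' Runs the full prediction pipeline. After strain alignment and L2
#' normalization of the genetic interaction queries, a resampled-profile null
#' is generated from the treatment conditions; similarity and process scores
#' are computed for every condition (treatments, experimental controls and
#' resampled profiles); per-term z-scores and empirical p-values are derived
#' from the experimental-control, resampled and within-profile nulls and
#' combined conservatively (largest p wins; ties take the smallest z); and
#' per-profile false discovery rates are estimated against both control
#' types. Combined statistics are computed for all profile types because the
#' FDR maps require the control types' own best predictions.
#'
#' @param cg a [ChemGenProfileSet-class] with treatment and control columns.
#' @param gi a raw [GeneticInteractionMatrix-class].
#' @param ann an [AnnotationMatrix-class] over the query genes.
#' @param nGamma number of resampled null profiles (study-scale default
#'   50000; scale down for small screens).
#' @param nPerm within-profile permutation count (study-scale default
#'   10000).
#' @param minTermSize,maxTermSize term size bounds re-applied after any
#'   queries are dropped during normalization (defaults 4 and 200).
#' @param seed optional integer master seed; resampling and permutation
#'   seeds are derived from it.
#' @param fdrCap upper bound for reported FDR values (default 1).
#' @return An object of class `"BioprocessPredictions"`: a list with
#'   `predictions` (long-format data frame for the treatment profiles),
#'   `combined` (per profile type: combined z/p/source matrices),
#'   `fdrMaps` (list of two [FdrMap-class]), `fdr` (per-treatment-term FDR
#'   matrices), `ptop` (per type), `fdrTable` (threshold summary), `scores`
#'   (similarity and process-score matrices for treatments), `giNorm`,
#'   `ann`, and `params`.
#' @export
predictBioprocesses <- function(cg, gi, ann, nGamma = 50000L, nPerm = 10000L,
                                minTermSize = 4L, maxTermSize = 200L,
                                seed = NULL, fdrCap = 1) {
    aligned <- alignStrains(cg, gi)
    cg <- aligned$cg
    giNorm <- l2NormalizeQueries(aligned$gi)
    ann <- restrictGenes(ann, queryIds(giNorm))
    ann <- filterTermSizes(ann, minTermSize, maxTermSize)
    if (length(termIds(ann)) == 0L)
        stop("no terms survive size filtering on the aligned query universe")

    gamma <- resampleProfiles(cg, nGamma, seed = .deriveSeed(seed, 0L))
    all <- ChemGenProfileSet(
        cbind(cgScores(cg), cgScores(gamma)),
        c(unname(conditionType(cg)), unname(conditionType(gamma))))
    type <- conditionType(all)

    S <- similarityScores(all, giNorm)
    X <- processScores(S, ann)

    ctl <- controlStatistics(X, X[type == "control", , drop = FALSE])
    res <- controlStatistics(X, X[type == "resampled", , drop = FALSE])
    wth <- withinStatistics(S, ann, nPerm = nPerm,
                            seed = .deriveSeed(seed, 1L))

    comb <- combineStatistics(
        zList = list(control = ctl$z, resampled = res$z, within = wth$z),
        pList = list(control = ctl$p, resampled = res$p, within = wth$p),
        denominators = c(control = ctl$n, resampled = res$n, within = wth$n))

    byType <- function(m) lapply(
        c(treatment = "treatment", control = "control",
          resampled = "resampled"),
        function(t) m[type == t, , drop = FALSE])
    combByType <- lapply(comb[c("z", "p", "source", "pNum", "pDen")], byType)

    pAll <- sort(unique(as.vector(comb$p)))
    ptop <- lapply(combByType$p, bestPPerProfile)
    fdrMaps <- list(
        control = buildFdrMap(ptop$treatment, ptop$control, pAll,
                              "control", cap = fdrCap),
        resampled = buildFdrMap(ptop$treatment, ptop$resampled, pAll,
                                "resampled", cap = fdrCap))
    fdr <- lapply(fdrMaps, applyFdr, P = combByType$p$treatment)

    trIdx <- which(type == "treatment")
    Xtreat <- X[trIdx, , drop = FALSE]
    predictions <- data.frame(
        condition_id = rep(rownames(Xtreat), times = ncol(Xtreat)),
        term_id = rep(colnames(Xtreat), each = nrow(Xtreat)),
        term_name = rep(unname(termNames(ann)), each = nrow(Xtreat)),
        score = as.vector(Xtreat),
        z = as.vector(combByType$z$treatment),
        p_count_numerator = as.vector(combByType$pNum$treatment),
        p_count_denominator = as.vector(combByType$pDen$treatment),
        p = as.vector(combByType$p$treatment),
        source = as.vector(combByType$source$treatment),
        fdr_control = as.vector(fdr$control),
        fdr_resampled = as.vector(fdr$resampled),
        stringsAsFactors = FALSE)
    ord <- order(predictions$condition_id, predictions$p, -predictions$z,
                 predictions$term_id)
    predictions <- predictions[ord, , drop = FALSE]
    rownames(predictions) <- NULL

    structure(list(
        predictions = predictions,
        combined = combByType,
        fdrMaps = fdrMaps,
        fdr = fdr,
        ptop = ptop,
        fdrTable = fdrSummary(fdrMaps$control, fdrMaps$resampled,
                              ptop$treatment, ptop$control, ptop$resampled),
        scores = list(similarity = S[trIdx, , drop = FALSE],
                      process = Xtreat),
        giNorm = giNorm,
        ann = ann,
        cg = cg,
        params = list(nGamma = nGamma, nPerm = nPerm,
                      minTermSize = minTermSize, maxTermSize = maxTermSize,
                      seed = seed, fdrCap = fdrCap)),
        class = "BioprocessPredictions")
}

#' @export
print.BioprocessPredictions <- function(x, ...) {
    nTreat <- length(x$ptop$treatment)
    disc <- sum(discoveredAtFdr(x$fdrMaps$resampled, x$ptop$treatment, 0.25))
    cat(sprintf(
        "BioprocessPredictions: %d treatment profiles x %d terms\n",
        nTreat, ncol(x$scores$process)))
    cat(sprintf(
        "  high-confidence profiles (resampled FDR <= 0.25): %d (%.1f%%)\n",
        disc, 100 * disc / nTreat))
    invisible(x)
}

#' Write pipeline output tables
#'
#' Writes `predictions.tsv` (long format, one row per treatment-term pair),
#' `fdr_summary.tsv` and a `run_manifest.txt` key-value file capturing every
#' parameter so published defaults are auditable. Numeric columns use
#' `"%.6g"`; empirical p-values additionally carry their exact integer
#' counts.
#'
#' @param result a `"BioprocessPredictions"` from [predictBioprocesses()].
#' @param dir output directory (created if needed).
#' @param digits significant digits for numeric table columns.
#' @return `dir`, invisibly.
#' @export
writePredictions <- function(result, dir, digits = 6L) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
    pred <- result$predictions
    for (cl in c("score", "z", "p", "fdr_control", "fdr_resampled"))
        pred[[cl]] <- fmt(pred[[cl]])
    utils::write.table(pred, file.path(dir, "predictions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    fdrTab <- result$fdrTable
    for (cl in c("p", "fdr_ctrl", "fdr_resampled"))
        fdrTab[[cl]] <- fmt(fdrTab[[cl]])
    utils::write.table(fdrTab, file.path(dir, "fdr_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    p <- result$params
    manifest <- c(
        sprintf("n_gamma\t%d", p$nGamma),
        sprintf("n_perm\t%d", p$nPerm),
        sprintf("min_term_size\t%d", p$minTermSize),
        sprintf("max_term_size\t%d", p$maxTermSize),
        sprintf("seed\t%s", if (is.null(p$seed)) "NA" else p$seed),
        sprintf("fdr_cap\t%g", p$fdrCap),
        sprintf("n_treatment\t%d", length(result$ptop$treatment)),
        sprintf("n_control\t%d", length(result$ptop$control)),
        sprintf("n_terms\t%d", ncol(result$scores$process)))
    writeLines(manifest, file.path(dir, "run_manifest.txt"))
    invisible(dir)
}

#' Run the prediction pipeline from a configuration list or file
#'
#' @param config either a named list or the path of a YAML / `key: value`
#'   file with keys `chemgen`, `condition_types`, `genetic`, `gene_sets`,
#'   `out_dir` and optionally `n_gamma`, `n_perm`, `min_term_size`,
#'   `max_term_size`, `seed`.
#' @param ... overrides applied on top of the config.
#' @return The `"BioprocessPredictions"` object, invisibly; tables are
#'   written to `out_dir`.
#' @export
runPredict <- function(config, ...) {
    if (is.character(config) && length(config) == 1L) {
        if (!file.exists(config)) stop("config file not found: ", config)
        if (requireNamespace("yaml", quietly = TRUE)) {
            config <- yaml::read_yaml(config)
        } else {
            lines <- grep(":", readLines(config), fixed = TRUE, value = TRUE)
            kv <- strsplit(lines, ":", fixed = TRUE)
            config <- setNames(lapply(kv, function(x)
                trimws(paste(x[-1L], collapse = ":"))),
                vapply(kv, function(x) trimws(x[[1L]]), ""))
        }
    }
    config <- utils::modifyList(as.list(config), list(...))
    need <- c("chemgen", "condition_types", "genetic", "gene_sets", "out_dir")
    miss <- setdiff(need, names(config))
    if (length(miss))
        stop("config error: missing key(s): ", paste(miss, collapse = ", "))
    num <- function(key, default) {
        if (is.null(config[[key]])) default else as.numeric(config[[key]])
    }
    cg <- readLabeledMatrix(config$chemgen, "chemgen",
                            conditionTypes = config$condition_types)
    gi <- readLabeledMatrix(config$genetic, "genetic")
    ann <- readGeneSets(config$gene_sets, universe = queryIds(gi))
    res <- predictBioprocesses(
        cg, gi, ann,
        nGamma = as.integer(num("n_gamma", 50000L)),
        nPerm = as.integer(num("n_perm", 10000L)),
        minTermSize = as.integer(num("min_term_size", 4L)),
        maxTermSize = as.integer(num("max_term_size", 200L)),
        seed = if (is.null(config$seed)) NULL else as.integer(config$seed))
    writePredictions(res, config$out_dir)
    invisible(res)
}
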