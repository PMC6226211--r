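## Readers and writers for the on-disk formats: labeled TSV matrices, GMT
## gene-set files, and the condition-type sidecar table. Strains are rows on
## disk for both matrix kinds; `transpose` handles nonconforming files.

.readTsvMatrix <- function(path, transpose = FALSE, imputeZero = FALSE) {
    if (!file.exists(path))
        stop("cannot read file: ", path)
    df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = NULL,
                            check.names = FALSE, quote = "",
                            comment.char = "", stringsAsFactors = FALSE)
    if (ncol(df) < 2L || nrow(df) < 1L)
        stop("format error in ", path, ": empty matrix")
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
        stop("format error in ", path, ": duplicated row id '",
             ids[duplicated(ids)][1L], "'")
    cn <- colnames(df)[-1L]
    if (anyDuplicated(cn))
        stop("format error in ", path, ": duplicated column id '",
             cn[duplicated(cn)][1L], "'")
    body <- df[, -1L, drop = FALSE]
    m <- matrix(NA_real_, nrow(body), ncol(body), dimnames = list(ids, cn))
    for (j in seq_len(ncol(body))) {
        v <- body[[j]]
        if (!is.numeric(v)) {
            suppressWarnings(vn <- as.numeric(v))
            bad <- which(is.na(vn) & !is.na(v))
            if (length(bad))
                stop("format error in ", path, ": non-numeric cell at row '",
                     ids[bad[1L]], "', column '", cn[j], "'")
            v <- vn
        }
        m[, j] <- v
    }
    if (anyNA(m)) {
        if (imputeZero) {
            warning(sum(is.na(m)), " missing cells imputed to 0 in ", path)
            m[is.na(m)] <- 0
        } else {
            bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
            stop("format error in ", path, ": missing cell at row '",
                 rownames(m)[bad[1L]], "', column '", colnames(m)[bad[2L]],
                 "' (use imputeZero = TRUE to convert to 0)")
        }
    }
    if (transpose) m <- t(m)
    m
}

#' Read a labeled interaction matrix from TSV
#'
#' Reads a tab-separated matrix with one header row of column identifiers and
#' a first column of row identifiers, returning a typed container. Strains are
#' expected as rows; set `transpose = TRUE` for files stored the other way.
#'
#' @param path path to the TSV file.
#' @param what `"chemgen"` for a [ChemGenProfileSet-class] or `"genetic"` for
#'   a [GeneticInteractionMatrix-class].
#' @param conditionTypes for `what = "chemgen"`: either a named character
#'   vector (condition id -> type) or the path of a two-column sidecar TSV
#'   with columns `condition_id` and `type` (`treatment`/`control`).
#' @param transpose logical; transpose the on-disk matrix before typing.
#' @param imputeZero logical; convert missing cells to 0 with a warning
#'   instead of failing (missingness is otherwise rejected, since the scoring
#'   model assumes dense matrices).
#' @return A [ChemGenProfileSet-class] or [GeneticInteractionMatrix-class].
#' @export
readLabeledMatrix <- function(path, what = c("chemgen", "genetic"),
                              conditionTypes = NULL, transpose = FALSE,
                              imputeZero = FALSE) {
    what <- match.arg(what)
    m <- .readTsvMatrix(path, transpose = transpose, imputeZero = imputeZero)
    if (what == "genetic")
        return(GeneticInteractionMatrix(m))
    if (is.null(conditionTypes)) {
        ct <- rep("treatment", ncol(m))
    } else {
        if (is.character(conditionTypes) && length(conditionTypes) == 1L &&
            file.exists(conditionTypes))
            conditionTypes <- readConditionTypes(conditionTypes)
        missing <- setdiff(colnames(m), names(conditionTypes))
        if (length(missing))
            stop("no condition type given for: ",
                 paste(utils::head(missing, 5L), collapse = ", "))
        ct <- unname(conditionTypes[colnames(m)])
    }
    ChemGenProfileSet(m, ct)
}

#' Read a condition-type sidecar table
#'
#' @param path TSV with header columns `condition_id` and `type`.
#' @return Named character vector mapping condition id to type.
#' @export
readConditionTypes <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, quote = "",
                            comment.char = "")
    if (!all(c("condition_id", "type") %in% colnames(df)))
        stop("condition-type table needs columns 'condition_id' and 'type'")
    bad <- setdiff(unique(df$type), .CONDITION_TYPES)
    if (length(bad))
        stop("unknown condition type(s): ", paste(bad, collapse = ", "))
    if (anyDuplicated(df$condition_id))
        stop("duplicated condition_id in ", path)
    setNames(as.character(df$type), df$condition_id)
}

#' Write a labeled matrix to TSV
#'
#' Writes strains as rows with full double precision (`%.17g`), so a
#' write-then-read round trip reproduces values exactly.
#'
#' @param x a [ChemGenProfileSet-class], [GeneticInteractionMatrix-class], or
#'   plain dimnamed numeric matrix.
#' @param path output file path.
#' @param digits printf precision used for the numeric body.
#' @return `path`, invisibly.
#' @export
writeLabeledMatrix <- function(x, path, digits = 17L) {
    m <- if (is(x, "ChemGenProfileSet")) cgScores(x)
         else if (is(x, "GeneticInteractionMatrix")) giScores(x)
         else as.matrix(x)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("", colnames(m)), collapse = "\t"), con)
    fmt <- paste0("%.", digits, "g")
    body <- apply(m, 1L, function(r) paste(sprintf(fmt, r), collapse = "\t"))
    writeLines(paste(rownames(m), body, sep = "\t"), con)
    invisible(path)
}

#' Write the condition-type sidecar for a ChemGenProfileSet
#'
#' @param cg a [ChemGenProfileSet-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeConditionTypes <- function(cg, path) {
    df <- data.frame(condition_id = conditionIds(cg),
                     type = unname(conditionType(cg)))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One term per line: `term_id<TAB>term_name<TAB>member1<TAB>member2...`.
#' Members outside `universe` are dropped (a message reports the count); terms
#' left with zero members are retained until [filterTermSizes()].
#'
#' @param path GMT file path.
#' @param universe character vector of gene identifiers defining the rows of
#'   the resulting matrix.
#' @return An [AnnotationMatrix-class] over `universe`.
#' @export
readGeneSets <- function(path, universe) {
    if (!file.exists(path))
        stop("cannot read file: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        stop("format error in ", path, ": empty GMT file")
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 2L))
        stop("format error in ", path, ": line ", which(nf < 2L)[1L],
             " has fewer than 2 fields")
    ids <- vapply(fields, `[[`, "", 1L)
    if (anyDuplicated(ids))
        stop("format error in ", path, ": duplicated term id '",
             ids[duplicated(ids)][1L], "'")
    nms <- vapply(fields, `[[`, "", 2L)
    universe <- as.character(universe)
    m <- matrix(0, length(universe), length(ids),
                dimnames = list(universe, ids))
    dropped <- 0L
    for (j in seq_along(fields)) {
        mem <- unique(fields[[j]][-(1:2)])
        keep <- mem[mem %in% universe]
        dropped <- dropped + length(mem) - length(keep)
        if (length(keep) == 0L && length(mem) > 0L)
            warning("term '", ids[j], "' has no members in the universe")
        m[keep, j] <- 1
    }
    if (dropped > 0L)
        message(dropped, " gene memberships outside the universe were dropped")
    AnnotationMatrix(m, nms)
}

#' Write an AnnotationMatrix as a GMT file
#'
#' @param ann an [AnnotationMatrix-class].
#' @param path output GMT path.
#' @return `path`, invisibly.
#' @export
writeGeneSets <- function(ann, path) {
    m <- membership(ann)
    nms <- termNames(ann)
    lines <- vapply(seq_len(ncol(m)), function(j) {
        paste(c(colnames(m)[j], nms[[j]], rownames(m)[m[, j] > 0]),
              collapse = "\t")
    }, "")
    writeLines(lines, path)
    invisible(path)
}

#' Align a chemical-genetic and a genetic interaction matrix on shared strains
#'
#' Restricts both matrices to the intersection of their strain identifiers, in
#' a single canonical order (the chemical-genetic order), so that inner
#' products between profiles are taken over matched mutants. Idempotent.
#'
#' @param cg a [ChemGenProfileSet-class].
#' @param gi a [GeneticInteractionMatrix-class].
#' @return A list with elements `cg` and `gi`, both restricted to the common
#'   strains in identical row order.
#' @export
alignStrains <- function(cg, gi) {
    stopifnot(is(cg, "ChemGenProfileSet"), is(gi, "GeneticInteractionMatrix"))
    common <- intersect(strainIds(cg), strainIds(gi))
    if (length(common) == 0L)
        stop("alignment error: no shared strains between the two matrices")
    dropCg <- nrow(cg) - length(common)
    dropGi <- nrow(gi) - length(common)
    if (dropCg > 0L || dropGi > 0L)
        message("alignStrains: dropped ", dropCg,
                " chemical-genetic and ", dropGi, " genetic strains")
    list(cg = cg[common, ], gi = gi[common, ])
}
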