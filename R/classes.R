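#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

.CONDITION_TYPES <- c("treatment", "control", "resampled")

#' ChemGenProfileSet: chemical-genetic interaction profiles
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding a dense
#' strains x conditions matrix of chemical-genetic interaction z-scores (assay
#' `"zscore"`), with a per-condition type label (`treatment`, `control` or
#' `resampled`) in `colData`. Rows are deletion-mutant (array) strains, the
#' dimension shared with the genetic interaction compendium; columns are
#' screened conditions (compound treatments, solvent controls, or resampled
#' null profiles).
#'
#' Validity requires unique strain and condition identifiers, all-finite
#' values, and a condition type drawn from the three allowed labels.
#'
#' @export
setClass("ChemGenProfileSet", contains = "SummarizedExperiment")

setValidity("ChemGenProfileSet", function(object) {
    msg <- character()
    if (!"zscore" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'zscore' is required")
    m <- SummarizedExperiment::assay(object, 1L)
    if (nrow(m) == 0L || ncol(m) == 0L)
        msg <- c(msg, "profile matrix must be non-empty")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "strain identifiers must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "condition identifiers must be present and unique")
    if (!all(is.finite(m)))
        msg <- c(msg, "all interaction scores must be finite (no NA/NaN/Inf)")
    ct <- colData(object)$conditionType
    if (is.null(ct)) {
        msg <- c(msg, "colData must contain a 'conditionType' column")
    } else if (!all(ct %in% .CONDITION_TYPES)) {
        msg <- c(msg, sprintf("conditionType must be one of: %s",
                              paste(.CONDITION_TYPES, collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a ChemGenProfileSet
#'
#' @param values numeric matrix, strains (rows) x conditions (columns), with
#'   dimnames giving strain and condition identifiers.
#' @param conditionType character vector of per-condition labels, each one of
#'   `"treatment"`, `"control"`, `"resampled"`. Recycled if length 1.
#' @return A [ChemGenProfileSet-class] object.
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("s1", "s2"), c("c1", "c2", "c3")))
#' cg <- ChemGenProfileSet(m, c("treatment", "treatment", "control"))
#' conditionCounts(cg)
#' @export
ChemGenProfileSet <- function(values, conditionType) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (length(conditionType) == 1L)
        conditionType <- rep(conditionType, ncol(values))
    if (length(conditionType) != ncol(values))
        stop("conditionType must have one entry per condition")
    se <- SummarizedExperiment(
        assays = list(zscore = values),
        colData = DataFrame(conditionType = as.character(conditionType),
                            row.names = colnames(values)))
    new("ChemGenProfileSet", se)
}

#' GeneticInteractionMatrix: genetic interaction profiles
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding a dense
#' strains x query-genes matrix of genetic interaction (epsilon) scores, assay
#' `"score"`. Rows are the array strains shared with chemical-genetic
#' profiles; columns are query genes whose profiles define functional
#' similarity. The `normalized` slot records whether each column has been
#' scaled to unit Euclidean norm (see [l2NormalizeQueries()]).
#'
#' @export
setClass("GeneticInteractionMatrix",
         contains = "SummarizedExperiment",
         representation(normalized = "logical"),
         prototype(normalized = FALSE))

setValidity("GeneticInteractionMatrix", function(object) {
    msg <- character()
    m <- SummarizedExperiment::assay(object, 1L)
    if (nrow(m) == 0L || ncol(m) == 0L)
        msg <- c(msg, "interaction matrix must be non-empty")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "strain identifiers must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "query identifiers must be present and unique")
    if (!all(is.finite(m)))
        msg <- c(msg, "all interaction scores must be finite (no NA/NaN/Inf)")
    if (length(object@normalized) != 1L)
        msg <- c(msg, "'normalized' must be a single logical")
    else if (object@normalized) {
        nrm <- sqrt(colSums(m^2))
        if (any(abs(nrm - 1) > 1e-9))
            msg <- c(msg, "normalized flag set but some column norms differ from 1")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a GeneticInteractionMatrix
#'
#' @param values numeric matrix, strains (rows) x query genes (columns), with
#'   dimnames giving strain and query identifiers.
#' @param normalized logical; `TRUE` only if every column already has unit
#'   Euclidean norm.
#' @return A [GeneticInteractionMatrix-class] object.
#' @examples
#' g <- matrix(rnorm(8), 2, 4,
#'             dimnames = list(c("s1", "s2"), paste0("q", 1:4)))
#' gi <- GeneticInteractionMatrix(g)
#' isNormalized(gi)
#' @export
GeneticInteractionMatrix <- function(values, normalized = FALSE) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    se <- SummarizedExperiment(assays = list(score = values))
    new("GeneticInteractionMatrix", se, normalized = normalized)
}

#' AnnotationMatrix: binary gene-to-term membership
#'
#' Binary membership of genes (rows; query genes for bioprocess prediction, or
#' array strains for the direct-enrichment baseline) in bioprocess terms
#' (columns), together with human-readable term names. Term sizes are the
#' column sums.
#'
#' @slot membership numeric 0/1 matrix, genes x terms, with dimnames.
#' @slot termNames character vector of display names, one per term.
#' @export
setClass("AnnotationMatrix",
         representation(membership = "matrix", termNames = "character"))

setValidity("AnnotationMatrix", function(object) {
    msg <- character()
    m <- object@membership
    if (nrow(m) > 0L && (is.null(rownames(m)) || anyDuplicated(rownames(m))))
        msg <- c(msg, "gene identifiers must be present and unique")
    if (ncol(m) > 0L && (is.null(colnames(m)) || anyDuplicated(colnames(m))))
        msg <- c(msg, "term identifiers must be present and unique")
    if (!all(m %in% c(0, 1)))
        msg <- c(msg, "membership entries must be 0 or 1")
    if (length(object@termNames) != ncol(m))
        msg <- c(msg, "termNames must have one entry per term")
    if (length(msg)) msg else TRUE
})

#' Construct an AnnotationMatrix
#'
#' @param membership numeric or logical genes x terms matrix (coerced to 0/1)
#'   with dimnames.
#' @param termNames optional character vector of display names per term;
#'   defaults to the term identifiers.
#' @return An [AnnotationMatrix-class] object.
#' @examples
#' b <- matrix(c(1, 1, 0, 0, 1, 1), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("T1", "T2")))
#' ann <- AnnotationMatrix(b)
#' termSizes(ann)
#' @export
AnnotationMatrix <- function(membership, termNames = NULL) {
    membership <- as.matrix(membership)
    storage.mode(membership) <- "double"
    membership[] <- as.numeric(membership != 0)
    if (is.null(termNames))
        termNames <- colnames(membership)
    new("AnnotationMatrix", membership = membership,
        termNames = as.character(termNames))
}

#' FdrMap: monotone p-value to false-discovery-rate step function
#'
#' Maps every observed p-value to an estimated false discovery rate, for one
#' control profile type. `rStar` holds the raw per-threshold ratio of control
#' to treatment discovery fractions; `r` is its suffix running minimum, so the
#' map is nondecreasing in p.
#'
#' @slot controlType `"control"` or `"resampled"`.
#' @slot pAll sorted ascending unique vector of all observed p-values.
#' @slot rStar raw FDR estimate per threshold in `pAll`.
#' @slot r monotone-adjusted FDR per threshold.
#' @slot nTreat,nCtrl numbers of treatment / control profiles used.
#' @export
setClass("FdrMap",
         representation(controlType = "character", pAll = "numeric",
                        rStar = "numeric", r = "numeric",
                        nTreat = "integer", nCtrl = "integer"))

setValidity("FdrMap", function(object) {
    msg <- character()
    if (is.unsorted(object@pAll, strictly = TRUE))
        msg <- c(msg, "pAll must be strictly increasing")
    if (length(object@pAll) != length(object@r) ||
        length(object@pAll) != length(object@rStar))
        msg <- c(msg, "pAll, rStar and r must have equal length")
    if (length(object@r) > 1L && any(diff(object@r) < 0))
        msg <- c(msg, "r must be nondecreasing along pAll")
    suffixMin <- rev(cummin(rev(object@rStar)))
    if (any(abs(object@r - suffixMin) > 1e-12))
        msg <- c(msg, "r must equal the suffix minimum of rStar")
    if (length(msg)) msg else TRUE
})

#' SimulatedProfileSet: simulated chemical-genetic profiles
#'
#' Simulated treatment profiles derived from query genetic interaction
#' profiles, each inheriting the bioprocess annotations of its parent query
#' gene as a gold standard.
#'
#' @slot profiles a [ChemGenProfileSet-class] of type `treatment`.
#' @slot parentQuery character vector, parent query gene per profile.
#' @slot inheritedTerms named list of term-id character vectors per profile.
#' @export
setClass("SimulatedProfileSet",
         representation(profiles = "ChemGenProfileSet",
                        parentQuery = "character",
                        inheritedTerms = "list"))

setValidity("SimulatedProfileSet", function(object) {
    msg <- character()
    n <- ncol(object@profiles)
    if (length(object@parentQuery) != n)
        msg <- c(msg, "parentQuery must have one entry per profile")
    if (length(object@inheritedTerms) != n)
        msg <- c(msg, "inheritedTerms must have one entry per profile")
    if (length(msg)) msg else TRUE
})

## ---- accessors --------------------------------------------------------

#' @rdname ChemGenProfileSet-class
#' @param x,object an object of the documented class.
#' @export
setGeneric("cgScores", function(x) standardGeneric("cgScores"))

#' @rdname ChemGenProfileSet-class
#' @export
setMethod("cgScores", "ChemGenProfileSet",
          function(x) SummarizedExperiment::assay(x, "zscore"))

#' @rdname ChemGenProfileSet-class
#' @export
setGeneric("conditionType", function(x) standardGeneric("conditionType"))

#' @rdname ChemGenProfileSet-class
#' @export
setMethod("conditionType", "ChemGenProfileSet",
          function(x) setNames(colData(x)$conditionType, colnames(x)))

#' @rdname ChemGenProfileSet-class
#' @export
setGeneric("conditionIds", function(x) standardGeneric("conditionIds"))

#' @rdname ChemGenProfileSet-class
#' @export
setMethod("conditionIds", "ChemGenProfileSet", function(x) colnames(x))

#' @rdname ChemGenProfileSet-class
#' @export
setGeneric("conditionCounts", function(x) standardGeneric("conditionCounts"))

#' @rdname ChemGenProfileSet-class
#' @export
setMethod("conditionCounts", "ChemGenProfileSet", function(x) {
    ct <- factor(colData(x)$conditionType, levels = .CONDITION_TYPES)
    table(ct)
})

#' @rdname ChemGenProfileSet-class
#' @export
setGeneric("strainIds", function(x) standardGeneric("strainIds"))

#' @rdname ChemGenProfileSet-class
#' @export
setMethod("strainIds", "ChemGenProfileSet", function(x) rownames(x))

#' @rdname GeneticInteractionMatrix-class
#' @export
setMethod("strainIds", "GeneticInteractionMatrix", function(x) rownames(x))

#' @rdname GeneticInteractionMatrix-class
#' @param x,object an object of the documented class.
#' @export
setGeneric("giScores", function(x) standardGeneric("giScores"))

#' @rdname GeneticInteractionMatrix-class
#' @export
setMethod("giScores", "GeneticInteractionMatrix",
          function(x) SummarizedExperiment::assay(x, "score"))

#' @rdname GeneticInteractionMatrix-class
#' @export
setGeneric("queryIds", function(x) standardGeneric("queryIds"))

#' @rdname GeneticInteractionMatrix-class
#' @export
setMethod("queryIds", "GeneticInteractionMatrix", function(x) colnames(x))

#' @rdname GeneticInteractionMatrix-class
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname GeneticInteractionMatrix-class
#' @export
setMethod("isNormalized", "GeneticInteractionMatrix",
          function(x) x@normalized)

#' @rdname AnnotationMatrix-class
#' @param x,object an object of the documented class.
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @rdname AnnotationMatrix-class
#' @export
setMethod("membership", "AnnotationMatrix", function(x) x@membership)

#' @rdname AnnotationMatrix-class
#' @export
setGeneric("termIds", function(x) standardGeneric("termIds"))

#' @rdname AnnotationMatrix-class
#' @export
setMethod("termIds", "AnnotationMatrix", function(x) colnames(x@membership))

#' @rdname AnnotationMatrix-class
#' @export
setGeneric("termNames", function(x) standardGeneric("termNames"))

#' @rdname AnnotationMatrix-class
#' @export
setMethod("termNames", "AnnotationMatrix",
          function(x) setNames(x@termNames, colnames(x@membership)))

#' @rdname AnnotationMatrix-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname AnnotationMatrix-class
#' @export
setMethod("geneIds", "AnnotationMatrix", function(x) rownames(x@membership))

#' @rdname AnnotationMatrix-class
#' @export
setGeneric("termSizes", function(x) standardGeneric("termSizes"))

#' @rdname AnnotationMatrix-class
#' @export
setMethod("termSizes", "AnnotationMatrix", function(x) colSums(x@membership))

#' Term members of an AnnotationMatrix
#'
#' @param x an [AnnotationMatrix-class].
#' @param termId a single term identifier.
#' @return Character vector of member gene identifiers.
#' @export
setGeneric("termMembers", function(x, termId) standardGeneric("termMembers"))

#' @rdname termMembers
#' @export
setMethod("termMembers", "AnnotationMatrix", function(x, termId) {
    if (!termId %in% colnames(x@membership))
        stop("unknown term: ", termId)
    rownames(x@membership)[x@membership[, termId] > 0]
})

#' Restrict an AnnotationMatrix to a gene universe
#'
#' Drops annotation rows for genes outside `genes` and adds all-zero rows for
#' genes of `genes` absent from the matrix, so the row space matches the given
#' universe exactly (in its order). Term sizes shrink accordingly; terms are
#' not removed (use [filterTermSizes()] afterwards).
#'
#' @param x an [AnnotationMatrix-class].
#' @param genes character vector of gene identifiers defining the universe.
#' @return An [AnnotationMatrix-class] over `genes`.
#' @export
setGeneric("restrictGenes", function(x, genes) standardGeneric("restrictGenes"))

#' @rdname restrictGenes
#' @export
setMethod("restrictGenes", "AnnotationMatrix", function(x, genes) {
    genes <- as.character(genes)
    if (anyDuplicated(genes))
        stop("gene universe contains duplicated identifiers")
    m <- matrix(0, nrow = length(genes), ncol = ncol(x@membership),
                dimnames = list(genes, colnames(x@membership)))
    keep <- intersect(genes, rownames(x@membership))
    m[keep, ] <- x@membership[keep, , drop = FALSE]
    AnnotationMatrix(m, x@termNames)
})

## ---- FdrMap accessors -------------------------------------------------

#' @rdname FdrMap-class
#' @param x,object an object of the documented class.
#' @export
setGeneric("fdrThresholds", function(x) standardGeneric("fdrThresholds"))

#' @rdname FdrMap-class
#' @export
setMethod("fdrThresholds", "FdrMap", function(x) x@pAll)

#' @rdname FdrMap-class
#' @export
setGeneric("fdrValues", function(x) standardGeneric("fdrValues"))

#' @rdname FdrMap-class
#' @export
setMethod("fdrValues", "FdrMap", function(x) x@r)

#' @rdname FdrMap-class
#' @export
setGeneric("controlType", function(x) standardGeneric("controlType"))

#' @rdname FdrMap-class
#' @export
setMethod("controlType", "FdrMap", function(x) x@controlType)

## ---- SimulatedProfileSet accessors ------------------------------------

#' @rdname SimulatedProfileSet-class
#' @param x,object an object of the documented class.
#' @export
setGeneric("profiles", function(x) standardGeneric("profiles"))

#' @rdname SimulatedProfileSet-class
#' @export
setMethod("profiles", "SimulatedProfileSet", function(x) x@profiles)

#' @rdname SimulatedProfileSet-class
#' @export
setGeneric("parentQuery", function(x) standardGeneric("parentQuery"))

#' @rdname SimulatedProfileSet-class
#' @export
setMethod("parentQuery", "SimulatedProfileSet",
          function(x) setNames(x@parentQuery, colnames(x@profiles)))

#' @rdname SimulatedProfileSet-class
#' @export
setGeneric("inheritedTerms", function(x) standardGeneric("inheritedTerms"))

#' @rdname SimulatedProfileSet-class
#' @export
setMethod("inheritedTerms", "SimulatedProfileSet",
          function(x) setNames(x@inheritedTerms, colnames(x@profiles)))

## ---- show methods -----------------------------------------------------

setMethod("show", "ChemGenProfileSet", function(object) {
    cnt <- conditionCounts(object)
    cat(sprintf("ChemGenProfileSet: %d strains x %d conditions\n",
                nrow(object), ncol(object)))
    cat(sprintf("  treatment: %d  control: %d  resampled: %d\n",
                cnt[["treatment"]], cnt[["control"]], cnt[["resampled"]]))
})

setMethod("show", "GeneticInteractionMatrix", function(object) {
    cat(sprintf("GeneticInteractionMatrix: %d strains x %d queries (%s)\n",
                nrow(object), ncol(object),
                if (object@normalized) "L2 column-normalized" else "raw"))
})

setMethod("show", "AnnotationMatrix", function(object) {
    sz <- termSizes(object)
    cat(sprintf("AnnotationMatrix: %d genes x %d terms (sizes %s-%s)\n",
                nrow(object@membership), ncol(object@membership),
                if (length(sz)) min(sz) else NA,
                if (length(sz)) max(sz) else NA))
})

setMethod("show", "FdrMap", function(object) {
    cat(sprintf(
        "FdrMap (vs %s profiles): %d thresholds, FDR range [%.4g, %.4g]\n",
        object@controlType, length(object@pAll),
        min(object@r), max(object@r)))
})

setMethod("show", "SimulatedProfileSet", function(object) {
    cat(sprintf(
        "SimulatedProfileSet: %d profiles from %d parent queries\n",
        ncol(object@profiles), length(unique(object@parentQuery))))
})
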