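## Building, propagating and filtering term-membership matrices.

#' Propagate direct annotations up an is_a hierarchy
#'
#' Annotates every gene to all ancestors (transitive closure over `is_a`
#' edges) of each of its direct terms, in addition to the direct terms
#' themselves. Only `is_a` relationships are honored. The operation is
#' monotone (output membership contains the input) and idempotent.
#'
#' @param direct data frame with columns `gene_id` and `term_id` of direct
#'   annotations.
#' @param edges data frame with columns `child_id` and `parent_id` giving
#'   `is_a` edges between term identifiers; must be acyclic. `NULL` or empty
#'   means no propagation.
#' @return A data frame with columns `gene_id` and `term_id` containing the
#'   propagated annotations (unique rows).
#' @export
propagateAnnotations <- function(direct, edges = NULL) {
    stopifnot(all(c("gene_id", "term_id") %in% colnames(direct)))
    direct <- unique(direct[, c("gene_id", "term_id")])
    if (is.null(edges) || nrow(edges) == 0L)
        return(direct)
    stopifnot(all(c("child_id", "parent_id") %in% colnames(edges)))
    parents <- split(as.character(edges$parent_id), as.character(edges$child_id))

    ## ancestors by memoized DFS with cycle detection
    anc <- new.env(parent = emptyenv())
    onPath <- character()
    ancestorsOf <- function(term) {
        if (!is.null(anc[[term]])) return(anc[[term]])
        if (term %in% onPath)
            stop("annotation error: cycle in is_a hierarchy involving term '",
                 term, "'")
        onPath <<- c(onPath, term)
        ps <- parents[[term]]
        out <- character()
        for (p in ps)
            out <- union(out, c(p, ancestorsOf(p)))
        onPath <<- setdiff(onPath, term)
        anc[[term]] <- out
        out
    }
    allTerms <- union(unique(direct$term_id),
                      union(edges$child_id, edges$parent_id))
    for (t in as.character(allTerms)) ancestorsOf(t)

    extra <- lapply(seq_len(nrow(direct)), function(i) {
        a <- anc[[as.character(direct$term_id[i])]]
        if (length(a))
            data.frame(gene_id = direct$gene_id[i], term_id = a,
                       stringsAsFactors = FALSE)
        else NULL
    })
    out <- unique(rbind(direct, do.call(rbind, extra)))
    rownames(out) <- NULL
    out
}

#' Build an AnnotationMatrix from an annotation table
#'
#' @param annotations data frame with columns `gene_id` and `term_id`
#'   (typically the output of [propagateAnnotations()]); an optional
#'   `term_name` column supplies display names.
#' @param universe gene identifiers defining the rows; annotations outside it
#'   are dropped.
#' @return An [AnnotationMatrix-class].
#' @export
buildAnnotationMatrix <- function(annotations, universe) {
    stopifnot(all(c("gene_id", "term_id") %in% colnames(annotations)))
    universe <- as.character(universe)
    terms <- sort(unique(as.character(annotations$term_id)))
    m <- matrix(0, length(universe), length(terms),
                dimnames = list(universe, terms))
    keep <- annotations$gene_id %in% universe
    if (any(!keep))
        message(sum(!keep), " annotations outside the gene universe dropped")
    a <- annotations[keep, , drop = FALSE]
    m[cbind(as.character(a$gene_id), as.character(a$term_id))] <- 1
    nms <- terms
    if ("term_name" %in% colnames(annotations)) {
        lut <- annotations[!duplicated(annotations$term_id), ]
        nms <- as.character(lut$term_name[match(terms, lut$term_id)])
        nms[is.na(nms)] <- terms[is.na(nms)]
    }
    AnnotationMatrix(m, nms)
}

#' Filter terms by annotation count
#'
#' Keeps only terms whose size (number of annotated genes in the current
#' universe) lies within `[minSize, maxSize]`; the gene universe itself is
#' unchanged. The defaults retain terms with 4-200 gene annotations, the
#' range in which gene-set aggregation is informative: smaller sets give
#' unstable scores, larger ones are too generic to interpret.
#'
#' @param ann an [AnnotationMatrix-class].
#' @param minSize,maxSize inclusive size bounds; `minSize >= 1`,
#'   `maxSize >= minSize`.
#' @return A filtered [AnnotationMatrix-class] (possibly with zero terms, with
#'   a warning).
#' @export
filterTermSizes <- function(ann, minSize = 4L, maxSize = 200L) {
    if (minSize < 1L || maxSize < minSize)
        stop("require 1 <= minSize <= maxSize")
    sz <- termSizes(ann)
    keep <- sz >= minSize & sz <= maxSize
    if (!any(keep))
        warning("no terms left after size filtering")
    AnnotationMatrix(membership(ann)[, keep, drop = FALSE],
                     ann@termNames[keep])
}

#' Overlap index of two sets
#'
#' Size of the intersection divided by the size of the smaller set. Symmetric;
#' equals 1 exactly when one set contains the other.
#'
#' @param setA,setB nonempty vectors treated as sets.
#' @return A fraction in `[0, 1]`.
#' @examples
#' overlapIndex(c("a", "b", "c"), c("c", "d", "e"))  # 1/3
#' @export
overlapIndex <- function(setA, setB) {
    setA <- unique(setA); setB <- unique(setB)
    if (length(setA) == 0L || length(setB) == 0L)
        stop("overlapIndex is undefined for empty sets")
    length(intersect(setA, setB)) / min(length(setA), length(setB))
}
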