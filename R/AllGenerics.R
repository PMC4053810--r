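#' Extract beta values as a plain matrix
#'
#' @param x a [BetaSet] (or subclass).
#' @return numeric matrix, probes x samples.
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' @rdname betaValues
setMethod("betaValues", "BetaSet", function(x) assay(x, "beta"))

#' Per-sample cell-type labels of a sorted reference
#'
#' @param x a [SortedReference].
#' @return factor of cell-type labels, one per sample.
#' @export
setGeneric("cellTypeLabels", function(x) standardGeneric("cellTypeLabels"))

#' @rdname cellTypeLabels
setMethod("cellTypeLabels", "SortedReference", function(x)
    factor(colData(x)$cell_type, levels = unique(colData(x)$cell_type)))

#' Per-sample ages
#'
#' @param x a [BetaSet] (or subclass) whose colData carries an \code{age}
#'   column, or \code{NULL}-yielding otherwise.
#' @return numeric vector of ages in years, or \code{NULL} when absent.
#' @export
setGeneric("sampleAges", function(x) standardGeneric("sampleAges"))

#' @rdname sampleAges
setMethod("sampleAges", "BetaSet", function(x) {
    cd <- colData(x)
    if ("age" %in% colnames(cd)) as.numeric(cd$age) else NULL
})

#' Cell types of a signature or proportion estimate
#'
#' @param x a [ReferenceSignature] or [CellProportions].
#' @return character vector of cell-type labels, in declared order.
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname cellTypes
setMethod("cellTypes", "ReferenceSignature", function(x) colnames(x@means))

#' @rdname cellTypes
setMethod("cellTypes", "CellProportions", function(x) colnames(x@proportions))

#' Signature accessors
#'
#' \code{signatureMeans()} returns the probes x cell-types mean-beta design
#' matrix, \code{signatureProbes()} its probe ids, and
#' \code{signatureMeta()} the per-probe selection record.
#'
#' @param x a [ReferenceSignature].
#' @return matrix, character vector, or data.frame respectively.
#' @export
setGeneric("signatureMeans", function(x) standardGeneric("signatureMeans"))

#' @rdname signatureMeans
setMethod("signatureMeans", "ReferenceSignature", function(x) x@means)

#' @rdname signatureMeans
#' @export
setGeneric("signatureProbes", function(x) standardGeneric("signatureProbes"))

#' @rdname signatureMeans
setMethod("signatureProbes", "ReferenceSignature", function(x) rownames(x@means))

#' @rdname signatureMeans
#' @export
setGeneric("signatureMeta", function(x) standardGeneric("signatureMeta"))

#' @rdname signatureMeans
setMethod("signatureMeta", "ReferenceSignature", function(x) x@meta)

#' Proportion accessors
#'
#' \code{proportions()} returns the raw constrained solution (samples x
#' cell types), \code{normalizedProportions()} the row-normalised copy,
#' \code{constraintMode()} the constraints applied, and
#' \code{residualNorms()} the per-sample fit residual norms.
#'
#' @param x a [CellProportions].
#' @return matrix, matrix, character, numeric respectively.
#' @export
setGeneric("proportions", function(x) standardGeneric("proportions"))

#' @rdname proportions
setMethod("proportions", "CellProportions", function(x) x@proportions)

#' @rdname proportions
#' @export
setGeneric("normalizedProportions",
    function(x) standardGeneric("normalizedProportions"))

#' @rdname proportions
setMethod("normalizedProportions", "CellProportions", function(x) x@normalized)

#' @rdname proportions
#' @export
setGeneric("constraintMode", function(x) standardGeneric("constraintMode"))

#' @rdname proportions
setMethod("constraintMode", "CellProportions", function(x) x@constraintMode)

#' @rdname proportions
#' @export
setGeneric("residualNorms", function(x) standardGeneric("residualNorms"))

#' @rdname proportions
setMethod("residualNorms", "CellProportions", function(x) x@residualNorms)

#' Probe-filter drop report
#'
#' @param x a [BetaSet] returned by [filterProbes()].
#' @return data.frame with one row per filter criterion and the number of
#'   probes dropped under it (first-match accounting), or \code{NULL}.
#' @export
setGeneric("filterReport", function(x) standardGeneric("filterReport"))

#' @rdname filterReport
setMethod("filterReport", "BetaSet", function(x) metadata(x)$filter_report)

setMethod("show", "ReferenceSignature", function(object) {
    cat(sprintf("ReferenceSignature: %d probes x %d cell types (%s)\n",
        nrow(object@means), ncol(object@means),
        paste(colnames(object@means), collapse = ", ")))
    tab <- table(object@meta$target_cell_type, object@meta$direction)
    print(tab)
    invisible(NULL)
})

setMethod("show", "CellProportions", function(object) {
    cat(sprintf("CellProportions: %d samples x %d cell types, mode '%s'\n",
        nrow(object@proportions), ncol(object@proportions),
        object@constraintMode))
    cat("column means (normalized):\n")
    print(round(colMeans(object@normalized), 3))
    invisible(NULL)
})

setMethod("show", "CetsProfiles", function(object) {
    cat(sprintf(
        "CetsProfiles: %d probes x %d individuals (pi in [%.2f, %.2f])%s\n",
        nrow(object@Y), ncol(object@Y),
        min(object@pi), max(object@pi),
        if (length(object@muN)) ", individual profiles known" else ""))
    invisible(NULL)
})
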