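#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData rowData<- colData<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Paired methylated/unmethylated intensity container
#'
#' A \linkS4class{SummarizedExperiment} carrying the two raw fluorescence
#' channels of a methylation array as assays \code{"M"} (methylated) and
#' \code{"U"} (unmethylated), probes as rows and samples as columns.
#' Intensities must be non-negative and complete; the readers in this
#' package enforce that at load time.
#'
#' @seealso [readChannelMatrix()], [computeBeta()], [quantileNormalize()]
#' @export
setClass("MethylChannels", contains = "SummarizedExperiment")

setValidity("MethylChannels", function(object) {
    msg <- character()
    if (!all(c("M", "U") %in% assayNames(object)))
        msg <- c(msg, "assays 'M' and 'U' are required")
    else {
        for (nm in c("M", "U")) {
            a <- assay(object, nm)
            if (anyNA(a))
                msg <- c(msg, sprintf("assay '%s' contains missing values", nm))
            else if (any(a < 0))
                msg <- c(msg, sprintf("assay '%s' contains negative intensities", nm))
        }
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "probe ids must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be unique")
    if (length(msg)) msg else TRUE
})

#' Beta-value (proportion methylation) container
#'
#' A \linkS4class{SummarizedExperiment} whose single assay \code{"beta"}
#' holds proportion-methylation values in \eqn{[0, 1]} (probes x samples).
#' Probe annotation lives in \code{rowData()}, the sample sheet in
#' \code{colData()}.
#'
#' @seealso [BetaSet()], [readBetaMatrix()], [alignDataset()]
#' @export
setClass("BetaSet", contains = "SummarizedExperiment")

setValidity("BetaSet", function(object) {
    msg <- character()
    if (!"beta" %in% assayNames(object))
        msg <- c(msg, "assay 'beta' is required")
    else {
        b <- assay(object, "beta")
        if (anyNA(b))
            msg <- c(msg, "beta values contain missing entries")
        else if (any(b < 0) || any(b > 1))
            msg <- c(msg, "beta values must lie in [0, 1]")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "probe ids must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be unique")
    if (length(msg)) msg else TRUE
})

#' Flow-sorted reference container
#'
#' A [BetaSet] of purified (flow-sorted) samples whose \code{colData()}
#' carries a \code{cell_type} label per sample and, optionally, an
#' \code{age} in years. At least two samples per cell type are required so
#' that within-type variances are estimable.
#'
#' @seealso [SortedReference()], [selectSignature()], [compositionAnova()]
#' @export
setClass("SortedReference", contains = "BetaSet")

setValidity("SortedReference", function(object) {
    msg <- character()
    cd <- colData(object)
    if (!"cell_type" %in% colnames(cd)) {
        msg <- c(msg, "colData must contain a 'cell_type' column")
    } else {
        tab <- table(cd$cell_type)
        if (any(tab < 2))
            msg <- c(msg, sprintf(
                "need >= 2 samples per cell type (short: %s)",
                paste(names(tab)[tab < 2], collapse = ", ")))
    }
    if ("age" %in% colnames(cd) && any(!is.na(cd$age) & cd$age < 0))
        msg <- c(msg, "ages must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Cell-type signature for constrained projection
#'
#' Holds the selected composition-discriminating probes and their mean beta
#' profile per cell type -- the design matrix of the proportion projection.
#' Per-probe selection metadata (target cell type, hyper/hypo direction,
#' t statistic and p value from the one-vs-rest test) is retained.
#'
#' @slot means numeric matrix, signature probes x cell types, beta scale.
#' @slot meta data.frame with columns \code{probe_id},
#'   \code{target_cell_type}, \code{direction}, \code{t}, \code{p}.
#' @seealso [selectSignature()], [projectProportions()], [writeSignature()]
#' @export
setClass("ReferenceSignature",
    representation(means = "matrix", meta = "data.frame"))

setValidity("ReferenceSignature", function(object) {
    msg <- character()
    m <- object@means
    if (is.null(rownames(m)) || is.null(colnames(m)))
        msg <- c(msg, "means must have probe rownames and cell-type colnames")
    else {
        if (anyDuplicated(rownames(m)))
            msg <- c(msg, "signature probe ids must be unique")
        if (anyNA(m) || any(m < 0) || any(m > 1))
            msg <- c(msg, "signature means must lie in [0, 1]")
    }
    meta <- object@meta
    need <- c("probe_id", "target_cell_type", "direction", "t", "p")
    if (!all(need %in% colnames(meta)))
        msg <- c(msg, sprintf("meta must have columns: %s",
                              paste(need, collapse = ", ")))
    else if (!identical(sort(meta$probe_id), sort(rownames(m))))
        msg <- c(msg, "meta probe_ids must match the rows of means")
    if (length(msg)) msg else TRUE
})

#' Estimated cell-type proportions
#'
#' Per-sample mixing weights from [projectProportions()]. In
#' \code{"nonneg"} mode the raw non-negative weights need not sum to one;
#' a post-hoc normalised copy is carried alongside and the constraint mode
#' is recorded. Residual norms of the least-squares fits are attached per
#' sample.
#'
#' @slot proportions numeric matrix, samples x cell types (raw solution).
#' @slot normalized numeric matrix, samples x cell types, rows summing to 1.
#' @slot constraintMode character, \code{"nonneg"} or \code{"simplex"}.
#' @slot residualNorms numeric, per-sample \eqn{\|y - Xw\|_2}.
#' @seealso [projectProportions()], [ageTrend()], [naiveAdjust()]
#' @export
setClass("CellProportions",
    representation(proportions = "matrix", normalized = "matrix",
                   constraintMode = "character", residualNorms = "numeric"))

setValidity("CellProportions", function(object) {
    msg <- character()
    p <- object@proportions
    if (any(p < -1e-12))
        msg <- c(msg, "proportions must be non-negative")
    if (!identical(dim(p), dim(object@normalized)))
        msg <- c(msg, "normalized copy must match proportions in shape")
    if (length(object@residualNorms) != nrow(p))
        msg <- c(msg, "one residual norm per sample is required")
    if (!object@constraintMode %in% c("nonneg", "simplex"))
        msg <- c(msg, "constraintMode must be 'nonneg' or 'simplex'")
    if (length(msg)) msg else TRUE
})

#' Two-cell-type mixed profiles for the CETS transform
#'
#' The generative quantities of the two-component (neuron/glia style)
#' mixture model \eqn{Y_i = \pi_i \mu_{i,N} + (1-\pi_i)\mu_{i,G} +
#' \epsilon_i}: observed mixed profiles, per-individual cell-type profiles,
#' the population-average profiles used by the transform, mixing fractions
#' and measurement error. Individual profiles and errors are optional for
#' applying the transform but required for the bias decomposition.
#'
#' @slot Y numeric matrix, probes x individuals, observed mixtures.
#' @slot muN,muG numeric matrices, per-individual cell-type profiles
#'   (0 x 0 when unknown).
#' @slot muBarN,muBarG numeric vectors, average cell-type profiles.
#' @slot pi numeric, per-individual first-component (neuron) fraction.
#' @slot eps numeric matrix, measurement error (0 x 0 when unknown).
#' @seealso [cetsTransform()], [cetsBias()], [simulateTwoCelltypeBrain()]
#' @export
setClass("CetsProfiles",
    representation(Y = "matrix", muN = "matrix", muG = "matrix",
                   muBarN = "numeric", muBarG = "numeric",
                   pi = "numeric", eps = "matrix"))

setValidity("CetsProfiles", function(object) {
    msg <- character()
    np <- nrow(object@Y); ni <- ncol(object@Y)
    if (length(object@pi) != ni)
        msg <- c(msg, "one mixing fraction per individual is required")
    if (any(object@pi < 0 | object@pi > 1))
        msg <- c(msg, "mixing fractions must lie in [0, 1]")
    if (length(object@muBarN) != np || length(object@muBarG) != np)
        msg <- c(msg, "average profiles must have one value per probe")
    for (nm in c("muN", "muG", "eps")) {
        m <- slot(object, nm)
        if (length(m) && !identical(dim(m), dim(object@Y)))
            msg <- c(msg, sprintf("'%s' must match the shape of Y", nm))
    }
    for (nm in c("muBarN", "muBarG")) {
        v <- slot(object, nm)
        if (any(v < 0 | v > 1))
            msg <- c(msg, sprintf("'%s' must lie in [0, 1]", nm))
    }
    if (length(msg)) msg else TRUE
})
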