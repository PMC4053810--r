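#' Across-array quantile normalization
#'
#' Forces every sample (column) to share the same marginal distribution:
#' the mean of the order statistics across columns, with ties resolved by
#' averaging the target quantile values across the tied ranks. Applied to
#' intensity data this is done within the M and U channels separately.
#'
#' @param x a numeric probes x samples matrix, or a [MethylChannels]
#'   object (each channel normalized independently).
#' @return object of the same class with normalized values.
#' @export
setGeneric("quantileNormalize", function(x) standardGeneric("quantileNormalize"))

#' @rdname quantileNormalize
#' @importFrom limma normalizeQuantiles
setMethod("quantileNormalize", "matrix", function(x) {
    if (anyNA(x)) stop("quantile normalization requires complete data")
    if (ncol(x) < 1L) stop("need at least one column")
    if (ncol(x) == 1L) return(x)
    out <- limma::normalizeQuantiles(x, ties = TRUE)
    dimnames(out) <- dimnames(x)
    out
})

#' @rdname quantileNormalize
setMethod("quantileNormalize", "MethylChannels", function(x) {
    M <- quantileNormalize(assay(x, "M"))
    U <- quantileNormalize(assay(x, "U"))
    se <- SummarizedExperiment(assays = list(M = M, U = U),
                               rowData = rowData(x), colData = colData(x))
    new("MethylChannels", se)
})

#' Compute beta values from intensity channels via the logit route
#'
#' Intensities are floored at `floor`, the logit-scale methylation value
#' \eqn{x = \log_2(M/U)} is computed, and mapped to the beta scale as
#' \eqn{\beta = 2^x / (1 + 2^x)} -- algebraically \eqn{M/(M+U)} on the
#' floored intensities. No \code{+100} stabilising offset is applied
#' anywhere: the logit route replaces the manufacturer formula
#' \eqn{M/(M+U+100)}.
#'
#' @param channels a [MethylChannels] object.
#' @param floor positive intensity floor applied to both channels before
#'   the log ratio (default 1), the minimal perturbation that keeps zero
#'   intensities finite on the logit scale.
#' @return a [BetaSet-class] with values in \eqn{(0, 1)}; row/column
#'   metadata are carried over.
#' @export
computeBeta <- function(channels, floor = 1) {
    stopifnot(is(channels, "MethylChannels"), floor > 0)
    M <- pmax(assay(channels, "M"), floor)
    U <- pmax(assay(channels, "U"), floor)
    x <- log2(M / U)
    beta <- 1 / (1 + 2^(-x))
    se <- SummarizedExperiment(assays = list(beta = beta),
                               rowData = rowData(channels),
                               colData = colData(channels))
    new("BetaSet", se)
}

.FILTER_CRITERIA <- c("sex_chromosomes", "snp_at_cpg", "snp_at_sbe",
                      "snp_in_probe")

#' Filter probes by annotation criteria
#'
#' Removes probes on the sex chromosomes and/or probes with annotated SNPs
#' at the CpG site, at the single-base-extension site, or in the probe
#' body. The drop report counts each probe once, under the first selected
#' criterion it matches, in the fixed order sex_chromosomes, snp_at_cpg,
#' snp_at_sbe, snp_in_probe. SNPs in the probe body are not filtered by
#' default.
#'
#' @param beta a [BetaSet].
#' @param annotation probe annotation data.frame; taken from
#'   \code{rowData(beta)} when `NULL`.
#' @param policy subset of
#'   \code{c("sex_chromosomes", "snp_at_cpg", "snp_at_sbe", "snp_in_probe")};
#'   empty policy is the identity.
#' @param strict error on probes absent from the annotation (default);
#'   otherwise drop them with a warning (reported as `unannotated`).
#' @return the filtered [BetaSet]; the per-criterion drop report is
#'   available via [filterReport()].
#' @export
filterProbes <- function(beta,
                         annotation = NULL,
                         policy = c("sex_chromosomes", "snp_at_cpg",
                                    "snp_at_sbe"),
                         strict = TRUE) {
    stopifnot(is(beta, "BetaSet"))
    if (length(policy)) policy <- match.arg(policy, .FILTER_CRITERIA,
                                            several.ok = TRUE)
    if (is.null(annotation)) {
        annotation <- as.data.frame(rowData(beta))
        if (!"probe_id" %in% colnames(annotation))
            annotation$probe_id <- rownames(beta)
    }
    probes <- rownames(beta)
    hit <- annotation[match(probes, annotation$probe_id), , drop = FALSE]
    unann <- is.na(hit$probe_id)
    if (any(unann)) {
        if (strict)
            stop("probe(s) absent from annotation: ",
                 .fewIds(probes[unann]))
        warning(sum(unann), " probe(s) absent from annotation dropped")
    }
    crit <- function(name) {
        v <- switch(name,
            sex_chromosomes = hit$chromosome %in% c("chrX", "chrY"),
            snp_at_cpg = hit$snp_at_cpg,
            snp_at_sbe = hit$snp_at_sbe,
            snp_in_probe = hit$snp_in_probe)
        if (is.null(v)) v <- rep(FALSE, length(probes))
        v & !is.na(v)
    }
    assigned <- rep(NA_character_, length(probes))
    for (name in .FILTER_CRITERIA[.FILTER_CRITERIA %in% policy]) {
        m <- crit(name) & is.na(assigned) & !unann
        assigned[m] <- name
    }
    assigned[unann] <- "unannotated"
    crits <- c(.FILTER_CRITERIA[.FILTER_CRITERIA %in% policy],
               if (any(unann) && !strict) "unannotated")
    report <- data.frame(
        criterion = crits,
        dropped = vapply(crits, function(k)
            sum(assigned == k, na.rm = TRUE), integer(1)),
        row.names = NULL)
    out <- beta[is.na(assigned), ]
    metadata(out)$filter_report <- report
    out
}
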