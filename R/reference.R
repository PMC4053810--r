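# Signature-probe selection from flow-sorted reference data: per-probe
# age screen, one-vs-rest t statistics per cell type, and selection of the
# most differentially methylated hyper/hypo probes per type.

#' Screen reference probes for age association
#'
#' Identifies probes whose methylation associates with donor age in the
#' sorted reference, so they can be excluded from signature selection
#' (cell-type profiles are assumed age-stable at signature probes). The
#' pooled screen regresses beta on age with cell type as an additive
#' covariate; the per-cell-type variant fits beta ~ age within each type
#' and flags a probe if any type reaches significance.
#'
#' @param ref a [SortedReference] with ages.
#' @param alpha significance level on the age term (default 0.05).
#' @param method `"pooled"` (default) or `"per_cell_type"`.
#' @return character vector of probe ids to exclude. Probes with constant
#'   beta are never flagged (their age p value is taken as 1).
#' @export
agePrefilter <- function(ref, alpha = 0.05,
                         method = c("pooled", "per_cell_type")) {
    stopifnot(is(ref, "SortedReference"))
    method <- match.arg(method)
    age <- sampleAges(ref)
    if (is.null(age) || anyNA(age))
        stop("ages are required for the age prefilter; ",
             "skip the filter when they are unavailable")
    Y <- betaValues(ref)
    ct <- cellTypeLabels(ref)
    if (method == "pooled") {
        X <- stats::model.matrix(~ age + ct)
        colnames(X)[2] <- "age"
        fit <- .rowwiseLm(Y, X)
        p <- fit$p["age", ]
    } else {
        p <- rep(1, nrow(Y))
        for (k in levels(ct)) {
            idx <- ct == k
            Xk <- cbind(`(Intercept)` = 1, age = age[idx])
            fitk <- .rowwiseLm(Y[, idx, drop = FALSE], Xk)
            p <- pmin(p, fitk$p["age", ])
        }
    }
    rownames(Y)[p <= alpha]
}

#' One-vs-rest t statistics per cell type
#'
#' For each cell type and probe, a two-sample t test of that type's
#' samples against all other samples pooled. Welch (unequal-variance) by
#' default; a pooled-variance variant is available. Probes with zero
#' variance in both groups and equal means are reported as t = 0, p = 1.
#'
#' @param ref a [SortedReference].
#' @param varEqual use the pooled-variance t test (default `FALSE`,
#'   i.e. Welch).
#' @return list of probes x cell-types matrices `t`, `p` and `effect`
#'   (difference of group means, target minus rest, on the beta scale).
#' @export
oneVsRestTstats <- function(ref, varEqual = FALSE) {
    stopifnot(is(ref, "SortedReference"))
    Y <- betaValues(ref)
    ct <- cellTypeLabels(ref)
    types <- levels(ct)
    t <- p <- eff <- matrix(NA_real_, nrow(Y), length(types),
                            dimnames = list(rownames(Y), types))
    for (k in types) {
        idx <- ct == k
        res <- .rowTtest(Y[, idx, drop = FALSE], Y[, !idx, drop = FALSE],
                         varEqual = varEqual)
        t[, k] <- res$t; p[, k] <- res$p; eff[, k] <- res$diff
    }
    list(t = t, p = p, effect = eff)
}

#' Mean beta profile per cell type
#'
#' The per-probe, per-cell-type mean across that type's reference samples
#' (equivalently the cell-type coefficients of a no-intercept linear model
#' on cell-type indicators).
#'
#' @param ref a [SortedReference].
#' @param probes optional probe ids to restrict to (order preserved).
#' @return numeric matrix, probes x cell types.
#' @export
estimateReferenceMeans <- function(ref, probes = NULL) {
    stopifnot(is(ref, "SortedReference"))
    Y <- betaValues(ref)
    if (!is.null(probes)) {
        missing <- setdiff(probes, rownames(Y))
        if (length(missing))
            stop("probes absent from reference: ", .fewIds(missing))
        Y <- Y[probes, , drop = FALSE]
    }
    ct <- cellTypeLabels(ref)
    vapply(levels(ct),
           function(k) rowMeans(Y[, ct == k, drop = FALSE]),
           numeric(nrow(Y)))
}

#' Select composition-discriminating signature probes
#'
#' Per cell type, among probes passing the one-vs-rest significance
#' threshold and not in the exclusion set, ranks candidates by effect size
#' (difference of group means on the beta scale by default, with `|t|` as
#' an option) and takes the top `nHyper` hypermethylated and `nHypo`
#' hypomethylated probes. The union across cell types is deduplicated
#' (first declared cell type keeps a twice-selected probe, with a warning)
#' and mean profiles are recomputed on the final probe set. Ties are broken
#' by larger `|t|`, then lexicographic probe id, so selection is invariant
#' to probe and sample order.
#'
#' With the defaults (p < 1e-8, 50 + 50 per type) a six-cell-type blood
#' reference yields the classic 600-probe signature.
#'
#' @param ref a [SortedReference].
#' @param pThreshold one-vs-rest p-value threshold (default `1e-8`).
#' @param nHyper,nHypo probes per direction per cell type (default 50).
#' @param exclude probe ids to exclude up front (e.g. from
#'   [agePrefilter()]).
#' @param rankBy `"effect"` (default) or `"t"`.
#' @param tstats optional precomputed [oneVsRestTstats()] result.
#' @param varEqual passed to [oneVsRestTstats()] when `tstats` is `NULL`.
#' @return a [ReferenceSignature-class]. When fewer than the requested
#'   probes pass the threshold for some type, all passing probes are taken
#'   and a warning reports the counts.
#' @export
selectSignature <- function(ref, pThreshold = 1e-8, nHyper = 50, nHypo = 50,
                            exclude = character(),
                            rankBy = c("effect", "t"),
                            tstats = NULL, varEqual = FALSE) {
    stopifnot(is(ref, "SortedReference"))
    rankBy <- match.arg(rankBy)
    if (is.null(tstats)) tstats <- oneVsRestTstats(ref, varEqual = varEqual)
    types <- colnames(tstats$t)
    probes <- rownames(tstats$t)
    excluded <- probes %in% exclude
    meta <- list()
    for (k in types) {
        pass <- tstats$p[, k] < pThreshold & !excluded
        for (dir in c("hyper", "hypo")) {
            want <- if (dir == "hyper") nHyper else nHypo
            sgn <- if (dir == "hyper") 1 else -1
            cand <- which(pass & sgn * tstats$effect[, k] > 0)
            if (!length(cand) && want > 0) {
                warning(sprintf(
                    "cell type %s: 0 of %d requested %smethylated probes pass p < %g",
                    k, want, dir, pThreshold))
                next
            }
            key <- if (rankBy == "effect") abs(tstats$effect[cand, k])
                   else abs(tstats$t[cand, k])
            ord <- cand[order(-key, -abs(tstats$t[cand, k]), probes[cand])]
            if (length(ord) < want)
                warning(sprintf(
                    "cell type %s: only %d of %d requested %smethylated probes pass p < %g",
                    k, length(ord), want, dir, pThreshold))
            take <- utils::head(ord, want)
            meta[[paste(k, dir)]] <- data.frame(
                probe_id = probes[take],
                target_cell_type = k,
                direction = dir,
                t = tstats$t[take, k],
                p = tstats$p[take, k],
                row.names = NULL)
        }
    }
    meta <- do.call(rbind, meta)
    if (is.null(meta) || !nrow(meta))
        stop("no probes passed the selection threshold for any cell type")
    dup <- duplicated(meta$probe_id)
    if (any(dup)) {
        warning(sum(dup), " probe(s) selected for more than one cell type; ",
                "kept once under the first declared type")
        meta <- meta[!dup, , drop = FALSE]
    }
    rownames(meta) <- NULL
    means <- estimateReferenceMeans(ref, meta$probe_id)
    new("ReferenceSignature", means = means, meta = meta)
}

#' Write / read a reference signature as TSV
#'
#' The serialized form is one row per signature probe: `probe_id`,
#' `target_cell_type`, `direction`, `t`, `p`, then one `<type>_mean`
#' column per cell type -- the package's distributable analog of a
#' flow-sorted reference table.
#'
#' @param sig a [ReferenceSignature].
#' @param path file path.
#' @param provenance optional leading comment lines.
#' @return the path ([writeSignature()]) or a rebuilt
#'   [ReferenceSignature-class] ([readSignature()]).
#' @export
writeSignature <- function(sig, path, provenance = NULL) {
    stopifnot(is(sig, "ReferenceSignature"))
    means <- sig@means[sig@meta$probe_id, , drop = FALSE]
    colnames(means) <- paste0(colnames(means), "_mean")
    df <- cbind(sig@meta, as.data.frame(means, check.names = FALSE))
    .writeTsv(df, path, provenance)
}

#' @rdname writeSignature
#' @export
readSignature <- function(path) {
    df <- .readDelim(path)
    meanCols <- grep("_mean$", colnames(df), value = TRUE)
    if (!length(meanCols)) stop("no '<type>_mean' columns in ", path)
    means <- as.matrix(df[, meanCols, drop = FALSE])
    rownames(means) <- df$probe_id
    colnames(means) <- sub("_mean$", "", meanCols)
    meta <- df[, c("probe_id", "target_cell_type", "direction", "t", "p")]
    new("ReferenceSignature", means = means, meta = meta)
}
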