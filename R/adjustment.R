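# Confounding-handling strategies for per-probe association with age (or
# any continuous trait): the univariate model, naive adjustment with
# composition estimates as covariates, and two-step RUV with signature
# probes as negative controls.

.covariateMatrix <- function(covariates, n) {
    if (is.null(covariates)) return(NULL)
    if (is.matrix(covariates)) {
        if (is.null(colnames(covariates)))
            colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
        return(covariates)
    }
    df <- as.data.frame(covariates)
    if (nrow(df) != n) stop("covariates must have one row per sample")
    mm <- stats::model.matrix(~ ., data = df)
    mm[, -1, drop = FALSE]
}

.ewasFit <- function(Y, age, covariates, method, fdr = 0.05) {
    X <- cbind(`(Intercept)` = 1, age = age)
    cm <- .covariateMatrix(covariates, ncol(Y))
    if (!is.null(cm)) X <- cbind(X, cm)
    fit <- .rowwiseLm(Y, X)
    p <- fit$p["age", ]
    q <- stats::p.adjust(p, method = "BH")
    t <- fit$t["age", ]
    thr <- if (any(q < fdr)) min(abs(t)[q < fdr]) else Inf
    res <- data.frame(probe_id = rownames(Y),
                      estimate = fit$coef["age", ],
                      t = t, p = p, fdr = q, method = method,
                      row.names = NULL)
    attr(res, "fdr_threshold_t") <- thr
    attr(res, "df") <- fit$df
    res
}

#' Per-probe association with age, univariate model
#'
#' Regresses beta on age (plus optional covariates such as processing
#' plate) at every probe, reporting the age coefficient (beta units per
#' year), its t statistic and p value, the Benjamini-Hochberg FDR, and the
#' `|t|` cutoff attaining FDR < 5% (attribute `fdr_threshold_t`; `Inf`
#' when nothing is significant).
#'
#' @param beta a [BetaSet] or probes x samples matrix.
#' @param age numeric, one age per sample.
#' @param covariates optional data.frame/matrix of additional covariates;
#'   factors are expanded to indicators. Perfectly collinear covariates
#'   raise an error naming the offending columns.
#' @param fdr FDR level for the threshold attribute (default 0.05).
#' @return data.frame with columns `probe_id`, `estimate`, `t`, `p`,
#'   `fdr`, `method`.
#' @export
univariateEwas <- function(beta, age, covariates = NULL, fdr = 0.05) {
    Y <- .asBetaMatrix(beta)
    if (length(age) != ncol(Y)) stop("one age per sample is required")
    .ewasFit(Y, age, covariates, "univariate", fdr)
}

#' Naive composition adjustment
#'
#' The univariate model with the estimated cell-type proportions added as
#' covariates. Because proportions live on the simplex, the last declared
#' cell-type column is dropped to avoid collinearity with the intercept
#' (the dropped column is recorded in the `dropped_cell_type` attribute).
#'
#' @inheritParams univariateEwas
#' @param props a [CellProportions] or samples x cell-types matrix.
#' @return as [univariateEwas()], method tag `"naive"`.
#' @export
naiveAdjust <- function(beta, age, props, covariates = NULL, fdr = 0.05) {
    Y <- .asBetaMatrix(beta)
    P <- if (is(props, "CellProportions")) normalizedProportions(props)
         else as.matrix(props)
    if (nrow(P) != ncol(Y))
        stop("proportions must have one row per sample")
    keep <- P[, -ncol(P), drop = FALSE]
    cm <- .covariateMatrix(covariates, ncol(Y))
    res <- .ewasFit(Y, age, cbind(cm, keep), "naive", fdr)
    attr(res, "dropped_cell_type") <- colnames(P)[ncol(P)]
    res
}

#' Two-step RUV adjustment with control probes
#'
#' Step one extracts the top `k` principal directions of variation among
#' negative-control probes (probes believed to respond to the confounder
#' -- cell composition -- but not to the outcome; the composition
#' signature probes are the natural choice). Step two includes the
#' per-sample scores of those directions as surrogate covariates in the
#' per-probe regression. With `k = 0` the result is identical to the
#' univariate model.
#'
#' @inheritParams univariateEwas
#' @param controlProbes character vector of control probe ids, a subset of
#'   the rows of `beta`.
#' @param k number of surrogate variables; must be smaller than the
#'   number of samples and at most the number of control probes. Use
#'   [ruvScree()] to choose.
#' @return as [univariateEwas()], method tag `"ruv2"`.
#' @export
ruv2Adjust <- function(beta, age, controlProbes, k, covariates = NULL,
                       fdr = 0.05) {
    Y <- .asBetaMatrix(beta)
    missing <- setdiff(controlProbes, rownames(Y))
    if (length(missing))
        stop("control probes absent from beta: ", .fewIds(missing))
    n <- ncol(Y)
    if (k >= n)
        stop("k (", k, ") must be smaller than the number of samples (",
             n, ")")
    if (k > length(controlProbes))
        stop("k (", k, ") exceeds the number of control probes (",
             length(controlProbes), ")")
    sur <- NULL
    if (k > 0) {
        C <- Y[controlProbes, , drop = FALSE]
        pc <- stats::prcomp(t(C), center = TRUE, scale. = FALSE)
        k <- min(k, sum(pc$sdev > 1e-12))
        sur <- pc$x[, seq_len(k), drop = FALSE]
        colnames(sur) <- paste0("ruv", seq_len(k))
    }
    cm <- .covariateMatrix(covariates, n)
    .ewasFit(Y, age, cbind(cm, sur), "ruv2", fdr)
}

#' Scree of control-probe variation
#'
#' Variance-explained fractions of the principal directions of the
#' control-probe submatrix, the diagnostic used to choose `k` for
#' [ruv2Adjust()].
#'
#' @inheritParams ruv2Adjust
#' @param maxK number of components to report (default 20, truncated to
#'   the rank).
#' @return data.frame with `component` and `var_explained`.
#' @export
ruvScree <- function(beta, controlProbes, maxK = 20) {
    Y <- .asBetaMatrix(beta)
    C <- Y[intersect(controlProbes, rownames(Y)), , drop = FALSE]
    pc <- stats::prcomp(t(C), center = TRUE, scale. = FALSE)
    ve <- pc$sdev^2 / sum(pc$sdev^2)
    kk <- seq_len(min(maxK, length(ve)))
    data.frame(component = kk, var_explained = ve[kk])
}
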