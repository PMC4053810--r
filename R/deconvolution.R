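# Constrained projection of whole-tissue beta profiles onto the reference
# signature. The contract is the optimisation problem: per sample y,
# minimise ||y - Xw||^2 subject to w >= 0 ("nonneg", the default) or
# additionally sum(w) = 1 ("simplex"). Non-negative least squares is solved
# exactly by the Lawson-Hanson active-set routine; the equality constraint
# is imposed through a heavily weighted augmentation row followed by exact
# renormalisation (see the methods vignette for the numerical argument).

#' Estimate cell-type proportions by constrained projection
#'
#' Restricts the target profiles to the signature probes (at least 80% of
#' the signature must be present, missing probes below that threshold are
#' dropped with a warning) and solves the constrained least-squares
#' problem per sample. In `"nonneg"` mode the raw weights are returned
#' together with a post-hoc normalised copy; in `"simplex"` mode the
#' weights themselves sum to one.
#'
#' @param target a [BetaSet] or probes x samples matrix of mixed-tissue
#'   beta values.
#' @param signature a [ReferenceSignature].
#' @param mode `"nonneg"` (default) or `"simplex"`.
#' @param minOverlap minimum fraction of signature probes that must be
#'   present in the target (default 0.8).
#' @return a [CellProportions-class] with per-sample residual norms.
#' @examples
#' cfg <- simConfig(seed = 7, nProbes = 400, nHyper = 10, nHypo = 10,
#'                  nMixtures = 5)
#' ref <- simulateReference(cfg)
#' sig <- selectSignature(ref$reference, nHyper = 10, nHypo = 10)
#' mix <- simulateMixtures(ref$truth$typeMeans, cfg)
#' projectProportions(mix$beta, sig)
#' @export
projectProportions <- function(target, signature,
                               mode = c("nonneg", "simplex"),
                               minOverlap = 0.8) {
    mode <- match.arg(mode)
    stopifnot(is(signature, "ReferenceSignature"))
    Y <- .asBetaMatrix(target)
    X <- signatureMeans(signature)
    present <- rownames(X) %in% rownames(Y)
    if (mean(present) < minOverlap)
        stop(sprintf(
            "only %.0f%% of signature probes present in target (need >= %.0f%%); missing: %s",
            100 * mean(present), 100 * minOverlap,
            .fewIds(rownames(X)[!present])))
    if (!all(present))
        warning(sum(!present), " signature probe(s) absent from target; ",
                "projection uses the remaining ", sum(present))
    X <- X[present, , drop = FALSE]
    Y <- Y[rownames(X), , drop = FALSE]
    K <- ncol(X)
    if (qr(X)$rank < K)
        stop("signature mean matrix is rank deficient; ",
             "cell-type profiles are not separable")
    n <- ncol(Y)
    W <- matrix(0, n, K, dimnames = list(colnames(Y), colnames(X)))
    rn <- numeric(n)
    lambda <- 1e3 * sqrt(nrow(X))        # equality-row weight, simplex mode
    Xa <- rbind(X, rep(lambda, K))
    for (i in seq_len(n)) {
        y <- Y[, i]
        w <- if (mode == "nonneg") pracma::lsqnonneg(X, y)$x
             else pracma::lsqnonneg(Xa, c(y, lambda))$x
        w[w < 0] <- 0                     # clamp active-set round-off
        if (mode == "simplex") {
            s <- sum(w)
            if (s > 0) w <- w / s
        }
        W[i, ] <- w
        rn[i] <- sqrt(sum((y - X %*% w)^2))
    }
    s <- rowSums(W)
    norm <- W / ifelse(s > 0, s, NA_real_)
    norm[is.na(norm)] <- 0
    new("CellProportions", proportions = W, normalized = norm,
        constraintMode = mode, residualNorms = rn)
}

#' Leave-one-out cross-validation of the composition pipeline
#'
#' Mirrors the in-sample validation design for sorted references: in each
#' fold one sample per cell type is held out, the signature is rebuilt on
#' the remaining samples only, and the held-out (purified) samples are
#' projected. For a sorted sample the true composition is the unit vector
#' on its own type, so the estimated own-type proportion measures
#' concordance.
#'
#' @param ref a [SortedReference] with at least 3 samples per cell type.
#' @param pThreshold,nHyper,nHypo,rankBy,varEqual signature-selection
#'   parameters, see [selectSignature()].
#' @param ageAlpha when non-`NULL` and ages are present, the age prefilter
#'   is rerun within each training fold at this level.
#' @param mode projection constraint mode, see [projectProportions()].
#' @return data.frame with one row per held-out sample: fold, sample id,
#'   true cell type, estimated own-type proportion, and the full vector of
#'   normalised proportion estimates.
#' @export
crossvalidateReference <- function(ref, pThreshold = 1e-8, nHyper = 50,
                                   nHypo = 50, rankBy = "effect",
                                   varEqual = FALSE, ageAlpha = NULL,
                                   mode = "nonneg") {
    stopifnot(is(ref, "SortedReference"))
    ct <- cellTypeLabels(ref)
    tab <- table(ct)
    if (any(tab < 3))
        stop("leave-one-out cross-validation needs >= 3 samples per cell ",
             "type (short: ", paste(names(tab)[tab < 3], collapse = ", "), ")")
    nFolds <- min(tab)
    Y <- betaValues(ref)
    age <- sampleAges(ref)
    withinIdx <- stats::ave(seq_along(ct), ct, FUN = seq_along)
    out <- vector("list", nFolds)
    for (f in seq_len(nFolds)) {
        held <- withinIdx == f
        train <- SortedReference(Y[, !held, drop = FALSE],
                                 cellType = as.character(ct[!held]),
                                 age = if (!is.null(age)) age[!held])
        exclude <- if (!is.null(ageAlpha) && !is.null(age))
            agePrefilter(train, alpha = ageAlpha) else character()
        sig <- selectSignature(train, pThreshold = pThreshold,
                               nHyper = nHyper, nHypo = nHypo,
                               exclude = exclude, rankBy = rankBy,
                               varEqual = varEqual)
        props <- projectProportions(Y[, held, drop = FALSE], sig,
                                    mode = mode)
        est <- normalizedProportions(props)
        own <- vapply(seq_len(nrow(est)), function(i) {
            k <- as.character(ct[held][i])
            if (k %in% colnames(est)) est[i, k] else NA_real_
        }, numeric(1))
        out[[f]] <- data.frame(
            fold = f,
            sample_id = colnames(Y)[held],
            cell_type = as.character(ct[held]),
            own_type_proportion = own,
            est, check.names = FALSE, row.names = NULL)
    }
    do.call(rbind, out)
}
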