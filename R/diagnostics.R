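# Composition-variability diagnostics: per-probe one-way ANOVA across cell
# types (the distributable composition table), variance partitioning
# between age and cell type, principal-component/composition correlation,
# per-cell-type age trends, and the composition filter.

#' Per-probe composition ANOVA table
#'
#' One-way ANOVA of beta across cell-type groups at every probe of a
#' sorted reference, with per-cell-type means and the beta range across
#' all samples. Columns follow the distributable composition-table
#' convention: `Name`, `Fstat`, `p.value`, one `<type>_mean` per cell
#' type, `DNAm_min`, `DNAm_max`, `DNAm_range`.
#'
#' @param ref a [SortedReference] (>= 2 samples per cell type).
#' @return data.frame, one row per probe. Probes with zero total variance
#'   are reported with F = 0 and p = 1.
#' @export
compositionAnova <- function(ref) {
    stopifnot(is(ref, "SortedReference"))
    Y <- betaValues(ref)
    ct <- cellTypeLabels(ref)
    types <- levels(ct)
    G <- length(types); n <- ncol(Y)
    grand <- rowMeans(Y)
    means <- estimateReferenceMeans(ref)
    nPer <- as.vector(table(ct)[types])
    ssb <- as.vector((means - grand)^2 %*% nPer)
    sst <- rowSums((Y - grand)^2)
    ssw <- pmax(sst - ssb, 0)
    F <- (ssb / (G - 1)) / (ssw / (n - G))
    p <- stats::pf(F, G - 1, n - G, lower.tail = FALSE)
    degen <- sst < 1e-20
    F[degen] <- 0; p[degen] <- 1
    exact <- !degen & ssw < 1e-20            # between-group signal, no noise
    F[exact] <- Inf; p[exact] <- 0
    colnames(means) <- paste0(types, "_mean")
    bmin <- apply(Y, 1, min); bmax <- apply(Y, 1, max)
    data.frame(Name = rownames(Y), Fstat = F, p.value = p,
               as.data.frame(means, check.names = FALSE),
               DNAm_min = bmin, DNAm_max = bmax,
               DNAm_range = bmax - bmin, row.names = NULL)
}

#' Partition per-probe variance between age and cell type
#'
#' Fits, at every probe, linear models with (i) age, (ii) cell type, and
#' (iii) age, cell type and their interaction, summarising each with the
#' (adjusted) coefficient of determination, plus per-cell-type age
#' p values.
#'
#' @param ref a [SortedReference] with ages.
#' @return data.frame with columns `probe_id`; `r2_age`, `r2_celltype`,
#'   `r2_full` and their `adj_` counterparts; and one `p_age_<type>`
#'   column per cell type. The interaction model is skipped (NA, with a
#'   warning) when its residual degrees of freedom are exhausted.
#' @export
variancePartition <- function(ref) {
    stopifnot(is(ref, "SortedReference"))
    age <- sampleAges(ref)
    if (is.null(age) || anyNA(age)) stop("ages are required")
    Y <- betaValues(ref)
    ct <- cellTypeLabels(ref)
    n <- ncol(Y)
    r2 <- function(X) {
        fit <- .rowwiseLm(Y, X)
        raw <- 1 - fit$rss / fit$tss
        raw[fit$tss < 1e-20] <- 0
        adj <- 1 - (1 - raw) * (n - 1) / (n - ncol(X))
        list(raw = raw, adj = adj)
    }
    m1 <- r2(stats::model.matrix(~ age))
    m2 <- r2(stats::model.matrix(~ ct))
    Xf <- stats::model.matrix(~ age * ct)
    if (n - ncol(Xf) < 1) {
        warning("interaction model skipped: no residual degrees of freedom")
        mf <- list(raw = rep(NA_real_, nrow(Y)), adj = rep(NA_real_, nrow(Y)))
    } else mf <- r2(Xf)
    out <- data.frame(probe_id = rownames(Y),
                      r2_age = m1$raw, adj_r2_age = m1$adj,
                      r2_celltype = m2$raw, adj_r2_celltype = m2$adj,
                      r2_full = mf$raw, adj_r2_full = mf$adj,
                      row.names = NULL)
    for (k in levels(ct)) {
        idx <- ct == k
        fitk <- .rowwiseLm(Y[, idx, drop = FALSE],
                           cbind(`(Intercept)` = 1, age = age[idx]))
        out[[paste0("p_age_", k)]] <- fitk$p["age", ]
    }
    out
}

#' Correlate global methylation PCs with composition
#'
#' Computes principal components of the beta matrix (samples as
#' observations, probes centred but not scaled) and the first principal
#' component of the proportion estimates, and reports their Pearson
#' correlations together with per-PC variance-explained fractions. A PC
#' sign is arbitrary, so the absolute correlation is reported alongside
#' the signed one.
#'
#' @param beta a [BetaSet] or probes x samples matrix.
#' @param props a [CellProportions] or samples x cell-types matrix over
#'   the same samples.
#' @param nPcs number of beta-matrix PCs to correlate (default 2).
#' @return data.frame with columns `pc`, `cor`, `abs_cor`,
#'   `var_explained`, `degenerate`. When the proportions are constant
#'   across samples the correlation is undefined and reported as 0 with
#'   `degenerate = TRUE`.
#' @export
pcCompositionCorrelation <- function(beta, props, nPcs = 2) {
    Y <- .asBetaMatrix(beta)
    P <- if (is(props, "CellProportions")) normalizedProportions(props)
         else as.matrix(props)
    if (ncol(Y) != nrow(P))
        stop("beta and proportions must cover the same samples")
    pc <- stats::prcomp(t(Y), center = TRUE, scale. = FALSE)
    varExpl <- pc$sdev^2 / sum(pc$sdev^2)
    rank <- sum(pc$sdev > 1e-12)
    if (nPcs > rank) {
        warning("requested ", nPcs, " PCs but rank is ", rank,
                "; truncating")
        nPcs <- rank
    }
    degenerate <- all(apply(P, 2, stats::sd) < 1e-12)
    if (degenerate) {
        propPc1 <- rep(0, nrow(P))
    } else {
        propPc1 <- stats::prcomp(P, center = TRUE, scale. = FALSE)$x[, 1]
        if (stats::sd(propPc1) < 1e-12) degenerate <- TRUE
    }
    cors <- vapply(seq_len(nPcs), function(i) {
        if (degenerate) 0 else stats::cor(pc$x[, i], propPc1)
    }, numeric(1))
    data.frame(pc = seq_len(nPcs), cor = cors, abs_cor = abs(cors),
               var_explained = varExpl[seq_len(nPcs)],
               degenerate = degenerate, row.names = NULL)
}

#' Per-cell-type age trends of estimated proportions
#'
#' Spearman correlation (asymptotic p by default; exact for small n on
#' request) of each cell type's estimated proportion with age, plus a
#' loess-smoothed trend curve.
#'
#' @param props a [CellProportions] or samples x cell-types matrix.
#' @param ages numeric ages in years, one per sample.
#' @param span,degree loess parameters (defaults 0.75, 2).
#' @param exact logical passed to [stats::cor.test()]; default uses the
#'   asymptotic approximation.
#' @return list with `stats` (cell_type, rho, p) and `curves`
#'   (cell_type, age, fit) data.frames.
#' @export
ageTrend <- function(props, ages, span = 0.75, degree = 2, exact = FALSE) {
    P <- if (is(props, "CellProportions")) normalizedProportions(props)
         else as.matrix(props)
    if (length(ages) != nrow(P))
        stop("one age per sample is required")
    if (nrow(P) < 3) stop("age trends need at least 3 samples")
    grid <- seq(min(ages), max(ages), length.out = 101)
    stats_ <- curves <- list()
    for (k in colnames(P)) {
        ctest <- suppressWarnings(
            stats::cor.test(P[, k], ages, method = "spearman",
                            exact = exact))
        stats_[[k]] <- data.frame(cell_type = k,
                                  rho = unname(ctest$estimate),
                                  p = ctest$p.value)
        fit <- tryCatch(
            stats::predict(stats::loess(P[, k] ~ ages, span = span,
                                        degree = degree), newdata = grid),
            error = function(e) rep(NA_real_, length(grid)))
        curves[[k]] <- data.frame(cell_type = k, age = grid, fit = fit)
    }
    list(stats = do.call(rbind, c(stats_, list(make.row.names = FALSE))),
         curves = do.call(rbind, c(curves, list(make.row.names = FALSE))))
}

#' Filter candidate probes by composition association
#'
#' Removes probes strongly associated with cell composition: those
#' meeting BOTH the ANOVA p-value criterion and the beta-range criterion
#' (p < `pCut` AND range > `rangeCut`; defaults 1e-4 and 10%). Raising
#' `pCut` or lowering `rangeCut` can only remove more probes, never fewer.
#'
#' @param probes character vector of candidate probe ids.
#' @param stats a [compositionAnova()] table covering them.
#' @param pCut,rangeCut thresholds (defaults `1e-4`, `0.10`).
#' @param strict error on probes absent from `stats` (default); otherwise
#'   pass them through with a warning.
#' @return list with `retained`, `removed` and a one-row `report`
#'   (n_query, n_removed, n_missing).
#' @export
compositionFilter <- function(probes, stats, pCut = 1e-4, rangeCut = 0.10,
                              strict = TRUE) {
    idx <- match(probes, stats$Name)
    missing <- is.na(idx)
    if (any(missing)) {
        if (strict)
            stop("probe(s) absent from composition stats: ",
                 .fewIds(probes[missing]))
        warning(sum(missing), " probe(s) absent from composition stats ",
                "passed through unfiltered")
    }
    hit <- !missing &
        stats$p.value[idx] < pCut &
        stats$DNAm_range[idx] > rangeCut
    list(retained = probes[!hit],
         removed = probes[hit],
         report = data.frame(n_query = length(probes),
                             n_removed = sum(hit),
                             n_missing = sum(missing)))
}
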