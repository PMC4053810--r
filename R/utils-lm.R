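# Internal vectorised least-squares machinery. All per-probe models in the
# package share one design matrix across probes, so a single QR factorisation
# serves every probe; stats::lm is kept for the test oracles only.

.rowVars <- function(x) {
    n <- ncol(x)
    if (n < 2) return(rep(NA_real_, nrow(x)))
    m <- rowMeans(x)
    rowSums((x - m)^2) / (n - 1)
}

# Fit y ~ X for every row of Y (probes x samples) at once.
# Returns coefficients, per-coefficient t and p, residual/total SS.
# Degenerate probes (zero residual variance) get t = 0, p = 1 when the
# coefficient is also zero, and |t| = Inf, p = 0 otherwise.
.rowwiseLm <- function(Y, X) {
    if (is.null(colnames(X)))
        colnames(X) <- paste0("x", seq_len(ncol(X)))
    n <- ncol(Y); p <- ncol(X)
    if (n != nrow(X))
        stop("design has ", nrow(X), " rows but data has ", n, " samples")
    if (n <= p)
        stop("not enough samples (", n, ") for ", p, " design columns")
    qrX <- qr(X)
    if (qrX$rank < p) {
        bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, p)]]
        stop("collinear design columns: ", paste(bad, collapse = ", "))
    }
    B <- qr.coef(qrX, t(Y))                       # p x nprobes
    res <- t(Y) - X %*% B
    df <- n - p
    rss <- colSums(res^2)
    sigma2 <- rss / df
    xtxinv <- chol2inv(chol(crossprod(X)))
    tstat <- B / sqrt(outer(diag(xtxinv), sigma2))
    zero <- sigma2 < 1e-20
    if (any(zero)) {
        bz <- B[, zero, drop = FALSE]
        tz <- ifelse(abs(bz) < 1e-12, 0, sign(bz) * Inf)
        tstat[, zero] <- tz
    }
    pval <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
    tss <- rowSums((Y - rowMeans(Y))^2)
    list(coef = B, t = tstat, p = pval, df = df,
         rss = rss, tss = tss, sigma2 = sigma2)
}

# Two-sample t statistics for every row: group1 vs group2 matrices.
# Welch by default; pooled variance optionally. Zero-variance rows follow
# the same degenerate convention as .rowwiseLm.
.rowTtest <- function(X1, X2, varEqual = FALSE) {
    n1 <- ncol(X1); n2 <- ncol(X2)
    m1 <- rowMeans(X1); m2 <- rowMeans(X2)
    v1 <- .rowVars(X1); v2 <- .rowVars(X2)
    if (varEqual) {
        vp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
        se2 <- vp * (1 / n1 + 1 / n2)
        df <- rep(n1 + n2 - 2, length(m1))
    } else {
        a <- v1 / n1; b <- v2 / n2
        se2 <- a + b
        df <- se2^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
    }
    diff <- m1 - m2
    tstat <- diff / sqrt(se2)
    zero <- se2 < 1e-24
    if (any(zero)) {
        tstat[zero] <- ifelse(abs(diff[zero]) < 1e-12, 0,
                              sign(diff[zero]) * Inf)
        df[zero] <- n1 + n2 - 2
    }
    p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
    list(t = tstat, p = p, df = df, mean1 = m1, mean2 = m2, diff = diff)
}

.asBetaMatrix <- function(x) {
    if (is(x, "BetaSet")) return(assay(x, "beta"))
    if (is.matrix(x)) {
        if (is.null(rownames(x)))
            stop("beta matrix must carry probe rownames")
        return(x)
    }
    stop("expected a BetaSet or a probes x samples matrix")
}

.truncateBeta <- function(x, lo = 0.01, hi = 0.99) pmin(pmax(x, lo), hi)
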