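suppressPackageStartupMessages(library(SummarizedExperiment))

# Small hand-built fixtures shared across test files. Everything is
# constructed in code; tiny matrices are written to tempfiles where a
# reader is under test.

# A deterministic 6-type sorted reference with planted markers, built by
# hand (not via the synthetic module) so reference-builder tests do not
# depend on the generator they help validate.
tinySortedReference <- function(nPerType = 3, noiseSd = 0, seed = 42,
                                types = c("A", "B", "C")) {
    set.seed(seed)
    nTypes <- length(types)
    # 2 markers per type (one hyper, one hypo) + 4 background probes
    nProbes <- 2 * nTypes + 4
    probes <- sprintf("p%02d", seq_len(nProbes))
    means <- matrix(0.5, nProbes, nTypes, dimnames = list(probes, types))
    for (k in seq_len(nTypes)) {
        means[2 * k - 1, ] <- 0.2; means[2 * k - 1, k] <- 0.8  # hyper
        means[2 * k, ] <- 0.8;     means[2 * k, k] <- 0.2      # hypo
    }
    beta <- means[, rep(seq_len(nTypes), each = nPerType)]
    if (noiseSd > 0)
        beta <- beta + matrix(rnorm(length(beta), sd = noiseSd),
                              nrow(beta))
    beta <- pmin(pmax(beta, 0), 1)
    colnames(beta) <- paste0(rep(types, each = nPerType), "_",
                             seq_len(nPerType))
    SortedReference(beta, cellType = rep(types, each = nPerType),
                    age = rep(seq(20, 60, length.out = nPerType), nTypes))
}

writeTempMatrix <- function(m, sep = "\t", idName = "probe_id") {
    path <- tempfile(fileext = if (sep == ",") ".csv" else ".tsv")
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    colnames(df)[1] <- idName
    write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
    path
}

# Manual BH step-up at level alpha: reject the largest j with
# p_(j) <= j * alpha / m. Independent oracle for FDR bookkeeping.
bhRejectOracle <- function(p, alpha = 0.05) {
    m <- length(p)
    o <- order(p)
    ok <- which(p[o] <= seq_len(m) * alpha / m)
    rejected <- logical(m)
    if (length(ok)) rejected[o[seq_len(max(ok))]] <- TRUE
    rejected
}
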