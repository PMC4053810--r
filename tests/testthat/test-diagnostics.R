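test_that("composition ANOVA matches the stats::aov oracle", {
    set.seed(30)
    ref <- tinySortedReference(nPerType = 6, noiseSd = 0.05, seed = 30,
                               types = c("A", "B", "C", "D", "E", "F"))
    tab <- compositionAnova(ref)
    b <- betaValues(ref)
    ct <- cellTypeLabels(ref)
    for (pr in sample(rownames(b), 6)) {
        oracle <- summary(aov(b[pr, ] ~ ct))[[1]]
        i <- match(pr, tab$Name)
        expect_equal(tab$Fstat[i], oracle[["F value"]][1],
                     tolerance = 1e-10)
        expect_equal(tab$p.value[i], oracle[["Pr(>F)"]][1],
                     tolerance = 1e-10)
    }
    # group means, range bookkeeping
    expect_equal(tab$A_mean, unname(rowMeans(b[, ct == "A"])),
                 tolerance = 1e-12)
    expect_equal(tab$DNAm_range, unname(apply(b, 1, max) - apply(b, 1, min)),
                 tolerance = 1e-12)
    # a planted discriminating probe is overwhelming
    expect_lt(tab$p.value[tab$Name == "p01"], 1e-8)
})

test_that("composition ANOVA handles degenerate probes", {
    b <- matrix(0.4, 3, 12,
                dimnames = list(paste0("p", 1:3),
                                paste0("s", 1:12)))
    set.seed(31)
    b[2, ] <- runif(12)
    b[3, ] <- rep(c(0.2, 0.8), each = 6)   # pure between-group signal
    ref <- SortedReference(b, cellType = rep(c("A", "B"), each = 6))
    tab <- compositionAnova(ref)
    expect_equal(tab$Fstat[1], 0)
    expect_equal(tab$p.value[1], 1)
    expect_equal(tab$Fstat[3], Inf)
    expect_equal(tab$p.value[3], 0)
})

test_that("variance partitioning separates age-driven from type-driven probes", {
    set.seed(32)
    types <- c("A", "B", "C"); nPer <- 8
    n <- length(types) * nPer
    age <- rep(seq(20, 60, length.out = nPer), length(types))
    ct <- rep(types, each = nPer)
    b <- rbind(
        typeProbe = c(A = 0.2, B = 0.5, C = 0.8)[ct] + rnorm(n, sd = 0.01),
        ageProbe = 0.3 + 0.005 * age + rnorm(n, sd = 0.01),
        bothProbe = c(A = 0.1, B = 0.3, C = 0.5)[ct] + 0.004 * age +
            rnorm(n, sd = 0.01))
    b <- pmin(pmax(b, 0), 1)
    colnames(b) <- paste0("s", seq_len(n))
    ref <- SortedReference(b, cellType = ct, age = age)
    vp <- variancePartition(ref)

    expect_gt(vp$adj_r2_celltype[1], 0.9)
    expect_gt(vp$adj_r2_celltype[1], vp$adj_r2_age[1] + 0.5)
    expect_gt(vp$adj_r2_age[2], 0.9)
    expect_gt(vp$adj_r2_age[2], vp$adj_r2_celltype[2] + 0.5)
    # nested models: unadjusted R2 of the full model dominates both
    expect_true(all(vp$r2_full >= pmax(vp$r2_age, vp$r2_celltype) - 1e-12))
    # adjusted R2 agrees with the stats::lm oracle
    fit <- summary(lm(b[3, ] ~ age * factor(ct)))
    expect_equal(vp$adj_r2_full[3], fit$adj.r.squared, tolerance = 1e-10)
    # per-type age p values track the generative design
    expect_lt(vp$p_age_A[2], 1e-4)
})

test_that("beta-matrix PCs correlate with composition when mixtures drive variance", {
    set.seed(33)
    nProbes <- 200
    profA <- runif(nProbes, 0.05, 0.95)
    profB <- runif(nProbes, 0.05, 0.95)
    w <- seq(0.1, 0.9, length.out = 25)
    Y <- outer(profA, w) + outer(profB, 1 - w)
    dimnames(Y) <- list(sprintf("p%03d", 1:nProbes), sprintf("s%02d", 1:25))
    P <- cbind(A = w, B = 1 - w)
    got <- pcCompositionCorrelation(Y, P, nPcs = 2)
    expect_gt(got$abs_cor[1], 0.99)
    expect_false(got$degenerate[1])
    # variance-explained fractions are a decreasing sub-probability vector
    expect_true(all(diff(got$var_explained) <= 1e-12))
    expect_lte(sum(got$var_explained), 1 + 1e-12)

    # constant proportions are degenerate: correlation reported as 0
    Pconst <- cbind(A = rep(0.5, 25), B = rep(0.5, 25))
    Yn <- Y + matrix(rnorm(length(Y), sd = 0.01), nrow(Y))
    gotC <- pcCompositionCorrelation(pmin(pmax(Yn, 0), 1), Pconst)
    expect_true(all(gotC$degenerate))
    expect_equal(gotC$cor, c(0, 0))
})

test_that("age trends report Spearman rho with loess curves", {
    set.seed(34)
    n <- 40
    age <- runif(n, 5, 75)
    P <- cbind(up = plogis((age - 40) / 10),
               flat = 0.5 + rnorm(n, sd = 0.05))
    tr <- ageTrend(P, age)
    expect_equal(tr$stats$rho[tr$stats$cell_type == "up"], 1)
    expect_lt(abs(tr$stats$rho[tr$stats$cell_type == "flat"]), 0.5)
    expect_equal(nrow(tr$curves), 2 * 101)
    # monotone trend yields an increasing smoothed curve overall
    up <- tr$curves[tr$curves$cell_type == "up", ]
    expect_gt(up$fit[101], up$fit[1])
    expect_error(ageTrend(P[1:2, ], age[1:2]), "3 samples")
})

test_that("the composition filter applies the conjunctive rule", {
    stats <- data.frame(
        Name = c("a", "b", "c"),
        p.value = c(1e-6, 1e-6, 0.5),
        DNAm_range = c(0.25, 0.05, 0.25))
    got <- compositionFilter(c("a", "b", "c"), stats)
    expect_identical(got$removed, "a")          # both criteria met
    expect_identical(got$retained, c("b", "c")) # one criterion each
    expect_equal(got$report$n_removed, 1L)

    # missing probe: strict errors, lenient passes through
    expect_error(compositionFilter(c("a", "zzz"), stats), "zzz")
    expect_warning(len <- compositionFilter(c("a", "zzz"), stats,
                                            strict = FALSE),
                   "passed through")
    expect_true("zzz" %in% len$retained)
})

test_that("the composition filter is monotone in its thresholds", {
    set.seed(35)
    stats <- data.frame(Name = sprintf("p%03d", 1:200),
                        p.value = runif(200)^3,
                        DNAm_range = runif(200))
    probes <- stats$Name
    base <- compositionFilter(probes, stats)$retained
    # more permissive thresholds retain a superset
    lowerP <- compositionFilter(probes, stats, pCut = 1e-6)$retained
    higherR <- compositionFilter(probes, stats, rangeCut = 0.5)$retained
    expect_true(all(base %in% lowerP))
    expect_true(all(base %in% higherR))
    # more aggressive thresholds retain a subset
    aggressive <- compositionFilter(probes, stats, pCut = 0.05,
                                    rangeCut = 0.01)$retained
    expect_true(all(aggressive %in% base))
})
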