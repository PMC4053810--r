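test_that("age prefilter flags age-driven probes and spares constant ones", {
    ref <- tinySortedReference(nPerType = 4, noiseSd = 0)
    b <- betaValues(ref)
    age <- sampleAges(ref)
    # plant one noiseless age probe and one constant probe
    b["p07", ] <- 0.2 + 0.005 * age
    b["p08", ] <- 0.5
    ref2 <- SortedReference(b, cellType = as.character(cellTypeLabels(ref)),
                            age = age)
    ex <- agePrefilter(ref2, alpha = 0.05)
    expect_true("p07" %in% ex)
    expect_false("p08" %in% ex)

    noAge <- SortedReference(b, cellType = as.character(cellTypeLabels(ref)))
    expect_error(agePrefilter(noAge), "skip")
})

test_that("age prefilter type-I rate is near alpha on null probes", {
    set.seed(100)
    nProbes <- 4000; nPerType <- 6; types <- c("A", "B", "C")
    age <- rep(seq(20, 60, length.out = nPerType), length(types))
    b <- matrix(plogis(rnorm(nProbes * nPerType * length(types), sd = 0.1)),
                nProbes)
    rownames(b) <- sprintf("p%04d", seq_len(nProbes))
    colnames(b) <- paste0(rep(types, each = nPerType), seq_len(nPerType))
    ref <- SortedReference(b, cellType = rep(types, each = nPerType),
                           age = age)
    rate <- length(agePrefilter(ref, alpha = 0.05)) / nProbes
    expect_gt(rate, 0.035)
    expect_lt(rate, 0.065)
})

test_that("one-vs-rest t statistics match stats::t.test and are antisymmetric", {
    set.seed(101)
    ref <- tinySortedReference(nPerType = 4, noiseSd = 0.02, seed = 101)
    got <- oneVsRestTstats(ref)
    b <- betaValues(ref)
    ct <- cellTypeLabels(ref)
    for (k in levels(ct)) {
        for (pr in sample(rownames(b), 4)) {
            oracle <- t.test(b[pr, ct == k], b[pr, ct != k],
                             var.equal = FALSE)
            expect_equal(got$t[pr, k], unname(oracle$statistic),
                         tolerance = 1e-10)
            expect_equal(got$p[pr, k], oracle$p.value, tolerance = 1e-10)
        }
    }
    # pooled-variance option against its oracle
    gotP <- oneVsRestTstats(ref, varEqual = TRUE)
    oracleP <- t.test(b[1, ct == "A"], b[1, ct != "A"], var.equal = TRUE)
    expect_equal(gotP$t[1, "A"], unname(oracleP$statistic),
                 tolerance = 1e-10)

    # swapping the two groups negates t (2-type case)
    ref2 <- tinySortedReference(nPerType = 3, noiseSd = 0.02, seed = 7,
                                types = c("A", "B"))
    two <- oneVsRestTstats(ref2)
    expect_equal(two$t[, "A"], -two$t[, "B"], tolerance = 1e-10)

    # a strongly discriminating probe is detected
    expect_lt(got$p["p01", "A"], 1e-8)   # planted hyper marker for A
    # identical means -> t ~ 0: constant probe
    bc <- b; bc["p10", ] <- 0.5
    refc <- SortedReference(bc, cellType = as.character(ct),
                            age = sampleAges(ref))
    gc <- oneVsRestTstats(refc)
    expect_equal(unname(gc$t["p10", ]), rep(0, 3))
    expect_equal(unname(gc$p["p10", ]), rep(1, 3))
})

test_that("reference means equal group means and the ANOVA oracle", {
    ref <- tinySortedReference(nPerType = 3, noiseSd = 0.05, seed = 103)
    m <- estimateReferenceMeans(ref)
    b <- betaValues(ref)
    ct <- cellTypeLabels(ref)
    for (k in levels(ct))
        expect_equal(m[, k], rowMeans(b[, ct == k]), tolerance = 1e-12)
    # equals the cell-type coefficients of a no-intercept linear model
    fit <- lm(b[1, ] ~ 0 + ct)
    expect_equal(unname(m[1, ]), unname(coef(fit)), tolerance = 1e-10)
    # probe subset and order respected
    sub <- estimateReferenceMeans(ref, probes = c("p05", "p02"))
    expect_identical(rownames(sub), c("p05", "p02"))
    expect_error(estimateReferenceMeans(ref, probes = "nope"), "absent")
})

test_that("signature selection recovers planted markers and honors exclusions", {
    cfg <- simConfig(seed = 51, nProbes = 1500, nHyper = 10, nHypo = 10)
    sim <- simulateReference(cfg)
    sig <- selectSignature(sim$reference, nHyper = 10, nHypo = 10)
    expect_s4_class(sig, "ReferenceSignature")
    expect_length(signatureProbes(sig), 6 * 20)
    truth <- sim$truth$markers
    recovered <- mean(truth$probe_id %in% signatureProbes(sig))
    expect_gte(recovered, 0.95)
    # direction bookkeeping matches the planted design
    meta <- signatureMeta(sig)
    merged <- merge(meta, truth, by = "probe_id")
    expect_true(all(merged$direction.x == merged$direction.y))

    # excluded probe with the largest effect is absent
    drop <- truth$probe_id[1]
    sig2 <- selectSignature(sim$reference, nHyper = 10, nHypo = 10,
                            exclude = drop)
    expect_false(drop %in% signatureProbes(sig2))

    # fewer passing than requested -> all passing, with a warning
    expect_warning(
        sigW <- selectSignature(sim$reference, nHyper = 200, nHypo = 200),
        "of 200")
    expect_lt(length(signatureProbes(sigW)), 6 * 400)
})

test_that("signature selection is invariant to probe and sample order", {
    cfg <- simConfig(seed = 52, nProbes = 800, nHyper = 5, nHypo = 5,
                     cellTypes = c("X", "Y", "Z"))
    sim <- simulateReference(cfg)
    ref <- sim$reference
    sig <- selectSignature(ref, nHyper = 5, nHypo = 5)

    set.seed(1)
    pperm <- sample(nrow(ref)); sperm <- sample(ncol(ref))
    b <- betaValues(ref)[pperm, sperm]
    refPerm <- SortedReference(
        b, cellType = as.character(cellTypeLabels(ref))[sperm],
        age = sampleAges(ref)[sperm])
    sigPerm <- selectSignature(refPerm, nHyper = 5, nHypo = 5)
    expect_setequal(signatureProbes(sigPerm), signatureProbes(sig))
    expect_equal(
        signatureMeans(sigPerm)[signatureProbes(sig), cellTypes(sig)],
        signatureMeans(sig), tolerance = 1e-12)
})

test_that("signatures serialize to TSV and back", {
    cfg <- simConfig(seed = 53, nProbes = 600, nHyper = 5, nHypo = 5,
                     cellTypes = c("N", "G"))
    sig <- selectSignature(simulateReference(cfg)$reference,
                           nHyper = 5, nHypo = 5)
    path <- tempfile(fileext = ".tsv")
    writeSignature(sig, path, provenance = "unit test")
    back <- readSignature(path)
    expect_equal(signatureMeans(back), signatureMeans(sig),
                 tolerance = 1e-10)
    expect_equal(signatureMeta(back)$probe_id, signatureMeta(sig)$probe_id)
})
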