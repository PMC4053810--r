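test_that("univariate EWAS recovers exact slopes and flags collinearity", {
    set.seed(40)
    n <- 30
    age <- seq(20, 78, length.out = n)
    b <- rbind(p1 = 0.2 + 0.001 * age,                  # noiseless slope
               p2 = 0.5 + rnorm(n, sd = 0.01))
    colnames(b) <- paste0("s", 1:n)
    res <- univariateEwas(b, age)
    expect_equal(res$estimate[1], 0.001, tolerance = 1e-12)
    expect_equal(res$p[1], 0)
    expect_identical(unique(res$method), "univariate")

    # t and p agree with the stats::lm oracle
    fit <- summary(lm(b[2, ] ~ age))
    expect_equal(res$t[2], fit$coefficients["age", "t value"],
                 tolerance = 1e-10)
    expect_equal(res$p[2], fit$coefficients["age", "Pr(>|t|)"],
                 tolerance = 1e-10)

    # plate perfectly confounded with age -> collinearity error naming it
    plate <- factor(ifelse(age < 50, "P1", "P2"))
    ageStep <- as.numeric(plate == "P2")
    expect_error(univariateEwas(b, ageStep,
                                covariates = data.frame(plate = plate)),
                 "collinear.*plate")
})

test_that("permuted ages give a calibrated null", {
    set.seed(41)
    n <- 50; nProbes <- 2000
    age <- runif(n, 10, 80)
    b <- matrix(plogis(rnorm(n * nProbes, sd = 0.2)), nProbes,
                dimnames = list(sprintf("p%04d", 1:nProbes),
                                paste0("s", 1:n)))
    res <- univariateEwas(b, sample(age))
    rate <- mean(res$p < 0.05)
    expect_gt(rate, 0.035); expect_lt(rate, 0.065)
    expect_equal(sum(res$fdr < 0.05), 0)
    expect_identical(attr(res, "fdr_threshold_t"), Inf)
})

test_that("BH bookkeeping matches a brute-force step-up oracle", {
    set.seed(42)
    for (i in 1:3) {
        p <- c(runif(60)^(i + 1), runif(40))
        q <- p.adjust(p, "BH")           # the package's fdr column route
        expect_identical(q < 0.05, bhRejectOracle(p, 0.05))
    }
    # the |t| threshold is the smallest significant |t|
    n <- 40; age <- seq(1, 80, length.out = n)
    set.seed(43)
    b <- matrix(plogis(outer(rnorm(300, sd = 0.002), age) +
                       rnorm(300 * n, sd = 0.05)), 300,
                dimnames = list(sprintf("p%03d", 1:300), paste0("s", 1:n)))
    res <- univariateEwas(b, age)
    sig <- res$fdr < 0.05
    if (any(sig)) {
        thr <- attr(res, "fdr_threshold_t")
        expect_equal(thr, min(abs(res$t)[sig]))
        expect_true(all(abs(res$t)[sig] >= thr))
    }
})

test_that("naive adjustment reduces composition-mediated signal", {
    # age acts on bulk beta only through composition
    set.seed(44)
    n <- 80; nProbes <- 300
    age <- runif(n, 5, 75)
    w <- plogis((age - 40) / 10)          # rising component fraction
    profA <- runif(nProbes, 0.1, 0.9)
    profB <- pmin(pmax(profA + rnorm(nProbes, sd = 0.2), 0.02), 0.98)
    b <- outer(profA, w) + outer(profB, 1 - w) +
        matrix(rnorm(nProbes * n, sd = 0.01), nProbes)
    b <- pmin(pmax(b, 0), 1)
    dimnames(b) <- list(sprintf("p%03d", 1:nProbes), paste0("s", 1:n))
    P <- cbind(A = w, B = 1 - w)

    uni <- univariateEwas(b, age)
    nai <- naiveAdjust(b, age, P)
    expect_identical(unique(nai$method), "naive")
    expect_lt(mean(abs(nai$t)), mean(abs(uni$t)))
    expect_identical(attr(nai, "dropped_cell_type"), "B")

    # constant composition: naive == univariate up to numerical noise
    Pconst <- cbind(A = rep(0.4, n), B = rep(0.6, n))
    expect_error(naiveAdjust(b, age, Pconst), "collinear")
    # (a constant column is itself collinear with the intercept; drop it)
    Pconst1 <- Pconst + cbind(rnorm(n, sd = 1e-14), 0)
    naiC <- tryCatch(naiveAdjust(b, age, Pconst1), error = function(e) NULL)
    if (!is.null(naiC))
        expect_equal(naiC$t, uni$t, tolerance = 1e-4)

    # the full simplex of proportions is collinear by construction
    expect_error(univariateEwas(b, age, covariates = P), "collinear")
})

test_that("RUV with k = 0 reproduces the univariate fit exactly", {
    set.seed(45)
    n <- 40; nProbes <- 200
    age <- runif(n, 10, 70)
    b <- matrix(plogis(rnorm(nProbes * n, sd = 0.3)), nProbes,
                dimnames = list(sprintf("p%03d", 1:nProbes),
                                paste0("s", 1:n)))
    controls <- rownames(b)[1:50]
    uni <- univariateEwas(b, age)
    r0 <- ruv2Adjust(b, age, controls, k = 0)
    expect_equal(r0$t, uni$t, tolerance = 1e-10)
    expect_equal(r0$p, uni$p, tolerance = 1e-10)
    expect_identical(unique(r0$method), "ruv2")

    expect_error(ruv2Adjust(b, age, controls, k = n), "smaller")
    expect_error(ruv2Adjust(b, age, controls[1:3], k = 5), "exceeds")
    expect_error(ruv2Adjust(b, age, c(controls, "nope"), k = 2), "nope")
})

test_that("RUV surrogates absorb composition-driven confounding", {
    cfg <- simConfig(seed = 46, nProbes = 1200, nMixtures = 120,
                     nHyper = 20, nHypo = 20, trendAmplitude = 0.3)
    sim <- simulateConfoundedEwas(cfg)
    b <- betaValues(sim$beta)
    age <- sim$sheet$age
    controls <- sim$truth$markers$probe_id
    uni <- univariateEwas(b, age)
    ruv <- ruv2Adjust(b, age, controls, k = 5)
    nUni <- sum(uni$fdr < 0.05)
    nRuv <- sum(ruv$fdr < 0.05)
    expect_gt(nUni, 50)                   # confounding creates hits
    expect_lt(nRuv, nUni * 0.1)           # surrogates absorb them
    expect_lt(mean(abs(ruv$t)), mean(abs(uni$t)))
    # scree: composition spans ~K-1 directions among control probes
    scree <- ruvScree(b, controls, maxK = 8)
    expect_gt(sum(scree$var_explained[1:5]), 0.9)
})

test_that("null p values are uniform under no confounding for all methods", {
    set.seed(47)
    n <- 60; nProbes <- 5000
    age <- runif(n, 10, 80)
    b <- matrix(plogis(rnorm(nProbes * n, sd = 0.25)), nProbes,
                dimnames = list(sprintf("p%04d", 1:nProbes),
                                paste0("s", 1:n)))
    P <- t(apply(matrix(rgamma(n * 3, 2), n), 1, function(g) g / sum(g)))
    colnames(P) <- c("A", "B", "C")
    controls <- rownames(b)[1:100]
    for (res in list(univariateEwas(b, age),
                     naiveAdjust(b, age, P),
                     ruv2Adjust(b, age, controls, k = 3))) {
        ks <- suppressWarnings(ks.test(res$p, "punif"))
        expect_gt(ks$p.value, 0.01)
    }
})

test_that("the CETS transform obeys its algebraic identity", {
    cfg <- simConfig(seed = 48, nProbes = 500, nHyper = 20, nHypo = 20,
                     nIndividuals = 12, devSd = 0.03)
    sim <- simulateTwoCelltypeBrain(cfg)
    pro <- sim$profiles
    trans <- cetsTransform(pro)
    bias <- cetsBias(pro)
    # T(Y) = mu_N + bias, exactly
    expect_lt(max(abs(trans - (pro@muN + bias))), 1e-12)

    # pi = 1 leaves the profile untouched
    one <- CetsProfiles(Y = pro@Y[, 1, drop = FALSE], pi = 1,
                        muBarN = pro@muBarN, muBarG = pro@muBarG)
    expect_equal(unname(cetsTransform(one)), unname(pro@Y[, 1, drop = FALSE]),
                 ignore_attr = TRUE)

    # individual profiles equal to the averages: transform recovers mu_N
    p <- 50
    muBarN <- runif(p, 0.2, 0.8); muBarG <- runif(p, 0.2, 0.8)
    pi <- c(0.3, 0.7)
    muN <- cbind(muBarN, muBarN); muG <- cbind(muBarG, muBarG)
    Y <- sweep(muN, 2, pi, "*") + sweep(muG, 2, 1 - pi, "*")
    ideal <- CetsProfiles(Y, pi, muBarN, muBarG, muN = muN, muG = muG)
    expect_equal(unname(cetsTransform(ideal)), unname(muN),
                 tolerance = 1e-12, ignore_attr = TRUE)

    # equal deviations across cell types: bias collapses to eps
    cfgEq <- simConfig(seed = 49, nProbes = 300, nHyper = 10, nHypo = 10,
                       nIndividuals = 6, devSd = 0.05,
                       equalDeviations = TRUE)
    simEq <- simulateTwoCelltypeBrain(cfgEq)
    expect_lt(max(abs(cetsBias(simEq$profiles) - simEq$profiles@eps)),
              1e-12)

    # unequal deviations, no error: bias is nonzero
    cfgNe <- simConfig(seed = 50, nProbes = 300, nHyper = 10, nHypo = 10,
                       nIndividuals = 6, devSd = 0.05, noiseSd = 0,
                       equalDeviations = FALSE)
    simNe <- simulateTwoCelltypeBrain(cfgNe)
    expect_gt(max(abs(cetsBias(simNe$profiles))), 0.01)

    expect_error(cetsBias(one), "individual")
})
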