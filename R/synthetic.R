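# Seed-deterministic generators emulating the data structures the method
# operates on: flow-sorted blood references with planted cell-type markers
# (and optional planted age-associated probes), whole-tissue mixture
# cohorts whose composition follows a monotone age trend with an
# inflection near 40 years, confounded EWAS scenarios with known ground
# truth, and the two-cell-type brain design (titration series plus
# individual-level profile deviations) for the CETS analysis.
#
# Seeding: each public generator seeds the RNG once from config$seed
# (simulateMixtures offsets the seed by +1 so that a reference and a
# mixture cohort built from the same config draw independent streams);
# composite generators seed once and draw sequentially.

#' Simulation configuration
#'
#' Collects every knob of the synthetic generators with the package's
#' canonical study conditions as defaults: six blood cell types, 50
#' hypermethylated and 50 hypomethylated planted markers per type with a
#' beta-scale effect of 0.5 over a within-type logit-scale noise of 0.01,
#' six sorted donors per type, and an age-driven composition trend with
#' inflection at 40 years (granulocytes rising, T and NK cells declining).
#'
#' @param seed integer RNG seed; mandatory.
#' @param cellTypes cell-type labels, in declared order.
#' @param nProbes total probes simulated.
#' @param nHyper,nHypo planted markers per direction per cell type.
#' @param delta beta-scale marker effect (target type vs all others).
#' @param betweenTypeSd beta-scale SD of per-type deviations given to
#'   non-marker probes; `NULL` resolves to the generator's own default
#'   (0 for clean reference designs, 0.05 for confounded EWAS cohorts,
#'   where most probes differ somewhat across cell types).
#' @param noiseSd measurement-noise SD; applied on the logit scale by
#'   default (keeps betas in range and mimics the heteroskedastic error
#'   of beta values), or on the beta scale with truncation when
#'   `noiseScale = "beta"`.
#' @param noiseScale `"logit"` (default) or `"beta"`.
#' @param nSortedPerType sorted donors per cell type.
#' @param sortedAgeRange donor-age range (years) for the sorted design.
#' @param nAgeProbes,ageSlope planted age-associated probes in the sorted
#'   reference (slope in beta units per year, shared across types).
#' @param nMixtures mixture-cohort size.
#' @param mixtureAgeRange cohort age range (years).
#' @param proportionModel `"ageTrend"` (default) or `"dirichlet"`.
#' @param dirichletAlpha Dirichlet concentration (recycled to the number
#'   of cell types).
#' @param trendInflection,trendWidth logistic age-trend inflection (years)
#'   and width.
#' @param trendAmplitude total composition swing attributed to the trend
#'   (granulocyte fraction rises by this much across the logistic under
#'   the default directions).
#' @param trendDirections named vector of per-type trend directions
#'   (+1 rising, -1 declining, 0 flat); defaults to granulocytes +1 and
#'   CD8T/CD4T/NK -1 when those labels are present, else first type +1,
#'   second -1.
#' @param baseProps baseline composition (defaults to uniform).
#' @param ageEffectProbes,ageEffectSlope,ageEffectType planted true
#'   age effects: number of non-marker probes given a within-cell-type
#'   slope (beta/year) in `ageEffectType` (default: first cell type).
#' @param nIndividuals,devSd,equalDeviations two-cell-type brain design:
#'   number of mixed individuals, SD of individual profile deviations
#'   from the average profiles, and whether deviations are identical
#'   across the two cell types (the special case in which the CETS
#'   transform is unbiased).
#' @return a validated `simConfig` list.
#' @export
simConfig <- function(seed,
                      cellTypes = c("CD8T", "CD4T", "NK", "Bcell",
                                    "Mono", "Gran"),
                      nProbes = 5000,
                      nHyper = 50, nHypo = 50,
                      delta = 0.5,
                      betweenTypeSd = NULL,
                      noiseSd = 0.01,
                      noiseScale = c("logit", "beta"),
                      nSortedPerType = 6,
                      sortedAgeRange = c(20, 60),
                      nAgeProbes = 0, ageSlope = 0.01,
                      nMixtures = 100,
                      mixtureAgeRange = c(1, 80),
                      proportionModel = c("ageTrend", "dirichlet"),
                      dirichletAlpha = 1,
                      trendInflection = 40, trendWidth = 10,
                      trendAmplitude = 0.3,
                      trendDirections = NULL,
                      baseProps = NULL,
                      ageEffectProbes = 0, ageEffectSlope = 0.002,
                      ageEffectType = NULL,
                      nIndividuals = 9, devSd = 0.02,
                      equalDeviations = FALSE) {
    if (missing(seed) || is.null(seed))
        stop("a seed is mandatory for every synthetic generator")
    K <- length(cellTypes)
    if (is.null(trendDirections)) {
        trendDirections <- stats::setNames(rep(0, K), cellTypes)
        if (all(c("Gran", "CD8T", "CD4T", "NK") %in% cellTypes)) {
            trendDirections["Gran"] <- 1
            trendDirections[c("CD8T", "CD4T", "NK")] <- -1
        } else {
            trendDirections[1] <- 1
            if (K > 1) trendDirections[2] <- -1
        }
    }
    if (is.null(baseProps)) baseProps <- rep(1 / K, K)
    cfg <- list(seed = as.integer(seed), cellTypes = cellTypes,
                nProbes = nProbes, nHyper = nHyper, nHypo = nHypo,
                delta = delta, betweenTypeSd = betweenTypeSd,
                noiseSd = noiseSd,
                noiseScale = match.arg(noiseScale),
                nSortedPerType = nSortedPerType,
                sortedAgeRange = sortedAgeRange,
                nAgeProbes = nAgeProbes, ageSlope = ageSlope,
                nMixtures = nMixtures,
                mixtureAgeRange = mixtureAgeRange,
                proportionModel = match.arg(proportionModel),
                dirichletAlpha = rep_len(dirichletAlpha, K),
                trendInflection = trendInflection,
                trendWidth = trendWidth,
                trendAmplitude = trendAmplitude,
                trendDirections = trendDirections,
                baseProps = baseProps / sum(baseProps),
                ageEffectProbes = ageEffectProbes,
                ageEffectSlope = ageEffectSlope,
                ageEffectType = if (is.null(ageEffectType)) cellTypes[1]
                                else ageEffectType,
                nIndividuals = nIndividuals, devSd = devSd,
                equalDeviations = equalDeviations)
    nMarker <- K * (nHyper + nHypo)
    if (nMarker + nAgeProbes + ageEffectProbes > nProbes)
        stop("nProbes too small for the planted markers and age probes")
    class(cfg) <- "simConfig"
    cfg
}

.addNoise <- function(m, sd, scale) {
    if (sd <= 0) return(m)
    if (scale == "logit") {
        x <- stats::qlogis(.truncateBeta(m, 0.001, 0.999))
        stats::plogis(x + matrix(stats::rnorm(length(m), sd = sd),
                                 nrow(m)))
    } else {
        .truncateBeta(m + matrix(stats::rnorm(length(m), sd = sd),
                                 nrow(m)), 0, 1)
    }
}

.rdirichlet <- function(n, alpha) {
    g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
                n, length(alpha), byrow = TRUE)
    g / rowSums(g)
}

# Bimodal baseline probe means: methylation clusters near 0.1 and 0.9.
.baselineMeans <- function(nProbes) {
    mode <- sample(c(0.1, 0.9), nProbes, replace = TRUE)
    stats::plogis(stats::qlogis(mode) + stats::rnorm(nProbes, sd = 0.5))
}

# Core reference builder (does not seed); returns the type-mean matrix,
# marker bookkeeping and the sorted-sample beta matrix.
.genReference <- function(cfg) {
    K <- length(cfg$cellTypes)
    probes <- sprintf("cg%06d", seq_len(cfg$nProbes))
    base <- .truncateBeta(.baselineMeans(cfg$nProbes))
    betweenSd <- if (is.null(cfg$betweenTypeSd)) 0 else cfg$betweenTypeSd
    typeMeans <- matrix(base, cfg$nProbes, K,
                        dimnames = list(probes, cfg$cellTypes))
    if (betweenSd > 0)
        typeMeans <- .truncateBeta(
            typeMeans + matrix(stats::rnorm(cfg$nProbes * K,
                                            sd = betweenSd), cfg$nProbes))
    delta <- cfg$delta
    if (delta > 0.9) {
        warning("marker effect truncated to keep betas in range")
        delta <- 0.9
    }
    nMk <- cfg$nHyper + cfg$nHypo
    special <- sample(cfg$nProbes, K * nMk + cfg$nAgeProbes +
                      cfg$ageEffectProbes)
    markerIdx <- special[seq_len(K * nMk)]
    ageIdx <- special[K * nMk + seq_len(cfg$nAgeProbes)]
    effectIdx <- special[K * nMk + cfg$nAgeProbes +
                         seq_len(cfg$ageEffectProbes)]
    markers <- NULL
    pos <- 0L
    for (k in seq_len(K)) {
        for (dir in c("hyper", "hypo")) {
            want <- if (dir == "hyper") cfg$nHyper else cfg$nHypo
            if (!want) next
            idx <- markerIdx[pos + seq_len(want)]; pos <- pos + want
            lo <- if (dir == "hyper") 0.03 else delta + 0.03
            hi <- if (dir == "hyper") 0.97 - delta else 0.97
            b <- stats::runif(want, lo, hi)
            typeMeans[idx, ] <- b                # clean base in all types
            typeMeans[idx, k] <- b + if (dir == "hyper") delta else -delta
            markers <- rbind(markers, data.frame(
                probe_id = probes[idx], cell_type = cfg$cellTypes[k],
                direction = dir, row.names = NULL))
        }
    }
    list(probes = probes, typeMeans = typeMeans, markers = markers,
         ageProbes = probes[ageIdx], effectProbes = probes[effectIdx])
}

.genSortedSamples <- function(cfg, refParts) {
    K <- length(cfg$cellTypes)
    ns <- cfg$nSortedPerType
    ages <- stats::runif(ns, cfg$sortedAgeRange[1], cfg$sortedAgeRange[2])
    cols <- as.vector(outer(seq_len(ns), cfg$cellTypes,
                            function(s, k) paste0(k, "_", s)))
    mu <- refParts$typeMeans[, rep(seq_len(K), each = ns), drop = FALSE]
    ageCentered <- rep(ages - mean(ages), times = K)
    if (length(refParts$ageProbes)) {
        rows <- match(refParts$ageProbes, refParts$probes)
        mu[rows, ] <- mu[rows, ] +
            outer(rep(cfg$ageSlope, length(rows)), ageCentered)
    }
    mu <- .truncateBeta(mu, 0.001, 0.999)
    beta <- .addNoise(mu, cfg$noiseSd, cfg$noiseScale)
    colnames(beta) <- cols
    rownames(beta) <- refParts$probes
    SortedReference(beta,
                    cellType = rep(cfg$cellTypes, each = ns),
                    age = rep(ages, times = K))
}

#' Simulate a flow-sorted reference with planted markers
#'
#' Baseline probe means are drawn from a bimodal distribution near 0.1
#' and 0.9 (methylation's characteristic bimodality). Each cell type
#' receives `nHyper` hypermethylated and `nHypo` hypomethylated marker
#' probes shifted by `+/- delta` in that type only; optional planted
#' age-associated probes drift linearly with donor age across all types.
#' Replicate sorted samples add measurement noise on the logit scale.
#'
#' @param config a [simConfig()].
#' @return list with `reference` (a [SortedReference-class]) and `truth`
#'   (type-mean matrix, marker table, planted age probes, donor ages,
#'   seed).
#' @export
simulateReference <- function(config) {
    stopifnot(inherits(config, "simConfig"))
    set.seed(config$seed)
    parts <- .genReference(config)
    ref <- .genSortedSamples(config, parts)
    list(reference = ref,
         truth = list(typeMeans = parts$typeMeans,
                      markers = parts$markers,
                      ageProbes = parts$ageProbes,
                      ages = sampleAges(ref)[seq_len(config$nSortedPerType)],
                      seed = config$seed))
}

# Logistic age-composition trend, renormalised to the simplex. The total
# positive swing across the logistic equals trendAmplitude, split across
# the positively / negatively trending types in proportion to their
# direction weights, so proportions stay on the simplex without clamping
# under the defaults.
.trendProportions <- function(ages, cfg) {
    dirs <- cfg$trendDirections[cfg$cellTypes]
    posW <- sum(dirs[dirs > 0]); negW <- -sum(dirs[dirs < 0])
    w <- ifelse(dirs > 0, dirs / max(posW, 1),
                ifelse(dirs < 0, dirs / max(negW, 1), 0))
    t <- stats::plogis((ages - cfg$trendInflection) / cfg$trendWidth)
    P <- matrix(cfg$baseProps, length(ages), length(dirs), byrow = TRUE) +
        outer(t - 0.5, w * cfg$trendAmplitude)
    P <- pmax(P, 0.005)
    P / rowSums(P)
}

.genMixtures <- function(means, cfg, ages = NULL, props = NULL) {
    K <- ncol(means)
    n <- cfg$nMixtures
    if (is.null(ages))
        ages <- stats::runif(n, cfg$mixtureAgeRange[1],
                             cfg$mixtureAgeRange[2])
    if (is.null(props)) {
        props <- if (cfg$proportionModel == "dirichlet")
            .rdirichlet(n, cfg$dirichletAlpha)
        else .trendProportions(ages, cfg)
    }
    dimnames(props) <- list(sprintf("S%04d", seq_len(n)), colnames(means))
    mu <- means %*% t(props)
    if (cfg$ageEffectProbes > 0 && !is.null(attr(means, "effectProbes"))) {
        ep <- attr(means, "effectProbes")
        rows <- match(ep, rownames(means))
        wk <- props[, cfg$ageEffectType]
        mu[rows, ] <- mu[rows, ] +
            outer(rep(cfg$ageEffectSlope, length(rows)),
                  wk * (ages - mean(ages)))
    }
    mu <- .truncateBeta(mu, 0, 1)
    beta <- .addNoise(mu, cfg$noiseSd, cfg$noiseScale)
    colnames(beta) <- rownames(props)
    sheet <- data.frame(sample_id = rownames(props), age = ages)
    bs <- BetaSet(beta, sampleSheet = sheet)
    list(beta = bs,
         truth = list(proportions = props, ages = ages, seed = cfg$seed))
}

#' Simulate whole-tissue mixtures of reference profiles
#'
#' Draws per-sample proportions either from a Dirichlet or from the
#' monotone logistic age-trend model (inflection at 40 years by default),
#' assembles each sample as the proportion-weighted average of the
#' cell-type mean profiles -- exactly linear in the proportions -- and
#' adds measurement noise.
#'
#' @param means probes x cell-types matrix of reference profiles (e.g.
#'   `truth$typeMeans` from [simulateReference()] or
#'   [signatureMeans()]).
#' @param config a [simConfig()].
#' @param ages optional fixed ages (length `nMixtures`), drawn uniformly
#'   over `mixtureAgeRange` otherwise.
#' @param props optional fixed samples x cell-types proportion matrix
#'   overriding the proportion model (`nMixtures` is then taken from its
#'   rows).
#' @return list with `beta` (a [BetaSet] with ages in its colData) and
#'   `truth` (true proportions, ages, seed).
#' @export
simulateMixtures <- function(means, config, ages = NULL, props = NULL) {
    stopifnot(inherits(config, "simConfig"))
    if (!is.null(props)) config$nMixtures <- nrow(props)
    set.seed(config$seed + 1L)
    .genMixtures(as.matrix(means), config, ages = ages, props = props)
}

#' Simulate a composition-confounded EWAS cohort
#'
#' Generates a sorted reference and a mixture cohort whose composition
#' follows the age trend, from one configuration: the canonical
#' false-positive mechanism in which age acts on bulk methylation only
#' through composition. By default every probe differs somewhat across
#' cell types (`betweenTypeSd` resolves to 0.05), so composition change
#' moves much of the epigenome. Optionally, true within-cell-type age
#' effects are planted on `ageEffectProbes` probes of one cell type; the
#' mixed-tissue marginal slope of such a probe equals the planted slope
#' times the mean proportion of that type.
#'
#' @param config a [simConfig()].
#' @return list with `beta` (mixture cohort [BetaSet], ages in colData),
#'   `sheet` (sample sheet data.frame), `reference` (the paired
#'   [SortedReference-class]) and `truth` (type means, markers, true
#'   proportions, planted-effect probes, seed).
#' @export
simulateConfoundedEwas <- function(config) {
    stopifnot(inherits(config, "simConfig"))
    if (is.null(config$betweenTypeSd)) config$betweenTypeSd <- 0.05
    set.seed(config$seed)
    parts <- .genReference(config)
    ref <- .genSortedSamples(config, parts)
    means <- parts$typeMeans
    attr(means, "effectProbes") <- parts$effectProbes
    mix <- .genMixtures(means, config)
    list(beta = mix$beta,
         sheet = data.frame(sample_id = colnames(betaValues(mix$beta)),
                            age = mix$truth$ages),
         reference = ref,
         truth = list(typeMeans = parts$typeMeans,
                      markers = parts$markers,
                      ageProbes = parts$ageProbes,
                      effectProbes = parts$effectProbes,
                      effectSlope = config$ageEffectSlope,
                      effectType = config$ageEffectType,
                      proportions = mix$truth$proportions,
                      ages = mix$truth$ages,
                      seed = config$seed))
}

#' Simulate the two-cell-type brain design for the CETS analysis
#'
#' Builds a neuron/glia-style pair of average profiles with planted
#' discriminating markers, a sorted two-type reference, and a titration
#' series of mixed individuals at fractions 10%, 20%, ..., 90% (cycled
#' over `nIndividuals`). Each individual's cell-type profiles deviate
#' from the averages by Gaussian perturbations of SD `devSd` --
#' identically in both types when `equalDeviations = TRUE` (the only case
#' in which the CETS transform is unbiased) -- and the observed mixtures
#' add explicit measurement error `eps`.
#'
#' @param config a [simConfig()]; `cellTypes` is overridden to the pair
#'   `NeuN_pos`/`NeuN_neg`.
#' @return list with `profiles` (a [CetsProfiles-class] including the
#'   generative `muN`, `muG`, `eps`), `titration` (a [BetaSet] of the
#'   observed mixtures, values flagged rather than clamped),
#'   `reference` (sorted two-type [SortedReference-class]) and `truth`
#'   (designed fractions, average profiles, markers, seed).
#' @export
simulateTwoCelltypeBrain <- function(config) {
    stopifnot(inherits(config, "simConfig"))
    cfg <- config
    cfg$cellTypes <- c("NeuN_pos", "NeuN_neg")
    cfg$trendDirections <- stats::setNames(c(1, -1), cfg$cellTypes)
    cfg$dirichletAlpha <- rep_len(config$dirichletAlpha, 2)
    cfg$baseProps <- c(0.5, 0.5)
    set.seed(cfg$seed)
    parts <- .genReference(cfg)
    ref <- .genSortedSamples(cfg, parts)
    nI <- cfg$nIndividuals
    pis <- rep_len(seq(0.1, 0.9, by = 0.1), nI)
    muBarN <- parts$typeMeans[, "NeuN_pos"]
    muBarG <- parts$typeMeans[, "NeuN_neg"]
    p <- cfg$nProbes
    # deviations are clipped so individual profiles stay in [0, 1]; in the
    # equal-deviations case both types share one clipped draw, keeping the
    # special-case identity (bias = eps) exact
    devN <- matrix(stats::rnorm(p * nI, sd = cfg$devSd), p, nI)
    if (cfg$equalDeviations) {
        lo <- -pmin(muBarN, muBarG); hi <- 1 - pmax(muBarN, muBarG)
        devN <- pmin(pmax(devN, lo), hi)
        devG <- devN
    } else {
        devG <- matrix(stats::rnorm(p * nI, sd = cfg$devSd), p, nI)
        devN <- pmin(pmax(devN, -muBarN), 1 - muBarN)
        devG <- pmin(pmax(devG, -muBarG), 1 - muBarG)
    }
    muN <- muBarN + devN
    muG <- muBarG + devG
    eps <- matrix(stats::rnorm(p * nI, sd = cfg$noiseSd), p, nI)
    Y <- sweep(muN, 2, pis, "*") + sweep(muG, 2, 1 - pis, "*") + eps
    ids <- sprintf("I%02d", seq_len(nI))
    dimnames(Y) <- list(parts$probes, ids)
    dimnames(muN) <- dimnames(muG) <- dimnames(eps) <- dimnames(Y)
    profiles <- CetsProfiles(Y, pi = pis, muBarN = muBarN,
                             muBarG = muBarG, muN = muN, muG = muG,
                             eps = eps)
    titration <- BetaSet(.truncateBeta(Y, 0, 1))
    list(profiles = profiles, titration = titration, reference = ref,
         truth = list(pi = stats::setNames(pis, ids),
                      muBarN = muBarN, muBarG = muBarG,
                      markers = parts$markers, seed = cfg$seed))
}
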