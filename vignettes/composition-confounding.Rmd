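---
title: "Cell composition in methylation studies: estimation, confounding, and adjustment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell composition in methylation studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylcomp)
```

## The problem

Whole blood is a mixture of leukocyte classes whose DNA methylation
profiles differ enormously, and the mixing weights themselves change with
age, disease, and many exposures. A bulk-tissue measurement at CpG $j$ in
sample $i$ is therefore a composition-weighted average of cell-type
profiles,

$$ y_{ij} \;=\; \sum_{k=1}^{K} w_{ik}\,\mu_{jk} \;+\; \varepsilon_{ij},
\qquad w_{ik} \ge 0,\; \textstyle\sum_k w_{ik} = 1, $$

where $\mu_{jk}$ is the mean beta value of CpG $j$ in cell type $k$. When
the trait of interest is correlated with the weights $w_i$ — as age is in
blood — an epigenome-wide association scan on $y$ confuses composition
change for site-specific methylation change and produces false positives
at scale. `methylcomp` implements the reference-based remedy (estimate
$w$ from sorted-cell reference profiles and interrogate it explicitly)
along with the diagnostics and adjustment strategies that go with it.

## The estimation procedure

**Signature selection.** Starting from a flow-sorted reference
(`SortedReference`: beta values plus per-sample cell-type labels and,
optionally, donor ages), the pipeline is:

1. *Age screen* (`agePrefilter`): per probe, regress beta on age with
   cell type as an additive covariate and exclude probes whose age term
   reaches $p \le 0.05$. The projection assumes cell-type profiles are
   age-stable at signature probes; this screen enforces that assumption
   at the selection stage. Note the screen is a per-probe test at level
   $\alpha$: on truly null probes it removes a fraction $\alpha$ of
   candidates at random, which is the accepted cost of the guarantee.
2. *One-vs-rest contrasts* (`oneVsRestTstats`): for each cell type,
   Welch two-sample t statistics of that type against all other samples
   pooled. Welch is the default because within-type variances of beta
   values differ across types; a pooled-variance option exists.
3. *Selection* (`selectSignature`): among probes with one-vs-rest
   $p < 10^{-8}$, rank by effect size and keep the 50 most
   hypermethylated and 50 most hypomethylated probes per cell type. With
   six leukocyte types this yields the classic 600-probe signature. The
   significance threshold and per-direction counts are tunable; the
   defaults are the standard choices for blood.

"Effect size" is not uniquely defined by the selection recipe; we rank
by the difference of group means on the beta scale (the natural effect
measure for proportions), with $|t|$ ranking available
(`rankBy = "t"`). Ties break by larger $|t|$, then probe id, making
selection deterministic and order-invariant. A probe selected for two
cell types is kept once, under the first declared type, with a warning —
in a two-cell-type design every probe discriminates both directions, so
the warning is routine there.

**Constrained projection.** `projectProportions` restricts a target
profile $y$ to the signature probes and solves

$$ \hat w \;=\; \arg\min_{w \ge 0} \; \lVert y - Xw \rVert_2^2, $$

where $X$ is the signature-probe by cell-type matrix of reference means.
The contract is the optimisation problem, not a particular algorithm; the
implementation uses the Lawson–Hanson active-set routine
(`pracma::lsqnonneg`), which solves the non-negative problem exactly.
Two constraint modes are exposed because the displayed proportions in
this literature sum to one while the projection itself is usually run
with non-negativity only:

* `"nonneg"` (default): $w \ge 0$; a row-normalised copy
  ($w/\sum_k w_k$) is reported alongside the raw solution.
* `"simplex"`: additionally $\sum_k w_k = 1$. This is imposed by a
  heavily weighted augmentation row (weight $10^3\sqrt{p}$ for $p$
  signature probes) followed by exact renormalisation. The augmentation
  solution differs from the exactly constrained optimum by
  $O(\lambda^{-2})$, far below the measurement noise of any real array;
  the renormalisation makes the sum exactly one.

At least 80% of the signature probes must be present in the target;
missing probes below that threshold are dropped with a warning, above it
the call errors. A rank-deficient $X$ (indistinguishable cell-type
profiles) is refused.

**Validation design.** `crossvalidateReference` mirrors the in-sample
validation used for sorted panels: each fold holds out one sample per
cell type, rebuilds the signature on the remainder, and projects the
held-out purified samples, whose true composition is a unit vector. The
mean estimated own-type proportion is the concordance summary.

## Diagnostics

* `compositionAnova` — per-probe one-way ANOVA across cell types with
  per-type means and the beta range, serialised with the
  composition-table column convention (`Name`, `Fstat`, `p.value`,
  `<type>_mean`, `DNAm_min/max/range`). This is the lookup table a
  practitioner uses to ask "is my hit probe composition-driven?".
* `variancePartition` — per-probe adjusted $R^2$ under age-only,
  cell-type-only, and full interaction models, plus per-type age
  p values: the quantitative form of "cell type explains far more
  variability than age".
* `pcCompositionCorrelation` — principal components of the beta matrix
  (samples as observations; probes centred, not scaled, since beta
  values share a scale) correlated against the first PC of the
  proportion estimates. Signs of PCs are arbitrary, so the absolute
  correlation is reported alongside the signed value; constant
  proportions yield a flagged zero rather than NaN.
* `ageTrend` — per-type Spearman rank correlation of estimated
  proportions with age (asymptotic p by default; exact optionally for
  small n) and a loess curve (span 0.75, degree 2 — the smoother's
  usual defaults, since no parameters are dictated by the procedure).
* `compositionFilter` — removes probes with ANOVA $p < 10^{-4}$ **and**
  beta range $> 10\%$. The conjunction matters: a significant but tiny
  between-type difference does not disqualify a probe. More permissive
  thresholds (smaller `pCut`, larger `rangeCut`) always retain a
  superset.

## Adjustment strategies

`univariateEwas`, `naiveAdjust` and `ruv2Adjust` share one vectorised
per-probe regression core and one report format: age coefficient, t, p,
Benjamini–Hochberg FDR, and the $|t|$ cutoff attaining FDR < 5% (the
threshold drawn as a line in attenuation plots). BH is used because the
5% false-discovery cutoff is the convention in this analysis; the
procedure is `stats::p.adjust`, with a brute-force step-up oracle in the
test suite.

* *Naive adjustment* adds the estimated proportions as covariates,
  dropping the last declared cell type to avoid simplex collinearity
  (recorded in the output's `dropped_cell_type` attribute). It shrinks
  composition-mediated estimates toward zero but is not guaranteed
  unbiased under strong confounding.
* *Two-step RUV* first extracts the top $k$ principal directions of the
  control-probe submatrix (probes affected by composition but believed
  unrelated to the outcome — the signature probes are the natural
  choice, having been screened against age), then includes the
  per-sample scores as surrogate covariates. $k$ is deliberately a user
  decision, supported by `ruvScree`; with $K$ cell types the composition
  subspace has rank $K-1$ after centring, which is why $k = 5$ suffices
  for a six-type blood design. $k = 0$ reproduces the univariate fit
  exactly, a property the tests pin down. Published analyses have used
  $k = 10$ and $k = 30$ on real cohorts, chosen from diagnostic plots;
  real data carry batch structure beyond composition, which is why
  useful $k$ exceeds $K-1$ there.
* *The CETS transform* for two-cell-type tissue,
  $T(Y_i) = Y_i + (1-\pi_i)(\bar\mu_N - \bar\mu_G)$, shifts the observed
  profile using *population-average* profiles. Expanding the mixture
  model shows
  $T(Y_i) = \mu_{i,N} + (1-\pi_i)\big[(\bar\mu_N - \mu_{i,N}) -
  (\bar\mu_G - \mu_{i,G})\big] + \epsilon_i$: the pure neuronal signal is
  recovered only when an individual deviates from the average profile
  identically in both cell types. `cetsTransform` and `cetsBias`
  implement both sides of this identity, which holds to machine
  precision by construction, and the synthetic brain generator can
  produce the equal-deviations special case in which the bias collapses
  to measurement error alone. We take $\pi$ as given (the setting of the
  algebraic argument); calibrating $\pi$ from data is a separate problem
  the package does not address.

## Gene-set enrichment with composition filtering

`obsExpEnrichment` counts at the CpG level: for each gene set with at
least 25 member genes in the background universe, the observed count is
the number of query CpGs mapping to any set gene; the expected count is
the mapped query size times the background fraction of CpGs in the set.
The observed/expected ratio is the enrichment statistic and a one-sided
hypergeometric p ranks the sets. Only mapped CpGs enter the denominator
(background = CpGs with a gene annotation), a CpG mapping to several
genes of one set counts once, and no ontology database is bundled — sets
load from a plain two-column table or GMT, so GO, KEGG or synthetic
collections are interchangeable. `beforeAfterComparison` reruns the
enrichment after `compositionFilter` and reports per-set rank shifts;
when the composition-associated CpGs are the immune-themed ones, immune
sets sink and trait-specific sets rise, which is the intended reading.

No multiple-testing correction is applied across sets: the output is a
ranked table, not a significance claim.

## The synthetic test bed

Every stage is exercised against generators with complete ground truth
(`simulateReference`, `simulateMixtures`, `simulateConfoundedEwas`,
`simulateTwoCelltypeBrain`), all driven by a mandatory seed. Design
choices, made once:

* **Baseline probe means** are bimodal near 0.1 and 0.9 (logit-normal
  around each mode), matching methylation's characteristic bimodality.
* **Markers**: each cell type receives 50 hyper- and 50 hypomethylated
  probes shifted by $\delta = 0.5$ on the beta scale in that type only —
  the planted analog of a discriminating signature. Marker baselines are
  drawn so the shift stays inside $[0.03, 0.97]$.
* **Noise** is Gaussian on the logit scale (sd 0.01 by default), then
  inverse-transformed: this keeps betas in range and reproduces the
  heteroskedastic, edge-compressed error of real beta values. A
  truncated-Gaussian-on-beta option exists for settings (like the CETS
  algebra) where additive error is the model.
* **Age trend**: per-sample proportions follow a logistic-in-age trend
  with inflection at 40 years and width 10, granulocytes rising and
  CD8/CD4/NK declining, with a total swing of 0.3 split across the
  trending types so the simplex needs no clamping. This is a minimal
  monotone family matching the described age–composition relationship,
  not a biological claim. A Dirichlet mode provides trend-free mixtures.
* **Confounded cohorts** give every probe a per-type deviation
  (sd 0.05) so that composition change moves much of the epigenome —
  the synthetic counterpart of most CpGs differing across sorted cell
  types — while sorted references for selection invariants use clean
  planted markers only (`betweenTypeSd = 0`). Optional true age effects
  are planted within one cell type; by linearity their mixed-tissue
  marginal slope is the planted slope times that type's mean proportion.
* **Sizes**: the default scenario (5,000 probes, 200 samples, six types
  with six sorted donors each) keeps the full suite in minutes on one
  CPU while leaving every effect far from its detection boundary.

What passing tests on these generators does **not** show: robustness to
probe-design artefacts (type I/II chemistry, cross-hybridisation),
batch structure beyond composition, reference-panel mismatch between
populations, or cell types absent from the reference. Those require real
sorted data and are out of scope here.

## Numerical choices and degenerate inputs

* Quantile normalisation maps each column to the mean of the order
  statistics, averaging tied ranks (via `limma::normalizeQuantiles`,
  ties on). Beta values come from the logit route
  $\beta = 2^x/(1+2^x)$ with $x = \log_2(M/U)$ after flooring both
  channels at 1 — algebraically $M/(M+U)$ on the floored intensities.
  No $+100$ stabilising offset is used anywhere.
* Zero-variance probes: regression and t machinery report $t = 0$,
  $p = 1$ when the coefficient is also zero (a constant probe carries no
  evidence), and $|t| = \infty$, $p = 0$ for an exact nonzero effect.
  The composition ANOVA reports $F = 0, p = 1$ at probes with zero total
  variance.
* Collinear designs are refused with the offending columns named, rather
  than silently dropped.
* The filter/selection order question (normalise before or after probe
  filtering) is left to the caller; the CLI filters first, then
  normalises, and both operations are exposed separately.

## Known limitations

The package deliberately stops short of: reference-free deconvolution;
estimating $\pi$ for the CETS setting; RUV-4-style shrinkage variants;
GO graph propagation; IDAT parsing and array-manifest handling (inputs
are plain matrices plus annotation tables); and any claim about *which*
biological process drives an observed trend. Estimated proportions are
regression-calibration quantities: accurate to a few percent under a
faithful reference, but not cell counts.
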