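---
title: "Methods: growth curves, QTL, and co-expression networks in growthnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth curves, QTL, and co-expression networks in growthnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthnet)
```

growthnet dissects the genetic architecture of plant growth in a biparental
recombinant inbred line (RIL) population by combining four layers of
analysis: function-valued growth traits estimated from longitudinal field
heights, classical quantitative genetics on those traits, genome scans for
QTL and eQTL, and trait-seeded co-expression networks. This vignette
explains the models, the tunable parameters and their defaults, the
numerical choices, and what the synthetic-data generator does and does not
emulate.

## The growth model and its function-valued traits

Plant height on a thermal-time axis is modelled by the logistic ODE
dH/dt = r H (Hmax − H)/Hmax, whose solution is
H(t) = Hmax / (1 + exp(−r (t − iD))). The curve is summarised by four
function-valued traits: the growth rate `r` (1/DD), the asymptotic height
`Hmax` (cm), the inflection point `iD` (DD, where growth switches from
accelerating to decelerating), and the duration `d`, defined as the time at
which the plant reaches 95% of `Hmax`. Inverting the logistic at 95% gives
the closed form d = iD + ln(19)/r, so `d` is always derived, never fitted.

Thermal time is accumulated as degree days above a base of 0.96 °C, the
*Brassica rapa*-specific base temperature. `degree_days()` supports a daily
mode (daily mean minus base, floored at zero) and an hourly mode (hourly
excess divided by 24). The two agree whenever no hour dips below base; with
sub-base hours the hourly mode accumulates slightly more. The daily mode is
the default because replicate-level field phenotypes are recorded daily.

## The three-level hierarchical Bayesian fitter

`fit_hierarchical_growth()` retains the data structure of a field
experiment: a population level, a line (genotype) level, and a replicate
level.

* Population: means of (log r, log Hmax, iD), optionally with a linear
  term in a genotype-level covariate (`amax`) on log r and log Hmax, which
  factors out variation in carbon availability; between-line SDs.
* Line: (log r, log Hmax, iD) drawn around the population location.
  Working on the log scale for r and Hmax enforces positivity without
  constrained proposals.
* Replicate: additive deviations on all three parameters, plus Gaussian
  measurement noise on the heights. Block effects in the field design are
  absorbed by the replicate deviations rather than modelled separately.

Priors are weakly informative and data-scaled: Normal priors on the
population means centred on curve-heuristic initial values with SD 3 on the
log scales (and a wide SD for iD), and half-Normal priors on all SDs. The
paper trail for such models rarely pins priors down; these choices are
deliberately broad so the likelihood dominates with 5–13 measurements per
replicate.

Inference is single-chain random-walk Metropolis–Hastings (an `n_chains`
argument is unnecessary because determinism plus different seeds gives
independent chains). Three structural choices matter:

1. **Vectorised block updates.** All lines are proposed and
   accepted/rejected in one vectorised step (similarly all replicates),
   valid because lines are conditionally independent given the
   hyperparameters. This is what makes a 500,000-iteration schedule
   practical in pure R.
2. **A translation move along the line/replicate degeneracy.** The
   likelihood only sees theta_line + delta_replicate, so a random-walk
   sampler can park line effects inside the replicate deviations,
   inflating the replicate-level SD and biasing line posteriors. A
   dedicated move shifts a line's parameters and subtracts the same shift
   from its replicates' deviations; the likelihood is untouched and
   acceptance depends only on the priors. Without this move, coverage of
   line-level intervals collapses.
3. **Burn-in-only adaptation.** Proposal scales adapt toward 20–40%
   acceptance during burn-in and are frozen afterwards, so retained
   samples come from a fixed kernel.

Conjugate pieces (population means and the covariate slope) are drawn by
Gibbs; the seven SD parameters use scalar log-scale random walks with the
Jacobian included.

The retention schedule follows `mcmc_schedule()`: with 500,000 iterations,
440,000 burn-in and thinning to 1 in 20, exactly 3,000 samples per
parameter are retained. Derived quantities (`d`, and anything else computed
from the curve) are evaluated per retained sample and then summarised, so
their uncertainty propagates from the joint posterior instead of being
computed from posterior means.

`credible_envelopes()` reports two pointwise 95% bands per line: the model
envelope (quantiles of the line-level curve across retained samples) and
the predictive envelope (the same curves with a fresh replicate deviation
and measurement noise added), which is where future observations from the
same environment are expected. Because both envelopes are Monte-Carlo
quantiles, the predictive band can cross the model band by sampling noise;
the implementation takes the pointwise union so the nesting invariant holds
exactly.

## Quantitative genetics

`fit_random_effects()` fits the all-random mixed model
`value ~ (1|line) + (1|treatment) + (1|treatment:block) +
(1|line:treatment)` with lme4 and REML; block is nested within treatment
as in the randomized-block field layout. `plasticity_lrt()` compares ML
fits with and without one random term; the statistic is referred to a
plain chi-square with configurable df (df = 2 for block-within-treatment,
1 otherwise). Testing a variance on its boundary this way is conservative
— the mixture-chi-square refinement is deliberately not applied, so
reported p-values err on the safe side.

BLUPs for mapping and network seeding come from per-treatment fits of
`value ~ (1|line) + (1|block)`; they are shrunken genotype deviations that
sum to ~0. Broad-sense heritability is H² = 100·Vg/(Vg + Vblock + Vres).
Genetic correlations are Pearson correlations of line-matched BLUPs with a
Bonferroni factor (default family size 7).

## Genome scans

`genotype_probabilities()` runs a two-state forward–backward HMM per
chromosome: Haldane map distances give per-meiosis recombination fractions,
expanded to the selfed-RIL scale R = 2r/(1+2r); emissions allow a
genotyping error rate (default 0.001); pseudomarkers are inserted every
1 cM. Haley–Knott regression (`scan_hk()`) regresses the phenotype on the
expected genotype dosage; LOD = (n/2)·log10(RSS0/RSS1). With covariates,
phenotype and dosage are residualised first (Frisch–Waugh), which collapses
the scan to one correlation per position and makes 10,000-permutation
thresholds a single matrix cross-product. PVE = 100·(1 − 10^(−2·LOD/n))
is algebraically identical to the regression R² for a single-QTL
Haley–Knott model, and the tests assert that identity to 1e-10.

Composite interval mapping (`scan_cim()`) selects up to 3 marker
covariates by forward regression and drops any covariate within 10 cM of
the position under test; both defaults follow the conventions of the
standard implementation since no others are stated. The multi-QTL search
(`build_multi_qtl_model()`) seeds with genome-wide significant single-scan
peaks and iterates refine/add/drop against the permutation threshold until
membership stabilises. It uses Haley–Knott regression throughout rather
than multiple imputation: for additive models on essentially homozygous
RILs the two agree in expectation, and the regression form is
deterministic and directly testable. Ties at equal LOD break toward the
lowest chromosome then lowest position; lines with missing phenotypes are
dropped scan-wide and the recorded `n` feeds PVE.

Support intervals are either 1.5-LOD drop or an approximate Bayes interval
(normalised 10^LOD mass, highest positions first, spanned to contiguity).
A Bayes interval that collapses to a single grid position — common for
very large LOD peaks — is replaced by peak ± 2.5 cM and flagged, since a
one-point interval is unrealistic given the recombination content of ~120
RILs.

## Co-expression networks

Counts are filtered (> 2 CPM in at least 44 samples by default), TMM-
normalised via edgeR, and expressed as log2(CPM + 0.5) on effective library
sizes. Precision weights are not carried: no downstream stage here consumes
them, so the variance-stabilised log scale is sufficient. The 10,000 most
variable genes between lines (variance of per-line means; identical to the
fitted-line-effect ranking for balanced designs) enter the network stage.

Mutual ranks are the geometric mean of the two directed Pearson-correlation
ranks (rank 1 = most correlated, self excluded, ties averaged). Seeded
networks take every gene with MR ≤ threshold to at least one trait seed,
then gene–gene edges under the same threshold among joined genes — the
inclusive rule, since seeded-network figures typically show gene–gene
edges. Thresholds 10/20/30/50 form a nested family. Significance comes
from shuffling the seed-trait values across lines (jointly over seeds,
preserving trait–trait correlation) and counting seed–gene edges; the
add-one estimator keeps p ≥ 1/(n_perm + 1).

Module detection uses the signed-hybrid adjacency cor^power (negative
correlations map to exactly 0), the topological overlap matrix, and
average-linkage clustering of 1 − TOM. The soft power is the lowest one
whose connectivity distribution fits a scale-free form with squared
correlation > 0.9 (computed by histogram regression of log10 p(k) on
log10 k; a positive slope scores 0). The tree is cut statically at a
configurable height (default 0.25) with a minimum module size of 30;
dynamic tree cutting is not reimplemented because its parameters are not
derivable from any stated source, so module counts will differ from any
particular reference analysis. Eigengenes are the first principal
component of the standardised module expression, sign-oriented to the
module mean profile and scaled to unit variance; module–trait association
uses per-pair Pearson tests with Holm step-down correction across the
whole family.

## Integration

FVT QTL live in cM and gene models in bp; a monotone piecewise-linear map
through the markers (which carry both coordinates) converts between them.
All interval logic is closed at boundaries: a gene touching an interval
endpoint is "under" the QTL, and a cis call means the eQTL interval
contains the gene's physical location, with everything else (including
other chromosomes) trans. Enrichment uses the two-sided Fisher exact test.
Colocalization significance re-places each interval uniformly at random
(width preserved) on a chromosome drawn proportional to its length — a
standard uniform re-placement null, since none is prescribed — with the
add-one p-value estimator. The predictive-model comparison builds the
single-, two-, and three-data-type linear model families, removes the
least significant term one at a time (ties by name) until everything is
below the stay threshold p < 0.10, and reports F, adjusted R² and AIC,
with nested finals compared by F-test.

## The synthetic-data generator

The generator produces complete studies with the statistical structure the
pipeline assumes: a 10-chromosome map of ~1,460 markers at ~0.7 cM
spacing; ~120 RILs built by explicit repeated selfing (default 7
generations, with residual heterozygotes driven to fixation by continued
selfing so calls match the >99% homozygosity of real RIL panels);
longitudinal growth with planted QTL, genotype-level parameter
correlations, treatment and genotype-by-treatment structure, randomized
blocks, and 5–13 measurements per replicate; negative-binomial expression
with planted modules, cis-eQTL, trans hotspots and trait-coupled genes;
and hourly temperature series with prescribed daily means. Where the
emulated study states a value (sample sizes, marker density, measurement
counts, the MCMC schedule) the defaults reproduce it; where it does not
(growth-parameter means and SDs, expression effect sizes, dispersion),
defaults are chosen once at values a field study of this kind would find
realistic — e.g. r ≈ 0.02/DD, Hmax ≈ 110 cm, iD ≈ 600 DD, measurement
noise ≈ 1.5 cm, log2 cis effects of ~1–1.5, NB dispersion 0.05.

What the generator does **not** emulate: spatial field heterogeneity
beyond additive block effects, non-logistic growth (stress plateaus,
herbivory resets), count outliers and batch effects, linkage
disequilibrium beyond the meiotic model, and segregation distortion.
Passing recovery tests therefore demonstrates that the estimators are
correct under their own assumptions, not that those assumptions hold for
any particular field dataset.

## Problem sizes and numerical choices

The validation suite scales simulations to what the statistics need rather
than to the emulated study: parameter recovery uses 30 lines × 4
replicates with a 20,000-iteration chain (the full 500,000-iteration
schedule is exercised once, on a two-line model); QTL recovery uses 20
simulated studies of 120 RILs with 1,000-permutation thresholds;
calibration checks use 100 null traits at 200 permutations and mutual-rank
nulls at 50 permutations; network recovery uses 500 genes. Degenerate
inputs are handled explicitly: zero-variance phenotypes return flat LOD
curves with a warning, zero-variance expression nodes are excluded from MR
with a warning, constant modules and zero-count libraries are errors, and
an all-missing genotype line falls back to the 1/2 HMM prior.
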