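# Replicate-level mixed models on FVT traits: variance components,
# plasticity likelihood-ratio tests, BLUPs, broad-sense heritability, and
# genetic correlations. All models are fitted with lme4; every effect is
# random and block is nested within treatment, matching the randomized-
# block field design.

#' Fit the all-random mixed model
#'
#' Fits `value ~ 1 + (1|genotype) [+ (1|treatment) + (1|treatment:block) +
#' (1|genotype:treatment)]` by REML, returning variance components, BLUPs
#' for the genotype term, and the log-likelihood. Terms are included only
#' when the corresponding column varies; single-treatment data reduce to
#' the BLUP model `value ~ (1|genotype) + (1|block)`.
#'
#' @param data Tibble with columns `line`, `value`, and optionally
#'   `treatment` and `block`.
#' @param include Character subset of
#'   `c("genotype", "block", "treatment", "gxt")` naming random terms to
#'   include (defaults to all that the data support).
#' @return List of class `ranef_fit`: `varcomp` (tibble term/variance),
#'   `blups` (tibble line/blup), `logLik`, and the `lmer` fit.
#' @export
fit_random_effects <- function(data,
                               include = c("genotype", "block", "treatment", "gxt")) {
  if (!all(c("line", "value") %in% names(data))) {
    abort("data needs columns line and value")
  }
  has_tr <- "treatment" %in% names(data) && length(unique(data$treatment)) > 1
  has_bl <- "block" %in% names(data) && length(unique(data$block)) > 1
  terms <- c()
  if ("genotype" %in% include) terms <- c(terms, "(1|line)")
  if ("treatment" %in% include && has_tr) terms <- c(terms, "(1|treatment)")
  if ("block" %in% include && has_bl) {
    terms <- c(terms, if (has_tr) "(1|treatment:block)" else "(1|block)")
  }
  if ("gxt" %in% include && has_tr) terms <- c(terms, "(1|line:treatment)")
  if (length(terms) == 0) abort("no random terms to fit")
  if (length(unique(data$line)) < 2) abort("need >= 2 genotypes")
  fml <- stats::as.formula(paste("value ~ 1 +", paste(terms, collapse = " + ")))
  fit <- tryCatch(
    lme4::lmer(fml, data = data,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           check.nobs.vs.nlev = "ignore",
                                           check.nobs.vs.nRE = "ignore")),
    error = function(e) abort(paste("mixed model could not be fitted:",
                                    conditionMessage(e)))
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- tibble(term = vc$grp, variance = vc$vcov)
  re <- lme4::ranef(fit)$line
  blups <- tibble(line = rownames(re), blup = re[, 1])
  structure(list(varcomp = varcomp, blups = blups,
                 logLik = as.numeric(logLik(fit)), fit = fit),
            class = "ranef_fit")
}

#' @exportS3Method
tidy.ranef_fit <- function(x, ...) x$varcomp

#' Broad-sense heritability
#'
#' H2 = 100 * Vg / (Vg + Vblock + Vres), in percent: the genotypic variance
#' over the sum of genotypic, block, and residual variances.
#'
#' @param vg,vblock,vres Variance components (>= 0). Alternatively pass a
#'   `ranef_fit` as `vg` and the components are taken from it (`line`,
#'   block-containing term, `Residual`).
#' @return Percent in \[0, 100\].
#' @export
heritability <- function(vg, vblock = 0, vres = 0) {
  if (inherits(vg, "ranef_fit")) {
    vc <- vg$varcomp
    get <- function(pat) sum(vc$variance[grepl(pat, vc$term)])
    vblock <- get("block"); vres <- get("^Residual$"); vg <- get("^line$")
  }
  if (any(c(vg, vblock, vres) < 0)) abort("variance components must be >= 0")
  tot <- vg + vblock + vres
  if (tot == 0) abort("all variance components are zero; H2 undefined")
  100 * vg / tot
}

#' Likelihood-ratio test for a random term
#'
#' Compares the full all-random model against the model with `term`
#' removed: statistic = 2 (LL_full - LL_reduced), referred to a chi-square
#' with the configured df (1 by default; the randomized-block layout uses
#' df = 2 for block-within-treatment). Testing a variance component on the
#' boundary this way is conservative. Models are fitted by ML so the
#' likelihoods are comparable.
#'
#' @param data As for [fit_random_effects()].
#' @param term One of `"genotype"`, `"block"`, `"treatment"`, `"gxt"`.
#' @param df Degrees of freedom for the reference distribution.
#' @return Tibble: `term`, `chisq`, `df`, `p.value`.
#' @export
plasticity_lrt <- function(data, term, df = 1) {
  all_terms <- c("genotype", "block", "treatment", "gxt")
  if (!term %in% all_terms) abort("unknown term")
  ml_fit <- function(include) {
    f <- fit_random_effects(data, include = include)
    as.numeric(stats::logLik(stats::update(f$fit, REML = FALSE)))
  }
  ll_full <- ml_fit(all_terms)
  ll_red <- ml_fit(setdiff(all_terms, term))
  stat <- max(0, 2 * (ll_full - ll_red))
  tibble(term = term, chisq = stat, df = df,
         p.value = pchisq(stat, df, lower.tail = FALSE))
}

#' Genotype BLUPs per treatment
#'
#' Fits `value ~ (1|line) + (1|block)` separately within each treatment and
#' returns the shrunken genotype deviations, the model used for the trait
#' values that downstream mapping and network seeding consume.
#'
#' @param data Tibble: `line`, `value`, `block`, optionally `treatment`.
#' @return Tibble: `treatment`, `line`, `blup`.
#' @export
blups_by_treatment <- function(data) {
  if (!"treatment" %in% names(data)) data$treatment <- "all"
  purrr::map_dfr(split(data, data$treatment), function(d) {
    f <- fit_random_effects(d, include = c("genotype", "block"))
    f$blups %>% mutate(treatment = d$treatment[1], .before = 1)
  })
}

#' Genetic correlations among trait BLUPs
#'
#' Pairwise Pearson correlations of line-matched BLUPs with Bonferroni
#' adjustment over `n_tests` comparisons (adjusted p = min(1, p * n_tests)).
#' Zero-variance traits yield `NA` correlations with a warning.
#'
#' @param blups Wide tibble: `line` plus one numeric column per trait.
#' @param n_tests Bonferroni family size (default 7).
#' @return Tibble: `trait_a`, `trait_b`, `r`, `n`, `p.value`, `p.adj`.
#' @export
genetic_correlations <- function(blups, n_tests = 7) {
  traits <- setdiff(names(blups), "line")
  if (length(traits) < 2) abort("need at least two trait columns")
  pairs <- utils::combn(traits, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    a <- blups[[pr[1]]]; b <- blups[[pr[2]]]
    ok <- stats::complete.cases(a, b)
    if (sum(ok) < 3) abort(sprintf("fewer than 3 shared lines for %s-%s",
                                   pr[1], pr[2]))
    if (sd(a[ok]) == 0 || sd(b[ok]) == 0) {
      warn(sprintf("zero-variance trait in pair %s-%s", pr[1], pr[2]))
      return(tibble(trait_a = pr[1], trait_b = pr[2], r = NA_real_,
                    n = sum(ok), p.value = NA_real_, p.adj = NA_real_))
    }
    ct <- cor.test(a[ok], b[ok])
    tibble(trait_a = pr[1], trait_b = pr[2], r = unname(ct$estimate),
           n = sum(ok), p.value = ct$p.value,
           p.adj = min(1, ct$p.value * n_tests))
  })
}
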