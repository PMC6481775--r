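---
title: "Predicting heterosis from allometric curvature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting heterosis from allometric curvature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allohet)
```

## The model

Heterosis is the deviation of an F1 hybrid from its parents. For a trait
$Y$ measured on parents (genotype means $Y_1$, $Y_2$) and their hybrid
($Y_{1\times2}$), the package uses the two standard measures

$$\mathrm{MPH} = \frac{Y_{1\times2} - \overline{Y_{1},Y_{2}}}{\overline{Y_{1},Y_{2}}},
\qquad
\mathrm{BPH} = \frac{Y_{1\times2} - \max(Y_1, Y_2)}{\max(Y_1, Y_2)}.$$

The scientific claim the package operationalizes is geometric. In plants,
fitness-related traits are tightly constrained by vegetative biomass $M$
through *allometric* relationships. Two forms are fitted by nonlinear
least squares on the untransformed trait:

* growth rate: a power law with mass-corrected exponent,
  $g(M) = a\,M^{\,b + c\log_{10} M}$, which is a concave quadratic in
  log-log space when $c < 0$;
* fruit number: an inverse quadratic,
  $f(M) = M / (a + bM + cM^2)$, hump-shaped with an interior maximum at
  $M = \sqrt{a/c}$ (source/sink competition depresses fruit production
  in very large plants).

If hybrids obey the *same* curve as their parents, and hybrid mass is
(near-)additive, then curvature alone produces heterosis of the
downstream trait — Wright's physiological-dominance argument lifted to
whole-plant traits. The curvature-only prediction is the *nonlinear
deviation*:

$$\mathrm{MP}_{pred} = \tfrac12\{g(M_1) + g(M_2)\},\quad
\mathrm{BP}_{pred} = \max\{g(M_1), g(M_2)\},$$
$$\mathrm{NLDev_{MP}} = \frac{g(M_{1\times2}) - \mathrm{MP}_{pred}}{\mathrm{MP}_{pred}},
\qquad
\mathrm{NLDev_{BP}} = \frac{g(M_{1\times2}) - \mathrm{BP}_{pred}}{\mathrm{BP}_{pred}},$$

computed with the model fitted on *accessions only* — never on the
hybrids being predicted (`nldev()`, `nldev_table()`); a pooled fit is
available for sensitivity analysis. `compare_predictions()` then reports
the $r^2$ between predictions and observations, and between NLDev and
observed MPH/BPH.

```{r jensen}
gm <- list(form = "power_mass_corrected",
           coefficients = c(a = 0.022, b = 1.483, c = -0.164))
nldev(gm, m1 = 10, m2 = 100, m12 = 55)
```

A hybrid whose mass is exactly mid-parent is predicted to exceed the
mid-parent growth rate by ~8% (Jensen's inequality on a concave curve)
while remaining ~41% below the best parent.

### Where the curvature argument holds

With $c < 0$ the log-log curve is concave everywhere, but on the raw
scale $g$ has an inflection: writing $\varphi = b + 2c\log_{10}M$ for the
local log-log slope, $g'' < 0$ exactly where
$\varphi^2 - \varphi + 2c/\ln 10 < 0$. For the default accession
coefficients this places the inflection near 12.2 mg
(`concavity_threshold()`): the curve is convex below ~12 mg and concave
from there through the largest observed masses. The Jensen positivity of
$\mathrm{NLDev_{MP}}$ is therefore asserted (and tested) for parent
pairs above that threshold; very small plants sit on the convex toe of
the curve where the sign can reverse.

## Fitting choices

* **Untransformed-scale NLS.** Both allometries are fitted on the raw
  trait via `minpack.lm::nlsLM`, with analytic starting values (the
  quadratic log-log regression for growth; the linear regression of
  $M/F$ on $(1, M, M^2)$ for fruit) and a small multi-start grid as a
  fallback. The log in the mass-corrected exponent is base 10; the
  package's noise-free round-trip tests confirm that base-10 evaluation
  reproduces the generative coefficients exactly.
* **CIs** are asymptotic (Wald) with $t_{n-p}$ quantiles.
* **Model comparison** uses the Gaussian-likelihood AIC
  $n\log(\mathrm{rss}/n) + 2k$ with $k$ = parameters + 1; the additive
  constant cancels in `compare_models_aic()`, whose sign convention is
  AIC(alternative) − AIC(retained).
* **SMA regression** (`fit_sma()`) is implemented from the closed form:
  slope $= \mathrm{sign}(r)\,s_y/s_x$, CI from
  $B = F_{0.95;1,n-2}(1-r^2)/(n-2)$, and the one-sample slope test (e.g.
  against the metabolic-scaling exponent 3/4) via the correlation of the
  residual axis $y - \beta_0 x$ with the fitted axis $y + \beta_0 x$.
  The between-group slope comparison uses a normal approximation on the
  delta-method SEs — adequate at the cohort sizes involved (hundreds of
  genotypes).
* **Degenerate inputs.** Fitting requires at least 10 observations and
  3 distinct masses; duplicate masses are allowed; an inverse-quadratic
  fit whose denominator crosses zero inside the data range is rejected.

## Heterosis testing and heritability

`classify_heterosis()` follows the bootstrap design: the F1 trait
distribution is estimated from 1,000 resamples (with replacement) of the
hybrid's replicates; parents enter as fixed genotype means. The
bootstrap mean is compared to mid (two-sided), best and worst parent
(one-sided) with t-type statistics in which the bootstrap standard
deviation of the mean serves directly as the standard error (so the
reference distribution has `n_boot - 1` df — dividing the bootstrap sd
by $\sqrt{n_{boot}}$ again would declare every hybrid significant, while
a `n_reps - 1` reference gives the tests essentially no power under a
Bonferroni family of `3 * n_hybrids` tests; the family size is
configurable). Exactly one of five categories results: `below_worst`,
`negative`, `additive`, `positive`, `above_best`; the share with "any
significant heterosis" is 100 minus the additive percentage. "Best"
defaults to the larger value for every trait; a per-trait `direction`
flag flips this for traits like age at reproduction where the preferred
direction is ambiguous.

Broad-sense heritability is
$H^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_e)$ from the REML
random-intercept model `Y ~ (1 | genotype)` (`lme4::lmer`), computed on
the pooled accession + hybrid data by default, with a method-of-moments
ANOVA fallback for degenerate data (e.g. zero residual variance).

## Distance baselines

The competing predictors of heterosis are parental distances:

* **genetic** — allele-count differences between homozygous inbred
  lines (2 alleles per differing biallelic site; a per-site mode
  exists), over pairwise-complete calls, log10-transformed for
  regression; markers are pre-filtered at MAF ≥ 5% and call rate ≥ 85%
  (`filter_snps()`), optionally restricted to the 1% of markers with the
  strongest absolute effects (`top_snp_subset()`);
* **geographic** — great-circle distance on a sphere of mean Earth
  radius 6,371 km (`geosphere`);
* **phenotypic** — Euclidean distance over traits standardized to unit
  variance (raw scales mix mg, days and counts incoherently; a raw mode
  exists), or the absolute mass difference.

`regress_heterosis_on_distance()` fits `h ~ d + d^2` by OLS (the
quadratic term tests for an optimal intermediate distance) and reports
the linear-only fit alongside. No multiplicity correction is applied
across the regression battery; thresholds are the caller's.

## The synthetic cohort

`synthetic_config()` fixes the simulated study design: accessions with
2 replicates and hybrids (crosses among them) with 4, masses
$10^{N(1.6,\,0.7^2)}$ mg spanning roughly 1–2,000 mg, growth from the
mass-corrected power law with multiplicative lognormal noise
(sd 0.05 on the log10 scale, giving the tight $r^2 > 0.9$ scatter
characteristic of growth allometries), fruit from the inverse quadratic
with much looser noise (sd 0.3), and hybrid mass equal to mid-parent
mass times $1+\delta$, $\delta \sim N(-0.05, 0.15^2)$ — slightly
negative-skewed, as negative mass heterosis predominates in wide
intraspecific crosses. Age at reproduction is *derived* as
$M/\mathrm{growth}$ so the definitional identity growth = M/age holds
exactly; replicate-level jitter is multiplicative with a 10% coefficient
of variation (the within-genotype variance is a free parameter of the
design — no published value constrains it). SNP matrices draw each
marker's allele frequency from a logistic spatial gradient in a random
geographic direction, producing the isolation-by-distance correlation
between genetic and geographic distance; there is no linkage
disequilibrium or recombination model. A single integer seed governs
everything through fixed per-stage sub-streams, so equal configs give
byte-identical tables.

What the generator does *not* emulate: the real, right-skewed and
multi-modal mass distribution of field accessions; trait-specific
hybrid effects beyond mass (unless `hybrid_trait_dev_sd` is set);
measurement error structure of image-derived fruit counts; population
structure beyond a smooth spatial gradient. Consequently, passing the
simulation-based tests demonstrates correctness of the estimators under
the generative model, not the empirical values of the original field
study — e.g. the SMA slope of simulated cohorts reflects the simulated
mass distribution, and hybrid masses are structurally narrower than
parental masses (an average of two lognormals), so only the
*conditional* trait law given mass is shared between the groups.

## Problem sizes and reproducibility

The test suite simulates cohorts of 25–450 genotypes and checks
recovery with 20–200 Monte-Carlo replicates per property — sizes chosen
so the whole suite completes in well under a minute while keeping the
Monte-Carlo error far below the asserted tolerances. The acceptance
script regenerates 200 cohorts of 450 genotypes from the accession
growth curve (log-scale noise sd 0.1) and reports the median refitted
mass-correction coefficient; its sampling spread at those sizes is a
few percent of the coefficient's magnitude.

```{r pipeline, eval = FALSE}
rep <- run_pipeline(pipeline_config(
  synthetic = TRUE,
  synthetic_config = synthetic_config(n_accessions = 100, n_hybrids = 100,
                                      seed = 1),
  seed = 1, out_dir = "out"))
rep
```

## Known limitations

* The bootstrap classification treats parental means as fixed; parental
  sampling error is not propagated.
* NLDev uses the hybrid's *observed* mass; predicting mass itself from
  the parents (the additive baseline) is available but the main
  pipeline does not chain the two predictions.
* The SMA between-group test is a normal approximation, not the
  likelihood-ratio common-slope test.
* Quadratic heterosis–distance regressions are purely descriptive OLS;
  pair non-independence (shared parents) is ignored, as in the original
  analysis design.
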