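# allohet

Quantify and **predict heterosis from the curvature of allometric
relationships** between plant traits.

## The problem

Heterosis — the deviation of an F1 hybrid's phenotype from its parents —
is usually approached genetically, yet parental genetic distance
typically explains only a few percent of it. `allohet` implements a
geometric alternative: in plants, fitness-related traits such as growth
rate and fruit number are tightly constrained by vegetative dry mass
*M* through nonlinear allometric relationships. If hybrids follow the
*same* curve as inbred accessions and hybrid mass is near-additive,
curvature alone generates heterosis of the downstream traits (Wright's
physiological dominance at the whole-plant level). The package is aimed
at quantitative geneticists and plant breeders working with replicated
accession/hybrid phenotyping panels (the motivating system is
*Arabidopsis thaliana*).

## The model

Two allometries are fitted by nonlinear least squares on the raw trait:

* growth rate: `g(M) = a * M^(b + c*log10 M)` — a power law whose
  exponent declines with log mass (concave in log-log space for c < 0);
* fruit number: `f(M) = M / (a + b*M + c*M^2)` — hump-shaped, peaking
  at `M = sqrt(a/c)`.

Heterosis of a trait *Y* with parental means `Y1, Y2` and hybrid mean
`Y12` is `MPH = (Y12 - mean(Y1,Y2)) / mean(Y1,Y2)` and
`BPH = (Y12 - max(Y1,Y2)) / max(Y1,Y2)`. The curvature-only prediction
(NLDev) evaluates the accession-fitted curve at the parental and hybrid
masses:

```
MP_pred  = (g(M1) + g(M2)) / 2          BP_pred  = max(g(M1), g(M2))
NLDev_MP = (g(M12) - MP_pred)/MP_pred   NLDev_BP = (g(M12) - BP_pred)/BP_pred
```

Around these sit SMA regression (log-log scaling exponents, test
against 3/4), logistic growth-curve fitting, bootstrap classification
of hybrids against parental values, broad-sense heritability
(`H2 = var(G)/(var(G)+var(res))`), genetic/geographic/phenotypic
distance baselines, and a seeded synthetic-data generator for the whole
design.

## Worked example

```r
library(allohet)

# curvature-predicted heterosis for two parents of 10 and 100 mg whose
# hybrid sits exactly at the mid-parent mass (55 mg)
gm <- list(form = "power_mass_corrected",
           coefficients = c(a = 0.022, b = 1.483, c = -0.164))
nldev(gm, m1 = 10, m2 = 100, m12 = 55)
#>   m1  m2 m12   pred mp_pred bp_pred nldev_mp nldev_bp
#> 1 10 100  55 2.6708  2.4752  4.4918    0.079  -0.4054
```

The hybrid is predicted to grow 7.9% faster than the parental mean
(positive mid-parent heterosis from concavity alone) while staying 41%
below the best parent.

```r
cfg <- synthetic_config(n_accessions = 150, n_hybrids = 120, seed = 1)
rep <- run_pipeline(pipeline_config(synthetic = TRUE, synthetic_config = cfg,
                                    n_boot = 300, seed = 1))
rep
#> allohet pipeline report (seed 1, synthetic mode)
#>   780 records: 150 accessions, 120 hybrids
#>   accession growth allometry: a 0.0483, b 1.15, c -0.0866 (dAIC 31.2 vs fixed exponent)
#>   SMA slope 1.018 (r2 0.973)
#>   NLDev (growth_mg_per_d): r2 pred 0.97, MP 0.38, BP 0.57
#>   NLDev (fruit_n): r2 pred 0.24, MP 0.15, BP 0.05
```

Reading the report: the mass-corrected exponent is preferred over a
fixed exponent (positive ΔAIC), its curvature coefficient is negative,
and the accession-fitted curve predicts hybrid growth rate almost
perfectly (r² = 0.97) and a substantial share of growth-rate heterosis
(r² = 0.38/0.57 for NLDev vs MPH/BPH at this cohort size), while the
noisier fruit allometry predicts much less — the prediction quality
tracks the tightness of the underlying trait–mass relationship.

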