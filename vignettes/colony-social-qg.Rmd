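---
title: "Quantitative genetics of the colony social environment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative genetics of the colony social environment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In colonially breeding birds, the number of actively breeding neighbours
around a nest is a compact proxy for the social environment an individual
experiences: it scales competition for space and food, exposure to
conspecific aggression, and opportunities for information transfer. In
long-lived species this social environment may change systematically with
age ("social ageing"), and if individuals — or genotypes — differ in how
fast it changes, the trait can respond to selection. `colonyQG` implements
the full analysis chain needed to ask these questions in a pedigreed colony
monitored over decades: trait construction from mapped nest coordinates,
within-subject partitioning of age, and Bayesian overdispersed-Poisson
animal models including random-regression (reaction-norm) terms.

## The trait and its covariates

The response is the **active-neighbour count**: for a focal female's nest, the
number of other nests on the same island within a 2 m radius whose clutch
was initiated in the four weeks *up to and including* the focal laying date.
Four weeks approximates the laying-to-hatching span during which a pair
attends its nest continuously. Conventions that the literature leaves open
and that we had to fix:

* the activity window is closed at both ends, `[focal - 28, focal]`, so two
  same-day nests count each other while a nest started after the focal date
  never counts (a strictly one-sided window);
* distance ties at exactly the radius count as neighbours (`<=`, not `<`);
* neighbours are restricted to the focal island: the islands are separated
  by walls and a water gap, so cross-island "neighbourhood" is not
  biologically meaningful at a 2 m scale.

Covariates per record: **island density at breeding** (nests initiated on the
focal island in the same four-week window — a radius-infinity version of the
trait), **distance to the nearest wall** (`min(x, 10.7 - x, y, 4.6 - y)` on
the 10.7 x 4.6 m island rectangle, hence in `[0, 2.3]` m), **colony density**
(nests that season, computed from the records), year, and laying date.

Record filters mirror field practice: `known_age` drops all records of
females of unknown age; `presumed_dead` additionally keeps only females not
seen in either of the two most recent seasons, so that lifetime summaries
are not truncated by still-living birds.

## Within-subject centring of age

Population-level age effects confound two processes: individuals changing
with age, and individuals with different trait values entering or leaving
the population at different ages (selective appearance/disappearance). We
split each female's age into her mean age over all her records
(`mean_age`, between-individual) and the annual deviation from that mean
(`delta_age`, within-individual). `age = mean_age + delta_age` holds exactly
row-wise and `delta_age` sums to zero within each female. The posterior
contrast `mean_age - delta_age` is the selective-disappearance test: it is
computed from the joint posterior of the two slopes, not fitted as a
separate term.

Standardization divides by one population standard deviation (denominator
`n`) after mean-centring. A documented switch
(`standardize(x, divisor_sd_multiples = 2)`) provides the Gelman
two-standard-deviation convention; we default to one standard deviation
because "variance-standardized" covariates and "effects per 2 sd" are
mutually inconsistent conventions and the former is the one used for every
other covariate. Actual age is *not* standardized in the partitioned
intercept model (so its slopes are per year of age), but *is* standardized
when used as a random-regression gradient, so that intercept variances
refer to the average age.

## The animal model

Counts are modelled as overdispersed Poisson (Poisson-lognormal):

```
count_i ~ Poisson(exp(eta_i))
eta = X beta + Z_a a + Z_pe pe + Z_yr yr + Z_is is + e
a  ~ N(0, V_A * A)        # additive genetic, A from the pedigree
pe ~ N(0, V_PE * I)        # permanent environment (repeated measures)
yr ~ N(0, V_year * I);  is ~ N(0, V_island * I)
e  ~ N(0, V_resid * I)     # latent overdispersion residual
```

`A` is the additive (numerator) relationship matrix, built by the tabular
method (`A[i,i] = 1 + A[s,d]/2`, `A[i,j] = (A[j,s] + A[j,d])/2`), with the
equivalent sparse factor `A = L L'` (`L = T D^{1/2}` from the
parent-averaging recursion) used inside the sampler so that every random
effect has an iid prior after reparameterization. Founders are assumed
non-inbred; descendants' inbreeding is read off the factor itself.

Derived quantities are formed per posterior sample and then summarized
(never as ratios of summaries): heritability `h2 = V_A / V_P` and
repeatability `R = (V_A + V_PE) / V_P`, with `V_P` the sum of all estimated
random-component variances *including* the overdispersion residual and
excluding fixed-effect variance (latent-scale, conditional on fixed
effects; the proportions then sum to one across components). Evolvability
`CV_A = 100 * sqrt(V_A) / mean(count)` uses the data-scale trait mean — the
natural choice when the trait mean is directly observable; using
`exp(beta0)` instead would make the denominator prior-dependent. The
distribution-specific variance of the log link is deliberately excluded
from `V_P` so that the component percentages remain additive.

### Random regressions

`fit_random_regression()` adds (intercept, slope) pairs over standardized
age: at the individual level with an unstructured 2x2 covariance, or split
into additive-genetic plus permanent-environment levels (G x Age and
PE x Age), the genetic pairs having covariance `A (x) G2`. Because residual
heterogeneity can masquerade as slope variance, these models fit five
residual variances indexed by age quintile (the age-class boundaries are a
package convention; quantile bins with ties to the lower bin keep classes
non-empty). The variance-at-age function
`V(g) = V_int + 2 g COV + g^2 V_slope` is evaluated per sample; at the mean
gradient it equals `V_int` identically. Model comparison uses DIC under the
conditional-deviance convention: the deviance is evaluated at the posterior
mean of the latent predictor, `pD = mean(D) - D(eta_mean)`. DIC for
hierarchical models is representation-dependent; the conditional convention
matches the observation-level focus of the comparison (slopes vs intercepts)
and is stated wherever a DIC is reported.

### Sampler

The engine is Markov chain Monte Carlo with four move types per iteration:

1. a joint Gaussian Gibbs draw of all location parameters (fixed effects
   and every random-effect vector) given the latent predictor, solved
   through the sparse mixed-model normal equations with a supernodal
   Cholesky factorization whose symbolic analysis is computed once;
2. single-site random-walk Metropolis updates of each latent `eta_i`, with
   per-observation proposal scales adapted towards 44% acceptance during
   burn-in and frozen afterwards (preserving detailed balance);
3. conjugate inverse-gamma / inverse-Wishart draws for variances, each
   followed by a parameter-expansion move (a scaled working variable with a
   normal prior), which gives half-t-type marginal priors on standard
   deviations and keeps mixing healthy when a variance approaches zero;
4. a marginalized Metropolis move on the variance components themselves:
   correlated log-scale proposals (their covariance learned Haario-style
   during burn-in) evaluated under the marginal likelihood of the latent
   predictor with *all* location effects integrated out analytically via
   the same sparse factorization. This move is what breaks the strong
   posterior ridge between additive-genetic and permanent-environment
   variance that otherwise dominates the autocorrelation time.

Priors: fixed effects `N(0, 1e8)`; random standard deviations half-Cauchy
with scale 1 (parameter expansion with `nu = 1`), a weakly informative
choice on the latent log scale where total variance is of order 0.5;
residual variances inverse-gamma with `nu = 0.002`; 2x2 working covariance
matrices inverse-Wishart with 3 degrees of freedom and identity scale,
column-scaled by normal working parameters. All hyperparameters are
recorded in `mcmc_config()` and can be changed; a doubling of the
parameter-expansion scale moves variance posteriors by well under 20% at
moderate data sizes (this is tested).

One integer seed in `mcmc_config()` determines the whole chain. Default
chain lengths (`n_iter = 50000`, `burn_in = 8000`, `thin = 35`) are sized so
that variance-component chains reach an effective sample size near 1000
with lag-1 autocorrelation below 0.1 on mid-sized colony data (hundreds of
females, a few thousand records); exploratory fits can use much shorter
chains. Posterior point estimates are KDE modes (narrow 0.2-adjusted
bandwidth with a parabolic peak refinement, robust for skewed variance
posteriors) alongside medians and shortest 95% HPD intervals; convergence
reporting uses initial-positive-sequence effective sample sizes and lag-1
autocorrelations.

## The synthetic colony generator

Every downstream stage is testable without any field data because the
generator produces pedigreed datasets from known parameters
(`true_params()`). It emulates the study system the package targets:

* six 10.7 x 4.6 m islands, nests placed uniformly within islands
  (clustered placement is not modelled — nothing in the data we emulate
  constrains nest-site choice, so uniform is the neutral stand-in);
* 29 annual seasons with colony size ramping between 90 and 740 pairs;
* female ages 2-27 drawn from a geometric-like survival distribution with
  annual survival 0.87 (mean age near 8 years);
* laying date advancing with age (slope -1.1 d/yr around a reference age of
  8, individual noise sd 8.5 d) plus a year-level season-start shock
  (sd 3 d, emulating weather), which together put the annual-mean
  age/laying-date correlation near -0.5;
* overlapping generations: recruits enter at age 2 and descend from pairs
  breeding two seasons earlier with probability 0.8 (the rest are treated
  as immigrant founders), producing pedigrees whose depth grows over the
  study;
* default latent-scale variances (`V_A = 0.20`, `V_PE = 0.155`,
  `V_year = 0.05`, `V_island = 0.005`, `V_resid = 0.14`) chosen so the
  implied proportions (h2 ~ 0.36, PE ~ 0.28, year ~ 0.09, island ~ 0.01)
  are of the magnitude reported for neighbour-density traits in long-term
  colony studies; fixed-effect defaults follow the same logic
  (between-age -0.024, within-age -0.059 per year on the log scale).

Breeding values descend the pedigree by Mendelian-sampling recursion
(founder covariance `G2`; non-founders get the parental mean plus a
deviation with covariance `G2 * (1 - (F_s + F_d)/2) / 2`), which is
linear-time in pedigree size; the stacked values have covariance
`A (x) G2`, verified against the direct construction in tests. Counts are
then drawn from the same Poisson-lognormal model the sampler fits — so
parameter recovery is a genuine inverse problem, while the *geometric*
neighbour counts from the nest maps exercise the trait-construction code
independently.

What the generator does **not** emulate: spatial clustering and
territorial spacing-out of nests, within-season re-nesting, extra-pair
paternity, male phenotypes, cohort effects beyond the year intercepts, and
observation error in coordinates. Passing recovery tests therefore shows
the estimator is correct under the stated model, not that the model
captures every feature of real colony data.

## Numerical conventions and edge cases

* Pedigrees are topologically sorted in the canonical (depth, id) order, so
  the sort is independent of input row order; cycles are reported with an
  explicit cycle path; parents never listed as individuals are promoted to
  founders; duplicate ids are errors.
* "Pedigree depth" counts parent-offspring links along the longest
  founder-to-descendant path (founders = 0). Paternity/maternity counts are
  known-parent links in whatever pedigree is summarized — pruned counts are
  the auditable benchmark because pruning is part of the pipeline.
* The relationship matrix is dense below 3000 individuals and a sparse
  `L L'` product above, with an identical numerical contract (tested).
* Age-class boundaries are exact type-1 quantiles computed from order
  statistics (`ceiling(k n / c)`), avoiding floating-point drift in
  probability grids; ties go to the lower bin.
* Zero-variance chains yield errors (undefined autocorrelation), constant
  samples yield zero-width HPD intervals, and fewer than 100 stored samples
  refuse to produce point summaries.
* The sampler flags non-finite deviances as a sampler failure rather than
  returning silently broken chains.

## Problem sizes used in the test-suite

Oracle-equivalence checks run at full strength (100 random pedigrees
against a memoized kinship recursion; exhaustive O(n^2) neighbour-count
comparison over radii 1-4 m and windows 14/28/56 d). Sampler-dependent
checks run on reduced designs chosen to keep a complete run at desk scale:
parameter-recovery replicates use ~220 females with ~650 records and
chains of 3200 iterations (7 replicates, pooled 95% HPD coverage >= 85%);
genotype-by-age sign recovery uses 6 replicates of ~180 females; the
selective-disappearance contrast is detected on a single larger dataset
(~450 females, ~1800 records). The acceptance script
(`scripts/acceptance.R`) re-runs the full pipeline on a 29-season colony
with 60-240 pairs per season and reports the recomputed quantities as
JSON.

## Known limitations

* DIC is reported under one stated convention; alternative conventions
  (marginal deviance, WAIC) are not implemented.
* The sampler is single-chain; between-chain diagnostics (R-hat) are not
  provided — effective sample size and autocorrelation are the convergence
  currencies here, and seeds make replicate chains cheap.
* No multi-trait models, no male/paternal effects, no genomic relatedness,
  and no A-inverse machinery (the sampler works with the factor of A
  directly).
* The Gaussian identity-link path exists for validation against REML, not
  as a production feature.
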