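---
title: "Modelling offspring survival over generations of captive breeding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling offspring survival over generations of captive breeding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(studsurv)
```

## The question and the data

Conservation breeding programs keep studbooks: one record per animal with
parentage, sex, birth and death dates, birth location and origin (wild-caught
or captive-born). studsurv turns such registries into an answer to a
population-genetic question: *does offspring survival to reproductive
maturity change over generations of captive breeding, once inbreeding and
parental age are accounted for?*

From the pedigree alone we derive, for every offspring with two known
parents, seven predictors:

* **dam and sire generations in captivity** `G`: wild-born animals are `G0`;
  a captive-born animal is the mean of its parents' generations plus one
  (so `G` can be fractional — the offspring of a `G0 x G1` pairing is
  `G1.5`);
* **dam and sire age at the offspring's birth**, in days;
* **dam, sire and offspring inbreeding coefficients** `f`, where `f(x)` is
  the kinship of `x`'s parents computed under the conventions of managed
  pedigrees: wild-born founders are unrelated and non-inbred, and every
  unknown parent is treated as a distinct phantom wild founder ("set unknown
  parents to wild").

The response is a binary label: did the offspring survive to its
sex-specific age at reproductive maturity (the shorter of the two sexes'
ages when sex is unknown)?

## Dataset construction

The construction rules mirror standard studbook practice:

1. **Truncation.** The most recent 364 days of the studbook are dropped
   (recent deaths may not have been entered yet) and the reference date moves
   back accordingly.
2. **Too-young exclusion.** Any individual born within its maturity window
   of the truncated reference date has not had the opportunity to reach
   maturity and is excluded — dead or alive. (Excluding only the living
   would keep early deaths and bias survival downward near the end of the
   record.)
3. **Hybrids**, **wild-born offspring** and animals **released to the wild
   before maturity** (via an optional `release_date` column; absent column
   leaves the filter inert), and offspring with **unknown parents** are
   excluded, each tallied once under the first matching rule.
4. Excluded animals remain in the pedigree as *ancestors*: the filters
   choose analysis rows, they never delete pedigree nodes, otherwise `f` and
   `G` of descendants would be corrupted.
5. **Litters.** Litter-mates (same dam, same day for mammals; same dam, same
   calendar year for tortoise/skink-style clutches) are not independent.
   One offspring per litter is sampled uniformly at random; the sampling is
   repeated (five replicates by default) and all downstream estimates are
   pooled across replicates.
6. **Standardization.** Each predictor is centred and scaled to unit sample
   standard deviation *within species* (per replicate), so species with
   extreme raw scales cannot dominate and coefficients are comparable per
   within-species SD. A within-species constant predictor (a real occurrence:
   reptile studbooks with all parental `f = 0`) is centred but not scaled,
   with a warning — dropping the species would silently change the model.

## The model

The global model is a binomial GLMM on the logit scale:

```
survival ~ dam_generation + sire_generation + dam_age + sire_age +
           dam_f + sire_f + offspring_f +
           (1 | species) + (1 | species:birth_program) + (1 | species:year)
```

The nested random design `(1 | Species/BirthProgram) + (1 | Species:Year)`
is expanded into three independent intercept terms; with species-scoped
program and year labels this is exactly the nested structure, without
cross-classification machinery. Fitting is maximum likelihood via the
Laplace approximation (lme4). An empty random structure reduces the model to
plain logistic regression — the package treats that as "all variances
constrained to zero" and the fit then agrees with an independent
iteratively-reweighted-least-squares oracle to high precision (a tested
invariant).

**Model selection.** All `2^7 = 128` subsets of the fixed terms are fitted
with the random structure held constant and ranked by AICc. Models within 2
AICc of the best are retained (boundary ties retained) and model-averaged by
the *conditional* method: each predictor is averaged only over retained
models that contain it, with Akaike weights renormalized over those models.
The averaged standard error is the revised Burnham–Anderson estimator,
`sum(w * sqrt(se^2 + (b - b_avg)^2))`, which includes between-model spread.
Relative importance is the sum of retained-set weights of models containing
the predictor; we renormalize weights over the retained set (the behaviour
of a subset weight table) and document that choice here because the
convention is not universal. Replicate pooling reports, per predictor, the
mean estimate, the mean SE and `mean ± 1.96 * mean SE`; a pooled CI
excluding zero is flagged as a significant trend at `alpha = 0.05`.

**Species-level effects.** Model averaging cannot produce random slopes, so
per-predictor random-slope models are refitted *from the global model* on a
representative litter-sampling replicate. The slope is species-level and
uncorrelated with the species intercept (identifiable at realistic species
counts; the source analyses are silent on the correlation). The species
effect is fixed slope + species BLUP. Convergence failures are reported, not
forced — they genuinely occur when between-species slope variation is
negligible (sire age at breeding is the canonical example). "Representative"
is defined operationally as the replicate whose averaged estimates have the
smallest summed absolute deviation from the pooled means; this is a
documented stand-in, not a claim about how any particular study chose its
subset.

**Diagnostics.** Simulation-based randomized-quantile residuals (DHARMa
style): each observation's scaled residual is its tie-randomized position
among 250 unconditional simulations from the fitted model. We report a KS
uniformity test, a non-parametric dispersion ratio with a simulation
p-value, a zero-inflation ratio with a simulation p-value, and an outlier
test. The outlier test is one-sided (excess only): with a Bernoulli
response the simulated range is almost always `{0, 1}`, so a two-sided test
against the `2/(n_sims+1)` expectation would flag a *deficit* of outliers on
any well-specified model. Variance inflation factors (`1/(1-R^2)` from
regressing each predictor on the rest) flag values at or above 2.

**Phylogenetic signal.** Pagel's lambda multiplies the off-diagonal of the
Brownian-motion covariance of a rooted, branch-length tree. The Gaussian
likelihood is profiled (mean and rate analytic via GLS through a Cholesky
solve) and lambda is maximized on `[0, 1]` by bounded 1-D search (tolerance
`1e-8`). Because `lambda = 0` sits on the parameter boundary, the LRT null
is the equal mixture of a point mass at 0 and chi-square(1); the reported
p-value is `0.5 * P(chisq_1 >= LRT)` (1 when the LRT is zero). Trees
without branch lengths (topology-only synthesis trees) get unit lengths with
a warning. A star phylogeny makes the likelihood flat in lambda; the fit
returns an explicit "unidentifiable" flag rather than an arbitrary interior
value. Signal is assessed for species mean survival and for each
predictor's vector of species-level effects.

## The synthetic studbook generator

Real studbooks are proprietary, so the package carries a forward simulator
(`simulate_studbook()`) whose output is a valid studbook CSV plus the full
generative ground truth. Per species and year: occasional wild intakes
(G0 founders who enter as adults and live one to three maturities in the
program), pairing of mature living animals under a mating policy (kin
avoidance by default, as practiced; `prefer_kin` available to manufacture
inbreeding), litters sharing a dam and birth event (same-day mammal litters,
same-year reptile clutches spread over weeks), and Bernoulli survival with

```
logit p = intercept + species intercept + program effect + year effect +
          sum_j (beta_j + species deviation_j) * z_j
```

where `z_j` are the seven predictors standardized against *running*
within-species moments (10-offspring burn-in, values clamped to ±4). Running
moments — rather than final two-pass moments — are used because survival
feeds back into demography (dead juveniles cannot breed), so labels must be
drawn at birth; realized moments converge to the final ones, keeping
`beta_j` interpretable per within-species SD. Death dates are assigned so
the pipeline's labels recover the simulated outcomes exactly (survivors die
after maturity or are alive at studbook close; non-survivors die at a
uniform age below maturity), and the simulator's inbreeding bookkeeping uses
the same phantom-founder convention as the pipeline, so pedigree-computed
`f` reproduces the internal values exactly — both are tested invariants.

Default parameters describe a large managed multi-species dataset: 15
species (a fifth reptile-like), ~30 founders each, 60 years, litter mean
2.5, two-year maturity, weak generation effects, opposing modest parental
age effects (−0.06 dam, +0.06 sire per SD), near-zero parental-`f` effects
and offspring inbreeding depression of −0.16 per SD, species intercept SD
0.5, program and year SDs 0.2, and moderate species-slope heterogeneity
(0.15 SD on the generation slopes, smaller elsewhere). These are the
conditions a practitioner would call realistic for long-running zoo
programs; tests that need speed shrink the *size* parameters, never the
acceptance bars.

What the generator does **not** emulate: age-specific fecundity and
senescence, seasonality, parity effects, maternal/epigenetic mechanisms,
transfer histories (an animal keeps its birth program), and genotype-level
realism behind `f`. A green end-to-end test therefore establishes that the
pipeline recovers effects expressed through the stated generative model — it
does not validate those biological mechanisms.

## Numerical and design choices

* Dates are ISO-8601; all ages and durations are integer days. The studbook
  reference date is the latest date on file unless given explicitly.
* Kinship is memoized Karigl-style recursion; a tabular full-matrix path is
  provided and the two agree to 1e-12 (tested). Recursion keys on
  topological depth, which also detects parent-link cycles.
* Wright's `Ne = 4 Nm Nf / (Nm + Nf)` over distinct recorded breeders is an
  approximation to what pedigree-management software prints; equality with
  any particular program's output is not asserted.
* Wild-born animals are founders even when parents are recorded: their
  ancestry is zeroed for `f`, kinship and `G`. A `wild_as_founder = FALSE`
  switch restores recorded ancestry for sensitivity checks.
* GLMM convergence messages from the optimizer are recorded on the fit
  object; only hard fitting errors mark a dredge sub-model as failed
  (excluded from the weights with a warning). `|beta| > 15` on standardized
  data triggers a separation warning.
* `nAGQ = 0` (penalized-least-squares only) is exposed for large all-subsets
  screens; the default everywhere is the Laplace fit, `nAGQ = 1`.
* Litter-year for the same-year rule is the calendar year of birth; the Year
  random factor is likewise the offspring's calendar birth year.
* Seeds: one user seed per entry point; litter-replicate seeds are derived
  as `base_seed + 1, ..., base_seed + n` and logged in the run manifest.
  Seeded package functions restore the caller's RNG state.
* Parental age is measured at the offspring's *birth* (not conception), by
  date arithmetic; birth region only (no transfer histories).

## Known limitations

* Pedigree `f` understates true inbreeding when founders are in fact
  related; molecular estimates would be needed to do better.
* The Laplace approximation can bias variance components on sparse binary
  groups; the Wald-coverage test in the suite runs with a deliberate slack
  (≥ 80% at nominal 95%).
* Missing parents are excluded, not imputed (no multiple imputation), and
  the leverage-based outlier trimming used in some sensitivity analyses of
  real datasets is data-specific and out of scope.
* The extended (no litter sampling) run ignores litter non-independence by
  construction; it is a qualitative sensitivity check, not the headline
  analysis.
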