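---
title: "Variance components and continuous gene-environment interaction in family studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance components and continuous gene-environment interaction in family studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famgxe)
```

## The problem

Metabolic-syndrome traits (waist circumference, blood pressure, fasting
glucose, lipids) aggregate in families, and their expression may depend on how
physically active each family member is. famgxe implements the
quantitative-genetic machinery to ask two questions on nuclear-family data:

1. How much of the phenotypic variance is additive-genetic (heritability)?
2. Does the genetic architecture itself change with total daily energy
   expenditure (TDEE) — a continuous genotype-by-environment (GxE)
   interaction?

## The polygenic variance-components model

Let $y$ be a trait score and $\Phi$ the kinship matrix of a pedigree. Within a
family, scores are modelled as multivariate normal with

$$\Omega = 2\Phi\,\sigma^2_g + I\,\sigma^2_e ,$$

where $\sigma^2_g$ is the additive genetic variance and $\sigma^2_e$ the
residual environmental variance. Heritability is
$h^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_e)$. Families are independent, so
the log-likelihood is a sum of small dense Gaussian blocks; `fit_polygenic()`
maximizes it by bounded quasi-Newton on $(\mu, \log\sigma^2_e, \sigma^2_g)$
with $\sigma^2_g$ box-constrained at 0, so the no-heritability boundary is a
reachable point of the parameter space. The test of $h^2 = 0$ is a boundary
likelihood-ratio test with null $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$.

The relationship matrix $2\Phi$ comes from the recursive tabular method
(`kinship_matrix()`), processing parents before children:
$\phi_{ii} = \tfrac12(1 + \phi_{f_i m_i})$ and
$\phi_{ij} = \tfrac12(\phi_{f_i j} + \phi_{m_i j})$. Inbreeding appears on the
diagonal as $1 + f$. Two independent oracles check it in the test suite: exact
enumeration of all Mendelian transmission configurations (feasible for small
pedigrees, exact to machine precision) and Monte-Carlo gene dropping
(`gene_drop_kinship()`).

## The continuous GxE model

With an environmental index $q$ (standardized TDEE) per person, both variance
components become log-linear functions of the environment and the genetic
correlation between relatives decays with their environmental distance:

$$\sigma^2_g(q) = e^{\alpha_g + \gamma_g q}, \qquad
  \sigma^2_e(q) = e^{\alpha_e + \gamma_e q}, \qquad
  \rho_g(q_i, q_j) = e^{-\lambda |q_i - q_j|},$$

giving the family covariance

$$\Omega_{ij} = 2\Phi_{ij}\,\rho_g(q_i,q_j)\,\sigma_g(q_i)\,\sigma_g(q_j)
  + \delta_{ij}\,\sigma^2_e(q_i).$$

The exponential keeps variances positive for any slope, and the two
no-interaction nulls are points of this family: $\gamma_g = 0$ is variance
homogeneity and $\lambda = 0$ is a genetic correlation of exactly 1 ("the same
genes act at every activity level"). With
$\gamma_g = \gamma_e = \lambda = 0$ the model collapses to the polygenic one,
which is both a sanity check (tested to $10^{-6}$) and the reduced model of
the overall interaction test.

### Hypothesis tests

Boundary parameters make the usual $\chi^2$ calibration wrong, so
`standard_contrasts()` carries the correct mixture nulls:

| contrast | constraint | null |
|---|---|---|
| `variance_homogeneity` | $\gamma_g = 0$ | $\chi^2_1$ |
| `genetic_correlation_one` | $\lambda = 0$ | $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ |
| `full_vs_polygenic` | $\gamma_g=\gamma_e=\lambda=0$ | $\tfrac12\chi^2_2 + \tfrac12\chi^2_3$ |
| `h2_zero` | $\sigma^2_g = 0$ | $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ |

The full-vs-polygenic null mixes $\chi^2_2$ and $\chi^2_3$ because three
parameters are freed of which one ($\lambda$) sits on its boundary. This form
is validated empirically in two ways: it reproduces published p-values from
published statistics of a study using the same contrast (0.877 at $T=0.408$;
0.004 at $T=12.601$), and simulation under the polygenic null holds the
nominal 5% size within exact binomial bounds.

## From activity diaries to TDEE

The 3-day diary records the dominant activity of each 15-minute period on a
9-category intensity scale. `tdee_from_diary()` computes

$$\mathrm{TDEE} = w \cdot \tfrac13 \sum_{c=1}^{9} n_c \, \kappa_c
  \quad \text{(kcal/day)},$$

with $w$ body weight (kg), $n_c$ the period count of category $c$ over the
three days, and $\kappa_c$ the category's median energy cost in kcal/kg per
15 minutes. The nine costs are a required configuration input; the defaults in
`energy_cost_table()` (0.26 ... 1.95) are external constants from the
Bouchard diary literature, not values estimated here — replace them when a
study has its own calibration. Precomputed TDEE can be supplied directly,
bypassing the diary entirely.

TDEE enters the interaction model standardized (`standardize_tdee()`, mean 0,
SD 1): raw values of 2000-3500 kcal/day inside $e^{\gamma q}$ would overflow
or force minuscule slopes. Because the model's likelihood is invariant under
$q \to q + c$, $\alpha \to \alpha - \gamma c$ (a tested identity), the
standardization changes the parameterization, not the model; slopes and the
decay rate are additionally reported per 1000 kcal/day (`tidy()` on a
`gxee_fit`) for interpretability. Whether the original study entered TDEE raw
or rescaled is not stated anywhere we could check, which is exactly why both
scales are reported.

## Trait preparation

Traits are adjusted before modelling: OLS on
$\{1, \text{sex}, \text{age}, \text{age}^2, \text{age}\times\text{sex},
\text{age}^2\times\text{sex}\}$, then a rank-based inverse normal
transformation of the residuals using Blom fractions,
$\text{probit}\big((r - 3/8)/(n + 1/4)\big)$, ties sharing average ranks. The
full interaction set is the default because published covariate lists of this
kind rarely state a selection rule; `interactions = character(0)` drops them,
and the rank offset is configurable (0, 3/8, 1/2). Parents and offspring are
adjusted in one pooled regression, mirroring a single preliminary model;
missingness is handled by listwise deletion per trait with excluded ids
recorded — never imputation. The genetic models then carry only a grand mean.

A consequence worth knowing: the inverse normal transformation fixes the
marginal distribution of the scores, which *partially attenuates variance
heterogeneity* — the very signal $\gamma_g$ measures. In simulations at 300
families with a generating $\gamma_g = 0.5$, the variance-homogeneity test
run through the full pipeline has roughly 70% power (the overall
full-vs-polygenic test stays near 100%). The test suite's power check is
therefore a regression guard at 50%, not a statistical claim.

## The synthetic study generator

`simulate_study()` produces the fixture bundle every stage consumes, shaped
like a nuclear-family field study of 294 families and ~958 participants:

* both parents exist in every pedigree; offspring counts 1-4 with mean 1.79;
* participation thinning per role (fathers 180/294, mothers 253/294,
  offspring always) reproduces the 180/253/265/260
  father/mother/son/daughter profile in expectation, with at least two
  participants per family (redrawn otherwise, mirroring a recruitment rule);
* TDEE is drawn from role-conditional normals (fathers 3561.79 ± 962.71
  kcal/day, mothers 2788.37 ± 527.58, sons 2280.57 ± 774.43, daughters
  2024.85 ± 568.43) truncated below at 500 kcal/day to exclude nonphysical
  draws; offspring ages are uniform 10-18, parent ages normal around the
  study means; body weights are role-conditional normals (means 78/65/55/48
  kg), needed only for diary round-trips;
* optional diaries are built greedily to reproduce each drawn TDEE within one
  15-minute period's cost; draws below a subject's all-resting minimum are
  redrawn and counted;
* traits are drawn family-wise from the *same* covariance builder the
  likelihood uses (`gxee_covariance()`), plus configurable age/sex mean
  effects, so parameter-recovery tests close the loop generator -> fitter.

What the generator does **not** emulate: assortative mating, shared-household
environmental correlation, measurement error in the diary, non-Gaussian trait
tails (beyond what the inverse normal transform would remove anyway), or
marker genotypes. Passing tests therefore demonstrate internal consistency of
the method at field scale — not robustness to those real-data features.

## Numerical choices

* Optimization: `L-BFGS-B` with relative tolerance `factr = 1e6`, finite
  difference steps `1e-5`, multi-start (heritability splits 0.2/0.5; slopes
  $\{-0.5, 0, 0.5\}$; decay $\{0, 0.1, 1\}$; best three refined). The
  pipeline warm-starts constrained fits from the full solution and refits the
  full model from any submodel that beats it, so nesting
  ($\ell_{full} \ge \ell_{reduced}$) holds to $10^{-6}$ by construction.
* LRT statistics: negative values above $-10^{-6}$ are clamped to 0 (boundary
  solutions), larger violations raise an optimizer-failure error rather than
  producing a bogus p-value.
* $h^2$ standard errors: inverse observed information (numerical Hessian in
  the natural parameterization) with the delta method; reported `NA` on the
  boundary where Wald theory fails. Confidence intervals are Wald
  $h^2 \pm 1.96\,SE$ truncated to $[0,1]$ — interval methods differ across
  software and published tables of this kind often cannot be reproduced from
  their own printed SEs, so intervals here are explicitly Wald and labelled.
* Degenerate inputs fail loudly: constant TDEE (interaction unidentifiable),
  constant traits or zero residual variation, all-equal inverse-normal input,
  fewer than two informative families, phenotyped ids missing from the
  pedigree (silent drops would corrupt likelihoods).

## Problem sizes in the test suite

The suite exercises the models at the scales a single CPU handles in minutes:
exact kinship oracles on pedigrees up to 12 members; dense-MVN likelihood
cross-checks on 100 random family configurations; parameter recovery at 500
families x 50 replicates (each parameter's mean within 3 Monte-Carlo SEs of
truth); test size under the null at 100 families x 500 replicates (exact
binomial bounds around 5%); gene dropping at 200,000 drops. These sizes are
the package's own choices for routine verification; nothing prevents larger
runs.

## Known limitations

* The environmental correlation across TDEE is fixed at identity; only the
  genetic correlation gets the exponential decay, following the model this
  package implements. Discrete-environment GxE and marker-level interaction
  are out of scope.
* TDEE is not in the mean model by default (means are cleaned of age/sex
  only); that is a deliberate mirror of the two-stage design, and a mean
  effect of TDEE can be probed by adding it as a covariate upstream.
* $\gamma_e$ is always estimated and reported, never dropped for
  non-significance.
* The inverse normal transformation attenuates variance-heterogeneity signal
  (see above); analyses on the latent scale recover generating parameters
  without that attenuation.
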