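---
title: "Estimating mating systems from progeny arrays: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mating systems from progeny arrays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matingkit)
```

`matingkit` implements a family-level analysis of plant mating systems from
progeny-array microsatellite genotypes, built around the questions raised by
two contrasting populations of an annual, self-compatible desert plant: how
much does each maternal lineage self, how does that relate to herkogamy
(the pistil–stamen separation that physically modulates self-pollination),
and what do inbreeding coefficients across generations say about selection
against inbred offspring (purging)?

## The mixed-mating model and its EM estimator

The core model is classical mixed mating: each offspring of a maternal
plant is produced by self-fertilization with probability $s$ or by
outcrossing to a population-wide pollen pool with probability $t_m = 1-s$.
For one offspring with multilocus genotype $g$ and known (or inferred)
maternal genotype $m$,

$$P(g \mid s) = s \prod_l P_\text{self}(g_l \mid m_l)
             + (1-s) \prod_l P_\text{out}(g_l \mid m_l, p_l),$$

where $P_\text{self}$ enumerates Mendelian gamete pairs from the mother,
$P_\text{out}$ combines one Mendelian maternal gamete with one pollen
gamete drawn from the population allele frequencies $p_l$, and the product
runs over the loci scored for that offspring (missing loci simply drop out
of the product — this is what makes the EM formulation convenient with
missing data). The assumptions worth stating: loci are unlinked and in
linkage equilibrium; the pollen pool is shared across families and constant
within a population; there is no biparental inbreeding or correlated
paternity in the model (a family's "outcrossed" offspring are independent
draws from the pool).

`em_estimate()` runs the standard EM: the E-step computes each offspring's
posterior probability of being selfed,
$z_i = s L_{\text{self},i} / (s L_{\text{self},i} + (1-s)L_{\text{out},i})$,
and the M-step sets $s \leftarrow \bar z$. Because
$\log L(s) = \sum_i \log\bigl(L_{\text{out},i} + s(L_{\text{self},i} -
L_{\text{out},i})\bigr)$ is a sum of logs of affine functions of $s$, it is
concave: the EM fixed point is the global maximizer, and the test suite
verifies agreement with an exhaustive grid search of the same likelihood
computed by independent gamete enumeration.

Numerical choices: $s$ is clamped to $[10^{-9}, 1-10^{-9}]$ during
iteration (the E-step is undefined at the exact boundary) and snapped to an
exact 0 or 1 when within $10^{-6}$ at convergence, because real families do
sit at the boundaries and reporting $t_m = 1$ rather than $0.999999$
matters downstream. Convergence is declared on the log-likelihood change
(default tolerance $10^{-8}$); the degenerate single-locus case of a
heterozygous mother with an evenly split pollen pool makes the two kernels
identical and the likelihood exactly flat, in which case the estimate
honestly stays at its starting value and converges immediately.

A locus at which an offspring shares no allele with its mother has zero
probability under *both* kernels (pollen-pool smoothing guarantees the
outcross kernel is otherwise positive). Such mother–offspring mismatches —
in real data a signature of null alleles or scoring error — are demoted to
missing for that offspring–locus pair and counted in `n_mismatch_loci`.
Modeling null-allele frequencies jointly with $s$ is deliberately out of
scope; the count gives users the raw material to judge whether a locus
misbehaves.

### Maternal genotypes and the pollen pool

Mothers are typically not genotyped in progeny-array designs. When an
array lacks a maternal genotype, `infer_maternal_genotype()` scores every
unordered pair of alleles seen in the family or the population by the
mixed-mating likelihood of the entire offspring set at a fixed reference
$s = 0.5$ — neutral between the two kernels, so the inference does not lean
on the family's own, yet-to-be-estimated selfing rate — times a
Hardy–Weinberg prior from the pollen frequencies. Ties break toward the
higher-prior genotype, then lexicographically.

The pollen pool (`build_pollen_pool()`) pools allele counts from the
population's maternal genotypes and adds 0.5 to the count of every allele
observed anywhere (mothers or offspring) before renormalizing. The
smoothing guarantees every offspring allele has positive outcross
probability, so a zero outcross kernel can only mean a genuine mismatch.
The pool is estimated once per population and held fixed during each
family's EM and bootstrap — families stay independent, which is what makes
resampling individuals *within* families a valid bootstrap.

### Bootstrap

`bootstrap_family()` resamples offspring with replacement within the
family and re-runs the EM per replicate (maternal genotype and pollen pool
fixed). The standard error is the standard deviation of the $t_m$
replicates; the confidence interval is the 2.5/97.5 percentile interval.
Replicates with no informative offspring are redrawn up to 10 times, then
dropped with a warning. With a single replicate the SE is reported absent
rather than zero.

## Inbreeding across generations

The adult-cohort inbreeding coefficient $F$ is the heterozygosity deficit
$1 - H_\text{obs}/H_\text{exp}$ with the small-sample correction
$H_\text{exp} = \frac{2n}{2n-1}(1 - \sum \hat p^2)$, combined across
polymorphic loci as a ratio of sums. The ratio-of-sums form is stable for
the small per-lineage samples this summary is applied to; monomorphic loci
carry no information about heterozygosity deficit and are excluded (and
counted). A variance-components $F$ (Weir–Cockerham style) would be
preferable for hierarchical population samples, but that is not the design
here.

Under constant mixed mating the progeny cohort equilibrates at
$F_e = (1 - t_m)/(1 + t_m)$. The gap $F_e - F$ indexes selection against
inbred individuals between the progeny and adult stages: if inbred
offspring die before adulthood, adult $F$ stays below the equilibrium
value. `inbreeding_summary()` reports the gap two ways: per family
($F_e$ from the family's $t_m$; $F$ from the family's progeny genotypes,
which is *not* an adult-cohort quantity and is labelled as such) and at the
population level as $\overline{F_e} - \overline{F}$, the default report.
How a per-lineage adult $F$ should be computed when only seedlings were
genotyped is genuinely under-specified in this design; exposing both modes
rather than guessing is the package's resolution.

## Inbreeding depression and the primary selfing rate

The paired self/outcross pollination experiment yields
$\delta = 1 - \bar w_s / \bar w_o$, with per-fruit fitness the product of
seed-set (seeds/ovules) and per-seed mass. Only mothers with at least one
fruit in each treatment enter the estimate. "Mean fitness" is the mean of
per-fruit products rather than the product of treatment means: it is well
defined under unbalanced fruit counts and preserves the within-mother
pairing; the alternative (average within mother first) is available via
`mother_level = TRUE` since the original description is ambiguous on this
point. Negative $\delta$ (outbreeding depression) is reported as-is.

Marker-based selfing rates are measured *after* early inbreeding
depression has culled selfed zygotes, so they underestimate selfing at
fertilization. The primary selfing rate inverts that culling:
$$r = \frac{s}{1 - \delta + s\delta},$$
which is exactly the inverse of the thinning map
$s = r(1-\delta)/(1 - r\delta)$; the package verifies the round trip to
$10^{-12}$. $\delta$ is estimated per population and applied uniformly to
that population's families.

## The statistical layer

* **Variance components** (`variance_components()`): one-way
  random-intercept model with plant as the random factor, fitted by REML
  (`nlme::lme`) on possibly unbalanced flower counts. In the balanced case
  REML coincides with the expected-mean-squares ANOVA estimates, which is
  asserted in tests to $10^{-6}$. The fully degenerate case (zero
  within-plant variance) is detected before fitting.
* **Beta regression** (`beta_regression()`, `select_link()`): the primary
  selfing rate is a proportion, so its regression on herkogamy uses the
  beta likelihood in mean–precision form, shape parameters $\mu\phi$ and
  $(1-\mu)\phi$, with $\mu$ linked to the predictor by logit, log or
  cloglog and constant $\phi$ fitted on the log scale by BFGS. Standard
  errors come from the inverse observed information; AIC counts all three
  parameters. Families at exact 0 or 1 — which real data contain — cannot
  be scored by a beta density, so the standard compression
  $y' = (y(n-1) + 0.5)/n$ is applied, only when boundary values are
  present, and the fit records that it fired. This is the single most
  consequential undocumented choice in reproducing the original analysis.
  The "log" link is implemented as a mean link (the natural reading; the
  precision submodel has no covariates because a single $\phi$ is
  reported). Link selection is by minimum AIC over {cloglog, logit, log},
  ties toward logit, with the full AIC table returned.
* **Gaussian GLM, ANCOVA, correlation**: thin, typed wrappers over
  `stats::lm` (identity link, t-based p-values), `car::Anova` type-II
  marginal F-tests for population + herkogamy models (interaction behind a
  flag), and `stats::cor.test`.
* **Association matrix** (`association_table()`): pairwise estimates above
  the diagonal and SEs below, over (r, herkogamy, F, Fe, Fe−F). The
  r–herkogamy cell is the link-selected beta regression; cells pairing r or
  herkogamy with the inbreeding summaries are Gaussian slopes; Fe, F and
  Fe−F are deterministically entangled with each other, so those cells are
  `na`. No multiplicity correction is applied across cells.

## The synthetic-data generator

The generator exists so that every stage can be validated by parameter
recovery under the study's own design, and its defaults *are* that design:

* Two populations. "CM": 27 families, 5 loci, mean herkogamy −4.72 mm with
  total SD 5.5 mm split 50.6% among / 49.4% within plants,
  $\delta = 0.09$. "Map": 29 families, 6 loci, mean herkogamy +2.57 mm
  with total SD 11.15 mm split 77.3% / 22.7%, $\delta = 0.25$. Both: 20
  genotyped progeny per family, 5 alleles per locus with Dirichlet(1)
  frequencies, adult $F = 0$, 2% missing genotype calls, 4–6 measured
  flowers per plant.
* Family selfing is tied to the plant's true mean herkogamy through a
  logistic link with negative slope (−0.15 per mm; intercepts 0.17 and
  −0.38 chosen so the population mean selfing rates sit near the two
  study populations' published values of roughly 0.71 and 0.32). The
  original study reports the sign of the association, not a mechanism;
  the logistic link is the simplest monotone map onto $[0,1]$.
* Selfed zygotes are culled before genotyping with probability
  $\delta_\text{true}$ and redrawn until the array reaches its size —
  mirroring the fact that genotyped seedlings are a post-germination
  sample — which is precisely what makes the realized marker-based $s$
  smaller than the generating $r$ and gives the correction something real
  to undo.
* The crossing experiment simulates 100 candidate mothers with 2 flowers
  per treatment, 0.8 fruit set (mothers missing a treatment drop out, as
  in the greenhouse), Beta-distributed seed-set (outcross mean 0.8,
  precision 30) with the self-treatment mean reduced by $1-\delta$, and
  truncated-normal per-seed mass (9 ± 1.5 mg) common to both treatments —
  so the fitness ratio recovers $1-\delta$ in expectation and the
  depression signal lives in seed-set, the component the experiment
  measures most directly.
* An optional null-allele mode silently de-amplifies one allele per locus
  to stress-test mismatch handling; it is off by default.

What the generator does **not** emulate — and what passing recovery tests
therefore cannot certify on real data: biparental inbreeding and
correlated paternity, spatial or temporal pollen-pool structure, linkage,
genotyping error other than missingness and (optionally) null alleles, and
any environmental covariance between herkogamy and fitness. Simulated
recovery shows the estimators are correct under the model's assumptions,
not that the assumptions hold in the field.

## Problem sizes used in validation

Test and acceptance runs use the study-scale design throughout: 25 random
small instances (≤ 3 loci, ≤ 10 offspring) for exact EM-vs-grid agreement;
30 families × 20 progeny × 6 loci spanning $s \in \{0, 0.25, 0.5, 0.75,
1\}$ for recovery error; 300 families (three independent 100-family
populations) at $s = 0.5$ with B = 200 bootstrap replicates for interval
coverage; 500-mother crossing experiments for $\delta$ recovery at 0.09
and 0.25; 200 seeded study replicates for the r-correction comparison; and
2000 replicates at n = 500 for beta-regression interval calibration. The
two-population pipeline at full study scale with B = 200 completes in
well under five minutes on one CPU.

## Known limitations

* The estimator family is per-family mixed mating only: no single-locus
  $t_s$, no $t_m - t_s$ biparental-inbreeding statistic, no correlated
  paternity. Families are treated as one pollen-pool draw per offspring
  even though real arrays pool several fruits.
* The pollen pool is estimated from (inferred) maternal genotypes with
  additive smoothing, not jointly re-estimated within the EM; with few
  families this adds a small amount of noise relative to a joint
  estimator.
* Greenhouse $\delta$ is early-acting only (seed-set × seed mass) and
  likely underestimates field inbreeding depression; the primary-selfing
  correction inherits that conservatism.
* The among-plant share of herkogamy variance from ~29 plants has a
  sampling SD of roughly 0.07; single-population point estimates of that
  proportion should be read with that width in mind.
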