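---
title: "Dyadic relatedness, kin classification, and kin effects on residence: models and design choices"
author: "kindyad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dyadic relatedness, kin classification, and kin effects on residence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

kindyad answers a question that arises in studies of social mammals with
male dispersal: given multilocus microsatellite genotypes and longitudinal
group-membership records, which pairs of males are kin, and does having
kin around change how long a male stays in a group and how long he holds
high rank? This vignette is the package's own account of the models it
fits, the parameters that matter, and the choices made where the design
was genuinely open.

## The dyad likelihood and the DyadML estimator

For a non-inbred pair of diploid individuals, the genetic state of a
locus is summarised by the IBD coefficients $(k_0, k_1, k_2)$: the
probabilities that the pair shares 0, 1 or 2 alleles identical by
descent. The relatedness coefficient is $r = k_1/2 + k_2$. Canonical
pedigree categories sit at fixed points of the simplex: unrelated
$(1,0,0)$, half-siblings $(\tfrac12,\tfrac12,0)$, full-siblings
$(\tfrac14,\tfrac12,\tfrac14)$, parent–offspring $(0,1,0)$.

Conditional on the IBD state, genotypes are generated from the population
allele frequencies $p$: in state 2 both genotypes equal $\{x,y\}$ with
$x,y \sim p$; in state 1 the genotypes are $\{x,y\}$ and $\{x,z\}$ with a
shared gene $x$; in state 0 all four genes are independent. Genotyping
error is modelled as a per-locus, per-individual replacement event: with
probability $e$ the observed genotype is a fresh Hardy–Weinberg draw.
Because the marginal distribution of each genotype is Hardy–Weinberg
under every state, the error mixture has the closed form

$$\Pr(g_1,g_2 \mid k, e) \;=\; \sum_s k_s\left[(1-e)^2 P_s(g_1,g_2) +
\bigl(1-(1-e)^2\bigr)\,H(g_1)H(g_2)\right],$$

where $P_s$ is the state-conditional pair probability and $H$ the
Hardy–Weinberg genotype probability. `locus_pair_loglik()` implements
exactly this enumeration; the test suite verifies it against a mechanical
enumeration of the generative process and checks that it sums to one over
all genotype pairs.

`dyadml()` maximises the product of per-locus likelihoods over the
$(k_0,k_1,k_2)$ simplex and reports $\hat r = \hat k_1/2 + \hat k_2$,
which lies in $[0,1]$ by construction. The per-dyad log-likelihood is a
sum of logarithms of functions linear in $k$, hence concave on the
simplex; the optimiser is therefore a deterministic coarse grid (step
0.02, containing the four category vertices) followed by a Nelder–Mead
polish, rather than the multi-start searches sometimes used when
multi-modality is suspected. Tests compare it against a dense
(step 0.01) grid search. Allele frequencies are always supplied
externally — in a field study they come from the full genotyped sample,
never from the dyad itself. Missing loci are skipped; dyads with fewer
than `min_loci` (default 8) usable loci are refused rather than
estimated badly. The non-inbred feasibility constraint
$k_1^2 \ge 4 k_0 k_2$ is not imposed by default (the common convention
for this estimator); `constrain_noninbred = TRUE` enables it.

The symmetrised Queller–Goodnight moment estimator
(`queller_goodnight()`, numerator and denominator pooled over loci and
both orientations) is provided as the comparison point:
it is unbiased but noisier, and `benchmark_estimators()` reproduces the
selection exercise — mean, variance and MSE per relationship category
plus the pooled correlation of estimates with expected values — that
justifies using the likelihood estimator for downstream classification.

## Power of relationship inference

`pw_r()` measures, by simulation, the power to tell a primary
relationship hypothesis from a null one: simulate dyads under both
hypotheses, score each with the fixed-hypothesis log-likelihood ratio
$\log L(k_\text{primary}) - \log L(k_\text{null})$, place the rejection
threshold at the $(1-\alpha)$ empirical quantile of the null scores, and
report the fraction of primary scores strictly above it (ties count as
non-rejection). Two numerical choices matter:

* the statistic is the *fixed*-hypothesis ratio, not a ratio of fitted
  likelihoods — the two-simple-hypotheses framing that matches a stated
  confidence level; and
* the threshold is an order-statistic (type-1) quantile, because the
  null scores legitimately contain $-\infty$ (an unrelated dyad can be
  impossible under a parent–offspring hypothesis at $e=0$), and
  interpolated quantiles are undefined across infinities.

At the package's reference panel (18 loci, 8 equifrequent alleles),
parent–offspring vs unrelated power saturates at 1.00, while
half-sibling vs unrelated power is about 0.84 — imperfect, which is
precisely why classification needs explicit error-rate-aware cutoffs.

## Classification rules A1 and A2

Two cutoff constructions are implemented:

* **A1** (`a1_cutoff()`): from relatedness estimates of *known* related
  dyads (pedigree-confirmed maternal half-sibs, paternity-confirmed
  paternal half-sibs), retain the top `retain_fraction` (default 85%) of
  the empirical distribution; the threshold is its 15th percentile, and
  the boundary is inclusive. "Top 85 percentile" is read as retaining
  85% of known kin — the reading under which the rule's false-negative
  rate among known kin is 15% by construction.
* **A2** (`a2_cutoffs()`): from *simulated* half-sibling and unrelated
  estimate distributions, take the lower 5% quantile of the related
  distribution and the upper 5% quantile of the unrelated one, with an
  unassigned exclusion zone between them and exclusive boundaries.

Quantiles for cutoffs use linear interpolation between order statistics
(R type 7) — cutoffs are sensitive to the convention, so it is fixed and
documented.

A point the implementation had to settle: with a moderately informative
panel the two simulated distributions overlap enough that the "zone" can
*invert* — the related band's lower edge falls below the unrelated
band's upper edge (at the reference panel: HS 5th percentile ≈ 0.09, UR
95th percentile ≈ 0.17, consistent with half-sib power ≈ 0.84).
`a2_cutoffs()` warns when this happens. For classification, an estimate
falling in the overlap satisfies both the "looks related" and the
"looks unrelated" test; kindyad treats such ambiguous evidence as
unassigned. This resolution reduces exactly to the plain rule whenever
the zone is proper, keeps `classify()` monotone in $r$, and guarantees
by construction that at most the tail mass of unrelated dyads is ever
labelled related.

`validate_classification()` reproduces the bookkeeping used to report
rule performance on known-related pairs (counts and half-up
two-decimal percentages), and `mendelian_check()` provides the
allele-sharing compatibility test (default tolerance: one mismatching
locus, allowing a single genotyping error or null allele) used to
confirm maternal links.

## Synthetic data: what it emulates, and what it does not

No genotypes or field records ship with the package; generators stand in
for them and are first-class, tested code.

* `gen_frequencies()` draws per-locus allele frequencies from a
  symmetric Dirichlet. The default panel — 18 loci, 8 alleles,
  concentration 2 — mimics a moderately diverse microsatellite panel;
  `concentration = Inf` gives the equifrequent reference panel used in
  the acceptance analyses, where results do not depend on a particular
  Dirichlet draw.
* `simulate_dyads()` generates genotype pairs directly from the IBD
  model above; `gen_pedigree_cohort()` plus `drop_genotypes()` generate
  the same dyads the long way, through an explicit pedigree with
  paternity skew (a fraction of each cohort, default choice in tests:
  60–100%, sired by the cohort's top male, whose tenure spans two
  cohorts so that maternal, paternal and full sibships all arise). The
  two routes agree — a test checks that half-sib dyads extracted from
  gene-dropping and dyads simulated directly give the same mean
  relatedness within 0.02.
* `gen_demography()` generates residence spells with an exponential
  leaving hazard `baseline_hazard * kin_hazard_ratio^kin`, administrative
  right-censoring, and Gaussian high-rank tenure. The defaults are the
  study conditions the analyses are calibrated against: 37 males, ~2/3
  with a co-resident relative, baseline hazard 0.04/month (so roughly
  60% of kin-less males survive a year), kin log-hazard −2.36, censoring
  at month 146 (a 12-year observation window), tenure 14.2 months plus a
  12.7-month kin effect with SD 11.7. They are set once, from the
  magnitudes such a field system reports, and are not tuned per analysis.

What the generators do **not** emulate: selective (kin-directed)
dispersal between groups, overlapping multi-generation pedigrees,
microsatellite mutation, null alleles as a distinct mechanism (error is
a single HWE-redraw process), and time-varying kin presence within a
spell. Passing tests therefore demonstrate correctness of the estimators
and analyses under the stated generative model, not robustness to every
feature of real field data.

## Residence-time and tenure analyses

`km_curve()` gives product-limit curves of continued residence.
`cox_fit()` fits the proportional-hazards model by partial likelihood
(Breslow ties by default — tie counts are small at monthly resolution;
Efron available), supports the kin × dispersal-type interaction model,
and reports per-term Wald statistics plus the model likelihood-ratio
chi-square. `stay_one_year_test()` is the logistic likelihood-ratio test
of staying at least 12 months (records censored before month 12 carry no
information and are excluded, with the count reported).
`tenure_model()` compares high-rank tenure by OLS with a Gaussian
likelihood-ratio statistic after the eligibility filter: best rank 1–3,
tightened to 1–2 in groups with fewer than five non-natal males.

Random effects (individual nested in population) are deliberately not
fitted by maximum likelihood: with at most a couple of spells per male
the random-effect variance is weakly identified. Instead
`cluster_bootstrap()` resamples whole males with replacement and refits,
reporting a percentile interval and bootstrap SE alongside the
model-based SE. Monotone likelihoods (complete separation) in the Cox
and logistic fits are flagged in the returned object, never fatal.

Degenerate inputs are defined errors: all-missing loci, monomorphic loci
in the Hardy–Weinberg test, empty strata, no events, no eligible tenure
records, overlapping spells of one male in one group.

## Problem sizes and reproducibility

All randomness flows through explicit `seed` arguments (functions leave
the caller's RNG stream untouched when a seed is supplied). The package's
standard analysis sizes, used by the test suite and the acceptance
script, are: 1000 simulated dyads per category for estimator recovery
and cutoff construction; 10,000 simulations per hypothesis for power;
100 replicates of n = 300 for Cox effect recovery; 1000 null replicates
for the type-I error of the one-year-stay test. At these sizes the
Monte-Carlo standard error of a mean relatedness is about 0.003 and of a
power estimate at most 0.005.

## Known limitations

* Inbreeding is excluded throughout (3-state, not 9-state, identity
  model); founders are unrelated.
* The likelihood error model assumes one shared error rate across loci;
  per-locus rates would be a small extension.
* The power statistic is one operationalisation of "power of
  relationship inference"; other definitions (fitted-likelihood ratios,
  multi-category discrimination) would give different absolute values.
* Cutoff thresholds depend on the allele-frequency panel; thresholds
  published for one population do not transfer to another, which is why
  the package always derives them from the supplied frequencies.
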