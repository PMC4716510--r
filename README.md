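# kindyad

Kinship inference for dispersing males: dyadic relatedness from
microsatellite genotypes, related/unrelated classification with explicit
error control, and survival-style tests of whether co-resident kin
lengthen a male's residence in a group and his tenure at high rank.

In many group-living mammals males disperse before breeding, so kin
structure among adult males is invisible to observation and must be
inferred genetically. kindyad is aimed at researchers with (i) multilocus
codominant genotypes (GenePop or CSV), (ii) population allele
frequencies, and (iii) longitudinal group-membership records, who want to
go from raw genotypes to "does kin presence predict residence and rank
tenure?" in one auditable pipeline.

## The models at the core

**Relatedness.** For a non-inbred dyad, a locus is in IBD state 0, 1 or 2
with probabilities (k0, k1, k2), and relatedness is r = k1/2 + k2.
The per-locus pair likelihood enumerates the generative model (shared
genes drawn from the population frequencies; genotyping error as a
Hardy–Weinberg redraw with probability e per genotype). `dyadml()`
maximises the multilocus likelihood over the (k0, k1, k2) simplex — the
maximum-likelihood dyadic estimator — and `queller_goodnight()` provides
the classical moment estimator for comparison. `pw_r()` gives the
simulated power to discriminate two relationship hypotheses from the
log-likelihood-ratio distribution at a chosen confidence level.

**Classification.** `a1_cutoff()` derives a "related" threshold from
known half-sibling dyads (retain the top 85% of their r-distribution);
`a2_cutoffs()` derives dual thresholds from simulated half-sibling and
unrelated distributions (5% tails) with an unassigned exclusion zone.
`validate_classification()` reports the standard correct / incorrect /
unassigned accounting.

**Demographic consequences.** `cox_fit()` (proportional hazards, Breslow
ties), `stay_one_year_test()` (logistic LR test of staying 12 months),
`tenure_model()` (OLS on high-rank tenure with the small-group rank
filter), `km_curve()` (product-limit curves), and `cluster_bootstrap()`
(resampling whole males, the package's surrogate for individual-level
random effects).

Everything the analyses need that a field study would not publish —
allele-frequency panels, pedigreed genotypes under paternity skew,
residence records with a controllable kin effect — is generated by
first-class simulators (`gen_frequencies()`, `gen_pedigree_cohort()` +
`drop_genotypes()`, `simulate_dyads()`, `gen_demography()`).

## Worked example

```r
library(kindyad)

# a small synthetic offspring cohort shipped with the package
males <- read_genepop(system.file("extdata", "synthetic_offspring.gen",
                                  package = "kindyad"))
freqs <- read_frequency_csv(system.file("extdata", "synthetic_freqs.csv",
                                        package = "kindyad"))
males
#> Genotype table: 12 individuals x 6 loci ( 1 population(s), 0.0% missing )

fit <- dyadml(males, freqs, min_loci = 6)   # all 66 pairwise dyads
summary(fit)
#> DyadML fit over 66 dyads ( 0 refused )
#> mean r = 0.2169, var r = 0.0349
#>     0%     5%    25%    50%    75%    95%   100%
#> 0.0000 0.0000 0.0404 0.1849 0.3400 0.5583 0.6009
```

This cohort was bred with full paternity skew, so many dyads are paternal
half-siblings: the median estimate (0.18) sits near the half-sibling
expectation 0.25 and unrelated pairs pile up at 0.

```r
panel <- gen_frequencies(n_loci = 18, n_alleles = 8, concentration = Inf)
pw_r(panel, primary = "HS", null = "UR", n_sims = 5000, seed = 1)
#> PW_R (HS vs UR, alpha = 0.05, 5000 sims/hypothesis): 0.8430 (MC SE 0.0051)
```

Half-sib vs unrelated discrimination is imperfect even at 18 informative
loci, so classification uses explicit cutoffs:

```r
hs_sim <- dyadml(simulate_dyads(1000, "HS", panel, seed = 2), panel)
ur_sim <- dyadml(simulate_dyads(1000, "UR", panel, seed = 3), panel)
rule <- a2_cutoffs(coef(hs_sim), coef(ur_sim))
#> Warning: A2 exclusion zone empty or inverted (related threshold
#> 0.08907743 <= unrelated threshold 0.1666651)
labels <- classify(coef(dyadml(simulate_dyads(200, "HS", panel, seed = 4),
                               panel)), rule)
validate_classification(labels)
#> Validation of 200 known-related pairs: 169 correct (84.50%),
#> 7 incorrect (3.50%), 24 unassigned (12.00%)
```

(The warning is informative: at this panel the two simulated
distributions overlap, so the rule keeps an ambiguous band unassigned;
see the methods vignette.)

Finally, the demographic question, on synthetic records generated with a
protective kin effect on the leaving hazard of −2.36 (hazard ratio 0.09):

```r
demo <- gen_demography(n_males = 300, seed = 5)
cox_fit(demo, "kin_at_entry")
#> Cox (ties = breslow) fit: n = 300 , events = 194
#>               term   beta     se      z         p
#> 1 kin_at_entryTRUE -2.271 0.1655 -13.72 7.413e-43
#> LR chi2(1) = 180.213, p = 4.355e-41
```

The fitted log-hazard (−2.27 ± 0.17) recovers the generating effect.

## Documentation

The methods vignette (`vignettes/kindyad-methods.Rmd`) describes the
likelihood, the estimators, the cutoff constructions, what the synthetic
generators do and do not emulate, the numerical conventions (quantile
types, tie handling, optimiser), and known limitations.
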