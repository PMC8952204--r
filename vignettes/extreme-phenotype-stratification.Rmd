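---
title: "Methods: extreme-phenotype exome stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: extreme-phenotype exome stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomestrat)
```

## The design and the statistical model

`exomestrat` analyses a stratified design in which healthy individuals are
assigned to one of three phenotypically extreme constitution groups (V, P,
K) or to an unstratified background control group (C), in each of two
independent cohorts. The default group size is 18 diploid individuals — 36
alleles per group — which is the regime all defaults are tuned for.

The unit of inference is the single biallelic variant. For a group pair
the data reduce to a 2×2 allelic table

|            | alt | ref |
|------------|-----|-----|
| group A    | a   | b   |
| group B    | c   | d   |

with two alleles contributed per non-missing diploid genotype. Missing
genotypes (including half-calls such as `0/.`) contribute nothing — the
analysis is allelic and phase-free, so alt-allele *dosage* in {0, 1, 2} is
a sufficient representation and phase is discarded at ingestion.

The test is the two-sided Fisher exact test under the minimum-likelihood
rule: conditioning on the margins, the p-value sums the hypergeometric
probabilities of all tables whose probability does not exceed that of the
observed table. No mid-p variant and no tail doubling are used; this is
the convention of standard allelic association tools. Treating the 36
alleles of a group as independent draws is a Hardy–Weinberg assumption;
it is also exactly the sampling model the simulator uses, which keeps the
calibration checks interpretable.

## Stage-by-stage procedure and its parameters

**Call-rate filter** (`filter_by_call_rate`, threshold 0.5). Variants with
less than 50% genotyping call rate *over the union of the two compared
groups* are removed, independently for every pairwise comparison — a
variant can legitimately enter P–K but not V–K. The boundary is strict:
exactly 0.5 passes. A variant surviving the filter but with zero
non-missing genotypes in one group is dropped from that comparison.

**Pairwise scan** (`pairwise_scan`). Three contrasts by default: V–P, P–K,
V–K. Each surviving variant gets its table, both alternate-allele
frequencies, the Fisher p and a direction profile (`V+K-` = strictly
higher alt frequency in V). Exact frequency ties receive a tie marker
(`V=K`) rather than an arbitrary direction; ties are excluded from profile
replication, because a replication claim is a claim about direction. No
multiple-testing correction is applied here by design: the nominal 0.05
cut is the first of two gates, the permutation filter is the second.

**Permutation filter** (`permute_scan`). The pair's group labels are
shuffled uniformly (group sizes preserved) and the full per-variant scan
recomputed per iteration, on the identical call-rate-filtered variant set
(the missingness pattern does not depend on labels, so re-filtering per
permutation would only add noise). The empirical p-value uses the add-one
rule, (r + 1)/(n_perm + 1), so it can never be zero and is exact under
exchangeability. Retention requires the conjunction: observed p ≤ alpha
*and* empirical p ≤ alpha. The permutation-only rule is available via
`permutation_config(rule = "permutation")` for sensitivity analyses; we
default to the conjunction because the empirical p alone can retain a
variant whose nominal evidence is weak when the permutation distribution
is very discrete. The default `n_perm = 2000` gives an empirical-p
granularity of 1/2001, an order of magnitude below the 0.05 threshold;
the formula is scale-free, so full-scale runs (e.g. 80,000 iterations)
change only the granularity, not the estimand.

Implementation note: with the pair's samples fixed, a variant's total
allele number and total alt count are invariant under label shuffling;
only the split across groups varies. `permute_scan` therefore precomputes,
per variant, the exact two-sided p for every reachable split (indexed by
the alt count landing in group A and the number of missing genotypes
landing there) and reduces each permutation to two matrix cross-products
and a table lookup. Exceedance uses `permuted p <= observed p` on values
produced by the identical lookup, so floating-point ties are exact.

**Replication** (`replicate_cohorts`). Three nested levels: shared genes;
identical variant ids; identical variants with exactly matching profiles
for the same pair in both cohorts. Level 2 accepts retention for *any*
pair by default (the stricter same-pair reading is behind
`level2_same_pair = TRUE`); level 3 always requires the same pair and an
identical, non-tied profile. Variant identity across cohorts is by id;
the simulator guarantees consistent ids, and for real data the ingestion
falls back to `chrom:pos` (plus the alt allele for split multi-allelic
records) when rsIDs are absent. Variants lacking gene annotation are
excluded from level 1 only, with a message.

**Background contrasts** (`background_contrast`). Each of V, P, K against
C by the same allelic Fisher test, restricted by default to the
replicated-profile set — the question "does the group also differ from
the population mixture" is only meaningful for variants that survived
replication — with the option to run any variant list.

**Catalog stratification** (`map_to_catalog`, `random_set_enrichment`,
`trait_enrichment`, `risk_stratify`). The catalog is a TSV in the
download dialect of the public GWAS catalog (`SNPS`, `DISEASE/TRAIT`,
`PARENT_TERM`, `RISK_ALLELE` as `rsID-A`, `RAF` with `NR` for
unreported). Three analyses:

* *Random-set enrichment.* The observed catalog-match count of the
  differentiating set is compared with the median match count of
  `n_iter` random draws of the same size from the scanned pool. The
  statistic is a one-cell 1-df chi-square goodness-of-fit,
  (observed − median)² / median. This is one defensible reading of an
  unspecified "chi-square against the random median"; because the choice
  is an interpretation, the full null distribution is also returned and
  an add-one empirical tail probability reported alongside.
* *Trait enrichment.* Per (group, trait), a two-sided Fisher test of
  [trait hits in the group's matches, other hits; trait entries in the
  catalog, other entries] — i.e. the entire catalog is the background
  composition. A group's variants are those carrying that group on the
  `+` side of a retained profile: the group in which the variant's
  alternate allele is over-represented. This group-assignment rule is
  again an interpretation, stated here because other conventions
  (e.g. both groups of the pair) are defensible.
* *Risk table.* Group frequencies are re-oriented to the catalog risk
  allele (RAF = alt frequency if the risk allele is alt, else its
  complement; a risk allele matching neither allele drops the row with a
  message). A variant enters the table only if it has at least one
  significant group–group contrast *and* at least one significant
  group–control contrast — the conjunction that turns "differentiates
  the groups" into "identifies a deviating subgroup". The higher-RAF
  group of each significant pair is marked `##`, the lower `*`, and
  where the catalog RAF is reported, rows in which some group exceeds it
  are flagged (undefined when `NR`).

**Power** (`fisher_power`, `power_curve`). Allele counts are drawn
Binomial(2n, p) per group — equivalent to Hardy–Weinberg genotype
sampling at the allele-count level, and exactly the distribution the
allelic test sees — and the rejection rate at alpha estimated by
simulation. Raw estimates are reported without monotone smoothing, with
the binomial standard error. The default grid (18, 50, 100, 500, 1000,
10000 per group) spans the stepwise design question: what would this
study have detected at larger n? The test suite checks the estimates
against exact power computed by full enumeration of both binomials for
2n ≤ 20.

## What the simulator emulates, and what it does not

`simulate_cohort` draws, per variant and group, genotypes as
Binomial(2, f) with missingness applied independently at the configured
rate (default 0.02). Null variants share one frequency across V, P, K, C,
drawn uniformly on [0.05, 0.95]; planted variants (default 2%) put
(f_high, f_low) = (0.8, 0.2) on the target pair and the mean of the two
on the remaining groups so the pooled frequency stays comparable to a
null variant. `simulate_replication_pair` shares the V/P/K truth across
cohorts (direction flips at random when `replicate_profiles = FALSE`) and
jitters the C frequencies independently per cohort (Gaussian, SD 0.05),
because in this design the background population's allele frequencies are
not expected to agree across cohorts. The effect size 0.8 vs 0.2 is
deliberately strong — at 36 alleles per group the allelic Fisher test has
near-total power there, so recovery tests measure the pipeline, not the
test's luck; the uniform base-frequency distribution favours common
variants for the same reason.

The simulator deliberately omits: linkage disequilibrium (the method
treats variants marginally), realistic site-frequency spectra (rare
variants would mostly be removed by the nominal gate at this n),
relatedness and population structure, genotyping error beyond
missingness, and any mixture model tying C to V/P/K (C frequencies are
free parameters). Passing the suite therefore demonstrates correctness
of the statistics and the plumbing under the stated sampling model — not
robustness to LD, stratification artefacts, or allele-frequency
misspecification in real exomes.

The synthetic catalog mimics the schema only: a configurable fraction
(default 5%) of simulated variants get traits from a fixed ~30-trait
vocabulary rolled up to parent terms, a random ref-or-alt risk allele,
and a uniform catalog RAF with a small `NR` fraction. Trait content
carries no biology.

## Numerical choices and degenerate inputs

* Fisher minimum-likelihood comparisons use a relative tolerance of
  1 + 1e-7 when comparing hypergeometric masses, the standard guard
  against ties lost to floating point; p-values are clamped to ≤ 1.
* Tables with an empty margin (a group with zero non-missing genotypes
  is excluded upstream; a variant monomorphic across both groups, or an
  all-alt pool) give p = 1.
* A constant variant has observed p = 1 and every permuted p = 1, so its
  empirical p is 1 and it is never retained.
* An all-missing group yields an undefined frequency (`NA`); profiles
  with any undefined frequency are `NA` and excluded from replication.
* Empirical group frequencies estimated from 0 non-missing genotypes are
  an error in `allelic_counts` rather than silently 0/0.
* Seeds: every stochastic entry point takes an explicit seed;
  `run_pipeline` derives stage seeds from the master seed by fixed small
  offsets so stages are independently reproducible.

## Test and script problem sizes

The package's own verification runs at sizes chosen to finish a desk run
in minutes while leaving no statistical check underpowered: exhaustive
Fisher-oracle comparison over all 2×2 tables with total ≤ 40; null
permutation calibration at 5000 variants × 2000 permutations; planted
recovery and replication at 3000 variants across two cohorts; enrichment
nulls at 1000 draws; power grids at 1000–2000 simulations per point.
`scripts/acceptance.R` re-runs those computations from scratch at the
same sizes from a single command-line seed.

## Known limitations

* The empirical permutation p is per-variant; no family-wise (max-T)
  correction is implemented, matching the two-gate design rather than
  improving on it.
* The risk table's "differs between groups" criterion is nominal Fisher
  significance of the retained contrasts, not a numeric
  frequency-difference threshold.
* Sex chromosomes are treated as diploid autosomes; inputs are assumed
  build-harmonized (no liftover is performed).
* Power is computed for the single Fisher test, not for the full
  two-gate, two-cohort replication procedure; the latter has no standard
  closed form and would need its own simulation design.
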