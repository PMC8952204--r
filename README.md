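# exomestrat

Extreme-phenotype exome stratification by pairwise allelic association.

## The problem

Case–control association studies need large samples because common-disease
phenotypes are heterogeneous. An alternative is to stratify *healthy*
individuals into phenotypically homogeneous extreme groups and ask which
exonic variants differentiate the groups. `exomestrat` implements that
analysis for a design with three extreme constitution groups — V, P and K —
plus an unstratified background control group C, genotyped in two
independent cohorts of 18 individuals per group.

The pipeline, end to end:

1. **Ingest** a multi-sample diploid VCF and a sample sheet into an
   alt-allele dosage matrix (multi-allelic sites split into biallelic
   records; half-calls treated as missing).
2. **Filter** per pairwise comparison: variants with a genotyping call rate
   below 50% over the two compared groups are removed (a rate of exactly
   0.5 passes).
3. **Scan**: for each pair (V–P, P–K, V–K) and each surviving variant, the
   allelic 2×2 table opposes alt and ref allele counts (2 alleles per
   non-missing diploid) between the groups. Significance is the two-sided
   Fisher exact p by the minimum-likelihood rule: with margins fixed,
   p = Σ Pr(tables whose hypergeometric probability ≤ that of the observed
   table). Each variant gets a direction profile, e.g. `V+K-` = higher
   alternate-allele frequency in V than in K.
4. **Permutation filter**: group labels of the pair's samples are shuffled
   (sizes preserved) and the scan repeated; a variant's empirical p-value is
   (r + 1)/(n_perm + 1) where r counts permutations with a Fisher p at or
   below the observed one. Retention requires both the nominal (p ≤ 0.05)
   and the empirical (p ≤ 0.05) criterion.
5. **Replication** across the two cohorts at three levels: shared genes,
   identical variants, and identical variants with exactly matching
   profiles for the same pair ("replicated profile" variants). Those are
   then contrasted against the background control (V–C, P–C, K–C).
6. **Catalog stratification**: differentiating variants are joined to a
   GWAS-catalog-format table; over-representation is tested against the
   median catalog-match count of random same-size variant sets
   (1-df chi-square, plus an empirical tail); per-group trait enrichment
   uses Fisher tests against the full catalog composition; and a risk
   table reports the risk-allele frequency (RAF) per group, pooled, in the
   control and in the catalog, marking the higher-RAF group of each
   significant pair with `##` and the lower with `*`.
7. **Power**: simulated power of the two-group allelic Fisher test, with
   allele counts drawn Binomial(2n, p) per group, over the stepwise grid
   18, 50, 100, 500, 1000, 10000 samples per group.

A Hardy–Weinberg simulator (`simulate_cohort`,
`simulate_replication_pair`, `simulate_catalog`) generates two-cohort
datasets with planted between-group frequency differences and a synthetic
catalog, so the whole pipeline is testable without external data.

## Worked example

```r
library(exomestrat)

cfg <- sim_config(n_variants = 2000, n_per_group = 18, frac_planted = 0.02,
                  effect = c(0.8, 0.2), planted_pair = c("V", "K"),
                  seed = 42)
rp  <- simulate_replication_pair(cfg)

analyse <- function(cohort, seed) {
  scan <- pairwise_scan(cohort$matrix, cohort$design)
  pairs <- list(c("V", "P"), c("P", "K"), c("V", "K"))
  perm <- do.call(rbind, lapply(seq_along(pairs), function(k)
    permute_scan(cohort$matrix, cohort$design, pairs[[k]],
                 permutation_config(n_perm = 2000, seed = seed + k))))
  retained_scan(scan, perm)
}
retA <- analyse(rp$cohortA, 100)
retB <- analyse(rp$cohortB, 200)
replicate_cohorts(retA, retB)
#> replication_report:
#>   level 1 (shared genes):             51
#>   level 2 (identical variants):       44
#>   level 3 (replicated profiles):      42
```

The 40 planted V–K variants (2% of 2000) drive the replicated-profile set;
a planted variant can replicate on more than one pair because its
intermediate-frequency groups also separate from the extremes. Power at
the frequencies of a typical replicated variant (0.36 vs 0.11):

```r
power_curve(0.36, 0.11, sizes = c(18, 50, 100), n_sim = 2000, seed = 9)
#>     p1   p2 n_per_group alpha n_sim power          se
#> 1 0.36 0.11          18  0.05  2000 0.623 0.010836766
#> 2 0.36 0.11          50  0.05  2000 0.986 0.002627166
#> 3 0.36 0.11         100  0.05  2000 1.000 0.000000000
```

So a moderate frequency split that is marginal at 18 per group is
essentially always detected at 50 — the motivation for extreme-phenotype
designs of this size. The whole pipeline runs in one call from a YAML
config (see `inst/extdata/example_config.yaml`):

```r
run_pipeline(system.file("extdata", "example_config.yaml",
                         package = "exomestrat"),
             outdir = "exomestrat_out")
```

which writes per-stage TSVs (scan, permutation, retained sets, replication
levels, background contrasts, catalog matches, trait enrichment, risk
table, power curve) plus `manifest.json` with seeds, parameters and
per-stage counts. `inst/exec/exomestrat.R` wraps the same call for shell
use.

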