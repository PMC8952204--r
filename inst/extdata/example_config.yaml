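# Example run configuration: a small two-cohort simulated study.
# For real data, replace the simulation block with
#   inputs:
#     vcf_a: cohort1.vcf
#     sheet_a: cohort1_samples.tsv
#     vcf_b: cohort2.vcf
#     sheet_b: cohort2_samples.tsv
#     catalog: gwas_catalog_subset.tsv
simulation:
  two_cohorts: true
  n_per_group: 18
  n_variants: 2000
  frac_planted: 0.02
  effect: [0.8, 0.2]
  planted_pair: [V, K]
  missing_rate: 0.02
  catalog_fraction: 0.05
call_rate_threshold: 0.5
alpha: 0.05
permutation:
  n_perm: 2000
  rule: both
enrichment:
  n_iter: 1000
power:
  sizes: [18, 50, 100, 500, 1000, 10000]
  n_sim: 1000
seed: 42
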