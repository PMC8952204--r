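test_that("simulation is reproducible from the seed", {
  cc <- sim_config(n_variants = 300, seed = 123)
  a <- simulate_cohort(cc)
  b <- simulate_cohort(cc)
  expect_identical(a$matrix$genotypes, b$matrix$genotypes)
  expect_identical(a$truth, b$truth)
  rp1 <- simulate_replication_pair(cc)
  rp2 <- simulate_replication_pair(cc)
  expect_identical(rp1$cohortA$matrix$genotypes, rp2$cohortA$matrix$genotypes)
  expect_identical(rp1$cohortB$matrix$genotypes, rp2$cohortB$matrix$genotypes)
})

test_that("empirical group frequencies converge to configured truth at large n", {
  cc <- sim_config(n_per_group = 1000, n_variants = 60, frac_planted = 0.2,
                   missing_rate = 0, seed = 21)
  sim <- simulate_cohort(cc)
  for (g in c("V", "K")) {
    gs <- group_samples(sim$design, g)
    fhat <- colSums(sim$matrix$genotypes[gs, ]) / (2 * length(gs))
    f <- sim$truth[[paste0("f_", g)]]
    se <- sqrt(f * (1 - f) / (2 * length(gs)))
    expect_true(all(abs(fhat - f) <= 3.5 * se + 1e-9))
  }
})

test_that("truth profiles agree exactly with configured frequency orderings", {
  cc <- sim_config(n_variants = 500, frac_planted = 0.1,
                   planted_pair = c("P", "K"), seed = 4)
  sim <- simulate_cohort(cc)
  tr <- sim$truth
  pl <- tr[tr$planted, ]
  expect_true(all(pl$pair == "P-K"))
  expect_true(all(pl$profile == ifelse(pl$f_P > pl$f_K, "P+K-", "P-K+")))
  expect_true(all(pl$f_P > pl$f_K))   # f_high on the first pair member
  expect_true(all(is.na(tr$profile[!tr$planted])))
  # null variants share one frequency across groups
  nu <- tr[!tr$planted, ]
  expect_equal(nu$f_V, nu$f_P)
  expect_equal(nu$f_V, nu$f_C)
})

test_that("observed missingness matches the configured rate within a binomial CI", {
  cc <- sim_config(n_variants = 2000, missing_rate = 0.05, seed = 8)
  sim <- simulate_cohort(cc)
  m <- mean(is.na(sim$matrix$genotypes))
  n <- length(sim$matrix$genotypes)
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(m - 0.05), 4 * se)
})

test_that("a strong planted difference is visible in the observed frequencies", {
  # (0.9, 0.1) on V vs K with 36 alleles per group: the observed frequency
  # difference exceeds 0.5 with overwhelming probability
  cc <- sim_config(n_variants = 400, frac_planted = 0.5,
                   effect = c(0.9, 0.1), missing_rate = 0, seed = 31)
  sim <- simulate_cohort(cc)
  tr <- sim$truth
  gv <- group_samples(sim$design, "V"); gk <- group_samples(sim$design, "K")
  fv <- colSums(sim$matrix$genotypes[gv, ]) / 36
  fk <- colSums(sim$matrix$genotypes[gk, ]) / 36
  frac <- mean((fv - fk)[tr$planted] > 0.5)
  # exact tail: P(Bin(36,.9)/36 - Bin(36,.1)/36 > 0.5)
  pdiff <- sum(outer(dbinom(0:36, 36, 0.9), dbinom(0:36, 36, 0.1)) *
               outer(0:36, 0:36, function(i, j) (i - j) / 36 > 0.5))
  expect_gt(pdiff, 0.95)
  expect_gte(frac, 0.95)
})

test_that("replication pairs share planted direction and differ in C between cohorts", {
  cc <- sim_config(n_variants = 400, frac_planted = 0.1, seed = 13)
  rp <- simulate_replication_pair(cc)
  tr <- rp$truth
  pl <- tr[tr$planted, ]
  expect_true(all(pl$profile_A == pl$profile_B))
  expect_true(all(pl$profile_A == "V+K-"))
  # background C frequencies jittered independently per cohort
  expect_gt(mean(tr$f_C_A != tr$f_C_B), 0.99)
  # V/P/K truth shared across cohorts
  expect_identical(tr$f_V_A, tr$f_V_B)
  # with replicate_profiles = FALSE roughly half of planted directions flip
  cc2 <- sim_config(n_variants = 2000, frac_planted = 0.5,
                    replicate_profiles = FALSE, seed = 13)
  rp2 <- simulate_replication_pair(cc2)
  pl2 <- rp2$truth[rp2$truth$planted, ]
  agree <- mean(pl2$profile_A == pl2$profile_B)
  se <- sqrt(0.25 / nrow(pl2))
  expect_lt(abs(agree - 0.5), 4 * se)
})

test_that("synthetic catalog has the configured coverage and valid alleles", {
  cc <- sim_config(n_variants = 2000, catalog_fraction = 0.05, seed = 17)
  sim <- simulate_cohort(cc)
  cat <- simulate_catalog(cc, sim$matrix)
  n_snps <- length(unique(cat$variant_id))
  expect_equal(n_snps, round(0.05 * 2000))
  expect_true(all(cat$variant_id %in% sim$matrix$variants$id))
  v <- sim$matrix$variants
  i <- match(cat$variant_id, v$id)
  expect_true(all(cat$risk_allele == v$ref[i] | cat$risk_allele == v$alt[i]))
  expect_true(all(is.na(cat$catalog_raf) |
                  (cat$catalog_raf >= 0 & cat$catalog_raf <= 1)))
  # risk allele = ref complements the alt frequency
  expect_equal(align_risk_allele("A", "G", "A", 0.36), 0.64)
})

test_that("catalog TSV writing round-trips through read_catalog", {
  cc <- sim_config(n_variants = 500, seed = 19)
  sim <- simulate_cohort(cc)
  cat <- simulate_catalog(cc, sim$matrix)
  path <- tempfile(fileext = ".tsv")
  write_catalog(cat, path)
  back <- read_catalog(path)
  expect_equal(back$variant_id, cat$variant_id)
  expect_equal(back$risk_allele, cat$risk_allele)
  expect_equal(back$catalog_raf, cat$catalog_raf)
  expect_equal(back$parent_term, cat$parent_term)
})
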