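test_that("dosage mapping, missing calls and half-calls follow the allelic convention", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3", "s4", "s5"), collapse = "\t"),
    paste(c("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
            "0/0", "0/1", "1/1", "./.", "0|1"), collapse = "\t"),
    paste(c("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
            "0/.", "1/1", "0/0", "1|0", "0/0"), collapse = "\t")),
    vcf)
  sheet <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tcohort\tgroup",
               "s1\tA\tV", "s2\tA\tV", "s3\tA\tP", "s4\tA\tK", "s5\tA\tC"),
             sheet)
  got <- read_genotypes(vcf, sheet)
  G <- got$matrix$genotypes
  # phased and unphased are identical; half-calls fully missing
  expect_equal(unname(G[, "rs1"]), c(0L, 1L, 2L, NA, 1L))
  expect_equal(unname(G[, "rs2"]), c(NA, 2L, 0L, 1L, 0L))
  expect_equal(got$design$group, c("V", "V", "P", "K", "C"))
})

test_that("multi-allelic sites split into one biallelic record per alt allele", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3", "s4", "s5"), collapse = "\t"),
    paste(c("1", "100", ".", "A", "G,T", ".", "PASS", ".", "GT",
            "0/1", "1/2", "2/2", "0/0", "./."), collapse = "\t")),
    vcf)
  sheet <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tcohort\tgroup",
               "s1\tA\tV", "s2\tA\tV", "s3\tA\tP", "s4\tA\tK", "s5\tA\tC"),
             sheet)
  got <- read_genotypes(vcf, sheet)
  expect_equal(nrow(got$matrix$variants), 2L)
  # manual split of the fixture: each alt counted against its own record,
  # the other alt counts as reference
  expect_equal(unname(got$matrix$genotypes[, 1]), c(1L, 1L, 0L, 0L, NA))
  expect_equal(unname(got$matrix$genotypes[, 2]), c(0L, 1L, 2L, 0L, NA))
  # novel multi-allelic ids disambiguated by alt allele
  expect_equal(got$matrix$variants$id, c("1:100:G", "1:100:T"))
})

test_that("sheet/VCF sample mismatches: absent-from-VCF errors, absent-from-sheet warns", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    paste(c("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
            "0/0", "0/1", "1/1"), collapse = "\t")), vcf)
  sheet_bad <- tempfile(); sheet_sub <- tempfile()
  writeLines(c("sample\tcohort\tgroup", "s1\tA\tV", "sX\tA\tP"), sheet_bad)
  writeLines(c("sample\tcohort\tgroup", "s1\tA\tV", "s2\tA\tP"), sheet_sub)
  expect_error(read_genotypes(vcf, sheet_bad), "absent from VCF")
  expect_warning(got <- read_genotypes(vcf, sheet_sub), "dropped")
  expect_equal(got$matrix$samples, c("s1", "s2"))
  # group label outside {V,P,K,C} is rejected
  sheet_grp <- tempfile()
  writeLines(c("sample\tcohort\tgroup", "s1\tA\tQ"), sheet_grp)
  expect_error(read_genotypes(vcf, sheet_grp), "group labels")
})

test_that("call rate and the strict less-than filter boundary", {
  G <- matrix(NA_integer_, nrow = 36, ncol = 4)
  G[, 1] <- 1L                      # full call rate
  G[1:18, 2] <- 1L                  # exactly 0.5
  G[1:17, 3] <- 0L                  # 17/36 < 0.5
  # column 4 stays all-missing
  gm <- make_gm(G)
  s <- gm$samples
  expect_equal(call_rate(gm, 1, s), 1.0)
  expect_equal(call_rate(gm, 2, s), 0.5)
  expect_equal(call_rate(gm, 3, s[15:20]), 0.5)
  expect_error(call_rate(gm, 1, character(0)), "empty")
  kept <- filter_by_call_rate(gm, s, 0.5)
  expect_true(2 %in% kept)          # exactly 0.5 is kept ("less than" rule)
  expect_false(3 %in% kept)         # 0.47 removed
  expect_false(4 %in% kept)         # all-missing removed
})

test_that("alternate allele frequency matches the dosage definition", {
  # 18 diploids carrying 13 alt alleles in total -> 13/36
  g <- c(rep(1L, 13), rep(0L, 5))
  gm <- make_gm(matrix(g, ncol = 1))
  expect_equal(alt_allele_frequency(gm, 1, gm$samples), 13 / 36)
  gm0 <- make_gm(matrix(rep(0L, 18), ncol = 1))
  expect_equal(alt_allele_frequency(gm0, 1, gm0$samples), 0)
  gm1 <- make_gm(matrix(1L, 1, 1))
  expect_equal(alt_allele_frequency(gm1, 1, gm1$samples), 0.5)
  gmna <- make_gm(matrix(NA_integer_, 3, 1))
  expect_true(is.na(alt_allele_frequency(gmna, 1, gmna$samples)))
})

test_that("frequency complements and dosage conservation hold across partitions", {
  set.seed(42)
  G <- matrix(rbinom(50 * 20, 2, 0.3), nrow = 50)
  G[runif(length(G)) < 0.1] <- NA
  gm <- make_gm(G)
  s <- gm$samples
  parts <- split(s, rep(1:3, length.out = 50))
  for (vi in c(1, 7, 20)) {
    alt_by_part <- sum(vapply(parts, function(p)
      sum(gm$genotypes[p, vi], na.rm = TRUE), numeric(1)))
    expect_equal(alt_by_part, sum(gm$genotypes[, vi], na.rm = TRUE))
    f <- alt_allele_frequency(gm, vi, s)
    g <- gm$genotypes[s, vi]
    ref_freq <- sum(2 - g, na.rm = TRUE) / (2 * sum(!is.na(g)))
    expect_equal(1 - f, ref_freq)
  }
})

test_that("VCF round trip reproduces dosages and missingness exactly", {
  set.seed(7)
  G <- matrix(rbinom(12 * 30, 2, 0.4), nrow = 12)
  G[runif(length(G)) < 0.08] <- NA
  gm <- make_gm(G, genes = rep(sprintf("G%02d", 1:10), each = 3))
  design <- cohort_design(gm$samples, "A",
                          rep(c("V", "P", "K", "C"), each = 3))
  vcf <- tempfile(fileext = ".vcf"); sheet <- tempfile(fileext = ".tsv")
  write_genotypes(gm, vcf, design = design, sheet_path = sheet)
  back <- read_genotypes(vcf, sheet)
  expect_equal(unname(back$matrix$genotypes), unname(gm$genotypes))
  expect_equal(back$matrix$variants$id, gm$variants$id)
  expect_equal(back$matrix$variants$gene, gm$variants$gene)
  expect_equal(back$design$group, design$group)
})
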