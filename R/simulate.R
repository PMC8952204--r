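#' Simulation settings for stratified cohort genotypes
#'
#' Describes a two-cohort extreme-phenotype study design: four groups (V,
#' P, K and the background control C) of equal size per cohort, biallelic
#' variants with Hardy-Weinberg genotypes at group-specific allele
#' frequencies, a fraction of variants carrying planted between-group
#' frequency differences, and uniform random missingness.
#'
#' @param n_per_group samples per (cohort, group); default 18, the study
#'   design this generator emulates.
#' @param n_variants total number of simulated biallelic variants.
#' @param frac_planted fraction of variants with a true between-group
#'   frequency difference.
#' @param effect length-2 numeric \code{c(f_high, f_low)} with
#'   \code{f_high > f_low}: the alternate-allele frequencies planted on the
#'   target pair. Default \code{c(0.8, 0.2)}.
#' @param planted_pair the group pair carrying the planted difference;
#'   default \code{c("V","K")}. The first group receives \code{f_high}.
#' @param base_freq_range range of the uniform distribution from which
#'   null-variant frequencies are drawn; default \code{c(0.05, 0.95)}.
#' @param missing_rate per-genotype missingness probability in [0,1);
#'   default 0.02.
#' @param replicate_profiles when \code{TRUE} (default) planted variants
#'   share their direction in both cohorts of a replication pair; when
#'   \code{FALSE} cohort B redraws the direction at random.
#' @param c_jitter_sd per-cohort Gaussian jitter (SD) applied to the
#'   background control group's frequencies in a replication pair, so that
#'   C frequencies differ between cohorts; default 0.05.
#' @param catalog_fraction fraction of variants entered into the synthetic
#'   risk-allele catalog; default 0.05.
#' @param catalog_nr_rate fraction of catalog entries with an unreported
#'   ("NR") catalog risk-allele frequency; default 0.05.
#' @param seed optional integer RNG seed.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_per_group = 18, n_variants = 10000,
                       frac_planted = 0.02, effect = c(0.8, 0.2),
                       planted_pair = c("V", "K"),
                       base_freq_range = c(0.05, 0.95),
                       missing_rate = 0.02, replicate_profiles = TRUE,
                       c_jitter_sd = 0.05, catalog_fraction = 0.05,
                       catalog_nr_rate = 0.05, seed = NULL) {
  if (n_per_group < 1 || n_variants < 1) stop("sizes must be positive")
  if (frac_planted < 0 || frac_planted > 1) stop("frac_planted in [0,1]")
  if (length(effect) != 2L || any(effect < 0 | effect > 1))
    stop("effect must be two frequencies in [0,1]")
  if (frac_planted > 0 && effect[1] <= effect[2])
    stop("planted effect needs f_high > f_low")
  if (!all(planted_pair %in% c("V", "P", "K", "C")) ||
      length(planted_pair) != 2L || planted_pair[1] == planted_pair[2])
    stop("planted_pair must be two distinct group labels")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate in [0,1)")
  if (any(base_freq_range < 0 | base_freq_range > 1) ||
      base_freq_range[1] > base_freq_range[2])
    stop("invalid base_freq_range")
  structure(list(n_per_group = as.integer(n_per_group),
                 n_variants = as.integer(n_variants),
                 frac_planted = frac_planted, effect = effect,
                 planted_pair = planted_pair,
                 base_freq_range = base_freq_range,
                 missing_rate = missing_rate,
                 replicate_profiles = isTRUE(replicate_profiles),
                 c_jitter_sd = c_jitter_sd,
                 catalog_fraction = catalog_fraction,
                 catalog_nr_rate = catalog_nr_rate,
                 seed = seed), class = "sim_config")
}

.sim_groups <- c("V", "P", "K", "C")

## variant metadata shared by both cohorts of a simulation
.sim_variants <- function(config) {
  V <- config$n_variants
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, V, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  data.frame(chrom = "1", pos = 10000L + seq_len(V) * 50L,
             id = sprintf("rs%06d", seq_len(V)),
             ref = ref, alt = unname(alt),
             gene = sprintf("GENE%04d", (seq_len(V) + 2L) %/% 3L),
             stringsAsFactors = FALSE)
}

## true per-group frequency matrix (groups x variants) and planted flags
.sim_frequencies <- function(config) {
  V <- config$n_variants
  base <- stats::runif(V, config$base_freq_range[1], config$base_freq_range[2])
  f <- matrix(rep(base, each = 4L), nrow = 4L,
              dimnames = list(.sim_groups, NULL))
  n_planted <- round(config$frac_planted * V)
  planted <- rep(FALSE, V)
  if (n_planted > 0) {
    idx <- sort(sample.int(V, n_planted))
    planted[idx] <- TRUE
    hi <- config$effect[1]; lo <- config$effect[2]
    # the non-target groups sit at the mean so the pooled frequency of a
    # planted variant stays close to its null counterpart
    f[, idx] <- (hi + lo) / 2
    f[config$planted_pair[1], idx] <- hi
    f[config$planted_pair[2], idx] <- lo
  }
  list(f = f, planted = planted)
}

## Hardy-Weinberg genotypes for one cohort given a frequency matrix
.sim_genotypes <- function(config, f, cohort_label) {
  n <- config$n_per_group; V <- config$n_variants
  G <- matrix(NA_integer_, nrow = 4L * n, ncol = V)
  samples <- character(4L * n)
  for (gi in seq_along(.sim_groups)) {
    rows <- (gi - 1L) * n + seq_len(n)
    G[rows, ] <- matrix(stats::rbinom(n * V, 2L, rep(f[gi, ], each = n)),
                        nrow = n)
    samples[rows] <- sprintf("%s_%s%02d", cohort_label, .sim_groups[gi],
                             seq_len(n))
  }
  if (config$missing_rate > 0) {
    G[stats::runif(length(G)) < config$missing_rate] <- NA_integer_
  }
  list(G = G, samples = samples)
}

#' Simulate one stratified cohort
#'
#' Draws Hardy-Weinberg genotypes (alt dosage ~ Binomial(2, f)) for four
#' equal groups V, P, K, C at group-specific allele frequencies. Null
#' variants share one frequency across all groups; planted variants carry
#' \code{f_high}/\code{f_low} on the target pair and the mean of the two on
#' the remaining groups. Missingness is applied independently per genotype.
#' Fully reproducible from \code{config$seed}.
#'
#' @param config a \code{sim_config}.
#' @param cohort_label cohort name used in sample ids and the design.
#' @return list with elements \code{matrix} (\code{genotype_matrix}),
#'   \code{design} (\code{cohort_design}) and \code{truth} (data.frame with
#'   per-variant planted flag, target pair, true group frequencies and true
#'   profile; the tie marker never occurs for planted variants).
#' @export
simulate_cohort <- function(config, cohort_label = "cohort1") {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  variants <- .sim_variants(config)
  fr <- .sim_frequencies(config)
  sim <- .sim_genotypes(config, fr$f, cohort_label)
  gm <- genotype_matrix(sim$G, variants, sim$samples)
  design <- cohort_design(sim$samples, cohort_label,
                          rep(.sim_groups, each = config$n_per_group))
  truth <- data.frame(variant_id = variants$id, planted = fr$planted,
                      pair = ifelse(fr$planted, .pair_key(config$planted_pair),
                                    NA_character_),
                      f_V = fr$f["V", ], f_P = fr$f["P", ],
                      f_K = fr$f["K", ], f_C = fr$f["C", ],
                      stringsAsFactors = FALSE)
  truth$profile <- ifelse(fr$planted,
                          assign_profile(fr$f[config$planted_pair[1], ],
                                         fr$f[config$planted_pair[2], ],
                                         config$planted_pair),
                          NA_character_)
  list(matrix = gm, design = design, truth = truth)
}

#' Simulate a two-cohort replication pair
#'
#' Both cohorts share the same variants and the same true V/P/K
#' frequencies. Background control (C) frequencies receive independent
#' per-cohort jitter, mimicking a background population whose allele
#' frequencies differ between cohorts. With
#' \code{config$replicate_profiles = TRUE}, planted variants share their
#' direction (same group higher) in both cohorts; with \code{FALSE},
#' cohort B flips each planted direction independently with probability
#' one half.
#'
#' @param config a \code{sim_config}.
#' @param cohort_labels character vector of length 2.
#' @return list with elements \code{cohortA}, \code{cohortB} (each a list
#'   \code{matrix}/\code{design} as in \code{\link{simulate_cohort}}) and a
#'   shared \code{truth} data.frame carrying per-cohort frequencies and
#'   per-cohort true profiles.
#' @export
simulate_replication_pair <- function(config,
                                      cohort_labels = c("cohort1", "cohort2")) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  variants <- .sim_variants(config)
  fr <- .sim_frequencies(config)
  V <- config$n_variants
  pp <- config$planted_pair

  fA <- fr$f
  fB <- fr$f
  if (!config$replicate_profiles && any(fr$planted)) {
    flip <- fr$planted & stats::runif(V) < 0.5
    fB[pp[1], flip] <- fr$f[pp[2], flip]
    fB[pp[2], flip] <- fr$f[pp[1], flip]
  }
  jitter_c <- function(f) {
    f["C", ] <- pmin(pmax(f["C", ] +
      stats::rnorm(V, 0, config$c_jitter_sd), 0.01), 0.99)
    f
  }
  fA <- jitter_c(fA); fB <- jitter_c(fB)

  simA <- .sim_genotypes(config, fA, cohort_labels[1])
  simB <- .sim_genotypes(config, fB, cohort_labels[2])
  mk <- function(sim, label) {
    list(matrix = genotype_matrix(sim$G, variants, sim$samples),
         design = cohort_design(sim$samples, label,
                                rep(.sim_groups, each = config$n_per_group)))
  }
  truth <- data.frame(variant_id = variants$id, planted = fr$planted,
                      pair = ifelse(fr$planted, .pair_key(pp), NA_character_),
                      f_V_A = fA["V", ], f_P_A = fA["P", ], f_K_A = fA["K", ],
                      f_C_A = fA["C", ],
                      f_V_B = fB["V", ], f_P_B = fB["P", ], f_K_B = fB["K", ],
                      f_C_B = fB["C", ],
                      stringsAsFactors = FALSE)
  truth$profile_A <- ifelse(fr$planted,
                            assign_profile(fA[pp[1], ], fA[pp[2], ], pp),
                            NA_character_)
  truth$profile_B <- ifelse(fr$planted,
                            assign_profile(fB[pp[1], ], fB[pp[2], ], pp),
                            NA_character_)
  list(cohortA = mk(simA, cohort_labels[1]),
       cohortB = mk(simB, cohort_labels[2]),
       truth = truth)
}

## fixed vocabulary for the synthetic catalog: trait -> parent term,
## mirroring the 17 top-level parent terms a live catalog rolls traits to
.catalog_vocab <- data.frame(
  trait = c("Body mass index", "Waist-to-hip ratio", "Height",
            "Type 2 diabetes", "Fasting glucose", "Insulin response",
            "HDL cholesterol", "LDL cholesterol", "Triglyceride levels",
            "Hemoglobin concentration", "Platelet count", "Lymphocyte count",
            "Mean arterial pressure", "Hypertension", "Liver fibrosis",
            "Liver enzyme levels", "Asthma", "Allergic rhinitis",
            "Atopic dermatitis", "Depressive symptoms", "Feeling worry",
            "Bone mineral density", "C-reactive protein levels",
            "Coronary artery disease", "Chronic kidney disease",
            "Age-related macular degeneration", "Breast carcinoma",
            "Alzheimer disease", "Rheumatoid arthritis",
            "Response to metformin"),
  parent_term = c("Body measurement", "Body measurement", "Body measurement",
                  "Metabolic disorder", "Metabolic disorder",
                  "Metabolic disorder", "Lipid or lipoprotein measurement",
                  "Lipid or lipoprotein measurement",
                  "Lipid or lipoprotein measurement",
                  "Hematological measurement", "Hematological measurement",
                  "Hematological measurement", "Cardiovascular measurement",
                  "Cardiovascular disease", "Digestive system disorder",
                  "Liver enzyme measurement", "Respiratory disease",
                  "Immune system disorder", "Immune system disorder",
                  "Neurological disorder", "Psychological trait",
                  "Body measurement", "Inflammatory measurement",
                  "Cardiovascular disease", "Urinary system disease",
                  "Eye disease", "Cancer", "Neurological disorder",
                  "Immune system disorder", "Drug response"),
  stringsAsFactors = FALSE)

#' Simulate a risk-allele catalog over simulated variants
#'
#' Assigns a random subset of the matrix's variants to synthetic
#' disease/trait names drawn from a small fixed vocabulary (each trait
#' mapped to a parent term), with a risk allele chosen at random between
#' the variant's ref and alt allele and a catalog risk-allele frequency
#' that is unreported ("NR") for a small fraction of entries. About one in
#' ten catalog variants receives a second trait, so (variant, trait) rows
#' outnumber catalog variants slightly.
#'
#' @param config a \code{sim_config} (uses \code{catalog_fraction},
#'   \code{catalog_nr_rate}; reseeding is the caller's responsibility —
#'   \code{simulate_cohort} already consumed the config seed).
#' @param gm the simulated \code{genotype_matrix}.
#' @return catalog data.frame with columns \code{variant_id, trait,
#'   parent_term, risk_allele, catalog_raf} (NA = unreported).
#' @export
simulate_catalog <- function(config, gm) {
  stopifnot(inherits(config, "sim_config"))
  v <- gm$variants
  n_cat <- round(config$catalog_fraction * nrow(v))
  if (n_cat == 0L)
    return(data.frame(variant_id = character(), trait = character(),
                      parent_term = character(), risk_allele = character(),
                      catalog_raf = numeric(), stringsAsFactors = FALSE))
  pick <- sort(sample.int(nrow(v), n_cat))
  extra <- pick[stats::runif(n_cat) < 0.1]
  rows <- c(pick, extra)
  trait <- sample(.catalog_vocab$trait, length(rows), replace = TRUE)
  use_alt <- stats::runif(length(rows)) < 0.5
  raf <- round(stats::runif(length(rows), 0.05, 0.95), 2)
  raf[stats::runif(length(rows)) < config$catalog_nr_rate] <- NA_real_
  data.frame(variant_id = v$id[rows], trait = trait,
             parent_term = .catalog_vocab$parent_term[
               match(trait, .catalog_vocab$trait)],
             risk_allele = ifelse(use_alt, v$alt[rows], v$ref[rows]),
             catalog_raf = raf, stringsAsFactors = FALSE)
}

#' Write a catalog table in the catalog-download TSV dialect
#'
#' Columns \code{SNPS, DISEASE/TRAIT, PARENT_TERM, RISK_ALLELE, RAF}; the
#' risk allele is written in the \code{rsID-A} dialect and an unreported
#' frequency as \code{NR}, so \code{\link{read_catalog}} round-trips.
#'
#' @param catalog catalog data.frame as from \code{\link{simulate_catalog}}.
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
write_catalog <- function(catalog, path) {
  out <- data.frame(
    SNPS = catalog$variant_id,
    "DISEASE/TRAIT" = catalog$trait,
    PARENT_TERM = catalog$parent_term,
    RISK_ALLELE = paste0(catalog$variant_id, "-", catalog$risk_allele),
    RAF = ifelse(is.na(catalog$catalog_raf), "NR",
                 format(catalog$catalog_raf, trim = TRUE)),
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
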