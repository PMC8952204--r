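.log <- function(...) message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)

.default_config <- function() {
  list(
    simulation = list(two_cohorts = TRUE),
    inputs = NULL,
    pairs = list(c("V", "P"), c("P", "K"), c("V", "K")),
    call_rate_threshold = 0.5,
    alpha = 0.05,
    permutation = list(n_perm = 2000, rule = "both"),
    enrichment = list(n_iter = 1000),
    power = list(sizes = c(18, 50, 100, 500, 1000, 10000), n_sim = 1000,
                 p1 = NULL, p2 = NULL),
    seed = 1L
  )
}

#' Read a pipeline run configuration
#'
#' YAML file with optional blocks \code{simulation} (fields of
#' \code{\link{sim_config}} plus \code{two_cohorts}) or \code{inputs}
#' (\code{vcf_a, sheet_a, vcf_b, sheet_b, catalog}), and the analysis
#' settings \code{pairs}, \code{call_rate_threshold}, \code{alpha},
#' \code{permutation} (\code{n_perm}, \code{rule}), \code{enrichment}
#' (\code{n_iter}), \code{power} (\code{sizes}, \code{n_sim}, \code{p1},
#' \code{p2}) and \code{seed}. Missing settings take package defaults.
#'
#' @param path path to a YAML config file.
#' @return config list for \code{\link{run_pipeline}}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(.default_config(), user)
  if (!is.null(user$inputs)) cfg$simulation <- NULL
  cfg
}

.write_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  nrow(as.data.frame(x))
}

## scan + permutation + retention for one cohort
.analyse_cohort <- function(gm, design, cfg, seed_base, tag, outdir) {
  pairs <- lapply(cfg$pairs, as.character)
  .log("cohort ", tag, ": pairwise allelic Fisher scan (",
       nrow(gm$variants), " variants)")
  scan <- pairwise_scan(gm, design, pairs = pairs,
                        call_rate_threshold = cfg$call_rate_threshold)
  perm <- do.call(rbind, lapply(seq_along(pairs), function(k) {
    pc <- permutation_config(n_perm = cfg$permutation$n_perm,
                             alpha = cfg$alpha,
                             seed = seed_base + k,
                             rule = cfg$permutation$rule)
    .log("cohort ", tag, ": permutations for ", .pair_key(pairs[[k]]),
         " (n_perm = ", pc$n_perm, ")")
    permute_scan(gm, design, pairs[[k]], pc,
                 call_rate_threshold = cfg$call_rate_threshold)
  }))
  ret <- retained_scan(scan, perm)
  diff_ids <- retain(perm, alpha = cfg$alpha, rule = cfg$permutation$rule)
  counts <- list(
    scan_rows = .write_tsv(scan, file.path(outdir,
                                           paste0(tag, "_scan.tsv"))),
    permutation_rows = .write_tsv(perm, file.path(outdir,
                                    paste0(tag, "_permutation.tsv"))),
    retained_rows = .write_tsv(ret, file.path(outdir,
                                    paste0(tag, "_retained.tsv"))),
    unique_variations = length(diff_ids),
    genes = length(unique(ret$gene[!is.na(ret$gene) & ret$gene != ""]))
  )
  list(scan = scan, perm = perm, retained = ret, diff_ids = diff_ids,
       counts = counts, gm = gm, design = design)
}

## which groups does a retained variant mark as high-frequency ("+")?
.group_matches <- function(retained, catalog) {
  rows <- do.call(rbind, lapply(seq_len(nrow(retained)), function(i) {
    g <- regmatches(retained$profile[i],
                    gregexpr("[VPK](?=\\+)", retained$profile[i],
                             perl = TRUE))[[1]]
    if (length(g) == 0) return(NULL)
    data.frame(group = g, variant_id = retained$variant_id[i],
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) return(NULL)
  rows <- unique(rows)
  m <- merge(rows, catalog[, c("variant_id", "trait")], by = "variant_id")
  if (nrow(m) == 0) return(NULL)
  m[, c("group", "variant_id", "trait")]
}

#' Run the full stratification pipeline
#'
#' Composes every stage: data acquisition (simulation or VCF + sample
#' sheet), per-comparison call-rate filtering, pairwise allelic Fisher
#' scans, label-permutation filtering and retention per cohort; when two
#' cohorts are available, three-level replication, background-control
#' contrasts on the replicated-profile set, catalog mapping, random-set
#' enrichment, per-group trait enrichment and the risk-stratification
#' table; and the Fisher power curve. All module outputs are written as
#' TSV/JSON under \code{outdir} together with a JSON manifest (seed,
#' parameters, package version, per-stage counts). Outputs are a pure
#' function of (inputs, config, seed).
#'
#' @param config config list (see \code{\link{read_run_config}}) or a
#'   path to a YAML config file.
#' @param outdir output directory (created if absent).
#' @param seed optional master seed overriding \code{config$seed}.
#' @return invisibly, a list with all in-memory stage results plus the
#'   manifest.
#' @export
run_pipeline <- function(config, outdir, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(.default_config(), config)
  if (!is.null(config$inputs)) cfg$simulation <- NULL
  if (!is.null(seed)) cfg$seed <- seed
  seed <- as.integer(cfg$seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(seed = seed,
                   package_version = as.character(
                     utils::packageVersion("exomestrat")),
                   parameters = cfg[c("pairs", "call_rate_threshold",
                                      "alpha", "permutation", "enrichment",
                                      "power")],
                   counts = list())

  ## --- stage: acquire ---------------------------------------------------
  two_cohorts <- FALSE
  truth <- NULL
  if (!is.null(cfg$simulation)) {
    simargs <- cfg$simulation
    two_cohorts <- !identical(simargs$two_cohorts, FALSE)
    simargs$two_cohorts <- NULL
    simargs$seed <- seed
    sc <- do.call(sim_config, simargs)
    if (two_cohorts) {
      .log("simulating two-cohort replication pair (",
           sc$n_variants, " variants, ", sc$n_per_group, " per group)")
      sim <- simulate_replication_pair(sc)
      cohA <- sim$cohortA; cohB <- sim$cohortB; truth <- sim$truth
    } else {
      .log("simulating single cohort")
      one <- simulate_cohort(sc)
      cohA <- list(matrix = one$matrix, design = one$design)
      truth <- one$truth
    }
    catalog <- simulate_catalog(sc, cohA$matrix)
    manifest$counts$truth_rows <- .write_tsv(truth,
                                             file.path(outdir, "truth.tsv"))
  } else {
    inp <- cfg$inputs
    .log("reading cohort A genotypes from ", inp$vcf_a)
    a <- read_genotypes(inp$vcf_a, inp$sheet_a)
    cohA <- list(matrix = a$matrix, design = a$design)
    if (!is.null(inp$vcf_b)) {
      .log("reading cohort B genotypes from ", inp$vcf_b)
      b <- read_genotypes(inp$vcf_b, inp$sheet_b)
      cohB <- list(matrix = b$matrix, design = b$design)
      two_cohorts <- TRUE
    }
    catalog <- if (!is.null(inp$catalog)) read_catalog(inp$catalog) else NULL
  }
  if (!is.null(catalog))
    manifest$counts$catalog_entries <- .write_tsv(
      catalog, file.path(outdir, "catalog.tsv"))

  ## --- stage: per-cohort scan + permutation -----------------------------
  resA <- .analyse_cohort(cohA$matrix, cohA$design, cfg, seed + 10L,
                          "cohortA", outdir)
  manifest$counts$cohortA <- resA$counts
  resB <- NULL
  if (two_cohorts) {
    resB <- .analyse_cohort(cohB$matrix, cohB$design, cfg, seed + 20L,
                            "cohortB", outdir)
    manifest$counts$cohortB <- resB$counts
  } else {
    manifest$counts$note <- "single cohort: replication stage skipped"
  }

  ## --- stage: replication + background contrasts ------------------------
  rep_report <- NULL; bg <- NULL
  if (two_cohorts) {
    .log("three-level cross-cohort replication")
    rep_report <- replicate_cohorts(resA$retained, resB$retained)
    manifest$counts$replication <- list(
      level1_genes = .write_tsv(
        data.frame(gene = rep_report$level1_genes),
        file.path(outdir, "replication_level1_genes.tsv")),
      level2_snps = .write_tsv(
        data.frame(variant_id = rep_report$level2_snps),
        file.path(outdir, "replication_level2_snps.tsv")),
      level3_profiles = .write_tsv(
        rep_report$level3,
        file.path(outdir, "replication_level3_profiles.tsv")))
    l3_ids <- unique(rep_report$level3$variant_id)
    if (length(l3_ids)) {
      .log("background-control contrasts on ", length(l3_ids),
           " replicated-profile variants")
      bg <- do.call(rbind, lapply(list(resA, resB), function(rr) {
        tagc <- rr$design$cohort[1]
        do.call(rbind, lapply(c("V", "P", "K"), function(g) {
          out <- background_contrast(rr$gm, rr$design, g, l3_ids,
                                     alpha = cfg$alpha)
          out$cohort <- tagc
          out
        }))
      }))
      manifest$counts$background_contrast_rows <- .write_tsv(
        bg, file.path(outdir, "background_contrasts.tsv"))
    }
  }

  ## --- stage: catalog annotation + enrichment + risk table --------------
  enrich <- list(); risk <- list(); traits <- list()
  if (!is.null(catalog)) {
    cohort_results <- Filter(Negate(is.null),
                             list(cohortA = resA, cohortB = resB))
    for (tag in names(cohort_results)) {
      rr <- cohort_results[[tag]]
      matches <- map_to_catalog(rr$diff_ids, catalog)
      manifest$counts[[paste0(tag, "_catalog_matches")]] <- .write_tsv(
        matches, file.path(outdir, paste0(tag, "_catalog_matches.tsv")))
      pool <- unique(rr$scan$variant_id)
      .log(tag, ": random-set enrichment (", cfg$enrichment$n_iter,
           " draws)")
      er <- random_set_enrichment(pool, rr$diff_ids, catalog,
                                  n_iter = cfg$enrichment$n_iter,
                                  seed = seed + 30L)
      enrich[[tag]] <- er[c("observed_count", "null_median", "chi_square",
                            "p", "empirical_p", "n_iter", "draw_size")]
      gmatch <- .group_matches(rr$retained, catalog)
      if (!is.null(gmatch) && nrow(gmatch)) {
        te <- trait_enrichment(gmatch, catalog)
        manifest$counts[[paste0(tag, "_trait_enrichment_rows")]] <-
          .write_tsv(te, file.path(outdir,
                                   paste0(tag, "_trait_enrichment.tsv")))
        traits[[tag]] <- te
      }
      cat_ids <- intersect(rr$diff_ids, unique(catalog$variant_id))
      if (length(cat_ids)) {
        bgr <- do.call(rbind, lapply(c("V", "P", "K"), function(g)
          background_contrast(rr$gm, rr$design, g, cat_ids,
                              alpha = cfg$alpha)))
        rt <- risk_stratify(rr$gm, rr$design, rr$retained, bgr, catalog,
                            alpha = cfg$alpha)
        manifest$counts[[paste0(tag, "_risk_rows")]] <- .write_tsv(
          rt, file.path(outdir, paste0(tag, "_risk_table.tsv")))
        risk[[tag]] <- rt
      }
    }
    jsonlite::write_json(enrich,
                         file.path(outdir, "enrichment_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  ## --- stage: power ------------------------------------------------------
  pcfg <- cfg$power
  p1 <- pcfg$p1; p2 <- pcfg$p2
  if (is.null(p1) || is.null(p2)) {
    if (!is.null(cfg$simulation)) {
      p1 <- cfg$simulation$effect[1] %||% 0.8
      p2 <- cfg$simulation$effect[2] %||% 0.2
    } else if (nrow(resA$retained)) {
      top <- resA$retained[which.min(resA$retained$p), ]
      p1 <- top$freq_a; p2 <- top$freq_b
    } else {
      p1 <- 0.8; p2 <- 0.2
    }
  }
  .log("power curve at p1 = ", p1, ", p2 = ", p2)
  pc <- power_curve(p1, p2, sizes = pcfg$sizes, alpha = cfg$alpha,
                    n_sim = pcfg$n_sim, seed = seed + 40L)
  manifest$counts$power_rows <- .write_tsv(
    pc, file.path(outdir, "power_curve.tsv"))

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .log("pipeline complete; outputs in ", outdir)
  invisible(list(cohortA = resA, cohortB = resB, truth = truth,
                 replication = rep_report, background = bg,
                 enrichment = enrich, trait_enrichment = traits,
                 risk = risk, power = pc, manifest = manifest,
                 catalog = catalog))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
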