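#' Read a risk-allele catalog TSV
#'
#' Accepts a catalog-download compatible subset with columns \code{SNPS},
#' \code{DISEASE/TRAIT}, \code{PARENT_TERM}, \code{RISK_ALLELE} and
#' \code{RAF}; extra columns are ignored. Risk alleles in the
#' \code{rsID-A} dialect are parsed by splitting on the final hyphen; an
#' \code{RAF} of \code{"NR"} (not reported) becomes \code{NA}.
#'
#' @param path path to the TSV.
#' @return data.frame \code{variant_id, trait, parent_term, risk_allele,
#'   catalog_raf}.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  req <- c("SNPS", "DISEASE/TRAIT", "PARENT_TERM", "RISK_ALLELE", "RAF")
  if (!all(req %in% names(raw)))
    stop("catalog must have columns: ", paste(req, collapse = ", "))
  risk <- raw$RISK_ALLELE
  has_dash <- grepl("-", risk, fixed = TRUE)
  risk[has_dash] <- sub(".*-", "", risk[has_dash])
  raf <- suppressWarnings(as.numeric(raw$RAF))
  bad <- !is.na(raf) & (raf < 0 | raf > 1)
  if (any(bad)) stop("catalog RAF out of [0,1] at row(s): ",
                     paste(which(bad), collapse = ", "))
  data.frame(variant_id = raw$SNPS, trait = raw$`DISEASE/TRAIT`,
             parent_term = raw$PARENT_TERM, risk_allele = risk,
             catalog_raf = raf, stringsAsFactors = FALSE)
}

#' Map differentiating variants to the catalog
#'
#' Inner join on variant id: one output row per (variant, trait) pair.
#' Parent-term rollup counts are attached as the \code{"parent_counts"}
#' attribute (one row per parent term with the number of matched
#' variant-trait rows), feeding bar-style summaries.
#'
#' @param snp_ids character vector of differentiating variant ids.
#' @param catalog catalog data.frame from \code{\link{read_catalog}} or
#'   \code{\link{simulate_catalog}}.
#' @return data.frame of matches (catalog columns, restricted to
#'   \code{snp_ids}).
#' @export
map_to_catalog <- function(snp_ids, catalog) {
  m <- catalog[catalog$variant_id %in% snp_ids, , drop = FALSE]
  rownames(m) <- NULL
  if (nrow(m)) {
    counts <- as.data.frame(table(parent_term = m$parent_term),
                            stringsAsFactors = FALSE)
    names(counts)[2] <- "n"
  } else {
    counts <- data.frame(parent_term = character(), n = integer(),
                         stringsAsFactors = FALSE)
  }
  attr(m, "parent_counts") <- counts
  m
}

#' Random-set resampling null for catalog enrichment
#'
#' Draws \code{n_iter} uniform random sets of \code{length(diff_set)}
#' variant ids (without replacement) from the scanned pool, counts each
#' draw's catalog matches, and compares the observed match count of the
#' differentiating set against the median of the null draws with a 1-df
#' chi-square goodness-of-fit statistic,
#' \code{(observed - median)^2 / median}. The full null distribution of
#' draw counts is returned so an empirical tail probability is also
#' available.
#'
#' @param pool character vector: all scanned variant ids.
#' @param diff_set character vector: differentiating variant ids (the draw
#'   size).
#' @param catalog catalog data.frame.
#' @param n_iter number of random draws; default 1000.
#' @param seed optional RNG seed.
#' @return list of class \code{enrichment_result}: \code{observed_count},
#'   \code{null_median}, \code{chi_square}, \code{p} (upper 1-df tail;
#'   \code{NA} with a message when the null median is 0),
#'   \code{empirical_p}, \code{n_iter}, \code{draw_size},
#'   \code{null_counts}.
#' @export
random_set_enrichment <- function(pool, diff_set, catalog, n_iter = 1000,
                                  seed = NULL) {
  draw_size <- length(diff_set)
  if (length(pool) < draw_size)
    stop("pool must be at least as large as the differentiating set")
  if (!is.null(seed)) set.seed(seed)
  cat_ids <- unique(catalog$variant_id)
  observed <- sum(unique(diff_set) %in% cat_ids)
  in_cat <- pool %in% cat_ids
  null_counts <- vapply(seq_len(n_iter), function(i)
    sum(in_cat[sample.int(length(pool), draw_size)]), integer(1))
  med <- stats::median(null_counts)
  if (med == 0) {
    message("null median is 0; chi-square statistic undefined")
    chi <- NA_real_; p <- NA_real_
  } else {
    chi <- (observed - med)^2 / med
    p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  }
  structure(list(observed_count = observed, null_median = med,
                 chi_square = chi, p = p,
                 empirical_p = (1 + sum(null_counts >= observed)) /
                   (n_iter + 1),
                 n_iter = n_iter, draw_size = draw_size,
                 null_counts = null_counts),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("random-set catalog enrichment:\n")
  cat("  observed matches:", x$observed_count,
      " null median:", x$null_median,
      sprintf(" (%d draws of %d)\n", x$n_iter, x$draw_size))
  cat("  chi-square:", format(x$chi_square),
      " p:", format(x$p),
      " empirical p:", format(x$empirical_p), "\n")
  invisible(x)
}

#' Per-group trait enrichment against the whole catalog
#'
#' For each (group, trait) with at least one match among the group's
#' differentiating variants, performs a two-sided Fisher exact test on the
#' 2x2 table [trait matches in group's SNPs, other-trait matches in
#' group's SNPs; trait entries in catalog, other entries in catalog] —
#' i.e. the full catalog is the background composition.
#'
#' @param group_matches data.frame with columns \code{group},
#'   \code{variant_id}, \code{trait}: catalog match rows per group.
#' @param catalog catalog data.frame.
#' @return data.frame \code{group, trait, parent_term, hits, group_total,
#'   catalog_trait, catalog_total, p} sorted by p within group.
#' @export
trait_enrichment <- function(group_matches, catalog) {
  if (!all(c("group", "variant_id", "trait") %in% names(group_matches)))
    stop("group_matches needs columns group, variant_id, trait")
  cat_tab <- table(catalog$trait)
  cat_total <- nrow(catalog)
  out <- do.call(rbind, lapply(split(group_matches, group_matches$group),
    function(gm) {
      tt <- table(gm$trait)
      total <- nrow(gm)
      rows <- lapply(names(tt), function(tr) {
        if (!tr %in% names(cat_tab))
          stop("trait absent from catalog: ", tr)
        hits <- as.integer(tt[[tr]])
        ct <- as.integer(cat_tab[[tr]])
        tab <- matrix(c(hits, total - hits, ct, cat_total - ct), nrow = 2)
        data.frame(group = gm$group[1], trait = tr,
                   parent_term = catalog$parent_term[
                     match(tr, catalog$trait)],
                   hits = hits, group_total = total,
                   catalog_trait = ct, catalog_total = cat_total,
                   p = stats::fisher.test(tab)$p.value,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }))
  out <- out[order(out$group, out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Orient group allele frequencies to the catalog risk allele
#'
#' The risk-allele frequency equals the alternate-allele frequency when
#' the catalog risk allele is the variant's alternate allele, and its
#' complement when it is the reference allele. A risk allele matching
#' neither allele is unalignable and yields \code{NA} (the caller should
#' drop and log such rows).
#'
#' @param ref,alt variant alleles (vectorised).
#' @param risk_allele catalog risk allele (vectorised).
#' @param alt_freq alternate-allele frequency (vectorised, may be a matrix
#'   with one column per group when ref/alt/risk are length 1).
#' @return risk-allele frequency, same shape as \code{alt_freq}, or
#'   \code{NA} where unalignable.
#' @export
align_risk_allele <- function(ref, alt, risk_allele, alt_freq) {
  n <- max(length(ref), length(alt), length(risk_allele), length(alt_freq))
  is_alt <- rep_len(risk_allele == alt, n)
  is_ref <- rep_len(risk_allele == ref, n)
  f <- rep_len(as.vector(alt_freq), n)
  out <- ifelse(is_alt, f, ifelse(is_ref, 1 - f, NA_real_))
  if (is.matrix(alt_freq) && length(alt_freq) == n)
    out <- matrix(out, nrow = nrow(alt_freq), dimnames = dimnames(alt_freq))
  else if (length(alt_freq) == n) names(out) <- names(alt_freq)
  out
}

#' Risk stratification table for catalog-matched differentiating variants
#'
#' Builds the per-variant risk table: risk-allele frequency (RAF) per
#' constitution group, pooled over V+P+K, in the background control and in
#' the catalog; the significant group-group and group-control contrasts;
#' and marks for the higher (\code{##}) and lower (\code{*}) RAF group of
#' each significant differentiating pair. Only variants with at least one
#' significant group-group contrast AND at least one significant
#' group-control contrast are kept. Rows whose catalog risk allele matches
#' neither variant allele are dropped with a message. When the catalog RAF
#' is reported, \code{exceeds_catalog} flags rows where some group's RAF
#' exceeds it (\code{NA} when unreported).
#'
#' @param gm a \code{genotype_matrix}.
#' @param design a \code{cohort_design}.
#' @param diff_results retained association results (from
#'   \code{\link{retained_scan}}) holding the significant group-group
#'   contrasts.
#' @param bg_contrasts rbind of \code{\link{background_contrast}} results
#'   for V, P and K.
#' @param catalog catalog data.frame.
#' @param cohort optional cohort restriction.
#' @param alpha significance threshold for contrasts; default 0.05.
#' @return data.frame of class \code{risk_table}: one row per (variant,
#'   trait) with columns \code{variant_id, gene, trait, risk_allele,
#'   raf_V, raf_P, raf_K, raf_pooled, raf_C, catalog_raf, sig_contrasts,
#'   high_group, low_group, exceeds_catalog}.
#' @export
risk_stratify <- function(gm, design, diff_results, bg_contrasts, catalog,
                          cohort = NULL, alpha = 0.05) {
  sig_gg <- diff_results[diff_results$p < alpha, , drop = FALSE]
  sig_gc <- bg_contrasts[bg_contrasts$p < alpha, , drop = FALSE]
  ids <- intersect(unique(sig_gg$variant_id), unique(sig_gc$variant_id))
  m <- catalog[catalog$variant_id %in% ids, , drop = FALSE]
  if (nrow(m) == 0L)
    return(structure(data.frame(variant_id = character(), gene = character(),
                                trait = character(), risk_allele = character(),
                                raf_V = numeric(), raf_P = numeric(),
                                raf_K = numeric(), raf_pooled = numeric(),
                                raf_C = numeric(), catalog_raf = numeric(),
                                sig_contrasts = character(),
                                high_group = character(),
                                low_group = character(),
                                exceeds_catalog = logical(),
                                stringsAsFactors = FALSE),
                     class = c("risk_table", "data.frame")))
  groups <- c("V", "P", "K", "C")
  gsam <- lapply(groups, group_samples, design = design, cohort = cohort)
  names(gsam) <- groups
  pooled <- unlist(gsam[c("V", "P", "K")], use.names = FALSE)

  rows <- lapply(seq_len(nrow(m)), function(i) {
    vid <- m$variant_id[i]
    vi <- match(vid, gm$variants$id)
    if (is.na(vi)) return(NULL)
    ref <- gm$variants$ref[vi]; alt <- gm$variants$alt[vi]
    risk <- m$risk_allele[i]
    if (risk != ref && risk != alt) {
      message("risk allele ", risk, " for ", vid,
              " matches neither ", ref, " nor ", alt, "; row dropped")
      return(NULL)
    }
    af <- vapply(groups, function(g)
      alt_allele_frequency(gm, vi, gsam[[g]]), numeric(1))
    af_pooled <- alt_allele_frequency(gm, vi, pooled)
    raf <- align_risk_allele(ref, alt, risk, af)
    raf_pooled <- align_risk_allele(ref, alt, risk, af_pooled)

    gg <- sig_gg[sig_gg$variant_id == vid, , drop = FALSE]
    gc <- sig_gc[sig_gc$variant_id == vid, , drop = FALSE]
    contrasts <- c(gg$pair, gc$pair)
    # mark per significant group-group pair: higher RAF group gets ##
    hi <- lo <- character(0)
    for (pr in gg$pair) {
      gs <- strsplit(pr, "-", fixed = TRUE)[[1]]
      if (is.na(raf[gs[1]]) || is.na(raf[gs[2]]) ||
          raf[gs[1]] == raf[gs[2]]) next
      hi <- c(hi, gs[which.max(raf[gs])])
      lo <- c(lo, gs[which.min(raf[gs])])
    }
    exceeds <- if (is.na(m$catalog_raf[i])) NA else
      any(raf[c("V", "P", "K")] > m$catalog_raf[i], na.rm = TRUE)
    data.frame(variant_id = vid, gene = gm$variants$gene[vi],
               trait = m$trait[i], risk_allele = risk,
               raf_V = raf[["V"]], raf_P = raf[["P"]], raf_K = raf[["K"]],
               raf_pooled = raf_pooled, raf_C = raf[["C"]],
               catalog_raf = m$catalog_raf[i],
               sig_contrasts = paste(unique(contrasts), collapse = ","),
               high_group = paste(unique(hi), collapse = ","),
               low_group = paste(unique(lo), collapse = ","),
               exceeds_catalog = exceeds,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  class(out) <- c("risk_table", "data.frame")
  out
}
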