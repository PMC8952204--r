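#' Three-level cross-cohort replication of differentiating variants
#'
#' Compares the retained (differentiating) association results of two
#' cohorts at three nested levels: (1) genes present in both cohorts'
#' differentiating sets, (2) identical variant ids retained in both, and
#' (3) identical variants whose direction profile matches exactly for the
#' same group pair in both cohorts ("replicated profile" variants). Tie
#' profiles never match at level 3. By construction level 3 is a subset of
#' level 2, and the genes of level-2 variants (when annotated) are a
#' subset of level 1.
#'
#' @param setA,setB retained association results of the two cohorts (as
#'   returned by \code{\link{retained_scan}}), analysed with identical
#'   pair definitions.
#' @param level2_same_pair when \code{TRUE}, level 2 additionally requires
#'   retention for the same group pair in both cohorts; default
#'   \code{FALSE} (any pair).
#' @return list of class \code{replication_report} with elements
#'   \code{level1_genes}, \code{level2_snps}, \code{level3} (data.frame
#'   \code{variant_id, pair, profile} of matching profile rows) and
#'   \code{detail} (per shared variant and pair: both cohorts' profiles and
#'   the match flag).
#' @export
replicate_cohorts <- function(setA, setB, level2_same_pair = FALSE) {
  genes_of <- function(s) {
    g <- unique(s$gene)
    miss <- sum(is.na(s$gene) | s$gene == "")
    if (miss)
      message(miss, " retained row(s) without gene annotation excluded ",
              "from level-1 gene replication")
    g[!is.na(g) & g != ""]
  }
  level1 <- sort(intersect(genes_of(setA), genes_of(setB)))

  if (level2_same_pair) {
    kA <- unique(paste(setA$variant_id, setA$pair))
    kB <- unique(paste(setB$variant_id, setB$pair))
    level2 <- sort(unique(sub(" .*", "", intersect(kA, kB))))
  } else {
    level2 <- sort(intersect(unique(setA$variant_id),
                             unique(setB$variant_id)))
  }

  kA <- paste(setA$variant_id, setA$pair)
  kB <- paste(setB$variant_id, setB$pair)
  shared <- intersect(kA, kB)
  iA <- match(shared, kA); iB <- match(shared, kB)
  detail <- data.frame(variant_id = setA$variant_id[iA],
                       pair = setA$pair[iA],
                       profile_A = setA$profile[iA],
                       profile_B = setB$profile[iB],
                       stringsAsFactors = FALSE)
  tie <- grepl("=", detail$profile_A, fixed = TRUE) |
    grepl("=", detail$profile_B, fixed = TRUE)
  detail$match <- !tie & detail$profile_A == detail$profile_B
  detail <- detail[detail$variant_id %in% level2, , drop = FALSE]
  rownames(detail) <- NULL

  l3 <- detail[detail$match, c("variant_id", "pair", "profile_A")]
  names(l3)[3] <- "profile"
  rownames(l3) <- NULL

  structure(list(level1_genes = level1, level2_snps = level2,
                 level3 = l3, detail = detail),
            class = "replication_report")
}

#' @export
print.replication_report <- function(x, ...) {
  cat("replication_report:\n")
  cat("  level 1 (shared genes):            ", length(x$level1_genes), "\n")
  cat("  level 2 (identical variants):      ", length(x$level2_snps), "\n")
  cat("  level 3 (replicated profiles):     ",
      length(unique(x$level3$variant_id)), "\n")
  invisible(x)
}

#' Contrast one constitution group against the background control
#'
#' Allelic two-sided Fisher test of a group (V, P or K) against the
#' background control group C within one cohort, for a listed set of
#' variants (typically the replicated-profile set). Rows with p below
#' \code{alpha} are flagged significant.
#'
#' @param gm a \code{genotype_matrix}.
#' @param design a \code{cohort_design} containing group C.
#' @param group the constitution group to contrast ("V", "P" or "K").
#' @param snp_set character vector of variant ids; all must exist in the
#'   matrix.
#' @param cohort optional cohort restriction.
#' @param alpha significance flag threshold; default 0.05.
#' @return data.frame \code{variant_id, pair, a, b, c, d, freq_group,
#'   freq_control, p, significant}.
#' @export
background_contrast <- function(gm, design, group, snp_set, cohort = NULL,
                                alpha = 0.05) {
  idx <- match(snp_set, gm$variants$id)
  if (anyNA(idx))
    stop("variant(s) not in matrix: ",
         paste(snp_set[is.na(idx)], collapse = ", "))
  sG <- group_samples(design, group, cohort)
  sC <- group_samples(design, "C", cohort)
  if (length(sC) == 0L) stop("design has no background control samples (C)")
  GG <- gm$genotypes[sG, idx, drop = FALSE]
  GC <- gm$genotypes[sC, idx, drop = FALSE]
  nG <- colSums(!is.na(GG)); nC <- colSums(!is.na(GC))
  if (any(nG == 0L | nC == 0L))
    stop("variant with no non-missing genotypes in group or control")
  aa <- colSums(GG, na.rm = TRUE); cc <- colSums(GC, na.rm = TRUE)
  bb <- 2L * nG - aa; dd <- 2L * nC - cc
  p <- fisher_two_sided(aa, bb, cc, dd)
  data.frame(variant_id = snp_set,
             pair = paste0(group, "-C"),
             a = as.integer(aa), b = as.integer(bb),
             c = as.integer(cc), d = as.integer(dd),
             freq_group = aa / (2 * nG), freq_control = cc / (2 * nC),
             p = p, significant = p < alpha,
             stringsAsFactors = FALSE)
}
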