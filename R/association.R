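#' Two-sided Fisher exact p-value for 2x2 allele-count tables
#'
#' Vectorised over tables. The two-sided p-value follows the
#' minimum-likelihood rule used by standard implementations (and by PLINK's
#' allelic test): with the margins fixed, it sums the hypergeometric
#' probabilities of every table whose probability does not exceed that of
#' the observed table (no mid-p, no tail doubling). A small relative
#' tolerance guards against ties lost to floating point.
#'
#' @param a,b alt and ref allele counts in group A.
#' @param c,d alt and ref allele counts in group B.
#' @return numeric vector of p-values in (0, 1].
#' @export
fisher_two_sided <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.integer(a), n); b <- rep_len(as.integer(b), n)
  c <- rep_len(as.integer(c), n); d <- rep_len(as.integer(d), n)
  if (anyNA(a) || anyNA(b) || anyNA(c) || anyNA(d))
    stop("allele counts must be non-missing")
  if (any(a < 0 | b < 0 | c < 0 | d < 0))
    stop("allele counts must be non-negative")
  key <- paste(a, b, c, d)
  first <- !duplicated(key)
  pu <- vapply(which(first), function(i)
    .fisher_p_one(a[i], b[i], c[i], d[i]), numeric(1))
  names(pu) <- key[first]
  unname(pu[key])
}

.fisher_p_one <- function(a, b, c, d) {
  m <- a + b; nn <- c + d; k <- a + c
  if (m == 0L || nn == 0L || k == 0L || k == m + nn) return(1)
  lo <- max(0L, k - nn); hi <- min(k, m)
  dens <- stats::dhyper(lo:hi, m, nn, k)
  p <- sum(dens[dens <= dens[a - lo + 1L] * (1 + 1e-7)])
  min(p, 1)
}

#' Allelic 2x2 table for one variant and two groups
#'
#' Counts alleles (two per non-missing diploid genotype); missing genotypes
#' contribute nothing.
#'
#' @param gm a \code{genotype_matrix}.
#' @param variant_index column index of the variant.
#' @param groupA,groupB character vectors of sample ids.
#' @return named integer vector \code{c(a, b, c, d)}: alt/ref counts in
#'   group A then group B.
#' @export
allelic_counts <- function(gm, variant_index, groupA, groupB) {
  gA <- gm$genotypes[groupA, variant_index]
  gB <- gm$genotypes[groupB, variant_index]
  nA <- sum(!is.na(gA)); nB <- sum(!is.na(gB))
  if (nA == 0L || nB == 0L)
    stop("no non-missing genotypes in one of the groups")
  altA <- sum(gA, na.rm = TRUE); altB <- sum(gB, na.rm = TRUE)
  c(a = altA, b = 2L * nA - altA, c = altB, d = 2L * nB - altB)
}

#' Allele-frequency profile label for a group pair
#'
#' \code{"V+K-"} marks a strictly higher alternate-allele frequency in V
#' than in K. Exact ties get the tie marker \code{"V=K"} and are excluded
#' from profile replication, which requires a strict direction.
#'
#' @param freq_a,freq_b alternate-allele frequencies of the two groups
#'   (vectorised).
#' @param labels character vector of length 2: the two group labels, in the
#'   same order as the frequencies.
#' @return character vector of profile labels.
#' @export
assign_profile <- function(freq_a, freq_b, labels) {
  if (length(labels) != 2L) stop("labels must name exactly two groups")
  ifelse(is.na(freq_a) | is.na(freq_b), NA_character_,
    ifelse(freq_a > freq_b, paste0(labels[1], "+", labels[2], "-"),
      ifelse(freq_a < freq_b, paste0(labels[1], "-", labels[2], "+"),
        paste0(labels[1], "=", labels[2]))))
}

.pair_key <- function(pair) paste0(pair[1], "-", pair[2])

#' Pairwise allelic Fisher scan
#'
#' For each requested group pair: applies the per-comparison call-rate
#' filter over that pair's samples, then computes the allelic 2x2 table,
#' both alternate-allele frequencies, the two-sided Fisher exact p-value
#' and the direction profile for every surviving variant. No
#' multiple-testing correction is applied at this stage; the permutation
#' filter is the second gate.
#'
#' @param gm a \code{genotype_matrix}.
#' @param design a \code{cohort_design}.
#' @param pairs list of length-2 character vectors of group labels;
#'   defaults to the three constitution contrasts V-P, P-K, V-K.
#' @param cohort optional cohort label to restrict samples to.
#' @param call_rate_threshold minimum per-pair call rate (default 0.5).
#' @return data.frame with one row per (pair, surviving variant):
#'   \code{variant_id, gene, pair, a, b, c, d, freq_a, freq_b, p, profile}.
#' @export
pairwise_scan <- function(gm, design,
                          pairs = list(c("V", "P"), c("P", "K"), c("V", "K")),
                          cohort = NULL, call_rate_threshold = 0.5) {
  known <- unique(design$group)
  res <- lapply(pairs, function(pr) {
    if (!all(pr %in% known))
      stop("unknown group label in pair: ", .pair_key(pr))
    sA <- group_samples(design, pr[1], cohort)
    sB <- group_samples(design, pr[2], cohort)
    if (length(sA) < 2L || length(sB) < 2L)
      stop("each compared group needs at least 2 samples (", .pair_key(pr), ")")
    keep <- filter_by_call_rate(gm, c(sA, sB), call_rate_threshold)
    if (length(keep) == 0L) return(NULL)
    GA <- gm$genotypes[sA, keep, drop = FALSE]
    GB <- gm$genotypes[sB, keep, drop = FALSE]
    nA <- colSums(!is.na(GA)); nB <- colSums(!is.na(GB))
    ok <- nA > 0L & nB > 0L
    keep <- keep[ok]
    if (length(keep) == 0L) return(NULL)
    GA <- GA[, ok, drop = FALSE]; GB <- GB[, ok, drop = FALSE]
    nA <- nA[ok]; nB <- nB[ok]
    aa <- colSums(GA, na.rm = TRUE); cc <- colSums(GB, na.rm = TRUE)
    bb <- 2L * nA - aa; dd <- 2L * nB - cc
    fa <- aa / (2 * nA); fb <- cc / (2 * nB)
    data.frame(variant_id = gm$variants$id[keep],
               gene = gm$variants$gene[keep],
               pair = .pair_key(pr),
               a = as.integer(aa), b = as.integer(bb),
               c = as.integer(cc), d = as.integer(dd),
               freq_a = fa, freq_b = fb,
               p = fisher_two_sided(aa, bb, cc, dd),
               profile = assign_profile(fa, fb, pr),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(variant_id = character(), gene = character(),
                      pair = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(), freq_a = numeric(),
                      freq_b = numeric(), p = numeric(),
                      profile = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("association_scan", "data.frame")
  out
}

#' Write a pairwise scan to TSV (one file per pair or a single table)
#'
#' @param scan an \code{association_scan} data.frame.
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
write_scan_tsv <- function(scan, path) {
  utils::write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
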