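#' Permutation settings
#'
#' @param n_perm number of label permutations (>= 1). Default 2000, a
#'   desk-scale setting; the full-scale analyses this mirrors used 80000.
#'   The empirical p-value formula is scale-free in \code{n_perm}.
#' @param alpha retention threshold in (0,1); default 0.05.
#' @param seed optional integer RNG seed for reproducible shuffles.
#' @param rule retention rule: \code{"both"} (default) requires the
#'   observed Fisher p and the empirical permutation p to both be at or
#'   below \code{alpha}; \code{"permutation"} uses the empirical p alone.
#' @return list of class \code{permutation_config}.
#' @export
permutation_config <- function(n_perm = 2000, alpha = 0.05, seed = NULL,
                               rule = c("both", "permutation")) {
  rule <- match.arg(rule)
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  structure(list(n_perm = as.integer(n_perm), alpha = alpha, seed = seed,
                 rule = rule), class = "permutation_config")
}

#' Empirical permutation p-value with add-one correction
#'
#' \code{(r + 1) / (n_perm + 1)}, where \code{r} counts permutations whose
#' test statistic was at least as extreme as the observed one. The add-one
#' correction keeps the p-value strictly positive.
#'
#' @param r exceedance count(s), \code{0 <= r <= n_perm}.
#' @param n_perm number of permutations.
#' @return numeric vector of empirical p-values in (0, 1].
#' @export
empirical_p <- function(r, n_perm) {
  if (any(r < 0) || any(r > n_perm)) stop("need 0 <= r <= n_perm")
  (r + 1) / (n_perm + 1)
}

## Precompute two-sided hypergeometric p-values for every reachable
## (missing-split, alt-count-split) of each variant. With the pair's
## samples fixed, a variant's total allele number and total alt count do
## not change under label shuffling; only the number of alleles landing in
## group A (mA, driven by how many missing genotypes fall there) and the
## alt count in A (x) vary. Layout: one block per variant, sub-blocks over
## h = number of missing genotypes assigned to A, each of length k+1
## indexed by x.
.perm_lookup <- function(ktot, Ntot, z, nA, nB) {
  V <- length(ktot)
  hmin <- pmax(0L, z - nB); hmax <- pmin(z, nA)
  nh <- hmax - hmin + 1L
  L <- ktot + 1L
  block <- nh * L
  off <- c(0L, cumsum(block))[seq_len(V)]
  big <- rep(NA_real_, sum(block))
  relerr <- 1 + 1e-7
  for (v in seq_len(V)) {
    k <- ktot[v]
    for (hi in seq_len(nh[v]) - 1L) {
      h <- hmin[v] + hi
      mA <- 2L * (nA - h); mB <- Ntot[v] - mA
      base <- off[v] + hi * L[v]
      if (mA == 0L || mB == 0L || k == 0L || k == Ntot[v]) {
        xs <- max(0L, k - mB):min(k, mA)
        big[base + xs + 1L] <- 1
        next
      }
      lo <- max(0L, k - mB); hivx <- min(k, mA)
      xs <- lo:hivx
      dens <- stats::dhyper(xs, mA, mB, k)
      ord <- order(dens)
      cs <- cumsum(dens[ord])
      idx <- findInterval(dens * relerr, dens[ord])
      big[base + xs + 1L] <- pmin(cs[pmax(idx, 1L)], 1)
    }
  }
  list(big = big, off = off, L = L, hmin = hmin)
}

#' Label-shuffling permutation scan for one group pair
#'
#' Re-tests every call-rate-surviving variant of a pairwise comparison
#' under random reassignments of the pair's group labels (group sizes
#' preserved), counting for each variant how often the permuted two-sided
#' Fisher p-value is at or below the observed one. The call-rate filter is
#' applied once to the observed labelling and the variant set held fixed
#' across permutations (the missingness pattern is label-independent).
#'
#' @param gm a \code{genotype_matrix}.
#' @param design a \code{cohort_design}.
#' @param pair character vector of the two group labels.
#' @param config a \code{permutation_config}.
#' @param cohort optional cohort restriction.
#' @param call_rate_threshold minimum per-pair call rate (default 0.5).
#' @return data.frame of class \code{permutation_result} with columns
#'   \code{variant_id, pair, observed_p, exceed_count, n_perm,
#'   empirical_p, retained}.
#' @export
permute_scan <- function(gm, design, pair, config = permutation_config(),
                         cohort = NULL, call_rate_threshold = 0.5) {
  stopifnot(inherits(config, "permutation_config"))
  sA <- group_samples(design, pair[1], cohort)
  sB <- group_samples(design, pair[2], cohort)
  nA <- length(sA); nB <- length(sB); nS <- nA + nB
  if (nA < 2L || nB < 2L) stop("each group needs at least 2 samples")
  keep <- filter_by_call_rate(gm, c(sA, sB), call_rate_threshold)
  G <- gm$genotypes[c(sA, sB), keep, drop = FALSE]
  M <- !is.na(G)
  keep_ok <- colSums(M) > 0L
  keep <- keep[keep_ok]
  G <- G[, keep_ok, drop = FALSE]; M <- M[, keep_ok, drop = FALSE]
  V <- length(keep)
  if (V == 0L) stop("no variant survives the call-rate filter")
  G0 <- G; G0[!M] <- 0L
  storage.mode(G0) <- "double"; Mn <- M * 1

  ktot <- as.integer(colSums(G0))
  Ntot <- as.integer(2 * colSums(Mn))
  z <- nS - as.integer(colSums(Mn))
  lut <- .perm_lookup(ktot, Ntot, z, nA, nB)

  obs_in_A <- seq_len(nA)
  altA_obs <- as.integer(colSums(G0[obs_in_A, , drop = FALSE]))
  h_obs <- nA - as.integer(colSums(Mn[obs_in_A, , drop = FALSE]))
  p_obs <- lut$big[lut$off + (h_obs - lut$hmin) * lut$L + altA_obs + 1L]

  if (!is.null(config$seed)) set.seed(config$seed)
  n_perm <- config$n_perm
  exceed <- integer(V)
  chunk <- 500L
  done <- 0L
  while (done < n_perm) {
    B <- min(chunk, n_perm - done)
    Pm <- matrix(0, nS, B)
    for (j in seq_len(B)) Pm[sample.int(nS, nA), j] <- 1
    altA <- crossprod(G0, Pm)
    hmat <- nA - crossprod(Mn, Pm)
    pos <- lut$off + (hmat - lut$hmin) * lut$L + altA + 1
    pp <- matrix(lut$big[pos], nrow = V)
    exceed <- exceed + rowSums(pp <= p_obs)
    done <- done + B
  }

  emp <- empirical_p(exceed, n_perm)
  retained <- if (config$rule == "both")
    p_obs <= config$alpha & emp <= config$alpha else emp <= config$alpha
  out <- data.frame(variant_id = gm$variants$id[keep],
                    pair = .pair_key(pair),
                    observed_p = p_obs,
                    exceed_count = as.integer(exceed),
                    n_perm = n_perm,
                    empirical_p = emp,
                    retained = retained,
                    stringsAsFactors = FALSE)
  class(out) <- c("permutation_result", "data.frame")
  out
}

#' Retained (differentiating) variant set
#'
#' Applies the retention rule to one or more permutation results (rows of
#' several pairs may be concatenated) and returns the deduplicated union of
#' retained variant ids — the cohort's set of unique differentiating
#' variations.
#'
#' @param results a \code{permutation_result} data.frame, or an rbind of
#'   several.
#' @param alpha retention threshold; default 0.05.
#' @param rule \code{"both"} (observed and empirical p at or below alpha)
#'   or \code{"permutation"} (empirical only).
#' @return character vector of unique retained variant ids.
#' @export
retain <- function(results, alpha = 0.05, rule = c("both", "permutation")) {
  rule <- match.arg(rule)
  keep <- if (rule == "both")
    results$observed_p <= alpha & results$empirical_p <= alpha
  else results$empirical_p <= alpha
  unique(results$variant_id[keep])
}

#' Subset a pairwise scan to permutation-retained rows
#'
#' Joins scan rows to permutation results by (variant, pair) and keeps the
#' rows flagged as retained, attaching the empirical p-value.
#'
#' @param scan an \code{association_scan}.
#' @param perm a \code{permutation_result} (rows of several pairs may be
#'   concatenated).
#' @return the retained subset of \code{scan} with an extra
#'   \code{empirical_p} column.
#' @export
retained_scan <- function(scan, perm) {
  key_s <- paste(scan$variant_id, scan$pair)
  key_p <- paste(perm$variant_id, perm$pair)
  i <- match(key_s, key_p)
  keep <- !is.na(i) & perm$retained[i]
  out <- scan[keep, , drop = FALSE]
  out$empirical_p <- perm$empirical_p[i[keep]]
  rownames(out) <- NULL
  out
}
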