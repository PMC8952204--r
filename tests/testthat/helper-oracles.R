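# Independent oracles and small fixture builders used across the suite.

# Two-sided Fisher p by direct hypergeometric enumeration with binomial
# coefficients (independent of the package's dhyper-based path).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  lo <- max(0, k - n); hi <- min(k, m)
  xs <- lo:hi
  pr <- exp(lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k))
  obs <- pr[xs == a]
  min(sum(pr[pr <= obs * (1 + 1e-7)]), 1)
}

# Exact power of the allelic Fisher test by full enumeration of both
# groups' binomial allele counts.
oracle_exact_power <- function(p1, p2, n_per_group, alpha = 0.05) {
  N <- 2 * n_per_group
  xs <- 0:N
  rej <- outer(xs, xs, function(i, j)
    mapply(function(a, c) oracle_fisher_p(a, N - a, c, N - c), i, j) <= alpha)
  sum(outer(dbinom(xs, N, p1), dbinom(xs, N, p2)) * rej)
}

# Build a genotype_matrix directly from a dosage matrix (samples x variants).
make_gm <- function(G, ids = NULL, genes = NULL) {
  V <- ncol(G)
  if (is.null(ids)) ids <- sprintf("rs%03d", seq_len(V))
  variants <- data.frame(chrom = "1", pos = seq_len(V) * 100L, id = ids,
                         ref = "A", alt = "G",
                         gene = if (is.null(genes)) NA_character_ else genes,
                         stringsAsFactors = FALSE)
  samples <- if (is.null(rownames(G))) sprintf("s%02d", seq_len(nrow(G)))
             else rownames(G)
  genotype_matrix(G, variants, samples)
}

# Minimal retained-scan-shaped data.frame for replication tests.
make_retained <- function(variant_id, pair, profile, gene = NA_character_) {
  data.frame(variant_id = variant_id, gene = gene, pair = pair,
             a = 1L, b = 1L, c = 1L, d = 1L, freq_a = 0.5, freq_b = 0.5,
             p = 0.01, profile = profile, empirical_p = 0.01,
             stringsAsFactors = FALSE)
}
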