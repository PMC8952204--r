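#' Simulated power of the two-group allelic Fisher exact test
#'
#' Per simulation, each group's alt-allele count is drawn as
#' Binomial(2 * n_per_group, p) — the allele-count distribution implied by
#' Hardy-Weinberg diploid sampling — and the two-sided Fisher exact test
#' applied to the resulting 2x2 table. Power is the fraction of
#' simulations rejecting at \code{alpha}.
#'
#' @param p1,p2 the two groups' allele frequencies in [0,1].
#' @param n_per_group diploid samples per group (alleles = 2n).
#' @param alpha significance level; default 0.05.
#' @param n_sim simulations; default 1000.
#' @param seed optional RNG seed.
#' @return one-row data.frame \code{p1, p2, n_per_group, alpha, n_sim,
#'   power, se} with \code{se = sqrt(power * (1 - power) / n_sim)}.
#' @export
fisher_power <- function(p1, p2, n_per_group, alpha = 0.05, n_sim = 1000,
                         seed = NULL) {
  if (p1 < 0 || p1 > 1 || p2 < 0 || p2 > 1) stop("frequencies in [0,1]")
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n_alleles <- 2L * as.integer(n_per_group)
  x1 <- stats::rbinom(n_sim, n_alleles, p1)
  x2 <- stats::rbinom(n_sim, n_alleles, p2)
  p <- fisher_two_sided(x1, n_alleles - x1, x2, n_alleles - x2)
  pw <- mean(p <= alpha)
  data.frame(p1 = p1, p2 = p2, n_per_group = as.integer(n_per_group),
             alpha = alpha, n_sim = as.integer(n_sim), power = pw,
             se = sqrt(pw * (1 - pw) / n_sim))
}

#' Power curve over a sample-size grid
#'
#' Evaluates \code{\link{fisher_power}} at each grid size. Raw estimates
#' are reported; no monotone smoothing is applied. The default grid is the
#' stepwise design 18, 50, 100, 500, 1000, 10000 samples per group.
#' Observed frequencies from an association result row can feed
#' \code{p1}/\code{p2} directly.
#'
#' @param p1,p2 the two groups' allele frequencies.
#' @param sizes strictly increasing integer grid of per-group sample
#'   sizes.
#' @param alpha significance level; default 0.05.
#' @param n_sim simulations per grid point; default 1000.
#' @param seed optional RNG seed (one stream across the grid).
#' @return data.frame of class \code{power_curve}, one row per size.
#' @export
power_curve <- function(p1, p2, sizes = c(18, 50, 100, 500, 1000, 10000),
                        alpha = 0.05, n_sim = 1000, seed = NULL) {
  if (any(diff(sizes) <= 0)) stop("sizes must be strictly increasing")
  if (!is.null(seed)) set.seed(seed)
  out <- do.call(rbind, lapply(sizes, function(n)
    fisher_power(p1, p2, n, alpha = alpha, n_sim = n_sim, seed = NULL)))
  class(out) <- c("power_curve", "data.frame")
  out
}
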