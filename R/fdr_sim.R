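# Simulation-based FDR for the site screens, Storey q-values, and the
# hypergeometric enrichment test. The FDR of a screen at fixed thresholds
# is estimated as x/y: the mean number of sites significant in binomial
# null resamplings (x) over the number significant in the observed data (y).

#' Build a pairwise comparison object for FDR estimation
#'
#' Pairs two samples' counts on shared sites; the null model replaces each
#' sample's methylated count with a binomial draw at the site's pooled
#' methylation level.
#'
#' @param sites_a,sites_b Site tables.
#' @param spec A pairwise [comparison_spec()].
#' @return Object of class `pairwise_comparison`.
#' @export
pairwise_comparison <- function(sites_a, sites_b,
                                spec = comparison_spec("strain")) {
  m <- merge(
    sites_a[, c("chrom", "pos", "strand", "meth_count", "total_count")],
    sites_b[, c("chrom", "pos", "strand", "meth_count", "total_count")],
    by = c("chrom", "pos", "strand"), suffixes = c("_a", "_b")
  )
  structure(list(chrom = m$chrom, pos = m$pos, strand = m$strand,
                 k_a = m$meth_count_a, n_a = m$total_count_a,
                 k_b = m$meth_count_b, n_b = m$total_count_b, spec = spec),
            class = "pairwise_comparison")
}

#' Build a group comparison object for FDR estimation
#'
#' Sites x samples count matrices for two groups; the null model redraws
#' every sample's methylated count as a binomial at the site's pooled level
#' across both groups, preserving the coverage pattern.
#'
#' @param meth_a,total_a,meth_b,total_b Integer matrices (sites x samples);
#'   `NA` totals mark uncovered sites.
#' @param spec A group-t-test [comparison_spec()].
#' @return Object of class `group_comparison`.
#' @export
group_comparison <- function(meth_a, total_a, meth_b, total_b,
                             spec = comparison_spec("allele")) {
  stopifnot(nrow(meth_a) == nrow(meth_b),
            all(dim(meth_a) == dim(total_a)),
            all(dim(meth_b) == dim(total_b)))
  structure(list(meth_a = meth_a, total_a = total_a,
                 meth_b = meth_b, total_b = total_b, spec = spec),
            class = "group_comparison")
}

#' Resample a comparison under its binomial null
#'
#' Structure-preserving null draw: every compared sample's methylated count
#' at a site is replaced by Binomial(n, p) with n the sample's observed
#' total and p the site's pooled methylation level across the compared
#' samples.
#'
#' @param x A `pairwise_comparison` or `group_comparison`.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return An object of the same class with resampled counts.
#' @export
simulate_null <- function(x, seed = NULL, ...) UseMethod("simulate_null")

#' @export
simulate_null.pairwise_comparison <- function(x, seed = NULL, ...) {
  draw <- function() {
    p <- (x$k_a + x$k_b) / (x$n_a + x$n_b)
    x$k_a <- stats::rbinom(length(p), x$n_a, p)
    x$k_b <- stats::rbinom(length(p), x$n_b, p)
    x
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' @export
simulate_null.group_comparison <- function(x, seed = NULL, ...) {
  draw <- function() {
    tot <- rowSums(x$total_a, na.rm = TRUE) + rowSums(x$total_b, na.rm = TRUE)
    met <- rowSums(x$meth_a, na.rm = TRUE) + rowSums(x$meth_b, na.rm = TRUE)
    p <- ifelse(tot > 0, met / tot, 0)
    redraw <- function(meth, total) {
      obs <- which(!is.na(total))
      meth[obs] <- stats::rbinom(length(obs), total[obs],
                                 p[(obs - 1L) %% nrow(total) + 1L])
      meth
    }
    x$meth_a <- redraw(x$meth_a, x$total_a)
    x$meth_b <- redraw(x$meth_b, x$total_b)
    x
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Count sites passing a comparison's significance criterion
#'
#' @param x A comparison object.
#' @param ... Unused.
#' @return Integer count of significant sites.
#' @export
count_significant <- function(x, ...) UseMethod("count_significant")

#' @export
count_significant.pairwise_comparison <- function(x, ...) {
  spec <- x$spec
  if (!length(x$k_a)) return(0L)
  level_a <- x$k_a / x$n_a
  level_b <- x$k_b / x$n_b
  ci_a <- binomial_ci(x$k_a, x$n_a, spec$ci_alpha)
  ci_b <- binomial_ci(x$k_b, x$n_b, spec$ci_alpha)
  sig <- x$n_a >= spec$min_coverage & x$n_b >= spec$min_coverage &
    (level_a < ci_b[, 1] | level_a > ci_b[, 2]) &
    (level_b < ci_a[, 1] | level_b > ci_a[, 2]) &
    abs(level_a - level_b) > spec$delta_threshold
  sum(sig)
}

#' @export
count_significant.group_comparison <- function(x, ...) {
  spec <- x$spec
  lev <- function(meth, total) {
    l <- meth / total
    l[is.na(total) | total < spec$min_coverage] <- NA_real_
    l
  }
  la <- lev(x$meth_a, x$total_a)
  lb <- lev(x$meth_b, x$total_b)
  r <- row_ttest(cbind(la, lb), seq_len(ncol(la)),
                 ncol(la) + seq_len(ncol(lb)))
  sig <- r$n_a >= spec$min_group_size & r$n_b >= spec$min_group_size &
    !is.na(r$p) & r$p < spec$p_threshold &
    abs(r$mean_a - r$mean_b) > spec$delta_threshold
  sum(sig, na.rm = TRUE)
}

#' Simulation-based FDR of a screen at fixed thresholds
#'
#' Runs the screen's significance criterion on `n_sims` binomial null
#' resamplings of the observed counts; the FDR is x/y with x the mean
#' significant count under the null and y the observed significant count.
#' With `n_sims = 1` this reproduces a single-draw estimate.
#'
#' @param comparison A `pairwise_comparison` or `group_comparison`.
#' @param n_sims Number of null resamplings (1000 for the study's t-test
#'   screens).
#' @param seed Integer seed.
#' @return Object of class `fdr_estimate` with fields `x`, `y`, `fdr`,
#'   `n_sims`, `seed` and the per-simulation counts.
#' @export
estimate_fdr <- function(comparison, n_sims = 1000, seed = 1) {
  y <- count_significant(comparison)
  if (y == 0) stopf("FDR undefined: no significant sites in observed data")
  xs <- vapply(seq_len(n_sims), function(i) {
    as.numeric(count_significant(simulate_null(comparison,
                                               derive_seed(seed, i))))
  }, numeric(1))
  structure(list(x = mean(xs), y = y, fdr = mean(xs) / y, n_sims = n_sims,
                 seed = seed, per_sim = xs),
            class = "fdr_estimate")
}

#' @export
print.fdr_estimate <- function(x, ...) {
  cat(sprintf("Simulation-based FDR: x = %.3f null-significant (mean of %d sims), y = %d observed, x/y = %.4g (%.3g%%)\n",
              x$x, x$n_sims, x$y, x$fdr, 100 * x$fdr))
  invisible(x)
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 = min(1, mean(p > lambda) / (1 -
#' lambda)) and converts p-values to q-values, q(i) = pi0 * min over p(j) >=
#' p(i) of m * p(j) / rank(j). Q-values are monotone non-decreasing in p and
#' capped at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param lambda Tuning value for the pi0 estimate (default 0.5).
#' @return List of class `qvalue_result` with `p_values`, `pi0`, `lambda`,
#'   `q_values`.
#' @export
storey_qvalue <- function(p_values, lambda = 0.5) {
  p <- p_values
  if (!length(p)) stopf("storey_qvalue: empty p-value vector")
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  if (lambda <= 0 || lambda >= 1) stopf("lambda must lie in (0, 1)")
  m <- length(p)
  pi0 <- min(1, mean(p > lambda) / (1 - lambda))
  o <- order(p)
  q_ord <- pi0 * m * p[o] / seq_len(m)
  q_ord <- rev(cummin(rev(q_ord)))
  q <- numeric(m)
  q[o] <- pmin(q_ord, 1)
  structure(list(p_values = p, pi0 = pi0, lambda = lambda, q_values = q),
            class = "qvalue_result")
}

#' Hypergeometric enrichment test
#'
#' Upper-tail probability P(X >= hits) of drawing at least `hits` members of
#' a category of size `category_size` in a list of `list_size` draws without
#' replacement from a universe of `universe_size`.
#'
#' @param hits_in_list Category members observed in the list.
#' @param list_size Size of the test list.
#' @param category_size Category members in the universe.
#' @param universe_size Universe size.
#' @return Upper-tail p-value.
#' @export
hypergeom_enrichment <- function(hits_in_list, list_size, category_size,
                                 universe_size) {
  if (hits_in_list < 0 || hits_in_list > min(list_size, category_size) ||
      max(list_size, category_size) > universe_size) {
    stopf("inconsistent hypergeometric counts")
  }
  stats::phyper(hits_in_list - 1, category_size,
                universe_size - category_size, list_size,
                lower.tail = FALSE)
}
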