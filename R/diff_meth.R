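# Site-level differential methylation statistics: the pairwise binomial
# CI-exclusion test, group t-tests with the strain/allele/sex/imprinting
# presets, epimutation detection between parental and F1 chromosomes,
# variance comparison, 100-kb binning, and gene-proximity annotation.

#' Specification of a two-group site comparison
#'
#' Presets encode the study's four screens:
#' \describe{
#'   \item{strain}{pairwise binomial: coverage >= 10 in both samples, mutual
#'     95% CI exclusion, delta > 0.5.}
#'   \item{allele}{group t-test: p < 0.05 and delta > 0.5 between B6 and DBA
#'     chromosome groups.}
#'   \item{sex}{group t-test: p < 0.001 and delta > 0.2 between females and
#'     males.}
#'   \item{imprinting}{group t-test: p < 1e-6 between maternal and paternal
#'     chromosome groups (no delta filter).}
#'   \item{epimutation}{pairwise binomial with delta > 0.5, applied to
#'     parent versus genotype-matched F1 chromosome.}
#' }
#'
#' @param preset One of `"strain"`, `"allele"`, `"sex"`, `"imprinting"`,
#'   `"epimutation"`, or `NULL` to set fields directly.
#' @param test `"pairwise_binomial"` or `"group_ttest"`.
#' @param grouping Label for what the two groups are (informational).
#' @param p_threshold Two-sided p-value cutoff for t-test screens.
#' @param delta_threshold Minimum absolute difference in methylation.
#' @param min_coverage Minimum reads for a sample's site to enter a test.
#' @param min_group_size Minimum per-group values for a t-test.
#' @param ci_alpha Confidence level complement for the binomial intervals.
#' @return List of class `comparison_spec`.
#' @export
comparison_spec <- function(preset = NULL, test = "group_ttest",
                            grouping = "custom", p_threshold = 0.05,
                            delta_threshold = 0.5, min_coverage = 10,
                            min_group_size = 3, ci_alpha = 0.05) {
  if (!is.null(preset)) {
    presets <- list(
      strain = list(test = "pairwise_binomial", grouping = "strain",
                    p_threshold = NA_real_, delta_threshold = 0.5),
      allele = list(test = "group_ttest", grouping = "allele",
                    p_threshold = 0.05, delta_threshold = 0.5),
      sex = list(test = "group_ttest", grouping = "sex",
                 p_threshold = 0.001, delta_threshold = 0.2),
      imprinting = list(test = "group_ttest", grouping = "parent_of_origin",
                        p_threshold = 1e-6, delta_threshold = 0),
      epimutation = list(test = "pairwise_binomial",
                         grouping = "parent_vs_F1",
                         p_threshold = NA_real_, delta_threshold = 0.5)
    )
    if (!preset %in% names(presets)) stopf("unknown preset '%s'", preset)
    p <- presets[[preset]]
    test <- p$test; grouping <- p$grouping
    p_threshold <- p$p_threshold; delta_threshold <- p$delta_threshold
  }
  if (!test %in% c("pairwise_binomial", "group_ttest")) {
    stopf("unknown test '%s'", test)
  }
  structure(list(test = test, grouping = grouping, p_threshold = p_threshold,
                 delta_threshold = delta_threshold,
                 min_coverage = min_coverage,
                 min_group_size = min_group_size, ci_alpha = ci_alpha,
                 preset = preset %||% "custom"),
            class = "comparison_spec")
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Equal-tailed exact interval for a binomial proportion, obtained from the
#' beta inversion of the binomial tails. Vectorised over `k`, `n`.
#'
#' @param k Successes (0 <= k <= n).
#' @param n Trials (n >= 1).
#' @param alpha 1 - confidence level (default 0.05 for 95% intervals).
#' @return Two-column matrix with columns `lower`, `upper`.
#' @export
#' @examples
#' binomial_ci(5, 10)
binomial_ci <- function(k, n, alpha = 0.05) {
  m <- max(length(k), length(n))
  k <- rep_len(k, m); n <- rep_len(n, m)
  if (any(n < 1)) stopf("binomial_ci requires n >= 1")
  if (any(k < 0 | k > n)) stopf("binomial_ci requires 0 <= k <= n")
  lower <- ifelse(k == 0, 0, stats::qbeta(alpha / 2, k, n - k + 1))
  upper <- ifelse(k == n, 1, stats::qbeta(1 - alpha / 2, k + 1, n - k))
  cbind(lower = lower, upper = upper)
}

#' Pairwise binomial CI-exclusion test between two samples
#'
#' A site is differentially methylated between two samples when both are
#' covered by at least `min_coverage` reads, each sample's methylation level
#' lies outside the other's exact 95% confidence interval, and the absolute
#' difference in levels exceeds `delta_threshold`. The test is symmetric in
#' its two arguments.
#'
#' @param sites_a,sites_b Site tables of the two samples; only sites shared
#'   on (chrom, pos, strand) are compared.
#' @param spec A [comparison_spec()] with `test = "pairwise_binomial"`.
#' @return `data.frame` with the site key, per-sample levels, counts,
#'   confidence bounds, `delta`, `tested` and `significant` flags.
#' @export
pairwise_site_test <- function(sites_a, sites_b,
                               spec = comparison_spec("strain")) {
  if (spec$test != "pairwise_binomial") {
    stopf("pairwise_site_test requires a pairwise_binomial spec")
  }
  m <- merge(
    sites_a[, c("chrom", "pos", "strand", "context", "meth_count",
                "total_count")],
    sites_b[, c("chrom", "pos", "strand", "meth_count", "total_count")],
    by = c("chrom", "pos", "strand"), suffixes = c("_a", "_b")
  )
  if (!nrow(m)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), context = character(0),
                      level_a = numeric(0), level_b = numeric(0),
                      n_a = integer(0), n_b = integer(0), delta = numeric(0),
                      ci_a_lower = numeric(0), ci_a_upper = numeric(0),
                      ci_b_lower = numeric(0), ci_b_upper = numeric(0),
                      tested = logical(0), significant = logical(0)))
  }
  level_a <- m$meth_count_a / m$total_count_a
  level_b <- m$meth_count_b / m$total_count_b
  ci_a <- binomial_ci(m$meth_count_a, m$total_count_a, spec$ci_alpha)
  ci_b <- binomial_ci(m$meth_count_b, m$total_count_b, spec$ci_alpha)
  tested <- m$total_count_a >= spec$min_coverage &
    m$total_count_b >= spec$min_coverage
  delta <- abs(level_a - level_b)
  excl <- (level_a < ci_b[, 1] | level_a > ci_b[, 2]) &
    (level_b < ci_a[, 1] | level_b > ci_a[, 2])
  out <- data.frame(
    chrom = m$chrom, pos = m$pos, strand = m$strand, context = m$context,
    level_a = level_a, level_b = level_b,
    n_a = m$total_count_a, n_b = m$total_count_b, delta = delta,
    ci_a_lower = ci_a[, 1], ci_a_upper = ci_a[, 2],
    ci_b_lower = ci_b[, 1], ci_b_upper = ci_b[, 2],
    tested = tested,
    significant = tested & excl & delta > spec$delta_threshold,
    stringsAsFactors = FALSE
  )
  out[order(out$chrom, out$pos, out$strand), ]
}

# Row-wise pooled-variance two-sample t-test on a matrix with NAs.
# Returns means, group sizes, t, p and a degenerate flag (zero pooled
# variance with unequal means -> p at the machine floor).
row_ttest <- function(x, cols_a, cols_b) {
  xa <- x[, cols_a, drop = FALSE]
  xb <- x[, cols_b, drop = FALSE]
  na <- rowSums(!is.na(xa))
  nb <- rowSums(!is.na(xb))
  ma <- rowMeans(xa, na.rm = TRUE)
  mb <- rowMeans(xb, na.rm = TRUE)
  ssa <- rowSums(xa * xa, na.rm = TRUE) - na * ma^2
  ssb <- rowSums(xb * xb, na.rm = TRUE) - nb * mb^2
  df <- na + nb - 2
  sp2 <- ifelse(df > 0, (pmax(ssa, 0) + pmax(ssb, 0)) / df, NA_real_)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- (ma - mb) / se
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- !is.na(sp2) & sp2 <= 0
  eq <- degenerate & abs(ma - mb) < .Machine$double.eps^0.5
  t[eq] <- 0; p[eq] <- 1
  ne <- degenerate & !eq
  t[ne] <- sign(ma - mb)[ne] * Inf
  p[ne] <- .Machine$double.xmin
  list(mean_a = ma, mean_b = mb, n_a = na, n_b = nb, t = t, p = p,
       degenerate = degenerate)
}

#' Two-sample pooled-variance t-test
#'
#' Classical equal-variance two-sample t statistic with a two-sided p-value
#' from the t distribution on `n_a + n_b - 2` degrees of freedom. With zero
#' pooled variance the test returns p = 1 for equal means and a
#' machine-floor p with `degenerate = TRUE` otherwise.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return List with `statistic`, `p_value`, `df`, `mean_a`, `mean_b`,
#'   `degenerate`.
#' @export
group_ttest <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stopf("group_ttest requires at least 2 values per group")
  }
  r <- row_ttest(matrix(c(a, b), nrow = 1),
                 seq_along(a), length(a) + seq_along(b))
  list(statistic = r$t, p_value = r$p, df = length(a) + length(b) - 2,
       mean_a = r$mean_a, mean_b = r$mean_b, degenerate = r$degenerate)
}

#' Per-site methylation level and count matrices over samples
#'
#' Builds sites x samples matrices of methylated counts, total counts and
#' levels over the union of sites; entries with coverage below
#' `min_coverage` are `NA` in the level matrix (absent sites are `NA`
#' throughout).
#'
#' @param tables Named list of site tables.
#' @param min_coverage Coverage filter applied to the level matrix.
#' @return List with `sites` (key `data.frame`), `meth`, `total`, `level`.
#' @export
site_matrix <- function(tables, min_coverage = 1) {
  if (!length(tables)) stopf("site_matrix: no samples")
  if (is.null(names(tables))) names(tables) <- paste0("s", seq_along(tables))
  keys <- lapply(tables, site_key)
  all_keys <- unique(unlist(keys, use.names = FALSE))
  first <- do.call(rbind, tables)[match(all_keys,
                                        unlist(keys, use.names = FALSE)), ]
  ord <- order(first$chrom, first$pos, first$strand)
  sites <- data.frame(chrom = first$chrom, pos = first$pos,
                      strand = first$strand, context = first$context,
                      stringsAsFactors = FALSE)[ord, ]
  rownames(sites) <- NULL
  all_keys <- all_keys[ord]
  meth <- total <- matrix(NA_integer_, nrow = length(all_keys),
                          ncol = length(tables),
                          dimnames = list(NULL, names(tables)))
  for (j in seq_along(tables)) {
    i <- match(keys[[j]], all_keys)
    meth[i, j] <- tables[[j]]$meth_count
    total[i, j] <- tables[[j]]$total_count
  }
  level <- meth / total
  level[is.na(total) | total < min_coverage] <- NA_real_
  list(sites = sites, meth = meth, total = total, level = level)
}

#' Screen sites for differential methylation between two groups of samples
#'
#' For a `group_ttest` spec, each site's per-sample methylation fractions
#' (coverage-filtered) are compared between the two groups with a
#' pooled-variance t-test; a site is significant when it was tested in at
#' least `min_group_size` samples per group, p is below `p_threshold` and
#' the absolute difference of group means exceeds `delta_threshold`. For a
#' `pairwise_binomial` spec with one sample per group this dispatches to
#' [pairwise_site_test()].
#'
#' @param group_a,group_b Named lists of site tables (one per sample or
#'   per-sample allele).
#' @param spec A [comparison_spec()].
#' @return `data.frame` of all tested sites with group means, `delta`, `t`,
#'   `p`, `tested`, `significant`.
#' @export
screen_sites <- function(group_a, group_b, spec = comparison_spec("allele")) {
  if (spec$test == "pairwise_binomial") {
    if (length(group_a) != 1 || length(group_b) != 1) {
      stopf("pairwise_binomial screens compare exactly one sample per group")
    }
    return(pairwise_site_test(group_a[[1]], group_b[[1]], spec))
  }
  if (is.null(names(group_a))) names(group_a) <- paste0("a", seq_along(group_a))
  if (is.null(names(group_b))) names(group_b) <- paste0("b", seq_along(group_b))
  names(group_b) <- make.unique(c(names(group_a), names(group_b)),
                                sep = "_")[length(group_a) +
                                             seq_along(group_b)]
  sm <- site_matrix(c(group_a, group_b), spec$min_coverage)
  ia <- seq_along(group_a)
  ib <- length(group_a) + seq_along(group_b)
  r <- row_ttest(sm$level, ia, ib)
  tested <- r$n_a >= spec$min_group_size & r$n_b >= spec$min_group_size
  delta <- abs(r$mean_a - r$mean_b)
  out <- cbind(sm$sites, data.frame(
    mean_a = r$mean_a, mean_b = r$mean_b, n_a = r$n_a, n_b = r$n_b,
    delta = delta, t = r$t, p = r$p, tested = tested,
    significant = tested & !is.na(r$p) & r$p < spec$p_threshold &
      delta > spec$delta_threshold
  ))
  out$significant[is.na(out$significant)] <- FALSE
  out
}

# transmitting-parent pairing: the F1's chromosome of strain s is compared
# with the parent mouse that contributed it (mother when s is the maternal
# strain of the cross, father otherwise)
epimutation_pairs <- function(samples) {
  f1 <- samples[samples$generation == "F1", , drop = FALSE]
  parents <- samples[samples$generation == "parent", , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(f1)), function(i) {
    do.call(rbind, lapply(c("B6", "DBA"), function(s) {
      sex <- if (s == f1$maternal_strain[i]) "F" else "M"
      pid <- parents$sample_id[parents$group == s & parents$sex == sex]
      if (!length(pid)) return(NULL)
      data.frame(parent_sample = pid[1], f1_sample = f1$sample_id[i],
                 allele = s, stringsAsFactors = FALSE)
    }))
  }))
  out
}

#' Detect intergenerational epimutations
#'
#' Compares methylation in each parent with the genotype-identical
#' chromosome in its own F1 offspring (B6 parents against the B6-allele
#' reads of the F1s they mothered/fathered, and likewise for DBA) using the
#' pairwise binomial CI-exclusion criterion with delta > 0.5. Sites inside
#' known imprinted regions are excluded. Each significant site is annotated
#' with its reproducibility class: the number of parent-F1 pairs in which
#' the same site and allele changed in a consistent direction.
#'
#' @param parent_tables Named list of parental site tables (names are the
#'   four parent sample ids).
#' @param f1_allele_tables Nested named list: F1 sample id -> allele
#'   (`"B6"`, `"DBA"`) -> site table, e.g. built with
#'   [allele_site_tables()].
#' @param samples Sample metadata ([sample_table()]).
#' @param known_imprinted Optional intervals (`chrom`, `start`, `end`) of
#'   known imprinted genes to exclude.
#' @param spec A [comparison_spec()], default the epimutation preset.
#' @return List with `calls` (one row per significant site x pair, with
#'   `reproducibility_class` joined) and `sites` (one row per site x allele
#'   with its class).
#' @export
detect_epimutations <- function(parent_tables, f1_allele_tables, samples,
                                known_imprinted = NULL,
                                spec = comparison_spec("epimutation")) {
  pairs <- epimutation_pairs(samples)
  if (is.null(pairs) || !nrow(pairs)) stopf("no parent-F1 pairs in metadata")
  calls <- list()
  for (i in seq_len(nrow(pairs))) {
    pt <- parent_tables[[pairs$parent_sample[i]]]
    ft <- f1_allele_tables[[pairs$f1_sample[i]]][[pairs$allele[i]]]
    if (is.null(pt) || is.null(ft) || !nrow(pt) || !nrow(ft)) next
    res <- pairwise_site_test(pt, ft, spec)
    sig <- res[res$significant, , drop = FALSE]
    if (!nrow(sig)) next
    calls[[i]] <- data.frame(
      chrom = sig$chrom, pos = sig$pos, strand = sig$strand,
      context = sig$context, parent_sample = pairs$parent_sample[i],
      f1_sample = pairs$f1_sample[i], allele = pairs$allele[i],
      level_parent = sig$level_a, level_f1 = sig$level_b, delta = sig$delta,
      direction = sign(sig$level_b - sig$level_a), stringsAsFactors = FALSE
    )
  }
  empty_calls <- data.frame(
    chrom = character(0), pos = integer(0), strand = character(0),
    context = character(0), parent_sample = character(0),
    f1_sample = character(0), allele = character(0),
    level_parent = numeric(0), level_f1 = numeric(0), delta = numeric(0),
    direction = numeric(0), reproducibility_class = integer(0),
    stringsAsFactors = FALSE
  )
  calls <- if (length(calls)) do.call(rbind, calls) else empty_calls
  if (nrow(calls) && !is.null(known_imprinted) && nrow(known_imprinted)) {
    gr <- GenomicRanges::GRanges(
      known_imprinted$chrom,
      IRanges::IRanges(known_imprinted$start, known_imprinted$end))
    sr <- GenomicRanges::GRanges(calls$chrom,
                                 IRanges::IRanges(calls$pos, calls$pos))
    drop <- suppressWarnings(IRanges::overlapsAny(sr, gr))
    calls <- calls[!drop, , drop = FALSE]
  }
  if (!nrow(calls)) {
    return(list(calls = empty_calls,
                sites = data.frame(chrom = character(0), pos = integer(0),
                                   strand = character(0), allele = character(0),
                                   reproducibility_class = integer(0),
                                   stringsAsFactors = FALSE)))
  }
  skey <- paste(calls$chrom, calls$pos, calls$strand, calls$allele,
                calls$direction)
  n_pairs <- stats::ave(seq_along(skey), skey, FUN = length)
  site_dir_key <- paste(calls$chrom, calls$pos, calls$strand, calls$allele)
  cls <- tapply(n_pairs, site_dir_key, max)
  calls$reproducibility_class <- as.integer(cls[site_dir_key])
  first <- !duplicated(site_dir_key)
  sites <- data.frame(chrom = calls$chrom[first], pos = calls$pos[first],
                      strand = calls$strand[first],
                      allele = calls$allele[first],
                      reproducibility_class = calls$reproducibility_class[first],
                      stringsAsFactors = FALSE)
  sites <- sites[order(sites$chrom, sites$pos, sites$allele), ]
  rownames(sites) <- NULL
  rownames(calls) <- NULL
  list(calls = calls, sites = sites)
}

#' Per-site variances for a set of samples
#'
#' @param level Sites x samples level matrix (e.g. from [site_matrix()]).
#' @param cols Columns (names or indices) defining the sample set.
#' @return Numeric vector of per-site variances; sites with fewer than two
#'   observed samples are dropped.
#' @export
site_variances <- function(level, cols) {
  x <- level[, cols, drop = FALSE]
  n <- rowSums(!is.na(x))
  m <- rowMeans(x, na.rm = TRUE)
  v <- (rowSums(x * x, na.rm = TRUE) - n * m^2) / (n - 1)
  pmax(v[n >= 2], 0)
}

#' Compare two distributions of per-site methylation variances
#'
#' Kolmogorov-Smirnov two-sample test between (for example) inter-strain and
#' intra-strain per-site variances, plus the fold difference of their means.
#'
#' @param v_a,v_b Numeric vectors of per-site variances (e.g. from
#'   [site_variances()]); conventionally inter-group first.
#' @return List with `D`, `p_value`, `fold` (= mean(v_a)/mean(v_b)).
#' @export
variance_ks <- function(v_a, v_b) {
  v_a <- v_a[!is.na(v_a)]; v_b <- v_b[!is.na(v_b)]
  if (length(v_a) < 2 || length(v_b) < 2) {
    stopf("variance_ks requires at least 2 variances per regime")
  }
  ks <- suppressWarnings(stats::ks.test(v_a, v_b))
  list(D = unname(ks$statistic), p_value = ks$p.value,
       fold = mean(v_a) / mean(v_b))
}

#' Count significant sites in fixed-width genomic bins
#'
#' Bin b (0-based) covers positions `[b*bin_size + 1, (b+1)*bin_size]`. The
#' per-bin significance threshold is the smallest count whose Poisson upper
#' tail, at the genome-wide mean count per bin, falls below a
#' Bonferroni-corrected level.
#'
#' @param sites Site table (typically the significant sites of a screen).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param bin_size Bin width in bp (default 100 kb).
#' @param alpha Family-wise level for the threshold (default 0.05).
#' @return List with `bins` (`chrom`, `start`, `end`, `count`), `threshold`,
#'   `lambda`.
#' @export
bin_counts <- function(sites, chrom_lengths, bin_size = 100000,
                       alpha = 0.05) {
  if (nrow(sites)) {
    bad <- setdiff(unique(sites$chrom), names(chrom_lengths))
    if (length(bad)) stopf("site on chromosome '%s' without a length", bad[1])
    over <- sites$pos > chrom_lengths[sites$chrom]
    if (any(over)) {
      stopf("site at %s:%d beyond chromosome length",
            sites$chrom[which(over)[1]], sites$pos[which(over)[1]])
    }
  }
  nb <- pmax(1L, as.integer(ceiling(chrom_lengths / bin_size)))
  bins <- data.frame(
    chrom = rep(names(chrom_lengths), nb),
    start = unlist(lapply(nb, function(k) {
      (seq_len(k) - 1L) * as.integer(bin_size) + 1L
    })),
    stringsAsFactors = FALSE
  )
  bins$end <- bins$start + as.integer(bin_size) - 1L
  bins$count <- 0L
  if (nrow(sites)) {
    key <- paste(sites$chrom, (sites$pos - 1) %/% bin_size)
    bkey <- paste(bins$chrom, (bins$start - 1) %/% bin_size)
    tab <- table(key)
    i <- match(names(tab), bkey)
    bins$count[i] <- as.integer(tab)
  }
  n_bins <- nrow(bins)
  lambda <- nrow(sites) / n_bins
  athr <- alpha / n_bins
  cthr <- max(1L, stats::qpois(1 - athr, lambda))
  while (stats::ppois(cthr - 1, lambda, lower.tail = FALSE) >= athr) {
    cthr <- cthr + 1L
  }
  list(bins = bins, threshold = cthr, lambda = lambda)
}

#' Genes within a window of differentially methylated sites
#'
#' A gene is reported when the minimum distance from any site to the gene
#' span is at most `window` (0 for sites inside the span).
#'
#' @param sites Site table.
#' @param annotation Gene intervals: `data.frame` with `chrom`, `start`,
#'   `end` (1-based inclusive) and `name`, or a `GRanges`.
#' @param window Maximum distance in bp (default 10 kb).
#' @return `data.frame` of associated genes with `n_sites` and
#'   `min_distance`.
#' @export
genes_near_sites <- function(sites, annotation, window = 10000) {
  if (methods::is(annotation, "GRanges")) {
    annotation <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(annotation)),
      start = GenomicRanges::start(annotation),
      end = GenomicRanges::end(annotation),
      name = annotation$name %||%
        as.character(seq_along(annotation)),
      stringsAsFactors = FALSE
    )
  }
  empty <- data.frame(name = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_sites = integer(0), min_distance = numeric(0),
                      stringsAsFactors = FALSE)
  if (!nrow(sites) || !nrow(annotation)) return(empty)
  unknown <- setdiff(unique(sites$chrom), unique(annotation$chrom))
  if (length(unknown)) {
    warning(sprintf("sites on chromosomes absent from annotation skipped: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(annotation)), function(i) {
    on_chrom <- sites$pos[sites$chrom == annotation$chrom[i]]
    if (!length(on_chrom)) return(NULL)
    d <- pmax(0, annotation$start[i] - on_chrom,
              on_chrom - annotation$end[i])
    hit <- d <= window
    if (!any(hit)) return(NULL)
    data.frame(name = annotation$name[i], chrom = annotation$chrom[i],
               start = annotation$start[i], end = annotation$end[i],
               n_sites = sum(hit), min_distance = min(d),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
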