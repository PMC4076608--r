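sites1 <- function(k, n, pos = 100L, chrom = "chr1") {
  cytosine_sites(chrom, pos, "+", "CG", k, n)
}

test_that("binomial CI hits the exact boundaries", {
  ci <- binomial_ci(0, 10)
  expect_equal(unname(ci[1, "lower"]), 0)
  ci <- binomial_ci(10, 10)
  expect_equal(unname(ci[1, "upper"]), 1)
  expect_error(binomial_ci(2, 0), "n >= 1")
  expect_error(binomial_ci(5, 4), "k <= n")
  # agrees with the exact interval of the standard binomial test
  for (kk in c(1, 5, 9)) {
    ref <- stats::binom.test(kk, 10)$conf.int
    expect_equal(as.numeric(binomial_ci(kk, 10)), as.numeric(ref),
                 tolerance = 1e-12)
  }
})

test_that("pairwise CI-exclusion test matches the screen definition", {
  # identical sites are never significant
  r <- pairwise_site_test(sites1(12, 20), sites1(12, 20))
  expect_false(r$significant)
  # 18/20 vs 2/20: delta 0.8 with mutual CI exclusion
  r <- pairwise_site_test(sites1(18, 20), sites1(2, 20))
  expect_true(r$significant)
  expect_equal(r$delta, 0.8)
  expect_gt(r$level_a, r$ci_b_upper)
  expect_lt(r$level_b, r$ci_a_lower)
  # below 10 reads the site is excluded, whatever the counts
  r <- pairwise_site_test(sites1(9, 9), sites1(0, 20))
  expect_false(r$tested)
  expect_false(r$significant)
  # delta must exceed 50% even with CI exclusion
  r <- pairwise_site_test(sites1(50, 100), sites1(90, 100))
  expect_true(r$level_a < r$ci_b_lower && r$level_b > r$ci_a_upper)
  expect_false(r$significant)
})

test_that("pairwise test is symmetric in its arguments", {
  withr::with_seed(3, {
    n <- 200
    a <- cytosine_sites("chr1", seq_len(n), "+", "CG",
                        rbinom(n, 30, runif(n)), rep(30L, n))
    b <- cytosine_sites("chr1", seq_len(n), "+", "CG",
                        rbinom(n, 25, runif(n)), rep(25L, n))
  })
  r_ab <- pairwise_site_test(a, b)
  r_ba <- pairwise_site_test(b, a)
  expect_equal(r_ab$significant, r_ba$significant)
  expect_equal(r_ab$delta, r_ba$delta)
  expect_equal(r_ab$level_a, r_ba$level_b)
})

test_that("pooled t-test matches the closed form and handles degeneracy", {
  expect_equal(group_ttest(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(group_ttest(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  deg <- group_ttest(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, .Machine$double.xmin)
  withr::with_seed(5, {
    for (i in 1:10) {
      a <- rnorm(sample(3:8, 1))
      b <- rnorm(sample(3:8, 1), mean = runif(1, -1, 1))
      ours <- group_ttest(a, b)
      ref <- stats::t.test(a, b, var.equal = TRUE)
      expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
    }
  })
  expect_error(group_ttest(1, c(1, 2)), "at least 2")
})

test_that("screen presets apply their p and delta thresholds jointly", {
  make_group <- function(levels, pos = c(100L, 200L), n = 40L) {
    lapply(seq_len(nrow(levels)), function(j) {
      cytosine_sites("chr1", pos, "+", "CG",
                     round(levels[j, ] * n), rep(n, length(pos)))
    })
  }
  # site 1: large separation; site 2: clear p but delta only ~0.15
  ga <- make_group(rbind(c(0.900, 0.650), c(0.925, 0.675),
                         c(0.875, 0.625), c(0.900, 0.650)))
  gb <- make_group(rbind(c(0.100, 0.500), c(0.125, 0.525),
                         c(0.075, 0.475), c(0.100, 0.500)))
  res <- screen_sites(ga, gb, comparison_spec("sex"))
  expect_equal(res$significant[res$pos == 100], TRUE)
  expect_lt(res$p[res$pos == 200], 0.001)   # p passes ...
  expect_false(res$significant[res$pos == 200])  # ... but delta <= 20%
  # significance always equals the joint rule
  for (preset in c("allele", "sex", "imprinting")) {
    spec <- comparison_spec(preset)
    res <- screen_sites(ga, gb, spec)
    manual <- res$tested & res$p < spec$p_threshold &
      res$delta > spec$delta_threshold
    expect_equal(res$significant, manual)
  }
  # imprinting preset requires p < 1e-6: moderate evidence is rejected
  ga2 <- make_group(rbind(c(0.80, 0.5), c(0.70, 0.5), c(0.76, 0.5),
                          c(0.72, 0.5)))
  gb2 <- make_group(rbind(c(0.45, 0.5), c(0.39, 0.5), c(0.48, 0.5),
                          c(0.42, 0.5)))
  res <- screen_sites(ga2, gb2, comparison_spec("imprinting"))
  p1 <- res$p[res$pos == 100]
  expect_true(p1 < 0.05 && p1 > 1e-6)  # real signal, below the bar
  expect_false(res$significant[res$pos == 100])
})

test_that("a group emptied by the coverage filter is skipped, not significant", {
  ga <- list(sites1(30, 40), sites1(28, 40), sites1(32, 40))
  gb <- list(sites1(2, 5), sites1(1, 5), sites1(3, 5))  # all below cov 10
  res <- screen_sites(ga, gb, comparison_spec("allele"))
  expect_false(res$tested)
  expect_false(res$significant)
})

test_that("epimutation detection pairs each F1 chromosome with its transmitting parent", {
  samples <- sample_table()
  pairs <- crossmeth:::epimutation_pairs(samples)
  expect_equal(nrow(pairs), 8)
  # BXD F1s received their B6 chromosome from the B6 mother
  expect_equal(pairs$parent_sample[pairs$f1_sample == "BXD_F" &
                                     pairs$allele == "B6"], "B6_F")
  expect_equal(pairs$parent_sample[pairs$f1_sample == "BXD_F" &
                                     pairs$allele == "DBA"], "DBA_M")
  expect_equal(pairs$parent_sample[pairs$f1_sample == "DXB_M" &
                                     pairs$allele == "B6"], "B6_M")
  expect_equal(pairs$parent_sample[pairs$f1_sample == "DXB_M" &
                                     pairs$allele == "DBA"], "DBA_F")
})

test_that("epimutations require CI exclusion, big delta, and respect exclusions", {
  samples <- sample_table()
  base <- sites1(0, 30)
  shifted <- sites1(25, 30)
  parent_tables <- list(B6_F = base, B6_M = base, DBA_F = base,
                        DBA_M = base)
  f1_tabs <- function(b6, dba) list(B6 = b6, DBA = dba)
  f1 <- list(BXD_F = f1_tabs(shifted, base), BXD_M = f1_tabs(shifted, base),
             DXB_F = f1_tabs(base, base), DXB_M = f1_tabs(base, base))
  out <- detect_epimutations(parent_tables, f1, samples)
  # shifted B6 chromosome in both BXD F1s, same transmitting mother:
  # two consistent pairs -> class 2
  expect_equal(nrow(out$calls), 2)
  expect_equal(unique(out$calls$parent_sample), "B6_F")
  expect_equal(out$sites$reproducibility_class, 2L)
  expect_equal(out$calls$delta, rep(25 / 30, 2), tolerance = 1e-12)
  # inside a known imprinted interval the site is excluded
  known <- data.frame(chrom = "chr1", start = 50L, end = 150L)
  out2 <- detect_epimutations(parent_tables, f1, samples,
                              known_imprinted = known)
  expect_equal(nrow(out2$calls), 0)
  # a single affected F1 chromosome gives class 1
  f1_one <- list(BXD_F = f1_tabs(shifted, base), BXD_M = f1_tabs(base, base),
                 DXB_F = f1_tabs(base, base), DXB_M = f1_tabs(base, base))
  out3 <- detect_epimutations(parent_tables, f1_one, samples)
  expect_equal(out3$sites$reproducibility_class, 1L)
  # small delta never calls
  f1_small <- list(BXD_F = f1_tabs(sites1(10, 30), base),
                   BXD_M = f1_tabs(base, base),
                   DXB_F = f1_tabs(base, base), DXB_M = f1_tabs(base, base))
  out4 <- detect_epimutations(parent_tables, f1_small, samples)
  expect_equal(nrow(out4$calls), 0)
})

test_that("variance comparison returns KS statistic, p and fold of means", {
  same <- variance_ks(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$D, 0)
  expect_equal(same$fold, 1)
  sep <- variance_ks(c(4, 5, 6), c(1, 2, 3))
  expect_equal(sep$D, 1)
  # exact enumeration oracle: P(D = 1) for 3 vs 3 distinct values is
  # 2 / choose(6, 3)
  combos <- utils::combn(6, 3)
  d_of <- function(ix) {
    x <- (1:6)[ix]; y <- (1:6)[-ix]
    max(abs(vapply(1:6, function(t) mean(x <= t) - mean(y <= t),
                   numeric(1))))
  }
  ds <- apply(combos, 2, d_of)
  expect_equal(sep$p_value, mean(ds >= 1 - 1e-9), tolerance = 1e-12)
  expect_equal(sep$fold, 5 / 2)
  expect_error(variance_ks(1, c(1, 2)), "at least 2")
})

test_that("per-site variances separate inter- from intra-strain regimes", {
  cross <- default_cross()
  sm <- site_matrix(cross$sim$sites[c("B6_F", "DBA_F", "B6_M", "DBA_M")],
                    min_coverage = 10)
  v_inter <- site_variances(sm$level, c("B6_F", "DBA_F"))
  # parents of the same strain stand in for biological replicates
  v_intra <- site_variances(sm$level, c("B6_F", "B6_M"))
  # planted strain effects inflate the inter-strain variance
  res <- variance_ks(v_inter, v_intra)
  expect_gt(res$fold, 1)
})

test_that("100-kb binning uses the documented boundary and threshold rules", {
  lens <- c(chr1 = 250000)
  s <- cytosine_sites("chr1", c(100000L, 100001L), "+", "CG", c(1, 1),
                      c(2, 2))
  bc <- bin_counts(s, lens)
  expect_equal(bc$bins$count, c(1L, 1L, 0L))
  expect_equal(sum(bc$bins$count), nrow(s))
  empty <- bin_counts(s[0, ], lens)
  expect_true(all(empty$bins$count == 0))
  expect_gte(empty$threshold, 1)
  # threshold is the smallest count with Bonferroni-Poisson tail below 0.05
  athr <- 0.05 / 3
  expect_lt(stats::ppois(bc$threshold - 1, bc$lambda, lower.tail = FALSE),
            athr)
  expect_gte(stats::ppois(bc$threshold - 2, bc$lambda, lower.tail = FALSE),
             athr)
  expect_error(bin_counts(cytosine_sites("chr1", 300001L, "+", "CG", 1, 2),
                          lens), "beyond chromosome length")
})

test_that("gene association uses a 10-kb window with an exact boundary", {
  genes <- data.frame(chrom = "chr1", start = 5000L, end = 6000L,
                      name = "g1", stringsAsFactors = FALSE)
  inside <- sites1(1, 20, pos = 5500L)
  expect_equal(genes_near_sites(inside, genes)$n_sites, 1)
  expect_equal(genes_near_sites(inside, genes)$min_distance, 0)
  at_10k <- sites1(1, 20, pos = 16000L)   # 10,000 bp past the gene end
  expect_equal(nrow(genes_near_sites(at_10k, genes)), 1)
  past <- sites1(1, 20, pos = 16001L)
  expect_equal(nrow(genes_near_sites(past, genes)), 0)
  expect_equal(nrow(genes_near_sites(inside[0, ], genes)), 0)
  expect_warning(genes_near_sites(sites1(1, 20, chrom = "chrX"), genes),
                 "absent from annotation")
})
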