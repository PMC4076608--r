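test_that("single-profile log-likelihood matches closed forms and brute force", {
  eps <- 1e-3
  # all states methylated: fitted levels clamp at 1 - eps
  mat <- matrix(1, nrow = 5, ncol = 4)
  r <- single_allele_loglik(mat)
  expect_equal(r$profile, rep(1 - eps, 4))
  expect_equal(r$loglik, 20 * log(1 - eps))
  # half methylated everywhere: 200 observed states at p = 1/2
  mat <- rbind(matrix(1, 5, 20), matrix(0, 5, 20))
  expect_equal(single_allele_loglik(mat)$loglik, 200 * log(0.5))
  # brute-force summation oracle on a random small matrix
  withr::with_seed(4, mat <- random_window_matrix(8, 6))
  r <- single_allele_loglik(mat)
  brute <- 0
  for (i in seq_len(nrow(mat))) for (j in seq_len(ncol(mat))) {
    x <- mat[i, j]
    if (!is.na(x)) {
      brute <- brute + if (x == 1) log(r$profile[j]) else
        log(1 - r$profile[j])
    }
  }
  expect_equal(r$loglik, brute, tolerance = 1e-10)
  expect_error(single_allele_loglik(matrix(NA_real_, 3, 3)), "no observed")
})

test_that("EM separates a perfect two-allele window and matches the analytic optimum", {
  eps <- 1e-3
  mat <- rbind(matrix(1, 10, 10), matrix(0, 10, 10))
  em <- two_allele_em(mat, seed = 1)
  expect_equal(em$profile_1, rep(1 - eps, 10), tolerance = 1e-6)
  expect_equal(em$profile_2, rep(eps, 10), tolerance = 1e-6)
  # analytic optimum: each read sits in its own component
  analytic <- 20 * (log(0.5) + 10 * log(1 - eps))
  expect_equal(em$loglik, analytic, tolerance = 1e-6)
  expect_true(all(em$responsibilities[1:10] > 0.99))
  expect_true(all(em$responsibilities[11:20] < 0.01))
})

test_that("EM is degenerate on identical reads and symmetric under label swap", {
  mat <- matrix(rep(c(1, 0), each = 30), nrow = 6, ncol = 10)  # same pattern
  em <- two_allele_em(mat, seed = 2)
  s1 <- single_allele_loglik(mat)
  expect_lt(abs(2 * (em$loglik - s1$loglik)), 1e-6)
  # swapping profile labels leaves the mixture likelihood unchanged
  withr::with_seed(6, mat <- random_window_matrix(15, 10))
  em <- two_allele_em(mat, seed = 3)
  W <- !is.na(mat); X <- mat; X[!W] <- 0
  mixll <- function(p1, p2) {
    a <- (X * W) %*% log(p1) + ((1 - X) * W) %*% log1p(-p1)
    b <- (X * W) %*% log(p2) + ((1 - X) * W) %*% log1p(-p2)
    sum(log(0.5 * exp(a) + 0.5 * exp(b)))
  }
  expect_equal(mixll(em$profile_1, em$profile_2),
               mixll(em$profile_2, em$profile_1), tolerance = 1e-10)
  expect_error(two_allele_em(mat[1:3, , drop = FALSE]), "at least 4")
})

test_that("AMR scan stays silent on uniform reads and recovers a planted region", {
  withr::with_seed(12, {
    cpg <- cumsum(sample(15:30, 60, replace = TRUE)) + 1000L
    # null: every CpG at 50% on a single population
    states <- replicate(300, paste(sample(c("M", "U"), 10, replace = TRUE),
                                   collapse = ""))
    starts <- sample(1:51, 300, replace = TRUE)
  })
  null_reads <- make_epireads(as.list(states), cpg, start_idx = starts)
  expect_equal(nrow(amr_scan(null_reads, seed = 4)), 0)

  # planted bimodal 12-CpG stretch (CpG indices 20..31)
  withr::with_seed(13, {
    starts <- sample(1:51, 400, replace = TRUE)
    states <- vapply(starts, function(s) {
      idx <- s:(s + 9)
      hi_allele <- runif(1) < 0.5
      p <- ifelse(idx >= 20 & idx <= 31, ifelse(hi_allele, 0.97, 0.03), 0.5)
      paste(c("U", "M")[rbinom(10, 1, p) + 1], collapse = "")
    }, character(1))
  })
  reads <- make_epireads(as.list(states), cpg, start_idx = starts)
  regions <- amr_scan(reads, seed = 4)
  expect_equal(nrow(regions), 1)
  expect_gte(regions$n_cpgs, 10)
  # the detected region covers at least 10 of the 12 planted CpGs
  covered <- sum(cpg[20:31] >= regions$start & cpg[20:31] <= regions$end)
  expect_gte(covered, 10)
  expect_gt(regions$delta, 0.5)

  # a small allele difference is rejected by the delta filter even where
  # the likelihood ratio is strong (the fitted separation overshoots the
  # true one somewhat, so the filter is tested well below the cutoff)
  withr::with_seed(14, {
    states <- vapply(starts, function(s) {
      idx <- s:(s + 9)
      hi_allele <- runif(1) < 0.5
      p <- ifelse(idx >= 20 & idx <= 31, ifelse(hi_allele, 0.65, 0.35), 0.5)
      paste(c("U", "M")[rbinom(10, 1, p) + 1], collapse = "")
    }, character(1))
  })
  weak <- make_epireads(as.list(states), cpg, start_idx = starts)
  win <- amr_windows(weak, seed = 4)
  expect_gt(min(win$p_value), 0)  # two-allele structure is visible ...
  expect_equal(nrow(amr_scan(weak, seed = 4, windows = win)), 0)
})

test_that("permutation p-values are a usable calibration alternative", {
  withr::with_seed(15, {
    cpg <- cumsum(sample(15:30, 14, replace = TRUE)) + 100L
    states <- replicate(40, paste(sample(c("M", "U"), 10, replace = TRUE),
                                  collapse = ""))
    starts <- sample(1:5, 40, replace = TRUE)
  })
  reads <- make_epireads(as.list(states), cpg, start_idx = starts)
  win <- amr_windows(reads, p_method = "permutation", n_perm = 20, seed = 2)
  expect_true(all(win$p_value > 0 & win$p_value <= 1))
  # null windows should not look extreme
  expect_gt(min(win$p_value), 1 / 21 - 1e-12)
})

test_that("candidate imprinted regions need 6 of 8 samples incl. a parent and an F1", {
  samples <- sample_table()
  region <- function(chrom = "chr1", start = 100L, end = 400L) {
    data.frame(chrom = chrom, start = start, end = end, first_cpg = 1L,
               last_cpg = 10L, n_cpgs = 10L, p_value = 1e-5, delta = 0.9,
               n_windows = 1L, stringsAsFactors = FALSE)
  }
  none <- region()[0, ]
  # present in all 8 -> candidate
  sets <- stats::setNames(replicate(8, region(), simplify = FALSE),
                          samples$sample_id)
  out <- candidate_imprinted_regions(sets, samples)
  expect_true(out$candidate)
  expect_equal(out$n_samples, 8)
  # in only 5 samples -> rejected
  sets5 <- sets
  for (s in c("B6_F", "B6_M", "DBA_F")) sets5[[s]] <- none
  expect_false(candidate_imprinted_regions(sets5, samples)$candidate)
  # in 6 samples but F1-only windows (plus one parent elsewhere) -> rejected:
  # genotype-driven allele-specific methylation is compatible with this
  sets_f1 <- stats::setNames(replicate(8, none, simplify = FALSE),
                             samples$sample_id)
  for (s in samples$sample_id[samples$generation == "F1"]) {
    sets_f1[[s]] <- region()
  }
  sets_f1$BXD_F <- rbind(region(), region(start = 150L, end = 350L))
  sets_f1$BXD_M <- rbind(region(), region(start = 120L, end = 390L))
  out <- candidate_imprinted_regions(sets_f1, samples)
  expect_false(any(out$candidate))
  expect_error(candidate_imprinted_regions(sets[1:7], samples), "missing")
})
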