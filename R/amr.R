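# Genotype-independent detection of allelically methylated regions from
# epireads: a fixed-width window (10 consecutive CpGs) is scored by the
# likelihood ratio between a single-methylation-profile model and an
# equal-weight two-allele mixture fitted by EM over reads, and significant
# overlapping windows are merged into regions. Cross-sample intersection
# nominates putative imprinted regions.

# Encode a set of reads over a CpG window as a reads x CpGs matrix of
# 0 (U) / 1 (M) / NA (N or not covered).
reads_to_matrix <- function(states, offsets, w) {
  mat <- matrix(NA_real_, nrow = length(states), ncol = w)
  for (i in seq_along(states)) {
    s <- states[[i]]
    o <- offsets[[i]]
    keep <- o >= 1L & o <= w & !is.na(s)
    mat[i, o[keep]] <- s[keep]
  }
  mat
}

#' Log-likelihood of a single-profile (non-AMR) model over a window
#'
#' Per-CpG methylation levels are the maximum-likelihood frequencies of the
#' observed states, clamped to `[eps, 1-eps]`; the log-likelihood sums log
#' p or log(1-p) over every observed state. Missing states are ignored.
#'
#' @param mat Reads x CpGs matrix of 0/1/`NA` states.
#' @param eps Clamping bound for fitted levels (default 1e-3).
#' @return List with `loglik` and `profile` (fitted per-CpG levels).
#' @export
single_allele_loglik <- function(mat, eps = 1e-3) {
  W <- !is.na(mat)
  if (!any(W)) stopf("window has no observed states")
  X <- mat
  X[!W] <- 0
  n_obs <- colSums(W)
  k <- colSums(X)
  p <- ifelse(n_obs > 0, k / pmax(n_obs, 1), 0.5)
  p <- pmin(pmax(p, eps), 1 - eps)
  loglik <- sum(k * log(p) + (n_obs - k) * log1p(-p))
  list(loglik = loglik, profile = p)
}

# Per-read log-likelihood under a profile: XW %*% log p + UW %*% log(1-p)
read_logliks <- function(XW, UW, p) {
  as.vector(XW %*% log(p) + UW %*% log1p(-p))
}

#' Fit the equal-weight two-allele mixture over a window by EM
#'
#' Reads are modelled as draws from one of two methylation profiles with
#' equal mixing weights (two chromosomes per cell); per-CpG emissions are
#' independent Bernoulli. The E-step computes read responsibilities from
#' per-CpG Bernoulli products; the M-step sets each profile's levels to the
#' responsibility-weighted methylated fractions (clamped to `[eps, 1-eps]`).
#' The observed-data log-likelihood never decreases across iterations. The
#' best of a deterministic pooled start (which floors the fit at the
#' single-profile likelihood) and `n_starts` random starts is returned;
#' profiles are ordered so `profile_1` has the higher mean.
#'
#' @param mat Reads x CpGs matrix of 0/1/`NA` states (>= 4 reads).
#' @param max_iter Maximum EM iterations per start (default 200).
#' @param tol Log-likelihood convergence tolerance, relative to
#'   `1 + |logL|` (default 1e-8).
#' @param n_starts Random initialisations in addition to the pooled start.
#' @param seed Optional integer seed for the random starts.
#' @param eps Profile clamping bound.
#' @return List with `loglik`, `profile_1`, `profile_2`, `responsibilities`
#'   (read membership in component 1), `trace` (log-likelihood per
#'   iteration of the best start), `converged`, `n_iter`.
#' @export
two_allele_em <- function(mat, max_iter = 200, tol = 1e-8, n_starts = 5,
                          seed = NULL, eps = 1e-3) {
  if (nrow(mat) < 4) stopf("two_allele_em requires at least 4 reads")
  W <- !is.na(mat)
  if (!any(W)) stopf("window has no observed states")
  X <- mat
  X[!W] <- 0
  XW <- X * W
  UW <- (1 - X) * W
  storage.mode(XW) <- "double"
  storage.mode(UW) <- "double"
  w <- ncol(mat)
  clamp <- function(p) pmin(pmax(p, eps), 1 - eps)

  run_em <- function(p1, p2) {
    trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    r <- rep(0.5, nrow(mat))
    for (it in seq_len(max_iter)) {
      a <- read_logliks(XW, UW, p1)
      b <- read_logliks(XW, UW, p2)
      mx <- pmax(a, b)
      ll <- sum(log(0.5) + mx + log(exp(a - mx) + exp(b - mx)))
      trace <- c(trace, ll)
      r <- 1 / (1 + exp(b - a))
      d1 <- as.vector(crossprod(W, r))
      d2 <- as.vector(crossprod(W, 1 - r))
      k1 <- as.vector(crossprod(XW, r))
      k2 <- as.vector(crossprod(XW, 1 - r))
      p1_new <- ifelse(d1 > 0, k1 / pmax(d1, 1e-12), p1)
      p2_new <- ifelse(d2 > 0, k2 / pmax(d2, 1e-12), p2)
      p1 <- clamp(p1_new)
      p2 <- clamp(p2_new)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
        converged <- TRUE
        break
      }
      ll_old <- ll
    }
    list(loglik = trace[length(trace)], p1 = p1, p2 = p2, r = r,
         trace = trace, converged = converged, n_iter = length(trace))
  }

  pooled <- single_allele_loglik(mat, eps)$profile
  starts <- list(list(pooled, pooled))
  if (n_starts > 0) {
    rand <- function() {
      lapply(1:2, function(i) clamp(stats::runif(w, 0.1, 0.9)))
    }
    more <- if (is.null(seed)) replicate(n_starts, rand(), simplify = FALSE)
    else with_seed(seed, replicate(n_starts, rand(), simplify = FALSE))
    starts <- c(starts, more)
  }
  fits <- lapply(starts, function(s) run_em(s[[1]], s[[2]]))
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  if (mean(best$p1) < mean(best$p2)) {
    best[c("p1", "p2")] <- best[c("p2", "p1")]
    best$r <- 1 - best$r
  }
  list(loglik = best$loglik, profile_1 = best$p1, profile_2 = best$p2,
       responsibilities = best$r, trace = best$trace,
       converged = best$converged, n_iter = best$n_iter)
}

#' Score fixed-width CpG windows for two-allele structure
#'
#' Slides a window of `w` consecutive CpGs (one CpG at a time) over each
#' chromosome's CpG index built from the reads, fits the single-profile and
#' two-allele models, and reports the likelihood-ratio statistic
#' `lrt = 2 (logL_two - logL_single)`, a p-value, and the mean absolute
#' difference `delta` between the two fitted profiles. Windows with fewer
#' than `min_reads` overlapping reads are skipped; chromosomes with fewer
#' than `w` CpGs are skipped.
#'
#' @param reads Epiread table for one sample.
#' @param w Window width in CpGs (default 10).
#' @param min_reads Minimum reads overlapping a window (default 4).
#' @param p_method `"chisq"` for a chi-square reference with `w` degrees of
#'   freedom, or `"permutation"` for an empirical p from shuffling states
#'   within CpG columns (mixture LRTs are irregular at the boundary; the
#'   permutation option provides a calibration check).
#' @param n_perm Permutations when `p_method = "permutation"`.
#' @param n_starts,max_iter,tol,eps Passed to [two_allele_em()]. The scan
#'   defaults trade the last ~1e-6 of log-likelihood for speed; window
#'   p-values are unaffected at the thresholds used.
#' @param seed Integer seed for EM starts (and permutations).
#' @return `data.frame`: one row per tested window with `chrom`,
#'   `first_cpg_index`, `start`, `end`, `n_reads`, `logl_single`,
#'   `logl_two`, `lrt`, `p_value`, `delta`.
#' @export
amr_windows <- function(reads, w = 10, min_reads = 4,
                        p_method = c("chisq", "permutation"), n_perm = 100,
                        n_starts = 5, max_iter = 100, tol = 1e-6,
                        eps = 1e-3, seed = 1) {
  p_method <- match.arg(p_method)
  out <- list()
  for (chrom in unique(reads$chrom)) {
    rr <- reads[reads$chrom == chrom, , drop = FALSE]
    cpg_pos <- sort(unique(unlist(rr$positions, use.names = FALSE)))
    n <- length(cpg_pos)
    if (n < w) next
    idx <- lapply(rr$positions, match, cpg_pos)
    st <- lapply(strsplit(rr$states, "", fixed = TRUE), function(s) {
      ifelse(s == "N", NA_real_, as.numeric(s == "M"))
    })
    lo <- vapply(idx, min, numeric(1))
    hi <- vapply(idx, max, numeric(1))
    for (i in seq_len(n - w + 1L)) {
      sel <- which(lo <= i + w - 1L & hi >= i)
      if (length(sel) < min_reads) next
      mat <- reads_to_matrix(st[sel], lapply(idx[sel], function(v) v - i + 1L),
                             w)
      keep <- rowSums(!is.na(mat)) > 0
      mat <- mat[keep, , drop = FALSE]
      if (nrow(mat) < min_reads) next
      s1 <- single_allele_loglik(mat, eps)
      em <- two_allele_em(mat, max_iter = max_iter, tol = tol,
                          n_starts = n_starts,
                          seed = derive_seed(seed, i), eps = eps)
      lrt <- 2 * (em$loglik - s1$loglik)
      delta <- mean(abs(em$profile_1 - em$profile_2))
      p <- if (p_method == "chisq") {
        stats::pchisq(max(lrt, 0), df = w, lower.tail = FALSE)
      } else {
        perm_lrt <- with_seed(derive_seed(seed, 10000 + i), {
          vapply(seq_len(n_perm), function(b) {
            pm <- apply(mat, 2, function(col) {
              obs <- !is.na(col)
              col[obs] <- sample(col[obs])
              col
            })
            ps1 <- single_allele_loglik(pm, eps)
            pem <- two_allele_em(pm, max_iter = max_iter, tol = tol,
                                 n_starts = max(2, n_starts - 3), eps = eps)
            2 * (pem$loglik - ps1$loglik)
          }, numeric(1))
        })
        (1 + sum(perm_lrt >= lrt)) / (n_perm + 1)
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, first_cpg_index = i, start = cpg_pos[i],
        end = cpg_pos[i + w - 1L], n_reads = nrow(mat),
        logl_single = s1$loglik, logl_two = em$loglik, lrt = lrt,
        p_value = p, delta = delta, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), first_cpg_index = integer(0),
                      start = integer(0), end = integer(0),
                      n_reads = integer(0), logl_single = numeric(0),
                      logl_two = numeric(0), lrt = numeric(0),
                      p_value = numeric(0), delta = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Scan one sample's epireads for allelically methylated regions
#'
#' Windows with `p < p_threshold` and `delta > delta_threshold` are merged
#' (any overlap in CpG index space) into maximal regions carrying the
#' minimum p and maximum delta of their member windows; every region spans
#' at least `w` consecutive CpGs.
#'
#' @inheritParams amr_windows
#' @param p_threshold Window p-value cutoff (default 0.01).
#' @param delta_threshold Minimum difference between the two methylation
#'   patterns (default 0.5).
#' @param windows Optional precomputed [amr_windows()] result.
#' @return `data.frame` of regions: `chrom`, `start`, `end`, `first_cpg`,
#'   `last_cpg`, `n_cpgs`, `p_value`, `delta`, `n_windows`.
#' @export
amr_scan <- function(reads, w = 10, p_threshold = 0.01,
                     delta_threshold = 0.5, min_reads = 4,
                     p_method = "chisq", n_starts = 5, seed = 1,
                     windows = NULL) {
  if (is.null(windows)) {
    windows <- amr_windows(reads, w = w, min_reads = min_reads,
                           p_method = p_method, n_starts = n_starts,
                           seed = seed)
  }
  sig <- windows[windows$p_value < p_threshold &
                   windows$delta > delta_threshold, , drop = FALSE]
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), first_cpg = integer(0),
                      last_cpg = integer(0), n_cpgs = integer(0),
                      p_value = numeric(0), delta = numeric(0),
                      n_windows = integer(0), stringsAsFactors = FALSE)
  if (!nrow(sig)) return(empty)
  out <- list()
  for (chrom in unique(sig$chrom)) {
    sc <- sig[sig$chrom == chrom, , drop = FALSE]
    ir <- IRanges::IRanges(sc$first_cpg_index, sc$first_cpg_index + w - 1L)
    red <- IRanges::reduce(ir)
    ov <- IRanges::findOverlaps(red, ir)
    for (j in seq_along(red)) {
      members <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == j]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = min(sc$start[members]),
        end = max(sc$end[members]),
        first_cpg = IRanges::start(red)[j], last_cpg = IRanges::end(red)[j],
        n_cpgs = IRanges::width(red)[j],
        p_value = min(sc$p_value[members]),
        delta = max(sc$delta[members]), n_windows = length(members),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, out)
  out[order(out$chrom, out$start), ]
}

#' Intersect per-sample AMRs to nominate putative imprinted regions
#'
#' Clusters AMRs across samples by any-overlap linkage. A cluster is a
#' candidate imprinted region when it is present in at least `min_samples`
#' of the samples *and* in at least one parental and one F1 sample: the
#' inbred parents carry two genotype-identical chromosomes, so a parental
#' AMR cannot be explained by genotype-driven allele-specific methylation.
#'
#' @param region_sets Named list (one entry per sample) of [amr_scan()]
#'   results; every sample in `samples` must be present.
#' @param samples Sample metadata ([sample_table()]).
#' @param min_samples Minimum samples sharing the region (default 6 of 8).
#' @param genes Optional gene annotation (`chrom`, `start`, `end`, `name`,
#'   optional `known_imprinted`) used to annotate candidates.
#' @return `data.frame` of clusters with `n_samples`, `samples_present`,
#'   `n_parents`, `n_f1`, `candidate` flag, and gene annotation when
#'   supplied.
#' @export
candidate_imprinted_regions <- function(region_sets, samples,
                                        min_samples = 6, genes = NULL) {
  missing <- setdiff(samples$sample_id, names(region_sets))
  if (length(missing)) {
    stopf("missing AMR set for sample '%s'", missing[1])
  }
  all <- do.call(rbind, lapply(samples$sample_id, function(s) {
    r <- region_sets[[s]]
    if (!nrow(r)) return(NULL)
    data.frame(chrom = r$chrom, start = r$start, end = r$end, sample_id = s,
               stringsAsFactors = FALSE)
  }))
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_samples = integer(0),
                      samples_present = character(0), n_parents = integer(0),
                      n_f1 = integer(0), candidate = logical(0),
                      stringsAsFactors = FALSE)
  if (is.null(all) || !nrow(all)) return(empty)
  gr <- GenomicRanges::GRanges(all$chrom,
                               IRanges::IRanges(all$start, all$end))
  red <- GenomicRanges::reduce(gr)
  ov <- GenomicRanges::findOverlaps(red, gr)
  parents <- samples$sample_id[samples$generation == "parent"]
  f1s <- samples$sample_id[samples$generation == "F1"]
  rows <- lapply(seq_along(red), function(j) {
    members <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == j]
    present <- sort(unique(all$sample_id[members]))
    np <- sum(present %in% parents)
    nf <- sum(present %in% f1s)
    data.frame(
      chrom = as.character(GenomicRanges::seqnames(red))[j],
      start = GenomicRanges::start(red)[j],
      end = GenomicRanges::end(red)[j],
      n_samples = length(present),
      samples_present = paste(present, collapse = ","),
      n_parents = np, n_f1 = nf,
      candidate = length(present) >= min_samples & np >= 1 & nf >= 1,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(genes) && nrow(genes)) {
    ggr <- GenomicRanges::GRanges(genes$chrom,
                                  IRanges::IRanges(genes$start, genes$end))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(out$chrom, IRanges::IRanges(out$start, out$end)),
      ggr))
    out$gene <- NA_character_
    out$known_imprinted <- FALSE
    for (j in seq_len(nrow(out))) {
      gi <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == j]
      if (length(gi)) {
        out$gene[j] <- paste(genes$name[gi], collapse = ",")
        if (!is.null(genes$known_imprinted)) {
          out$known_imprinted[j] <- any(genes$known_imprinted[gi])
        }
      }
    }
  }
  out[order(out$chrom, out$start), ]
}
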