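# Shared fixtures (built in code, cached across test files within a run).

.crossmeth_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  if (!exists(key, envir = .crossmeth_cache)) {
    assign(key, build(), envir = .crossmeth_cache)
  }
  get(key, envir = .crossmeth_cache)
}

# Default study-condition cross (60x, 1% error, delta-0.8 strain effects).
default_cross <- function() {
  cache_get("default_cross", function() {
    truth <- build_truth_model(truth_config(), seed = 20140430)
    sim <- simulate_cross(truth, seed = 101)
    list(truth = truth, sim = sim)
  })
}

# Same design without sequencing error, for the error-free recovery checks.
errorfree_cross <- function() {
  cache_get("errorfree_cross", function() {
    truth <- build_truth_model(truth_config(error_rate = 0), seed = 20140430)
    sim <- simulate_cross(truth, seed = 103)
    list(truth = truth, sim = sim)
  })
}

# SNP calls + parent genotypes derived from a simulated cross.
cross_genotypes <- function(cross) {
  pool_ids <- c("B6_F", "B6_M", "DBA_F", "DBA_M", "BXD_F", "BXD_M")
  pooled <- pool_base_counts(lapply(cross$sim$epireads[pool_ids],
                                    epiread_base_counts))
  snps <- call_snps(pooled)
  geno <- infer_parent_genotypes(
    snps,
    pool_base_counts(lapply(cross$sim$epireads[c("B6_F", "B6_M")],
                            epiread_base_counts)),
    pool_base_counts(lapply(cross$sim$epireads[c("DBA_F", "DBA_M")],
                            epiread_base_counts)))
  list(snps = snps, genotypes = geno)
}

# One full default-scale pipeline run shared by the acceptance tests.
default_pipeline_run <- function() {
  cache_get("default_pipeline_run", function() {
    outdir <- file.path(tempdir(), "crossmeth_acceptance_run")
    t0 <- Sys.time()
    summary <- suppressMessages(
      run_pipeline(pipeline_config(outdir = outdir, seed = 20140430)))
    list(summary = summary, outdir = outdir,
         elapsed = as.numeric(Sys.time() - t0, units = "secs"))
  })
}

# Simple epiread builder: one chromosome, reads given as level vectors over
# consecutive CpGs starting at a CpG index.
make_epireads <- function(states_list, cpg_pos, sample_id = "S1",
                          chrom = "chr1", start_idx = NULL) {
  n <- length(states_list)
  if (is.null(start_idx)) start_idx <- rep(1L, n)
  positions <- lapply(seq_len(n), function(i) {
    cpg_pos[seq(start_idx[i], length.out = nchar(states_list[[i]]))]
  })
  epireads(rep(chrom, n), sprintf("r%04d", seq_len(n)),
           rep(sample_id, n), positions, unlist(states_list))
}

# Draw a random read matrix (0/1/NA) for EM property tests.
random_window_matrix <- function(n_reads, w = 10) {
  p <- stats::runif(w)
  mat <- matrix(stats::rbinom(n_reads * w, 1, rep(p, each = n_reads)),
                nrow = n_reads)
  miss <- matrix(stats::runif(n_reads * w) < 0.15, nrow = n_reads)
  mat[miss] <- NA_real_
  # ensure each read keeps at least one observation
  empty <- rowSums(!is.na(mat)) == 0
  mat[empty, 1] <- stats::rbinom(sum(empty), 1, p[1])
  mat
}
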