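# End-to-end orchestration: simulate the eight-sample cross, call SNPs,
# assign reads to alleles, run the four site screens with simulation-based
# FDR, detect epimutations, scan for AMRs and candidate imprinted regions,
# run the expression screens, and write per-stage TSV/BED/JSON outputs plus
# a machine-readable summary. All randomness derives from one master seed,
# so reruns are byte-identical.

#' Pipeline configuration
#'
#' @param outdir Output directory.
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @param truth A [truth_config()] for the simulation stage.
#' @param sample_ids Samples to simulate/analyse (default: all eight).
#'   Stages whose required samples are absent are skipped and recorded.
#' @param n_sims_binomial Null resamplings for the pairwise binomial FDR.
#' @param n_sims_ttest Null resamplings for the t-test screen FDRs (the
#'   study's calibration used 1000).
#' @param amr_seed_offset Internal seed offset for the AMR stage.
#' @param run_amr,run_expression Toggles for the slower stages.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = tempfile("crossmeth_run_"), seed = 1,
                            truth = truth_config(),
                            sample_ids = sample_table()$sample_id,
                            n_sims_binomial = 25, n_sims_ttest = 1000,
                            amr_seed_offset = 7000,
                            run_amr = TRUE, run_expression = TRUE) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys override [pipeline_config()] fields; keys under `truth`
#' override [truth_config()] fields. Command-line style overrides passed as
#' `...` win over the file.
#'
#' @param path YAML file.
#' @param ... Named overrides applied after the file (e.g. `outdir`,
#'   `seed`).
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.list(y)) stopf("%s: not a YAML mapping", path)
  truth_over <- y$truth
  y$truth <- NULL
  y <- utils::modifyList(y, list(...))
  if (!is.null(truth_over)) {
    y$truth <- do.call(truth_config, truth_over)
  }
  bad <- setdiff(names(y), names(formals(pipeline_config)))
  if (length(bad)) stopf("unknown pipeline config field '%s'", bad[1])
  do.call(pipeline_config, y)
}

write_screen_outputs <- function(res, name, outdir, chrom_lengths) {
  dir.create(file.path(outdir, "screens"), showWarnings = FALSE,
             recursive = TRUE)
  write_hash_tsv(res, file.path(outdir, "screens", paste0(name, ".tsv")))
  sig <- res[res$significant, , drop = FALSE]
  export_bed(sig, file.path(outdir, "screens", paste0(name, ".bed")))
  bc <- bin_counts(sig, chrom_lengths)
  dir.create(file.path(outdir, "bins"), showWarnings = FALSE)
  write_hash_tsv(bc$bins, file.path(outdir, "bins", paste0(name, ".tsv")))
  invisible(sig)
}

context_rates <- function(res) {
  sig <- res[res$significant, , drop = FALSE]
  tested <- res[res$tested, , drop = FALSE]
  ctx <- c("CG", "CHG", "CHH")
  rates <- vapply(ctx, function(cc) {
    n <- sum(tested$context == cc)
    if (n == 0) return(NA_real_)
    sum(sig$context == cc) / n
  }, numeric(1))
  c(as.list(rates),
    list(overall = if (nrow(tested)) nrow(sig) / nrow(tested) else NA_real_))
}

#' Run the full synthetic-cross analysis pipeline
#'
#' Stage order: simulate, SNP calling, allele assignment, the four site
#' screens (strain, allele, sex, imprinting) with simulation-based FDR,
#' epimutation detection, the AMR scan with candidate imprinted regions,
#' and the expression screens. Writes per-stage outputs under
#' `config$outdir` and a `summary.json` whose counts equal the line counts
#' of the corresponding detail files; also emits a truth-versus-detected
#' recovery table for every planted effect class.
#'
#' @param config A [pipeline_config()].
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  outdir <- config$outdir
  seed <- config$seed
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(seed = seed, skipped = character(0))

  # -- simulate ---------------------------------------------------------
  truth <- build_truth_model(config$truth, derive_seed(seed, 1))
  sim <- simulate_cross(truth, derive_seed(seed, 2),
                        sample_ids = config$sample_ids)
  samples <- sim$samples
  write_truth_tables(truth, file.path(outdir, "truth"))
  dir.create(file.path(outdir, "sites"), showWarnings = FALSE)
  dir.create(file.path(outdir, "epireads"), showWarnings = FALSE)
  for (s in samples$sample_id) {
    write_site_table(sim$sites[[s]], file.path(outdir, "sites",
                                               paste0(s, ".tsv")))
  }
  write_hash_tsv(samples, file.path(outdir, "samples.tsv"))
  summary$n_samples <- nrow(samples)
  summary$sites_per_sample <- vapply(sim$sites, nrow, integer(1))
  parents <- samples$sample_id[samples$generation == "parent"]
  f1s <- samples$sample_id[samples$generation == "F1"]
  have <- function(ids) all(ids %in% samples$sample_id)
  skip <- function(stage, why) {
    message(sprintf("stage %s skipped: %s", stage, why))
    summary$skipped <<- c(summary$skipped, stage)
  }

  # -- SNP calling (pooled B6, DBA and BXD samples, per the study design)
  pool_ids <- intersect(c("B6_F", "B6_M", "DBA_F", "DBA_M", "BXD_F", "BXD_M"),
                        samples$sample_id)
  genotypes <- NULL
  if (length(pool_ids) >= 2) {
    pooled <- pool_base_counts(lapply(sim$epireads[pool_ids],
                                      epiread_base_counts))
    snps <- call_snps(pooled)
    write_snps(snps, file.path(outdir, "snps.tsv"))
    summary$n_snps <- nrow(snps)
    summary$n_snp_positions_filtered <- attr(snps, "n_filtered")
    b6_ids <- intersect(c("B6_F", "B6_M"), samples$sample_id)
    dba_ids <- intersect(c("DBA_F", "DBA_M"), samples$sample_id)
    if (length(b6_ids) && length(dba_ids)) {
      genotypes <- infer_parent_genotypes(
        snps,
        pool_base_counts(lapply(sim$epireads[b6_ids], epiread_base_counts)),
        pool_base_counts(lapply(sim$epireads[dba_ids], epiread_base_counts)))
    }
  } else {
    skip("snp_call", "needs pooled parental and BXD samples")
  }

  # -- allele assignment ------------------------------------------------
  f1_allele_tables <- NULL
  if (!is.null(genotypes) && length(f1s)) {
    conc_num <- conc_den <- 0
    n_polymorphic <- 0; n_reads <- 0
    for (s in f1s) {
      rr <- assign_read_allele(sim$epireads[[s]], genotypes)
      sim$epireads[[s]] <- rr
      informative <- rr$allele_tag %in% c("B6", "DBA")
      n_polymorphic <- n_polymorphic + sum(informative)
      n_reads <- n_reads + nrow(rr)
      conc_num <- conc_num + sum(rr$allele_tag[informative] ==
                                   rr$true_allele[informative])
      conc_den <- conc_den + sum(informative)
    }
    for (s in parents) {
      sim$epireads[[s]]$allele_tag <-
        samples$group[samples$sample_id == s]
    }
    summary$allele_concordance <- if (conc_den) conc_num / conc_den else NA
    summary$polymorphic_read_fraction <-
      if (n_reads) n_polymorphic / n_reads else NA
    f1_allele_tables <- lapply(sim$epireads[f1s], allele_site_tables)
    names(f1_allele_tables) <- f1s
  } else if (length(f1s)) {
    skip("assign_alleles", "no parent genotypes available")
  } else {
    skip("assign_alleles", "no F1 samples")
  }
  for (s in samples$sample_id) {
    write_epireads(sim$epireads[[s]],
                   file.path(outdir, "epireads", paste0(s, ".tsv")))
  }

  # -- screens ----------------------------------------------------------
  dir.create(file.path(outdir, "fdr"), showWarnings = FALSE)
  summary$screens <- list()
  run_fdr <- function(cmp, name, n_sims) {
    est <- tryCatch(estimate_fdr(cmp, n_sims = n_sims,
                                 seed = derive_seed(seed, 50 +
                                                      nchar(name))),
                    error = function(e) NULL)
    if (!is.null(est)) {
      jsonlite::write_json(
        list(x = est$x, y = est$y, fdr = est$fdr, n_sims = est$n_sims,
             seed = est$seed),
        file.path(outdir, "fdr", paste0(name, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
    est
  }

  if (have(c("B6_F", "DBA_F"))) {
    spec <- comparison_spec("strain")
    res <- pairwise_site_test(sim$sites$B6_F, sim$sites$DBA_F, spec)
    sig <- write_screen_outputs(res, "strain_female", outdir,
                                truth$chrom_lengths)
    est <- run_fdr(pairwise_comparison(sim$sites$B6_F, sim$sites$DBA_F,
                                       spec),
                   "strain_female", config$n_sims_binomial)
    summary$screens$strain_female <- list(
      n_tested = sum(res$tested), n_significant = nrow(sig),
      rates = context_rates(res),
      fdr = if (is.null(est)) NA else est$fdr)
    strain_sig_f <- sig
  } else {
    skip("screen_strain", "needs both female parents")
    strain_sig_f <- NULL
  }
  if (have(c("B6_M", "DBA_M"))) {
    spec <- comparison_spec("strain")
    res <- pairwise_site_test(sim$sites$B6_M, sim$sites$DBA_M, spec)
    sig <- write_screen_outputs(res, "strain_male", outdir,
                                truth$chrom_lengths)
    summary$screens$strain_male <- list(
      n_tested = sum(res$tested), n_significant = nrow(sig),
      rates = context_rates(res))
  }

  group_fdr <- function(group_a, group_b, spec, name) {
    sm <- site_matrix(c(group_a, group_b), min_coverage = 1)
    ia <- seq_along(group_a)
    ib <- length(group_a) + seq_along(group_b)
    cmp <- group_comparison(sm$meth[, ia, drop = FALSE],
                            sm$total[, ia, drop = FALSE],
                            sm$meth[, ib, drop = FALSE],
                            sm$total[, ib, drop = FALSE], spec)
    run_fdr(cmp, name, config$n_sims_ttest)
  }

  if (!is.null(f1_allele_tables) && length(parents) >= 2) {
    spec <- comparison_spec("allele")
    g_b6 <- c(sim$sites[intersect(c("B6_F", "B6_M"), parents)],
              lapply(f1_allele_tables, `[[`, "B6"))
    g_dba <- c(sim$sites[intersect(c("DBA_F", "DBA_M"), parents)],
               lapply(f1_allele_tables, `[[`, "DBA"))
    names(g_b6) <- paste0("b6_", seq_along(g_b6))
    names(g_dba) <- paste0("dba_", seq_along(g_dba))
    res <- screen_sites(g_b6, g_dba, spec)
    sig <- write_screen_outputs(res, "allele", outdir, truth$chrom_lengths)
    est <- group_fdr(g_b6, g_dba, spec, "allele")
    summary$screens$allele <- list(
      n_tested = sum(res$tested), n_significant = nrow(sig),
      rates = context_rates(res), fdr = if (is.null(est)) NA else est$fdr)
  } else {
    skip("screen_allele", "needs allele-resolved F1 reads and parents")
  }

  females <- samples$sample_id[samples$sex == "F"]
  males <- samples$sample_id[samples$sex == "M"]
  if (length(females) >= 3 && length(males) >= 3) {
    spec <- comparison_spec("sex")
    res <- screen_sites(sim$sites[females], sim$sites[males], spec)
    sig <- write_screen_outputs(res, "sex", outdir, truth$chrom_lengths)
    sex_sig_sites <- sig
    est <- group_fdr(sim$sites[females], sim$sites[males], spec, "sex")
    summary$screens$sex <- list(
      n_tested = sum(res$tested), n_significant = nrow(sig),
      rates = context_rates(res), fdr = if (is.null(est)) NA else est$fdr)
    sex_genes <- genes_near_sites(sig, truth$genes)
    write_hash_tsv(sex_genes, file.path(outdir, "screens", "sex_genes.tsv"))
    summary$screens$sex$n_genes <- nrow(sex_genes)
  } else {
    skip("screen_sex", "needs at least 3 samples per sex")
    sex_sig_sites <- NULL
  }

  if (!is.null(f1_allele_tables) && length(f1s) >= 3) {
    spec <- comparison_spec("imprinting")
    mat_tabs <- lapply(f1s, function(s) {
      strain <- samples$maternal_strain[samples$sample_id == s]
      f1_allele_tables[[s]][[strain]]
    })
    pat_tabs <- lapply(f1s, function(s) {
      strain <- samples$paternal_strain[samples$sample_id == s]
      f1_allele_tables[[s]][[strain]]
    })
    names(mat_tabs) <- paste0("mat_", f1s)
    names(pat_tabs) <- paste0("pat_", f1s)
    res <- screen_sites(mat_tabs, pat_tabs, spec)
    sig <- write_screen_outputs(res, "imprinting", outdir,
                                truth$chrom_lengths)
    est <- group_fdr(mat_tabs, pat_tabs, spec, "imprinting")
    summary$screens$imprinting <- list(
      n_tested = sum(res$tested), n_significant = nrow(sig),
      rates = context_rates(res), fdr = if (is.null(est)) NA else est$fdr)
  } else {
    skip("screen_imprinting", "needs allele-resolved reads from F1 samples")
  }

  # -- epimutations -----------------------------------------------------
  if (!is.null(f1_allele_tables) && length(parents) == 4) {
    # exclusion list: known imprinted genes plus the pipeline's own
    # sex-significant sites -- each parent-F1 chromosome pair spans mice of
    # different sexes, so sex-differential sites would masquerade as
    # epimutations
    known <- truth$imprinted_regions[, c("chrom", "start", "end")]
    if (!is.null(sex_sig_sites) && nrow(sex_sig_sites)) {
      known <- rbind(known,
                     data.frame(chrom = sex_sig_sites$chrom,
                                start = sex_sig_sites$pos,
                                end = sex_sig_sites$pos,
                                stringsAsFactors = FALSE))
    }
    epi <- detect_epimutations(sim$sites[parents], f1_allele_tables,
                               samples, known_imprinted = known)
    write_hash_tsv(epi$calls, file.path(outdir, "epimutations_calls.tsv"))
    write_hash_tsv(epi$sites, file.path(outdir, "epimutations_sites.tsv"))
    summary$epimutations <- list(
      n_calls = nrow(epi$calls),
      n_class1 = sum(epi$sites$reproducibility_class >= 1),
      n_class2 = sum(epi$sites$reproducibility_class >= 2))
    epi_sites <- epi$sites
  } else {
    skip("epimutations", "needs all four parents and allele-resolved F1s")
    epi_sites <- NULL
  }

  # -- AMR scan and candidate imprinted regions -------------------------
  amr_regions <- NULL
  if (isTRUE(config$run_amr)) {
    dir.create(file.path(outdir, "amr"), showWarnings = FALSE)
    amr_regions <- lapply(samples$sample_id, function(s) {
      r <- amr_scan(sim$epireads[[s]],
                    seed = derive_seed(seed, config$amr_seed_offset +
                                         match(s, samples$sample_id)))
      write_hash_tsv(r, file.path(outdir, "amr", paste0(s, ".tsv")))
      export_bed(r, file.path(outdir, "amr", paste0(s, ".bed")))
      r
    })
    names(amr_regions) <- samples$sample_id
    summary$amr <- list(regions_per_sample = vapply(amr_regions, nrow,
                                                    integer(1)))
    if (all(sample_table()$sample_id %in% samples$sample_id)) {
      cand <- candidate_imprinted_regions(amr_regions, samples,
                                          genes = truth$genes)
      write_hash_tsv(cand, file.path(outdir, "amr_candidates.tsv"))
      summary$amr$n_clusters <- nrow(cand)
      summary$amr$n_candidates <- sum(cand$candidate)
      amr_cand <- cand[cand$candidate, , drop = FALSE]
    } else {
      skip("amr_candidates", "needs the full eight-sample design")
      amr_cand <- NULL
    }
  } else {
    skip("amr", "disabled in config")
    amr_cand <- NULL
  }

  # -- expression screens ----------------------------------------------
  if (isTRUE(config$run_expression)) {
    dir.create(file.path(outdir, "expression"), showWarnings = FALSE)
    ac <- simulate_allelic_counts(truth, seed = derive_seed(seed, 41))
    imp <- imprinting_expression_screen(ac)
    write_hash_tsv(imp, file.path(outdir, "expression",
                                  "imprinting_fisher.tsv"))
    em <- simulate_expression_matrix(truth, seed = derive_seed(seed, 42))
    de <- sex_de_screen(em$expr, em$sex)
    write_hash_tsv(de, file.path(outdir, "expression", "sex_de.tsv"))
    summary$expression <- list(
      n_imprinted_p = sum(imp$significant_p),
      n_imprinted_fdr = sum(imp$significant_fdr),
      n_sex_de = sum(de$significant),
      imprinted_recall = if (any(ac$imprinted)) {
        mean(imp$significant_p[ac$imprinted] & imp$origin_flip[ac$imprinted])
      } else NA,
      sex_de_recall = if (any(em$sex_de)) {
        mean(de$significant[em$sex_de])
      } else NA)
  } else {
    skip("expression", "disabled in config")
  }

  # -- truth-versus-detected recovery -----------------------------------
  recovery <- list()
  if (!is.null(strain_sig_f) && nrow(truth$strain_sites)) {
    recovery$strain_sites <- mean(
      paste(truth$strain_sites$chrom, truth$strain_sites$pos) %in%
        paste(strain_sig_f$chrom, strain_sig_f$pos))
  }
  if (!is.null(summary$screens$sex) && nrow(truth$sex_sites)) {
    sexsig <- read_hash_tsv(file.path(outdir, "screens", "sex.tsv"))
    sexsig <- sexsig[sexsig$significant == "TRUE" | sexsig$significant == TRUE, ]
    recovery$sex_sites <- mean(
      paste(truth$sex_sites$chrom, truth$sex_sites$pos) %in%
        paste(sexsig$chrom, sexsig$pos))
  }
  if (!is.null(amr_cand) && nrow(truth$imprinted_regions)) {
    tr <- GenomicRanges::GRanges(
      truth$imprinted_regions$chrom,
      IRanges::IRanges(truth$imprinted_regions$start,
                       truth$imprinted_regions$end))
    if (nrow(amr_cand)) {
      cd <- GenomicRanges::GRanges(amr_cand$chrom,
                                   IRanges::IRanges(amr_cand$start,
                                                    amr_cand$end))
      recovery$imprinted_regions <-
        mean(suppressWarnings(IRanges::overlapsAny(tr, cd)))
      if (nrow(truth$strain_regions)) {
        sr <- GenomicRanges::GRanges(
          truth$strain_regions$chrom,
          IRanges::IRanges(truth$strain_regions$start,
                           truth$strain_regions$end))
        recovery$strain_region_false_candidates <-
          sum(suppressWarnings(IRanges::overlapsAny(cd, sr)))
      }
    } else {
      recovery$imprinted_regions <- 0
      recovery$strain_region_false_candidates <- 0
    }
  }
  if (!is.null(epi_sites) && nrow(truth$epimutations)) {
    tk <- paste(truth$epimutations$chrom, truth$epimutations$pos,
                truth$epimutations$strain)
    dk <- paste(epi_sites$chrom, epi_sites$pos, epi_sites$allele)
    recovery$epimutation_sites <- mean(tk %in% dk)
    hit <- match(tk, dk)
    recovery$epimutation_class_exact <- mean(
      !is.na(hit) & epi_sites$reproducibility_class[hit] ==
        truth$epimutations$expected_class)
  }
  summary$recovery <- recovery

  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(summary)
}
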