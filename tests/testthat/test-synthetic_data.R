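test_that("truth model is deterministic for a fixed seed and books effects exactly", {
  cfg <- truth_config(n_regions = 6, cpgs_per_region = 40,
                      n_strain_sites = 30, n_sex_sites = 10,
                      n_imprinted = 1, n_strain_regions = 1)
  t1 <- build_truth_model(cfg, seed = 5)
  t2 <- build_truth_model(cfg, seed = 5)
  expect_identical(t1, t2)
  t3 <- build_truth_model(cfg, seed = 6)
  expect_false(identical(t1$cpgs$baseline, t3$cpgs$baseline))
  # planted fractions match the config exactly
  expect_equal(nrow(t1$strain_sites), 30)
  expect_true(all(t1$strain_sites$delta == 0.8))
  expect_equal(abs(t1$strain_sites$b6_level - t1$strain_sites$dba_level),
               rep(0.8, 30))
  # effect site sets are disjoint
  keys <- c(paste(t1$strain_sites$chrom, t1$strain_sites$pos),
            paste(t1$sex_sites$chrom, t1$sex_sites$pos),
            paste(t1$epimutations$chrom, t1$epimutations$pos))
  expect_false(any(duplicated(keys)))
  expect_true(all(t1$imprinted_regions$n_cpgs >= 10))
  expect_error(build_truth_model(truth_config(imprinted_cpgs = 8)),
               "at least 10")
  expect_error(
    build_truth_model(truth_config(n_regions = 8, cpgs_per_region = 12,
                                   n_imprinted = 1, n_strain_regions = 1,
                                   imprinted_cpgs = 10,
                                   strain_region_cpgs = 10,
                                   n_strain_sites = 500)),
    "infeasible")
})

test_that("a zero-effect model gives every chromosome the same levels", {
  cfg <- truth_config(n_regions = 3, cpgs_per_region = 30,
                      n_strain_sites = 0, n_sex_sites = 0, n_imprinted = 0,
                      n_strain_regions = 0, n_epimutations_class1 = 0,
                      n_epimutations_class2 = 0)
  truth <- build_truth_model(cfg, seed = 2)
  for (r in truth$regions$region) {
    ref <- crossmeth:::chromosome_levels(truth, r, "B6", "maternal", "F",
                                         "B6_F")
    for (strain in c("B6", "DBA")) for (po in c("maternal", "paternal")) {
      for (sx in c("F", "M")) {
        expect_equal(crossmeth:::chromosome_levels(truth, r, strain, po, sx,
                                                   "DXB_M"), ref)
      }
    }
  }
})

test_that("error-free reads are deterministic images of planted levels", {
  # maternal and paternal levels pinned at 1 -> every covering read state M
  cfg <- truth_config(n_regions = 3, cpgs_per_region = 30, n_imprinted = 1,
                      maternal_level = 1, paternal_level = 1,
                      n_strain_regions = 0, n_strain_sites = 5,
                      n_sex_sites = 0, n_epimutations_class1 = 0,
                      n_epimutations_class2 = 0, error_rate = 0)
  truth <- build_truth_model(cfg, seed = 3)
  sim <- simulate_sample(truth, "BXD_F", seed = 4)
  ir <- truth$imprinted_regions
  in_run <- sim$sites$chrom == ir$chrom[1] & sim$sites$pos >= ir$start[1] &
    sim$sites$pos <= ir$end[1]
  expect_true(any(in_run))
  expect_equal(sim$sites$level[in_run], rep(1, sum(in_run)))
  # parent sample: every read comes from one genotype; truth equals strain
  psim <- simulate_sample(truth, "DBA_M", seed = 5)
  expect_true(all(psim$epireads$true_allele == "DBA"))
  expect_error(simulate_sample(truth, "CAST_F"), "unknown sample")
})

test_that("per-CpG coverage averages the configured depth", {
  cross <- default_cross()
  for (s in c("B6_F", "DXB_M")) {
    cg <- cross$sim$sites[[s]]
    cg <- cg[cg$context == "CG", ]
    expect_lt(abs(mean(cg$total_count) - 60) / 60, 0.05)
  }
})

test_that("same seed reproduces a sample exactly", {
  truth <- build_truth_model(
    truth_config(n_regions = 3, cpgs_per_region = 30, n_strain_sites = 10,
                 n_sex_sites = 5, n_imprinted = 1, n_strain_regions = 0,
                 n_epimutations_class1 = 1, n_epimutations_class2 = 0),
    seed = 9)
  s1 <- simulate_sample(truth, "BXD_M", seed = 77)
  s2 <- simulate_sample(truth, "BXD_M", seed = 77)
  expect_identical(s1, s2)
})

test_that("truth tables write with headers (even empty) and reload", {
  cfg <- truth_config(n_regions = 3, cpgs_per_region = 30,
                      n_strain_sites = 0, n_sex_sites = 0, n_imprinted = 1,
                      n_strain_regions = 0, n_epimutations_class1 = 0,
                      n_epimutations_class2 = 0)
  truth <- build_truth_model(cfg, seed = 8)
  outdir <- withr::local_tempdir()
  write_truth_tables(truth, outdir)
  ss <- crossmeth:::read_hash_tsv(file.path(outdir, "strain_sites.tsv"))
  expect_equal(nrow(ss), 0)
  expect_true(all(c("chrom", "pos", "b6_level") %in% names(ss)))
  ir <- crossmeth:::read_hash_tsv(file.path(outdir, "imprinted_regions.tsv"))
  expect_equal(ir$start, truth$imprinted_regions$start)
  bed <- read_bed(file.path(outdir, "imprinted_regions.bed"))
  expect_equal(nrow(bed), 1)
  expect_equal(bed$start, truth$imprinted_regions$start)
  snps <- crossmeth:::read_hash_tsv(file.path(outdir, "snps.tsv"))
  expect_equal(snps$pos, truth$snps$pos)
})

test_that("hidden allele truth agrees with SNP assignment on error-free reads", {
  cross <- errorfree_cross()
  gg <- cross_genotypes(cross)
  for (s in c("BXD_F", "DXB_M")) {
    rr <- assign_read_allele(cross$sim$epireads[[s]], gg$genotypes)
    informative <- rr$allele_tag %in% c("B6", "DBA")
    # every read overlapping >= 1 genotyped SNP is assigned, and correctly
    has_snp <- vapply(seq_len(nrow(rr)), function(i) {
      any(paste(rr$chrom[i], rr$snp_positions[[i]]) %in%
            paste(gg$genotypes$chrom, gg$genotypes$pos))
    }, logical(1))
    expect_equal(informative, has_snp)
    expect_true(all(rr$allele_tag[informative] ==
                      rr$true_allele[informative]))
  }
})

test_that("allelic expression counts skew with cross direction only for imprinted genes", {
  cross <- default_cross()
  ac <- simulate_allelic_counts(cross$truth, seed = 21)
  imp <- ac[ac$imprinted, ]
  expect_true(all(imp$bxd_b6 > imp$bxd_dba))
  expect_true(all(imp$dxb_dba > imp$dxb_b6))
  bal <- ac[!ac$imprinted, ]
  tot <- bal$bxd_b6 + bal$bxd_dba + bal$dxb_b6 + bal$dxb_dba
  frac_b6 <- (bal$bxd_b6 + bal$dxb_b6) / tot
  expect_lt(abs(mean(frac_b6) - 0.5), 0.1)
})
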