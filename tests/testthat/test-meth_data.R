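test_that("context classification follows the CG/CHG/CHH rules on both strands", {
  expect_equal(classify_context("ACGT", 2, "+"), "CG")
  expect_equal(classify_context("ACAGT", 2, "+"), "CHG")
  expect_equal(classify_context("ACAAT", 2, "+"), "CHH")
  # plus-strand "CCGG": the G at position 3 is a C on the minus strand
  # followed on the minus strand by a G (reverse-complement CG symmetry)
  expect_equal(classify_context("CCGG", 3, "-"), "CG")
  expect_equal(classify_context("CAG", 3, "-"), "CHG")
  # sequence ends padded as non-G
  expect_equal(classify_context("AC", 2, "+"), "CHH")
  expect_equal(classify_context("GA", 1, "-"), "CHH")
  expect_error(classify_context("ACGT", 1, "+"), "not a cytosine")
  expect_error(classify_context("ACGT", 2, "-"), "not a cytosine")
})

test_that("every reference cytosine gets exactly one context", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      ref <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                   collapse = "")
      ctx <- all_cytosine_contexts(ref)
      chars <- strsplit(ref, "")[[1]]
      expect_equal(nrow(ctx), sum(chars == "C") + sum(chars == "G"))
      expect_true(all(ctx$context %in% c("CG", "CHG", "CHH")))
      expect_false(any(duplicated(paste(ctx$pos, ctx$strand))))
    }
  })
})

test_that("site tables roundtrip through their TSV format", {
  withr::with_seed(7, {
    n <- 50
    tot <- sample(1:80, n, replace = TRUE)
    sites <- cytosine_sites(
      sample(c("chr1", "chr2"), n, replace = TRUE),
      sample.int(1e6, n), sample(c("+", "-"), n, replace = TRUE),
      sample(c("CG", "CHG", "CHH"), n, replace = TRUE),
      vapply(tot, function(t) sample.int(t + 1L, 1L) - 1L, integer(1)), tot)
  })
  path <- withr::local_tempfile(fileext = ".tsv")
  write_site_table(sites, path)
  expect_equal(load_site_table(path), sites, ignore_attr = TRUE)
})

test_that("site parsing errors name the offending line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#chrom\tpos\tstrand\tcontext\tmeth_count\ttotal_count",
               "chr1\t100\t+\tCG\t12\t10"), path)
  expect_error(load_site_table(path), "line 2")
  writeLines(c("#chrom\tpos\tstrand\tcontext\tmeth_count\ttotal_count",
               "chr1\t100\t+\tCG\t2\t10",
               "chr1\t200\t+\tCG\t0\t0"), path)
  expect_error(load_site_table(path), "line 3")
  writeLines(c("#chrom\tpos\tstrand\tcontext\tmeth_count\ttotal_count",
               "chr1\t100\t+\tCG\t2"), path)
  expect_error(load_site_table(path), "line 2")
  # the study's 1-based coordinate style is preserved
  writeLines(c("#chrom\tpos\tstrand\tcontext\tmeth_count\ttotal_count",
               "chr17\t34960471\t+\tCG\t5\t10"), path)
  expect_equal(load_site_table(path)$pos, 34960471L)
})

test_that("epireads roundtrip with allele tags and reject bad states", {
  reads <- epireads(rep("chr1", 3), c("r1", "r2", "r3"), "s1",
                    list(c(10L, 25L, 31L), c(25L, 31L), 40L),
                    c("MUN", "UM", "M"),
                    c("B6", "uninformative", "ambiguous"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_epireads(reads, path)
  back <- load_epireads(path)
  expect_equal(back, reads, ignore_attr = TRUE)
  expect_equal(back$allele_tag[1], "B6")
  expect_error(epireads("chr1", "r1", "s1", list(c(1L, 2L, 3L)), "MXU"),
               "outside \\{M,U,N\\}")
  expect_error(epireads("chr1", "r1", "s1", list(c(5L, 3L)), "MU"),
               "strictly increasing")
})

test_that("simulated epireads roundtrip including SNP observations", {
  cross <- default_cross()
  reads <- utils::head(cross$sim$epireads$BXD_F, 40)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_epireads(reads, path)
  back <- load_epireads(path)
  rownames(reads) <- NULL
  expect_equal(back, reads, ignore_attr = TRUE)
})

test_that("BED export uses 0-based half-open coordinates and roundtrips", {
  sites <- cytosine_sites("chr1", 100, "+", "CG", 1, 2)
  path <- withr::local_tempfile(fileext = ".bed")
  export_bed(sites, path)
  bed <- utils::read.table(path, sep = "\t")
  expect_equal(bed$V2, 99)
  expect_equal(bed$V3, 100)
  iv <- data.frame(chrom = "chr1", start = 1, end = 10, name = "x")
  export_bed(iv, path)
  bed <- utils::read.table(path, sep = "\t")
  expect_equal(c(bed$V2, bed$V3), c(0, 10))
  expect_equal(read_bed(path)[, c("chrom", "start", "end")],
               iv[, c("chrom", "start", "end")], ignore_attr = TRUE)
  # empty input -> empty file, success
  export_bed(iv[0, ], path)
  expect_length(readLines(path), 0)
  # randomized roundtrip
  withr::with_seed(11, {
    ivs <- data.frame(chrom = "chr2", start = sample.int(1000, 20),
                      stringsAsFactors = FALSE)
    ivs$end <- ivs$start + sample.int(50, 20)
    ivs$name <- sprintf("iv%02d", 1:20)
  })
  export_bed(ivs, path)
  expect_equal(read_bed(path)[, c("chrom", "start", "end", "name")], ivs,
               ignore_attr = TRUE)
})

test_that("global summary reports per-context means and handles empty strata", {
  full <- cytosine_sites("chr1", c(10, 20, 30), "+", c("CG", "CHG", "CHH"),
                         c(5, 8, 2), c(5, 8, 2))
  gs <- global_summary(full)
  expect_equal(gs$mean_level, rep(1, 4))
  chh_only <- cytosine_sites("chr1", 1:4, "+", "CHH", 0:3, rep(4, 4))
  gs <- global_summary(chh_only)
  expect_false("CG" %in% gs$context)
  expect_equal(gs$mean_level[gs$context == "overall"], mean(0:3 / 4))
  expect_error(global_summary(full[0, ]), "empty")
})

test_that("simulated CG baseline matches the configured genome-wide mean", {
  # law-of-large-numbers check at ~10,000 CpGs
  truth <- build_truth_model(
    truth_config(n_regions = 51, cpgs_per_region = 200, n_strain_sites = 0,
                 n_sex_sites = 0, n_imprinted = 0, n_strain_regions = 0,
                 n_epimutations_class1 = 0, n_epimutations_class2 = 0,
                 snps_per_region = 2),
    seed = 99)
  lev <- truth$cpgs$baseline
  se <- stats::sd(lev) / sqrt(length(lev))
  expect_gt(length(lev), 10000)
  expect_lt(abs(mean(lev) - 0.4839), 3 * se)
})
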