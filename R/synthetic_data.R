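# Ground-truthed RRBS-like data for the eight-sample reciprocal cross:
# two haplotypes differing at SNPs, context-specific methylation baselines,
# planted strain / sex / imprinted / epimutation effects, Poisson coverage
# and a symmetric per-state error model.

#' Sample metadata for the reciprocal cross design
#'
#' The eight-mouse design: female and male B6 and DBA parents plus the
#' reciprocal F1s (BXD: B6 mother x DBA father; DXB: DBA mother x B6
#' father), which decouples allele genotype from parental origin.
#'
#' @return `data.frame` with `sample_id`, `group`, `sex`, `generation`,
#'   `maternal_strain`, `paternal_strain`.
#' @export
sample_table <- function() {
  data.frame(
    sample_id = c("B6_F", "B6_M", "DBA_F", "DBA_M",
                  "BXD_F", "BXD_M", "DXB_F", "DXB_M"),
    group = c("B6", "B6", "DBA", "DBA", "BXD", "BXD", "DXB", "DXB"),
    sex = rep(c("F", "M"), 4),
    generation = rep(c("parent", "F1"), each = 4),
    maternal_strain = c("B6", "B6", "DBA", "DBA", "B6", "B6", "DBA", "DBA"),
    paternal_strain = c("B6", "B6", "DBA", "DBA", "DBA", "DBA", "B6", "B6"),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic truth model
#'
#' Defaults encode the study conditions the generator emulates: ~60x mean
#' coverage, a combined bisulfite/sequencing error rate below 1%, a CG
#' baseline averaging 48.39% drawn from a low/high two-component mixture
#' (unmethylated CpG islands versus highly methylated sparse CpGs), CHG/CHH
#' baselines near zero (0.71% / 0.75%), strain effects of delta 0.8, and
#' imprinted regions of at least 10 consecutive CpGs with maternal level
#' 0.95 and paternal level 0.05.
#'
#' @param n_regions Number of simulated RRBS target regions.
#' @param cpgs_per_region CpGs per region.
#' @param cpg_spacing Range (min, max) of base-pair spacing between CpGs.
#' @param region_gap Base pairs separating regions on a chromosome.
#' @param n_chroms Chromosomes the regions are spread over.
#' @param snps_per_region Haplotype-distinguishing SNPs per region.
#' @param ct_snp_fraction Fraction of SNPs whose alleles are C/T, which the
#'   bisulfite SNP caller must refuse to call.
#' @param cg_mean,cg_low_mean,cg_high_mean Target CG baseline mean and the
#'   means of the low/high mixture components; the mixture weight is solved
#'   so the site-average equals `cg_mean`.
#' @param chg_sites,chh_sites,chg_mean,chh_mean Number and mean level of
#'   non-CpG cytosines carried in site tables.
#' @param n_strain_sites,strain_delta Scattered single-CpG strain effects;
#'   levels are `(1 +/- strain_delta) / 2`.
#' @param n_strain_regions,strain_region_cpgs Contiguous strain-dependent
#'   blocks (genotype-driven allele-specific methylation, AMR-like in F1s
#'   but uniform in each inbred parent).
#' @param n_sex_sites,sex_delta Scattered single-CpG sex effects.
#' @param n_imprinted,imprinted_cpgs Imprinted regions (>= 10 CpGs each).
#' @param maternal_level,paternal_level Methylation of the maternal/paternal
#'   allele inside imprinted regions, independent of genotype.
#' @param n_epimutations_class1,n_epimutations_class2 Epimutation sites
#'   carried by one F1 chromosome (one parent-F1 pair) or by both F1s of one
#'   cross direction (two pairs sharing the transmitting parent).
#' @param epimutation_base,epimutation_shift Parental baseline and shifted F1
#'   level at epimutation sites.
#' @param coverage_mean Mean per-CpG read coverage.
#' @param error_rate Probability that an observed state or base is flipped
#'   (combined bisulfite non-conversion and sequencing error).
#' @param read_width CpGs covered per simulated read.
#' @return A list of class `truth_config`.
#' @export
truth_config <- function(n_regions = 12, cpgs_per_region = 60,
                         cpg_spacing = c(10, 40), region_gap = 50000,
                         n_chroms = 4,
                         snps_per_region = 10, ct_snp_fraction = 0.25,
                         cg_mean = 0.4839, cg_low_mean = 0.05,
                         cg_high_mean = 0.85,
                         chg_sites = 150, chh_sites = 150,
                         chg_mean = 0.0071, chh_mean = 0.0075,
                         n_strain_sites = 100, strain_delta = 0.8,
                         n_strain_regions = 2, strain_region_cpgs = 12,
                         n_sex_sites = 60, sex_delta = 0.6,
                         n_imprinted = 3, imprinted_cpgs = 12,
                         maternal_level = 0.95, paternal_level = 0.05,
                         n_epimutations_class1 = 2, n_epimutations_class2 = 2,
                         epimutation_base = 0.05, epimutation_shift = 0.9,
                         coverage_mean = 60, error_rate = 0.01,
                         read_width = 8) {
  cfg <- as.list(environment())
  class(cfg) <- "truth_config"
  cfg
}

beta_with_mean <- function(n, mean, shape1 = 2) {
  # Beta draw with fixed shape1 and mean-matched shape2
  mean <- min(max(mean, 1e-4), 1 - 1e-4)
  stats::rbeta(n, shape1, shape1 * (1 - mean) / mean)
}

#' Build the planted truth model for a synthetic cross
#'
#' Lays out regions and CpGs, places SNPs between the two haplotypes, draws
#' per-site baselines, and plants the four effect classes (strain, sex,
#' imprinting, epimutation) on disjoint site sets. Deterministic for a fixed
#' seed.
#'
#' @param config A [truth_config()].
#' @param seed Integer seed.
#' @return Object of class `truth_model`: region layout, CpG table, SNP
#'   table, effect truth tables, gene annotation and chromosome lengths.
#' @export
build_truth_model <- function(config = truth_config(), seed = 1) {
  cfg <- config
  if (cfg$imprinted_cpgs < 10) {
    stopf("imprinted regions must contain at least 10 CpGs")
  }
  n_special <- cfg$n_imprinted + cfg$n_strain_regions
  if (cfg$n_regions <= n_special) {
    stopf("config needs more regions than imprinted + strain regions")
  }
  if (cfg$imprinted_cpgs > cfg$cpgs_per_region ||
      cfg$strain_region_cpgs > cfg$cpgs_per_region) {
    stopf("region effect blocks longer than a region")
  }
  with_seed(seed, {
    nr <- cfg$n_regions
    chrom <- paste0("chr", ((seq_len(nr) - 1L) %% cfg$n_chroms) + 1L)
    idx_on_chrom <- stats::ave(seq_len(nr), chrom, FUN = seq_along)
    alloc <- cfg$region_gap + cfg$cpgs_per_region * cfg$cpg_spacing[2]

    cpgs <- vector("list", nr)
    for (r in seq_len(nr)) {
      gaps <- sample(seq(cfg$cpg_spacing[1], cfg$cpg_spacing[2]),
                     cfg$cpgs_per_region, replace = TRUE)
      start <- 10000L + (idx_on_chrom[r] - 1L) * alloc
      pos <- start + cumsum(gaps)
      cpgs[[r]] <- data.frame(region = r, chrom = chrom[r], pos = pos,
                              idx = seq_along(pos), stringsAsFactors = FALSE)
    }
    cpgs <- do.call(rbind, cpgs)

    # CG baseline: two-component mixture solved to hit the configured mean
    w_high <- (cfg$cg_mean - cfg$cg_low_mean) /
      (cfg$cg_high_mean - cfg$cg_low_mean)
    hi <- stats::runif(nrow(cpgs)) < w_high
    base <- numeric(nrow(cpgs))
    base[hi] <- beta_with_mean(sum(hi), cfg$cg_high_mean, shape1 = 8)
    base[!hi] <- beta_with_mean(sum(!hi), cfg$cg_low_mean, shape1 = 1)
    cpgs$baseline <- base

    # region roles
    role <- rep("free", nr)
    if (cfg$n_imprinted > 0) role[seq_len(cfg$n_imprinted)] <- "imprinted"
    if (cfg$n_strain_regions > 0) {
      role[cfg$n_imprinted + seq_len(cfg$n_strain_regions)] <- "strain_region"
    }
    regions <- data.frame(
      region = seq_len(nr), chrom = chrom, role = role,
      start = tapply(cpgs$pos, cpgs$region, min)[as.character(seq_len(nr))],
      end = tapply(cpgs$pos, cpgs$region, max)[as.character(seq_len(nr))],
      n_cpgs = cfg$cpgs_per_region, stringsAsFactors = FALSE
    )

    block <- function(rs, len, lev1, lev2, cols) {
      if (!length(rs)) {
        out <- data.frame(region = integer(0), chrom = character(0),
                          start = integer(0), end = integer(0),
                          idx_start = integer(0), n_cpgs = integer(0))
        out[[cols[1]]] <- numeric(0); out[[cols[2]]] <- numeric(0)
        return(out)
      }
      i0 <- floor((cfg$cpgs_per_region - len) / 2) + 1L  # centered run
      out <- do.call(rbind, lapply(rs, function(r) {
        rc <- cpgs[cpgs$region == r, ]
        data.frame(region = r, chrom = rc$chrom[1],
                   start = rc$pos[i0], end = rc$pos[i0 + len - 1L],
                   idx_start = i0, n_cpgs = len, stringsAsFactors = FALSE)
      }))
      out[[cols[1]]] <- lev1; out[[cols[2]]] <- lev2
      out
    }
    imprinted_regions <- block(which(role == "imprinted"), cfg$imprinted_cpgs,
                               cfg$maternal_level, cfg$paternal_level,
                               c("maternal_level", "paternal_level"))
    imprinted_regions$known <- seq_len(nrow(imprinted_regions)) == 1L
    hi_lev <- (1 + cfg$strain_delta) / 2
    lo_lev <- (1 - cfg$strain_delta) / 2
    strain_regions <- block(which(role == "strain_region"),
                            cfg$strain_region_cpgs, hi_lev, lo_lev,
                            c("b6_level", "dba_level"))

    # SNPs between CpGs (placed before effect sites so epimutations can be
    # restricted to phaseable CpGs)
    snp_pairs <- list(c("A", "C"), c("A", "G"), c("A", "T"),
                      c("C", "G"), c("G", "T"))
    snps <- do.call(rbind, lapply(seq_len(nr), function(r) {
      rc <- cpgs[cpgs$region == r, ]
      gi <- sample(seq_len(nrow(rc) - 1L), min(cfg$snps_per_region,
                                               nrow(rc) - 1L))
      gap <- rc$pos[gi + 1L] - rc$pos[gi]
      off <- vapply(gap, function(g) sample(seq(2L, max(2L, g - 2L)), 1L),
                    integer(1))
      data.frame(region = r, chrom = rc$chrom[1], pos = rc$pos[gi] + off,
                 stringsAsFactors = FALSE)
    }))
    n_snp <- nrow(snps)
    is_ct <- stats::runif(n_snp) < cfg$ct_snp_fraction
    alle <- matrix("", n_snp, 2)
    for (j in seq_len(n_snp)) {
      pair <- if (is_ct[j]) c("C", "T") else
        snp_pairs[[sample(length(snp_pairs), 1L)]]
      if (stats::runif(1) < 0.5) pair <- rev(pair)
      alle[j, ] <- pair
    }
    snps$b6 <- alle[, 1]
    snps$dba <- alle[, 2]
    snps$is_ct <- is_ct

    # scattered effects in free regions, on disjoint CpGs
    pool <- which(cpgs$region %in% which(role == "free"))
    n_epi <- cfg$n_epimutations_class1 + cfg$n_epimutations_class2
    need <- cfg$n_strain_sites + cfg$n_sex_sites + n_epi
    if (need > length(pool)) {
      stopf("infeasible config: %d effect sites requested, %d CpGs available",
            need, length(pool))
    }
    # epimutation sites must be phaseable: within read range of a usable
    # (non-C/T) SNP, so the allele-resolved parent-F1 comparison sees them
    reach <- (cfg$read_width - 1L) * cfg$cpg_spacing[1]
    usable <- snps[!snps$is_ct, , drop = FALSE]
    near_snp <- vapply(pool, function(i) {
      sp <- usable$pos[usable$region == cpgs$region[i]]
      length(sp) > 0 && min(abs(sp - cpgs$pos[i])) <= reach
    }, logical(1))
    epi_pool <- pool[near_snp]
    if (n_epi > length(epi_pool)) {
      stopf("infeasible config: %d epimutation sites requested, %d phaseable CpGs available",
            n_epi, length(epi_pool))
    }
    ei <- epi_pool[sample.int(length(epi_pool), n_epi)]
    pick <- sample(setdiff(pool, ei),
                   cfg$n_strain_sites + cfg$n_sex_sites)
    take <- function(n) {
      out <- pick[seq_len(n)]; pick <<- pick[-seq_len(n)]; out
    }

    si <- take(cfg$n_strain_sites)
    b6_high <- stats::runif(length(si)) < 0.5
    strain_sites <- data.frame(
      chrom = cpgs$chrom[si], pos = cpgs$pos[si],
      b6_level = ifelse(b6_high, hi_lev, lo_lev),
      dba_level = ifelse(b6_high, lo_lev, hi_lev),
      delta = rep(cfg$strain_delta, length(si)), stringsAsFactors = FALSE
    )

    xi <- take(cfg$n_sex_sites)
    f_high <- stats::runif(length(xi)) < 0.5
    shi <- (1 + cfg$sex_delta) / 2
    slo <- (1 - cfg$sex_delta) / 2
    sex_sites <- data.frame(
      chrom = cpgs$chrom[xi], pos = cpgs$pos[xi],
      f_level = ifelse(f_high, shi, slo),
      m_level = ifelse(f_high, slo, shi),
      delta = rep(cfg$sex_delta, length(xi)), stringsAsFactors = FALSE
    )

    f1s <- sample_table()$sample_id[5:8]
    carriers <- character(n_epi)
    if (cfg$n_epimutations_class1 > 0) {
      carriers[seq_len(cfg$n_epimutations_class1)] <-
        sample(f1s, cfg$n_epimutations_class1, replace = TRUE)
    }
    if (cfg$n_epimutations_class2 > 0) {
      cross <- sample(c("BXD", "DXB"), cfg$n_epimutations_class2,
                      replace = TRUE)
      carriers[cfg$n_epimutations_class1 + seq_len(cfg$n_epimutations_class2)] <-
        paste(paste0(cross, "_F"), paste0(cross, "_M"), sep = ",")
    }
    epimutations <- data.frame(
      chrom = cpgs$chrom[ei], pos = cpgs$pos[ei],
      strain = sample(c("B6", "DBA"), n_epi, replace = TRUE),
      carriers = carriers,
      base_level = rep(cfg$epimutation_base, n_epi),
      shift_level = rep(cfg$epimutation_shift, n_epi),
      expected_class = lengths(strsplit(carriers, ",", fixed = TRUE)),
      stringsAsFactors = FALSE
    )
    # epimutation sites sit at the parental baseline for everyone but carriers
    cpgs$baseline[ei] <- cfg$epimutation_base

    snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
    rownames(snps) <- NULL

    # non-CpG cytosines on a dedicated contig, baseline-only
    n_chc <- cfg$chg_sites + cfg$chh_sites
    chc <- data.frame(
      chrom = "chrC",
      pos = 1000L + 50L * seq_len(n_chc),
      strand = "+",
      context = rep(c("CHG", "CHH"), c(cfg$chg_sites, cfg$chh_sites)),
      level = c(beta_with_mean(cfg$chg_sites, cfg$chg_mean, shape1 = 0.3),
                beta_with_mean(cfg$chh_sites, cfg$chh_mean, shape1 = 0.3)),
      stringsAsFactors = FALSE
    )

    genes <- data.frame(
      chrom = regions$chrom,
      start = pmax(1L, as.integer(regions$start) - 200L),
      end = as.integer(regions$end) + 200L,
      name = sprintf("gene%02d", regions$region),
      imprinted = regions$role == "imprinted",
      stringsAsFactors = FALSE
    )
    genes$known_imprinted <- genes$imprinted &
      regions$region %in% imprinted_regions$region[imprinted_regions$known]

    lens <- tapply(c(cpgs$pos, chc$pos, snps$pos),
                   c(cpgs$chrom, chc$chrom, snps$chrom), max)
    chrom_lengths <- stats::setNames(as.integer(lens) + 20000L, names(lens))

    structure(list(config = cfg, seed = seed, samples = sample_table(),
                   regions = regions, cpgs = cpgs, chc = chc, snps = snps,
                   strain_sites = strain_sites, sex_sites = sex_sites,
                   epimutations = epimutations,
                   imprinted_regions = imprinted_regions,
                   strain_regions = strain_regions, genes = genes,
                   chrom_lengths = chrom_lengths),
              class = "truth_model")
  })
}

#' @export
print.truth_model <- function(x, ...) {
  cat("Synthetic cross truth model\n")
  cat(sprintf("  %d regions on %d chromosomes, %d CpGs, %d SNPs\n",
              nrow(x$regions), length(unique(x$regions$chrom)),
              nrow(x$cpgs), nrow(x$snps)))
  cat(sprintf("  planted: %d strain sites, %d sex sites, %d imprinted regions, %d strain regions, %d epimutation sites\n",
              nrow(x$strain_sites), nrow(x$sex_sites),
              nrow(x$imprinted_regions), nrow(x$strain_regions),
              nrow(x$epimutations)))
  cat(sprintf("  coverage %g x, error rate %g, read width %d CpGs\n",
              x$config$coverage_mean, x$config$error_rate,
              x$config$read_width))
  invisible(x)
}

# True methylation level of one chromosome (strain, parental origin) over a
# region's CpGs, for a given sample. Effect precedence is irrelevant because
# planted site sets are disjoint.
chromosome_levels <- function(truth, region_id, strain, po, sex, sample_id) {
  rc <- truth$cpgs[truth$cpgs$region == region_id, ]
  lev <- rc$baseline
  key <- paste(rc$chrom, rc$pos)

  ir <- truth$imprinted_regions
  ir <- ir[ir$region == region_id, , drop = FALSE]
  if (nrow(ir)) {
    run <- seq(ir$idx_start[1], length.out = ir$n_cpgs[1])
    lev[run] <- if (po == "maternal") ir$maternal_level[1] else
      ir$paternal_level[1]
  }
  sr <- truth$strain_regions
  sr <- sr[sr$region == region_id, , drop = FALSE]
  if (nrow(sr)) {
    run <- seq(sr$idx_start[1], length.out = sr$n_cpgs[1])
    lev[run] <- if (strain == "B6") sr$b6_level[1] else sr$dba_level[1]
  }
  m <- match(paste(truth$strain_sites$chrom, truth$strain_sites$pos), key)
  hit <- which(!is.na(m))
  if (length(hit)) {
    lev[m[hit]] <- if (strain == "B6") truth$strain_sites$b6_level[hit] else
      truth$strain_sites$dba_level[hit]
  }
  m <- match(paste(truth$sex_sites$chrom, truth$sex_sites$pos), key)
  hit <- which(!is.na(m))
  if (length(hit)) {
    lev[m[hit]] <- if (sex == "F") truth$sex_sites$f_level[hit] else
      truth$sex_sites$m_level[hit]
  }
  ep <- truth$epimutations
  m <- match(paste(ep$chrom, ep$pos), key)
  hit <- which(!is.na(m))
  for (j in hit) {
    carried <- sample_id %in% strsplit(ep$carriers[j], ",", fixed = TRUE)[[1]]
    lev[m[j]] <- if (carried && strain == ep$strain[j]) ep$shift_level[j] else
      ep$base_level[j]
  }
  lev
}

#' Simulate one sample's site table and epireads
#'
#' Reads are drawn from the sample's two chromosomes (both of the same
#' strain for inbred parents; one maternal and one paternal haplotype for
#' F1s). Read starts tile each region so per-CpG coverage is
#' Poisson-distributed around `coverage_mean`; each covered CpG's state is
#' Bernoulli at the level implied by the chromosome's strain, parental
#' origin, the sample's sex and any planted epimutation, then flipped with
#' probability `error_rate`. Reads record the bases they observe at
#' overlapping SNPs (with the same error rate) and carry their true
#' chromosome in the hidden `true_allele`/`true_po` columns. Imprinted
#' regions express the maternal level on the maternal allele in both cross
#' directions, independent of genotype.
#'
#' @param truth A [build_truth_model()] result.
#' @param sample_id One of the eight sample ids in `truth$samples`.
#' @param seed Integer seed.
#' @return `list(sites = <site table>, epireads = <epiread table>)`.
#' @export
simulate_sample <- function(truth, sample_id, seed = 1) {
  meta <- truth$samples[match(sample_id, truth$samples$sample_id), ]
  if (is.na(meta$sample_id)) stopf("unknown sample '%s'", sample_id)
  cfg <- truth$config
  chrom_strain <- c(meta$maternal_strain, meta$paternal_strain)
  chrom_po <- c("maternal", "paternal")

  with_seed(seed, {
    all_reads <- vector("list", nrow(truth$regions))
    all_sites <- vector("list", nrow(truth$regions))
    for (r in truth$regions$region) {
      rc <- truth$cpgs[truth$cpgs$region == r, ]
      pos <- rc$pos
      n <- length(pos)
      w <- min(cfg$read_width, n)
      lev <- cbind(
        chromosome_levels(truth, r, chrom_strain[1], chrom_po[1],
                          meta$sex, sample_id),
        chromosome_levels(truth, r, chrom_strain[2], chrom_po[2],
                          meta$sex, sample_id)
      )
      S <- n + w - 1L  # read start slots incl. partial overlaps at the edges
      n_reads <- stats::rpois(1, cfg$coverage_mean * S / w)
      if (n_reads == 0) next
      starts <- sample.int(S, n_reads, replace = TRUE) - (w - 1L)  # in 2-w..n
      chromo <- sample.int(2L, n_reads, replace = TRUE)
      lo <- pmax(1L, starts)
      hi <- pmin(n, starts + w - 1L)
      len <- hi - lo + 1L
      ridx <- rep.int(seq_len(n_reads), len)
      cidx <- sequence(len, from = lo)
      lv <- lev[cbind(cidx, chromo[ridx])]
      st <- stats::rbinom(length(lv), 1L, lv)
      if (cfg$error_rate > 0) {
        flip <- stats::rbinom(length(st), 1L, cfg$error_rate) == 1L
        st[flip] <- 1L - st[flip]
      }
      # per-site counts
      meth <- rowsum(st, cidx)
      tot <- rowsum(rep(1L, length(cidx)), cidx)
      cov_idx <- as.integer(rownames(tot))
      all_sites[[r]] <- data.frame(
        chrom = rc$chrom[1], pos = pos[cov_idx], strand = "+", context = "CG",
        meth_count = as.integer(meth[, 1]), total_count = as.integer(tot[, 1]),
        stringsAsFactors = FALSE
      )
      # epireads
      states <- vapply(split(c("U", "M")[st + 1L], ridx),
                       paste, character(1), collapse = "")
      positions <- split(pos[cidx], ridx)
      reads <- data.frame(
        chrom = rc$chrom[1],
        read_id = sprintf("%s_r%02d_%05d", sample_id, r, seq_len(n_reads)),
        sample_id = sample_id, states = unname(states),
        allele_tag = "uninformative", stringsAsFactors = FALSE
      )
      reads$positions <- unname(lapply(positions, as.integer))
      reads$true_allele <- chrom_strain[chromo]
      reads$true_po <- chrom_po[chromo]

      # SNP base observations for reads whose bp span covers a SNP
      sp <- truth$snps[truth$snps$region == r, ]
      snp_pos <- rep(list(integer(0)), n_reads)
      snp_base <- rep(list(character(0)), n_reads)
      if (nrow(sp)) {
        lo_bp <- pos[lo]
        hi_bp <- pos[hi]
        for (j in seq_len(nrow(sp))) {
          covering <- which(lo_bp <= sp$pos[j] & hi_bp >= sp$pos[j])
          if (!length(covering)) next
          true_base <- ifelse(reads$true_allele[covering] == "B6",
                              sp$b6[j], sp$dba[j])
          if (cfg$error_rate > 0) {
            err <- stats::runif(length(covering)) < cfg$error_rate
            if (any(err)) {
              true_base[err] <- vapply(true_base[err], function(b) {
                sample(setdiff(c("A", "C", "G", "T"), b), 1L)
              }, character(1))
            }
          }
          for (k in seq_along(covering)) {
            i <- covering[k]
            snp_pos[[i]] <- c(snp_pos[[i]], sp$pos[j])
            snp_base[[i]] <- c(snp_base[[i]], true_base[k])
          }
        }
      }
      reads$snp_positions <- snp_pos
      reads$snp_bases <- snp_base
      all_reads[[r]] <- reads
    }

    sites <- do.call(rbind, all_sites)
    # non-CpG cytosines: direct binomial counts with the same error model
    chc <- truth$chc
    if (nrow(chc)) {
      tot <- stats::rpois(nrow(chc), cfg$coverage_mean)
      lv_eff <- chc$level * (1 - cfg$error_rate) +
        (1 - chc$level) * cfg$error_rate
      k <- stats::rbinom(nrow(chc), tot, lv_eff)
      keep <- tot > 0
      sites <- rbind(sites, data.frame(
        chrom = chc$chrom[keep], pos = chc$pos[keep], strand = chc$strand[keep],
        context = chc$context[keep], meth_count = k[keep],
        total_count = tot[keep], stringsAsFactors = FALSE
      ))
    }
    sites <- sites[order(sites$chrom, sites$pos, sites$strand), ]
    rownames(sites) <- NULL
    sites$level <- sites$meth_count / sites$total_count
    validate_sites(sites)

    reads <- do.call(rbind, all_reads[!vapply(all_reads, is.null, logical(1))])
    rownames(reads) <- NULL
    reads <- reads[, c("chrom", "read_id", "sample_id", "positions", "states",
                       "allele_tag", "snp_positions", "snp_bases",
                       "true_allele", "true_po")]
    validate_epireads(reads)
    list(sites = sites, epireads = reads)
  })
}

#' Simulate all eight samples of the reciprocal cross
#'
#' @param truth A [build_truth_model()] result.
#' @param seed Master seed; each sample uses a seed derived from it.
#' @param sample_ids Samples to simulate (default: the full eight-sample
#'   design).
#' @return `list(sites = <named list>, epireads = <named list>,
#'   samples = <metadata>)`.
#' @export
simulate_cross <- function(truth, seed = truth$seed,
                           sample_ids = truth$samples$sample_id) {
  bad <- setdiff(sample_ids, truth$samples$sample_id)
  if (length(bad)) stopf("unknown sample '%s'", bad[1])
  sims <- lapply(seq_along(sample_ids), function(i) {
    simulate_sample(truth, sample_ids[i], derive_seed(seed, 100 + i))
  })
  names(sims) <- sample_ids
  list(sites = lapply(sims, `[[`, "sites"),
       epireads = lapply(sims, `[[`, "epireads"),
       samples = truth$samples[truth$samples$sample_id %in% sample_ids, ])
}

#' Write the planted-truth tables
#'
#' One TSV per effect class (headers written even when empty) plus a BED of
#' imprinted regions — the acceptance surface recovery tests compare
#' detections against.
#'
#' @param truth A `truth_model`.
#' @param outdir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_truth_tables <- function(truth, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  paths <- c(
    strain_sites = write_hash_tsv(truth$strain_sites, p("strain_sites.tsv")),
    sex_sites = write_hash_tsv(truth$sex_sites, p("sex_sites.tsv")),
    epimutations = write_hash_tsv(truth$epimutations, p("epimutations.tsv")),
    imprinted_regions = write_hash_tsv(truth$imprinted_regions,
                                       p("imprinted_regions.tsv")),
    strain_regions = write_hash_tsv(truth$strain_regions,
                                    p("strain_regions.tsv")),
    snps = write_hash_tsv(truth$snps, p("snps.tsv"))
  )
  ib <- truth$imprinted_regions
  ib$name <- sprintf("imprinted%02d", seq_len(nrow(ib)))
  export_bed(ib, p("imprinted_regions.bed"))
  gb <- truth$genes
  export_bed(gb, p("genes.bed"))
  invisible(c(paths, imprinted_bed = p("imprinted_regions.bed"),
              genes_bed = p("genes.bed")))
}

#' Simulate allelic RNA-seq count tables
#'
#' Per-gene 2x2 allelic counts indexed by cross direction (BXD, DXB) and
#' allele genotype (B6, DBA). Imprinted genes express predominantly from one
#' parental copy, so their B6:DBA skew flips with cross direction;
#' non-imprinted genes are balanced.
#'
#' @param truth A `truth_model`.
#' @param mean_count Mean informative read count per gene.
#' @param maternal_fraction Expression fraction from the maternal copy of an
#'   imprinted gene.
#' @param seed Integer seed.
#' @return `data.frame` with `gene`, `bxd_b6`, `bxd_dba`, `dxb_b6`,
#'   `dxb_dba` and the truth column `imprinted`.
#' @export
simulate_allelic_counts <- function(truth, mean_count = 60,
                                    maternal_fraction = 0.95, seed = 1) {
  g <- truth$genes
  with_seed(seed, {
    n <- nrow(g)
    tot_bxd <- stats::rpois(n, mean_count / 2)
    tot_dxb <- stats::rpois(n, mean_count / 2)
    # maternal copy is B6 in BXD and DBA in DXB
    p_b6_bxd <- ifelse(g$imprinted, maternal_fraction, 0.5)
    p_b6_dxb <- ifelse(g$imprinted, 1 - maternal_fraction, 0.5)
    data.frame(
      gene = g$name,
      bxd_b6 = stats::rbinom(n, tot_bxd, p_b6_bxd),
      bxd_dba = NA_integer_, dxb_b6 = stats::rbinom(n, tot_dxb, p_b6_dxb),
      dxb_dba = NA_integer_, imprinted = g$imprinted,
      stringsAsFactors = FALSE
    ) -> out
    out$bxd_dba <- tot_bxd - out$bxd_b6
    out$dxb_dba <- tot_dxb - out$dxb_b6
    out[, c("gene", "bxd_b6", "bxd_dba", "dxb_b6", "dxb_dba", "imprinted")]
  })
}

#' Simulate a sex-stratified expression matrix
#'
#' Poisson counts per gene and sample; genes whose region carries a planted
#' sex-methylation site are expressed `sex_fold`-fold higher in females.
#'
#' @param truth A `truth_model`.
#' @param n_f,n_m Numbers of female and male samples.
#' @param base_mean Mean expression of a non-differential gene.
#' @param sex_fold Female/male fold change of sex-differential genes.
#' @param seed Integer seed.
#' @return `list(expr = genes x samples matrix, sex = labels,
#'   sex_de = truth flags)`.
#' @export
simulate_expression_matrix <- function(truth, n_f = 10, n_m = 6,
                                       base_mean = 100, sex_fold = 2,
                                       seed = 1) {
  g <- truth$genes
  sex_regions <- unique(truth$cpgs$region[
    paste(truth$cpgs$chrom, truth$cpgs$pos) %in%
      paste(truth$sex_sites$chrom, truth$sex_sites$pos)])
  de <- truth$regions$region %in% sex_regions
  with_seed(seed, {
    mu_f <- ifelse(de, base_mean * sqrt(sex_fold), base_mean)
    mu_m <- ifelse(de, base_mean / sqrt(sex_fold), base_mean)
    expr <- cbind(
      matrix(stats::rpois(nrow(g) * n_f, rep(mu_f, n_f)), nrow = nrow(g)),
      matrix(stats::rpois(nrow(g) * n_m, rep(mu_m, n_m)), nrow = nrow(g))
    )
    rownames(expr) <- g$name
    colnames(expr) <- c(sprintf("F%02d", seq_len(n_f)),
                        sprintf("M%02d", seq_len(n_m)))
    list(expr = expr, sex = rep(c("F", "M"), c(n_f, n_m)), sex_de = de)
  })
}

#' Tally per-position base counts observed by epireads at SNPs
#'
#' Converts the per-read SNP base observations carried by simulated epireads
#' into a per-position A/C/G/T count table, the input to SNP calling.
#'
#' @param reads Epiread table with `snp_positions`/`snp_bases` columns.
#' @return `data.frame` with `chrom`, `pos`, `strand`, `A`, `C`, `G`, `T`.
#' @export
epiread_base_counts <- function(reads) {
  if (is.null(reads$snp_positions)) {
    stopf("epireads carry no SNP base observations")
  }
  len <- lengths(reads$snp_positions)
  if (!sum(len)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), A = integer(0), C = integer(0),
                      G = integer(0), T = integer(0),
                      stringsAsFactors = FALSE))
  }
  chrom <- rep(reads$chrom, len)
  pos <- unlist(reads$snp_positions, use.names = FALSE)
  base <- unlist(reads$snp_bases, use.names = FALSE)
  key <- paste(chrom, pos)
  out <- data.frame(key = sort(unique(key)), stringsAsFactors = FALSE)
  for (b in c("A", "C", "G", "T")) {
    cnt <- rowsum(as.integer(base == b), key)
    out[[b]] <- as.integer(cnt[match(out$key, rownames(cnt)), 1])
  }
  parts <- do.call(rbind, strsplit(out$key, " ", fixed = TRUE))
  data.frame(chrom = parts[, 1], pos = as.integer(parts[, 2]), strand = "+",
             A = out$A, C = out$C, G = out$G, T = out$T,
             stringsAsFactors = FALSE)
}
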