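# SNP calling from pooled bisulfite base counts and SNP-based assignment of
# reads to alleles and parents of origin. Bisulfite conversion makes C/T
# substitutions (and G/A on minus-strand-derived counts) indistinguishable
# from unmethylated cytosines, so such allele pairs are never called.

#' Pool per-sample base counts
#'
#' Element-wise sums of A/C/G/T counts over samples at each observed
#' position; positions observed in any sample pass through.
#'
#' @param counts_list List of base-count tables (`chrom`, `pos`, `strand`,
#'   `A`, `C`, `G`, `T`), e.g. from [epiread_base_counts()].
#' @return Pooled base-count table.
#' @export
pool_base_counts <- function(counts_list) {
  if (!length(counts_list)) stopf("pool_base_counts: empty sample list")
  all <- do.call(rbind, counts_list)
  key <- paste(all$chrom, all$pos, all$strand)
  sums <- rowsum(as.matrix(all[, c("A", "C", "G", "T")]), key)
  first <- !duplicated(key)
  out <- data.frame(chrom = all$chrom[first], pos = all$pos[first],
                    strand = all$strand[first], stringsAsFactors = FALSE)
  m <- sums[match(paste(out$chrom, out$pos, out$strand), rownames(sums)), ,
            drop = FALSE]
  out <- cbind(out, as.data.frame(m))
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}

#' Call SNPs from pooled bisulfite base counts
#'
#' Emits biallelic calls at positions with total coverage of at least
#' `min_total`, minor allele frequency of at least `maf_min`, and an allele
#' pair that is not C/T on the read strand (nor G/A for minus-strand-derived
#' counts, the reverse-complement of the bisulfite confound). Counts on
#' third alleles are tolerated up to `third_frac_max` of the total.
#' Filtered positions are dropped silently; the number dropped is attached
#' as the attribute `n_filtered`.
#'
#' @param pooled Pooled base-count table ([pool_base_counts()]).
#' @param min_total Minimum total coverage (default 6).
#' @param maf_min Minimum minor allele frequency (default 0.10).
#' @param third_frac_max Maximum tolerated fraction of counts on alleles
#'   other than the top two (default 0.05).
#' @return `data.frame` of calls: `chrom`, `pos`, `strand`, `major_allele`,
#'   `minor_allele`, `maf`, `total`.
#' @export
call_snps <- function(pooled, min_total = 6, maf_min = 0.10,
                      third_frac_max = 0.05) {
  bases <- c("A", "C", "G", "T")
  m <- as.matrix(pooled[, bases])
  storage.mode(m) <- "integer"
  if (any(m < 0)) stopf("negative base counts")
  total <- rowSums(m)
  i_major <- max.col(m, ties.method = "first")
  major_count <- m[cbind(seq_len(nrow(m)), i_major)]
  m2 <- m
  m2[cbind(seq_len(nrow(m)), i_major)] <- -1L
  i_minor <- max.col(m2, ties.method = "first")
  minor_count <- m[cbind(seq_len(nrow(m)), i_minor)]
  maf <- ifelse(total > 0, minor_count / total, 0)
  third <- total - major_count - minor_count
  major <- bases[i_major]
  minor <- bases[i_minor]
  pair <- paste(pmin(major, minor), pmax(major, minor))
  confound <- ifelse(pooled$strand == "-", "A G", "C T")
  keep <- total >= min_total & minor_count > 0L & maf >= maf_min &
    third <= third_frac_max * total & pair != confound
  out <- data.frame(chrom = pooled$chrom[keep], pos = pooled$pos[keep],
                    strand = pooled$strand[keep], major_allele = major[keep],
                    minor_allele = minor[keep], maf = maf[keep],
                    total = total[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_filtered") <- sum(!keep)
  out
}

#' Parent genotypes at called SNPs from strain-pure base counts
#'
#' For each called SNP, the B6 (resp. DBA) allele is the most frequent base
#' in base counts pooled over the B6 (resp. DBA) parental samples. SNPs not
#' covered in both parents, or where both parents show the same base, are
#' dropped.
#'
#' @param snp_calls Calls from [call_snps()].
#' @param b6_counts,dba_counts Base-count tables pooled over the parental
#'   samples of each strain.
#' @return `data.frame` with `chrom`, `pos`, `b6`, `dba`.
#' @export
infer_parent_genotypes <- function(snp_calls, b6_counts, dba_counts) {
  bases <- c("A", "C", "G", "T")
  top_base <- function(counts, key) {
    m <- as.matrix(counts[, bases])
    i <- max.col(m, ties.method = "first")
    ok <- rowSums(m) > 0
    stats::setNames(ifelse(ok, bases[i], NA_character_),
                    paste(counts$chrom, counts$pos))[key]
  }
  key <- paste(snp_calls$chrom, snp_calls$pos)
  b6 <- top_base(b6_counts, key)
  dba <- top_base(dba_counts, key)
  keep <- !is.na(b6) & !is.na(dba) & b6 != dba
  data.frame(chrom = snp_calls$chrom[keep], pos = snp_calls$pos[keep],
             b6 = unname(b6[keep]), dba = unname(dba[keep]),
             stringsAsFactors = FALSE)
}

#' Assign reads to parental alleles by majority vote over SNPs
#'
#' Each read votes with the bases it observed at SNPs with known parental
#' genotypes: `B6` or `DBA` by strict majority, `ambiguous` on a tie (or
#' when the minority vote fraction exceeds `conflict_frac`), and
#' `uninformative` when the read overlaps no informative SNP. Observed bases
#' matching neither parental allele are counted as mismatches (sequencing
#' error) and do not vote; the total is attached as attribute
#' `n_mismatch`.
#'
#' @param reads Epiread table with `snp_positions`/`snp_bases` columns.
#' @param genotypes Genotype table (`chrom`, `pos`, `b6`, `dba`), e.g. from
#'   [infer_parent_genotypes()].
#' @param conflict_frac Minority-vote fraction above which a read is
#'   `ambiguous` (default 0.5: strict majority, ties ambiguous).
#' @return `reads` with `allele_tag` filled in.
#' @export
assign_read_allele <- function(reads, genotypes, conflict_frac = 0.5) {
  if (is.null(reads$snp_positions)) {
    stopf("epireads carry no SNP base observations")
  }
  gkey <- paste(genotypes$chrom, genotypes$pos)
  n_mismatch <- 0L
  tag <- vapply(seq_len(nrow(reads)), function(i) {
    sp <- reads$snp_positions[[i]]
    if (!length(sp)) return("uninformative")
    j <- match(paste(reads$chrom[i], sp), gkey)
    ok <- !is.na(j)
    if (!any(ok)) return("uninformative")
    obs <- reads$snp_bases[[i]][ok]
    b6 <- genotypes$b6[j[ok]]
    dba <- genotypes$dba[j[ok]]
    v_b6 <- sum(obs == b6)
    v_dba <- sum(obs == dba)
    n_mismatch <<- n_mismatch + sum(obs != b6 & obs != dba)
    votes <- v_b6 + v_dba
    if (votes == 0L) return("uninformative")
    if (v_b6 == v_dba || min(v_b6, v_dba) / votes > conflict_frac) {
      return("ambiguous")
    }
    if (v_b6 > v_dba) "B6" else "DBA"
  }, character(1))
  reads$allele_tag <- tag
  attr(reads, "n_mismatch") <- n_mismatch
  reads
}

#' Map allele genotype to parent of origin for an F1 cross
#'
#' In BXD F1 mice (B6 mother, DBA father) the B6 chromosome is maternal; in
#' DXB mice (DBA mother, B6 father) it is paternal. The map is a bijection
#' per cross, so composing it over both crosses separates genotype effects
#' from parental-origin effects.
#'
#' @param allele `"B6"` or `"DBA"` (vectorised).
#' @param cross `"BXD"` or `"DXB"` (vectorised, recycled).
#' @return `"maternal"` or `"paternal"` per element.
#' @export
#' @examples
#' parent_of_origin("B6", "BXD")  # "maternal"
#' parent_of_origin("B6", "DXB")  # "paternal"
parent_of_origin <- function(allele, cross) {
  k <- max(length(allele), length(cross))
  allele <- rep_len(as.character(allele), k)
  cross <- rep_len(as.character(cross), k)
  if (any(!allele %in% c("B6", "DBA"))) {
    stopf("parent of origin is defined only for alleles B6 and DBA")
  }
  if (any(!cross %in% c("BXD", "DXB"))) {
    stopf("parent of origin is defined only for F1 crosses BXD and DXB")
  }
  maternal_strain <- ifelse(cross == "BXD", "B6", "DBA")
  ifelse(allele == maternal_strain, "maternal", "paternal")
}

#' Write / read SNP call tables
#'
#' @param snps SNP call table.
#' @param path File path.
#' @export
write_snps <- function(snps, path) {
  write_hash_tsv(as.data.frame(snps), path)
}

#' @rdname write_snps
#' @export
load_snps <- function(path) {
  df <- read_hash_tsv(path)
  df$chrom <- as.character(df$chrom)
  df
}

#' Split an F1 sample's epireads into per-allele site tables
#'
#' @param reads Epiread table with filled `allele_tag`.
#' @return `list(B6 = <site table>, DBA = <site table>)` aggregated from
#'   reads carrying each unambiguous tag.
#' @export
allele_site_tables <- function(reads) {
  lapply(stats::setNames(nm = c("B6", "DBA")), function(a) {
    epiread_site_table(reads[reads$allele_tag == a, , drop = FALSE])
  })
}
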