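# Expression-level validation screens: Fisher's exact test for imprinting
# on allelic RNA-seq counts (cross direction x allele genotype), and
# sex-difference expression screens with fold and Storey-FDR filters.

#' Fisher's exact test for imprinting on allelic counts
#'
#' Two-sided Fisher's exact test on the 2x2 table of read counts indexed by
#' cross direction (BXD, DXB) and allele genotype (B6, DBA). Under
#' imprinting the expressed allele follows the parent of origin, so the
#' B6:DBA ratio flips between cross directions (`origin_flip`); a skew in
#' the same direction in both crosses is instead the signature of a
#' genotype (cis-regulatory) effect. Tables with fewer than `min_total`
#' reads are not tested.
#'
#' @param bxd_b6,bxd_dba,dxb_b6,dxb_dba Non-negative allelic read counts;
#'   alternatively pass a 2x2 matrix (rows BXD, DXB; columns B6, DBA) as the
#'   first argument.
#' @param min_total Minimum total count to test (default 10).
#' @return List with `p_value`, `odds_ratio`, `tested`, `origin_flip`.
#' @export
#' @examples
#' fisher_imprinting_test(19, 1, 2, 18)  # maternal-biased in both crosses
fisher_imprinting_test <- function(bxd_b6, bxd_dba = NULL, dxb_b6 = NULL,
                                   dxb_dba = NULL, min_total = 10) {
  if (is.matrix(bxd_b6)) {
    m <- bxd_b6
  } else {
    m <- matrix(c(bxd_b6, dxb_b6, bxd_dba, dxb_dba), nrow = 2,
                dimnames = list(c("BXD", "DXB"), c("B6", "DBA")))
  }
  if (any(m < 0)) stopf("negative allelic counts")
  if (sum(m) < min_total) {
    return(list(p_value = NA_real_, odds_ratio = NA_real_, tested = FALSE,
                origin_flip = NA))
  }
  ft <- stats::fisher.test(m)
  r_bxd <- (m["BXD", "B6"] + 0.5) / (m["BXD", "DBA"] + 0.5)
  r_dxb <- (m["DXB", "B6"] + 0.5) / (m["DXB", "DBA"] + 0.5)
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate),
       tested = TRUE, origin_flip = (r_bxd > 1) != (r_dxb > 1))
}

#' Screen allelic count tables for imprinted expression
#'
#' Applies [fisher_imprinting_test()] per gene. Genes are reported at
#' `p < p_threshold`; a Storey-FDR variant additionally requires
#' `q < fdr_max` and a maternal/paternal fold difference above `fold_min`
#' (maternal counts are B6 in BXD plus DBA in DXB).
#'
#' @param tables `data.frame` with columns `gene`, `bxd_b6`, `bxd_dba`,
#'   `dxb_b6`, `dxb_dba`.
#' @param p_threshold Fisher p cutoff (default 0.05).
#' @param fdr_max,fold_min Thresholds of the FDR variant.
#' @param min_total Minimum total count to test.
#' @return `data.frame` per gene with `p`, `q`, `maternal`, `paternal`,
#'   `fold`, `origin_flip`, `tested`, `significant_p`, `significant_fdr`.
#' @export
imprinting_expression_screen <- function(tables, p_threshold = 0.05,
                                         fdr_max = 0.05, fold_min = 1.2,
                                         min_total = 10) {
  if (!nrow(tables)) stopf("empty allelic count input")
  res <- lapply(seq_len(nrow(tables)), function(i) {
    fisher_imprinting_test(tables$bxd_b6[i], tables$bxd_dba[i],
                           tables$dxb_b6[i], tables$dxb_dba[i],
                           min_total = min_total)
  })
  out <- data.frame(
    gene = tables$gene,
    p = vapply(res, `[[`, numeric(1), "p_value"),
    tested = vapply(res, `[[`, logical(1), "tested"),
    origin_flip = vapply(res, function(r) isTRUE(r$origin_flip), logical(1)),
    maternal = tables$bxd_b6 + tables$dxb_dba,
    paternal = tables$bxd_dba + tables$dxb_b6,
    stringsAsFactors = FALSE
  )
  out$fold <- pmax(out$maternal, out$paternal) /
    pmax(pmin(out$maternal, out$paternal), 0.5)
  out$q <- NA_real_
  if (any(out$tested)) {
    out$q[out$tested] <- storey_qvalue(out$p[out$tested])$q_values
  }
  out$significant_p <- out$tested & out$p < p_threshold
  out$significant_fdr <- out$tested & !is.na(out$q) & out$q < fdr_max &
    out$fold > fold_min
  out
}

#' Sex-difference expression screen
#'
#' Per-gene pooled-variance t-test between female and male samples, Storey
#' q-values, and linear-scale fold change (larger group mean over smaller).
#' A gene is significant when `q < fdr_max` and `fold > fold_min`. Constant
#' genes get p = 1.
#'
#' @param expr Genes x samples expression matrix (non-negative).
#' @param sex_labels `"F"`/`"M"` per column.
#' @param fold_min Minimum fold difference (default 1.2).
#' @param fdr_max Storey-FDR cutoff (default 0.05).
#' @return `data.frame` per gene with means, `fold`, `p`, `q`,
#'   `significant`.
#' @export
sex_de_screen <- function(expr, sex_labels, fold_min = 1.2, fdr_max = 0.05) {
  if (ncol(expr) != length(sex_labels)) {
    stopf("one sex label per expression column required")
  }
  if (any(expr < 0, na.rm = TRUE)) stopf("negative expression values")
  ia <- which(sex_labels == "F")
  ib <- which(sex_labels == "M")
  if (length(ia) < 2 || length(ib) < 2) {
    stopf("at least 2 samples per sex required")
  }
  r <- row_ttest(expr, ia, ib)
  hi <- pmax(r$mean_a, r$mean_b)
  lo <- pmin(r$mean_a, r$mean_b)
  fold <- ifelse(lo > 0, hi / lo, ifelse(hi > 0, Inf, 1))
  p <- r$p
  p[r$degenerate & abs(r$mean_a - r$mean_b) < .Machine$double.eps^0.5] <- 1
  q <- storey_qvalue(pmin(pmax(p, 0), 1))$q_values
  data.frame(
    gene = rownames(expr) %||% as.character(seq_len(nrow(expr))),
    mean_f = r$mean_a, mean_m = r$mean_b, fold = fold, p = p, q = q,
    significant = q < fdr_max & fold > fold_min,
    stringsAsFactors = FALSE
  )
}
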