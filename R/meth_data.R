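# Core data model and I/O: per-cytosine methylation counts, read-level
# epireads, sample metadata, and interval export. Coordinates are 1-based
# inclusive throughout; BED output is the only 0-based half-open boundary.

#' Construct a per-cytosine methylation count table
#'
#' The unit of all site-level tests: one row per cytosine per strand, with
#' methylated and total read counts. Plus- and minus-strand cytosines are
#' distinct sites and are never pooled.
#'
#' @param chrom Chromosome names.
#' @param pos 1-based positions of the cytosine on its strand.
#' @param strand `"+"` or `"-"`.
#' @param context Sequence context, one of `"CG"`, `"CHG"`, `"CHH"`.
#' @param meth_count Methylated read counts (0 <= k <= n).
#' @param total_count Total read counts (n >= 1).
#' @return A `data.frame` with the six columns above plus `level = k/n`.
#' @export
#' @examples
#' cytosine_sites("chr1", c(100, 150), "+", "CG", c(3, 10), c(10, 10))
cytosine_sites <- function(chrom, pos, strand, context, meth_count, total_count) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   strand = as.character(strand), context = as.character(context),
                   meth_count = as.integer(meth_count),
                   total_count = as.integer(total_count),
                   stringsAsFactors = FALSE)
  validate_sites(df)
  df$level <- df$meth_count / df$total_count
  df
}

# Validate site-table invariants; `lines` maps rows to file lines for
# parse-error messages.
validate_sites <- function(df, lines = NULL, file = NULL) {
  where <- function(i) {
    if (is.null(lines)) sprintf("record %d", i)
    else sprintf("%s line %d", file %||% "input", lines[i])
  }
  bad <- which(is.na(df$pos) | df$pos < 1L)
  if (length(bad)) stopf("invalid position at %s", where(bad[1]))
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad)) stopf("invalid strand at %s", where(bad[1]))
  bad <- which(!df$context %in% c("CG", "CHG", "CHH"))
  if (length(bad)) stopf("invalid context at %s", where(bad[1]))
  bad <- which(is.na(df$total_count) | df$total_count < 1L)
  if (length(bad)) stopf("non-positive total_count at %s", where(bad[1]))
  bad <- which(is.na(df$meth_count) | df$meth_count < 0L |
                 df$meth_count > df$total_count)
  if (length(bad)) {
    stopf("meth_count outside [0, total_count] at %s", where(bad[1]))
  }
  bad <- which(duplicated(site_key(df)))
  if (length(bad)) stopf("duplicate (chrom, pos, strand) at %s", where(bad[1]))
  invisible(df)
}

#' Classify the sequence context of a cytosine
#'
#' Returns `"CG"` when the next base 5'->3' on the cytosine's strand is G,
#' `"CHG"` when the base two positions downstream is G but the next is not,
#' and `"CHH"` otherwise (H = any base other than G). Bases beyond the
#' sequence ends are treated as non-G.
#'
#' @param ref Reference sequence as a single character string (see
#'   [read_reference_fasta()] to load one from FASTA).
#' @param pos 1-based positions; on the minus strand a position refers to the
#'   plus-strand coordinate of the base that is a C on the minus strand.
#' @param strand `"+"` or `"-"`, recycled against `pos`.
#' @return Character vector of contexts.
#' @export
#' @examples
#' classify_context("ACGT", 2, "+")   # "CG"
#' classify_context("ACAGT", 2, "+")  # "CHG"
#' classify_context("CCGG", 3, "-")   # "CG" (reverse-complement symmetry)
classify_context <- function(ref, pos, strand = "+") {
  if (length(ref) != 1L || !is.character(ref)) {
    stopf("ref must be a single character string")
  }
  ref <- toupper(ref)
  n <- nchar(ref)
  base_at <- function(i) {
    out <- rep("N", length(i))
    ok <- !is.na(i) & i >= 1L & i <= n
    if (any(ok)) out[ok] <- substring(ref, i[ok], i[ok])
    out
  }
  k <- max(length(pos), length(strand))
  pos <- rep_len(as.integer(pos), k)
  strand <- rep_len(as.character(strand), k)
  if (any(!strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  out <- character(k)

  plus <- strand == "+"
  if (any(plus)) {
    b <- base_at(pos[plus])
    if (any(b != "C")) {
      i <- pos[plus][which(b != "C")[1]]
      stopf("position %d on strand + is not a cytosine", i)
    }
    nxt <- base_at(pos[plus] + 1L)
    nn <- base_at(pos[plus] + 2L)
    out[plus] <- ifelse(nxt == "G", "CG", ifelse(nn == "G", "CHG", "CHH"))
  }
  minus <- !plus
  if (any(minus)) {
    # a C on the minus strand is a G on the plus strand; its 5'->3' neighbour
    # on the minus strand sits at plus-strand position pos - 1
    b <- base_at(pos[minus])
    if (any(b != "G")) {
      i <- pos[minus][which(b != "G")[1]]
      stopf("position %d on strand - is not a cytosine", i)
    }
    nxt_is_g <- base_at(pos[minus] - 1L) == "C"
    nn_is_g <- base_at(pos[minus] - 2L) == "C"
    out[minus] <- ifelse(nxt_is_g, "CG", ifelse(nn_is_g, "CHG", "CHH"))
  }
  out
}

#' Contexts of every cytosine in a reference sequence
#'
#' Enumerates all plus-strand Cs and minus-strand Cs (plus-strand Gs) and
#' classifies each; every reference cytosine receives exactly one context.
#'
#' @inheritParams classify_context
#' @return `data.frame` with columns `pos`, `strand`, `context`.
#' @export
all_cytosine_contexts <- function(ref) {
  chars <- strsplit(toupper(ref), "")[[1]]
  plus <- which(chars == "C")
  minus <- which(chars == "G")
  data.frame(
    pos = c(plus, minus),
    strand = rep(c("+", "-"), c(length(plus), length(minus))),
    context = c(
      if (length(plus)) classify_context(ref, plus, "+") else character(0),
      if (length(minus)) classify_context(ref, minus, "-") else character(0)
    ),
    stringsAsFactors = FALSE
  )
}

#' Read a reference sequence from a FASTA file
#'
#' @param path FASTA file; the first record is returned as a character string
#'   unless `name` selects another.
#' @param name Optional record name.
#' @return Single character string.
#' @export
read_reference_fasta <- function(path, name = NULL) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stopf("read_reference_fasta requires the Biostrings package")
  }
  seqs <- Biostrings::readDNAStringSet(path)
  if (!length(seqs)) stopf("%s: no FASTA records", path)
  if (!is.null(name)) {
    i <- match(name, sub("\\s.*$", "", names(seqs)))
    if (is.na(i)) stopf("%s: no record named '%s'", path, name)
  } else {
    i <- 1L
  }
  as.character(seqs[[i]])
}

#' Write / read a per-site methylation count table
#'
#' Tab-delimited with a `#`-prefixed header:
#' `chrom pos strand context meth_count total_count`. Positions are 1-based.
#' `load_site_table()` validates every record and reports the offending file
#' line on failure; `write_site_table()` followed by `load_site_table()` is
#' the identity.
#'
#' @param sites A site table as returned by [cytosine_sites()].
#' @param path File path.
#' @return `write_site_table()` returns `path` invisibly; `load_site_table()`
#'   returns a site table.
#' @export
write_site_table <- function(sites, path) {
  cols <- c("chrom", "pos", "strand", "context", "meth_count", "total_count")
  write_hash_tsv(sites[, cols], path)
}

#' @rdname write_site_table
#' @export
load_site_table <- function(path) {
  lines <- readLines(path)
  keep <- which(!startsWith(lines, "#") & nzchar(lines))
  if (!length(keep)) {
    return(cytosine_sites(character(0), integer(0), character(0),
                          character(0), integer(0), integer(0)))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6L)) {
    stopf("malformed line: expected 6 fields at %s line %d",
          path, keep[which(nf != 6L)[1]])
  }
  m <- matrix(unlist(fields), ncol = 6L, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  meth <- suppressWarnings(as.integer(m[, 5]))
  total <- suppressWarnings(as.integer(m[, 6]))
  bad <- which(is.na(pos) | is.na(meth) | is.na(total))
  if (length(bad)) stopf("non-numeric field at %s line %d", path, keep[bad[1]])
  df <- data.frame(chrom = m[, 1], pos = pos, strand = m[, 3], context = m[, 4],
                   meth_count = meth, total_count = total,
                   stringsAsFactors = FALSE)
  validate_sites(df, lines = keep, file = path)
  df$level <- df$meth_count / df$total_count
  df
}

#' Construct an epiread table
#'
#' One row per sequencing read: the ordered CpG positions the read covers and
#' its per-CpG methylation states over the alphabet `M` (methylated), `U`
#' (unmethylated), `N` (missing). The `allele_tag` records SNP-based read
#' assignment (`B6`, `DBA`, `ambiguous`, `uninformative`). Reads simulated by
#' [simulate_sample()] additionally carry the hidden truth columns
#' `true_allele`/`true_po` and per-read SNP base observations
#' (`snp_positions`, `snp_bases`).
#'
#' @param chrom,read_id,sample_id Character vectors.
#' @param positions List of strictly increasing integer vectors of 1-based
#'   CpG positions.
#' @param states Character vector of state strings over `{M, U, N}`, one
#'   character per covered CpG.
#' @param allele_tag Allele assignment, default `"uninformative"`.
#' @return `data.frame` (with list columns) of epireads.
#' @export
epireads <- function(chrom, read_id, sample_id, positions, states,
                     allele_tag = "uninformative") {
  if (!is.list(positions)) positions <- list(positions)
  df <- data.frame(chrom = as.character(chrom), read_id = as.character(read_id),
                   sample_id = as.character(sample_id),
                   states = as.character(states),
                   allele_tag = rep_len(as.character(allele_tag),
                                        length(chrom)),
                   stringsAsFactors = FALSE)
  df$positions <- lapply(positions, as.integer)
  df <- df[, c("chrom", "read_id", "sample_id", "positions", "states",
               "allele_tag")]
  validate_epireads(df)
  df
}

validate_epireads <- function(df, lines = NULL, file = NULL) {
  where <- function(i) {
    if (is.null(lines)) sprintf("read %d", i)
    else sprintf("%s line %d", file %||% "input", lines[i])
  }
  bad <- which(vapply(df$positions, function(p) {
    length(p) > 1L && any(diff(p) <= 0L)
  }, logical(1)))
  if (length(bad)) stopf("positions not strictly increasing at %s", where(bad[1]))
  bad <- which(nchar(df$states) != lengths(df$positions))
  if (length(bad)) {
    stopf("state string length differs from position count at %s", where(bad[1]))
  }
  bad <- which(grepl("[^MUN]", df$states))
  if (length(bad)) {
    stopf("state character outside {M,U,N} at %s", where(bad[1]))
  }
  bad <- which(!df$allele_tag %in% c("B6", "DBA", "ambiguous", "uninformative"))
  if (length(bad)) stopf("invalid allele_tag at %s", where(bad[1]))
  invisible(df)
}

#' Write / read epireads
#'
#' Tab-delimited with a `#`-prefixed header. Core columns are
#' `chrom read_id sample_id positions states allele_tag` with positions
#' comma-joined; the optional columns `snp_positions`, `snp_bases`,
#' `true_allele` and `true_po` are written when present and restored on load,
#' so write-then-load is the identity.
#'
#' @param reads Epiread table ([epireads()]).
#' @param path File path.
#' @export
write_epireads <- function(reads, path) {
  out <- data.frame(chrom = reads$chrom, read_id = reads$read_id,
                    sample_id = reads$sample_id,
                    positions = comma_join(reads$positions),
                    states = reads$states, allele_tag = reads$allele_tag,
                    stringsAsFactors = FALSE)
  if (!is.null(reads$snp_positions)) {
    out$snp_positions <- comma_join(reads$snp_positions)
    out$snp_bases <- comma_join(reads$snp_bases)
  }
  if (!is.null(reads$true_allele)) out$true_allele <- reads$true_allele
  if (!is.null(reads$true_po)) out$true_po <- reads$true_po
  write_hash_tsv(out, path)
}

#' @rdname write_epireads
#' @export
load_epireads <- function(path) {
  df <- read_hash_tsv(path, colClasses = "character")
  need <- c("chrom", "read_id", "sample_id", "positions", "states",
            "allele_tag")
  if (!all(need %in% names(df))) {
    stopf("%s: missing epiread columns %s", path,
          paste(setdiff(need, names(df)), collapse = ", "))
  }
  out <- data.frame(chrom = df$chrom, read_id = df$read_id,
                    sample_id = df$sample_id, states = df$states,
                    allele_tag = df$allele_tag, stringsAsFactors = FALSE)
  out$positions <- comma_split_int(df$positions)
  out <- out[, c("chrom", "read_id", "sample_id", "positions", "states",
                 "allele_tag")]
  if ("snp_positions" %in% names(df)) {
    out$snp_positions <- comma_split_int(df$snp_positions)
    out$snp_bases <- comma_split_chr(df$snp_bases)
  }
  if ("true_allele" %in% names(df)) out$true_allele <- df$true_allele
  if ("true_po" %in% names(df)) out$true_po <- df$true_po
  validate_epireads(out, lines = seq_len(nrow(out)) + 1L, file = path)
  out
}

#' Export sites or intervals as BED6
#'
#' Internal 1-based inclusive coordinates are emitted as 0-based half-open
#' BED: a site at position p becomes `[p-1, p)`; an interval `[start, end]`
#' becomes `[start-1, end)`.
#'
#' @param x A site table (column `pos`) or an interval table (columns
#'   `start`, `end`, optional `name`).
#' @param path Output path.
#' @export
export_bed <- function(x, path) {
  if (!is.null(x$pos)) {
    bed <- data.frame(chrom = x$chrom, start = x$pos - 1L, end = x$pos,
                      name = x$context %||% rep(".", nrow(x)),
                      score = rep(0L, nrow(x)),
                      strand = x$strand %||% rep(".", nrow(x)))
  } else {
    if (is.null(x$start) || is.null(x$end)) {
      stopf("export_bed needs either a pos column or start/end columns")
    }
    if (nrow(x) && any(x$start > x$end)) stopf("interval with start > end")
    bed <- data.frame(chrom = x$chrom, start = x$start - 1L, end = x$end,
                      name = x$name %||% rep(".", nrow(x)),
                      score = rep(0L, nrow(x)),
                      strand = x$strand %||% rep(".", nrow(x)))
  }
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file back to 1-based inclusive intervals
#'
#' @param path BED file (>= 3 columns).
#' @return `data.frame` with `chrom`, `start`, `end` (1-based inclusive) and
#'   `name` when present.
#' @export
read_bed <- function(path) {
  if (!length(readLines(path, n = 1L))) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      stringsAsFactors = FALSE))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]) + 1L,
                    end = as.integer(df[[3]]),
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 4L) out$name <- as.character(df[[4]])
  out
}

#' Per-context and overall methylation summary
#'
#' Mean of per-site methylation levels by context, plus the overall mean and
#' site counts. Contexts with no sites are omitted.
#'
#' @param sites Site table.
#' @return `data.frame` with columns `context` (including an `"overall"`
#'   row), `n_sites`, `mean_level`.
#' @export
global_summary <- function(sites) {
  if (is.null(sites) || !nrow(sites)) stopf("global_summary: empty site table")
  lev <- sites$meth_count / sites$total_count
  ctx <- intersect(c("CG", "CHG", "CHH"), unique(sites$context))
  out <- data.frame(
    context = c(ctx, "overall"),
    n_sites = c(vapply(ctx, function(cc) sum(sites$context == cc), integer(1)),
                nrow(sites)),
    mean_level = c(vapply(ctx, function(cc) mean(lev[sites$context == cc]),
                          numeric(1)),
                   mean(lev)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Aggregate epireads into a per-site methylation count table
#'
#' Tallies M/U states per covered CpG; `N` states are ignored. Used to build
#' allele-resolved site tables from reads with a given allele tag.
#'
#' @param reads Epiread table.
#' @param context Context to record for the aggregated sites (epireads cover
#'   CpGs, so the default is `"CG"`).
#' @param strand Strand recorded for aggregated sites.
#' @return Site table.
#' @export
epiread_site_table <- function(reads, context = "CG", strand = "+") {
  if (!nrow(reads)) {
    return(cytosine_sites(character(0), integer(0), character(0),
                          character(0), integer(0), integer(0)))
  }
  len <- lengths(reads$positions)
  chrom <- rep(reads$chrom, len)
  pos <- unlist(reads$positions, use.names = FALSE)
  st <- unlist(strsplit(reads$states, "", fixed = TRUE), use.names = FALSE)
  obs <- st != "N"
  key <- paste(chrom[obs], pos[obs])
  meth <- rowsum(as.integer(st[obs] == "M"), key)
  tot <- rowsum(rep(1L, sum(obs)), key)
  parts <- do.call(rbind, strsplit(rownames(meth), " ", fixed = TRUE))
  out <- cytosine_sites(parts[, 1], as.integer(parts[, 2]), strand, context,
                        as.integer(meth[, 1]), as.integer(tot[, 1]))
  out[order(out$chrom, out$pos), , drop = FALSE]
}
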