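# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Evaluate `code` under a temporary RNG state seeded at `seed`, restoring the
# caller's RNG stream afterwards. Keeps simulation stages independent of each
# other and of user code.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a stage- or sample-specific seed from a master seed; stays inside
# the 32-bit integer range R requires.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 2147483629 + 1000003 * (offset %% 2143)) %% 2147483629L)
}

site_key <- function(df) paste(df$chrom, df$pos, df$strand, sep = ":")

# TSV with a single '#'-prefixed header line, the package's interchange style.
write_hash_tsv <- function(df, path) {
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df)) {
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

read_hash_tsv <- function(path, colClasses = NA) {
  first <- readLines(path, n = 1L)
  if (!length(first) || !startsWith(first, "#")) {
    stopf("%s: missing '#'-prefixed header line", path)
  }
  cols <- strsplit(sub("^#", "", first), "\t", fixed = TRUE)[[1]]
  df <- utils::read.table(path, sep = "\t", skip = 1L, header = FALSE,
                          col.names = cols, colClasses = colClasses,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "")
  if (!nrow(df)) df <- df[0, , drop = FALSE]
  df
}

comma_join <- function(x) vapply(x, function(v) paste(v, collapse = ","), character(1))

comma_split_int <- function(x) {
  lapply(strsplit(as.character(x), ",", fixed = TRUE),
         function(v) as.integer(v[nzchar(v)]))
}

comma_split_chr <- function(x) {
  lapply(strsplit(as.character(x), ",", fixed = TRUE), function(v) v[nzchar(v)])
}
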