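# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Deterministic 31-bit string hash used to derive independent per-region RNG
# substreams; order of processing must not matter.
string_seed <- function(x, base_seed = 0L) {
  h <- as.double(base_seed %% 2147483647)
  for (code in utf8ToInt(as.character(x))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
}

# Strand-aware GRanges from a site/interval data.frame with columns
# ref, strand, start, end (0-based half-open).
intervals_to_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$ref,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand
  )
}

# Write a data.frame as TSV with stable formatting (no quotes, no rownames).
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
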