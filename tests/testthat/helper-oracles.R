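# Independent reference implementations used as oracles, plus small shared
# fixtures.  These deliberately avoid the package's own code paths.

# ---- recursive summit splitting, brute force over index sets -------------
split_sites_bruteforce <- function(v, summit_min = 100, primary = 0.30,
                                   secondary = 0.10) {
  res <- list()
  walk <- function(idx, frac) {
    if (length(idx) == 0L) return(invisible(NULL))
    vals <- v[idx]
    S <- max(vals)
    if (S < summit_min) return(invisible(NULL))
    s <- idx[min(which(vals == S))]
    thr <- frac * S
    qual <- idx[v[idx] >= thr]
    runs <- split(qual, cumsum(c(1L, diff(qual) != 1L)))
    run <- runs[[which(vapply(runs, function(r) s %in% r, logical(1)))]]
    res[[length(res) + 1L]] <<- c(start = min(run) - 1L, end = max(run),
                                  summit = s - 1L, height = S,
                                  area = sum(v[run]))
    walk(idx[idx < min(run) - 1L], secondary)
    walk(idx[idx > max(run) + 1L], secondary)
    invisible(NULL)
  }
  walk(seq_along(v), primary)
  if (length(res) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      summit = integer(), height = numeric(),
                      area = numeric()))
  }
  out <- as.data.frame(do.call(rbind, res))
  out[order(out$start), , drop = FALSE]
}

# ---- exhaustive Boltzmann enumeration over secondary structures ----------
ORACLE_RT <- 0.0019872 * 310.15

oracle_pair_energy <- function(a, b) {
  switch(paste0(a, b), AU = -2, UA = -2, CG = -3, GC = -3, GU = -1,
         UG = -1, NA_real_)
}

oracle_enum_structures <- function(s, minloop = 3L) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i >= j) return(list(list()))
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    out <- rec(i + 1L, j)
    if (i + minloop + 1L <= j) {
      for (k in (i + minloop + 1L):j) {
        if (!is.na(oracle_pair_energy(s[i], s[k]))) {
          for (a in rec(i + 1L, k - 1L)) {
            for (b in rec(k + 1L, j)) {
              out[[length(out) + 1L]] <- c(list(c(i, k)), a, b)
            }
          }
        }
      }
    }
    memo[[key]] <- out
    out
  }
  rec(1L, length(s))
}

oracle_struct_weight <- function(s, st) {
  if (length(st) == 0L) return(1)
  prod(vapply(st, function(p)
    exp(-oracle_pair_energy(s[p[1]], s[p[2]]) / ORACLE_RT), numeric(1)))
}

# unpaired-stretch probabilities for stretch length u, every start
oracle_unpaired_probs <- function(s, u) {
  sts <- oracle_enum_structures(s)
  ws <- vapply(sts, function(st) oracle_struct_weight(s, st), numeric(1))
  Z <- sum(ws)
  n <- length(s)
  vapply(1:(n - u + 1L), function(a) {
    b <- a + u - 1L
    free <- vapply(sts, function(st)
      !any(vapply(st, function(p) any(p >= a & p <= b), logical(1))),
      logical(1))
    sum(ws[free]) / Z
  }, numeric(1))
}

# ---- misc ---------------------------------------------------------------
pearson_bruteforce <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# small synthetic cohort shared by several test files (built once)
.fixture_cache <- new.env(parent = emptyenv())
fixture_pipeline <- function() {
  if (is.null(.fixture_cache$pl)) {
    cfg <- sim_config(seed = 7L, n_genes = 30L, n_sites = 15L,
                      n_replicates = 2L)
    .fixture_cache$pl <- run_pipeline(cfg)
    .fixture_cache$cfg <- cfg
  }
  list(pl = .fixture_cache$pl, cfg = .fixture_cache$cfg)
}

# Two-isoform toy gene used by annotation/scoring unit tests:
#   t1 exons [0,400) and [600,1000): intron [400,600)
#      utr5 [0,100) cds [100,400)+[600,800) utr3 [800,1000)
#   t2 exons [0,400) and [950,1000): intron [400,950)
#      utr5 [0,100) cds [100,400) utr3 [950,1000)
# So [600,800) is exonic in t1 and intronic in t2, and the t1 3'UTR
# overlaps the t2 intron (heterogeneous annotation).
fixture_toy_annotation <- function() {
  genes <- data.frame(gene_id = "gA", ref = "chr1", strand = "+",
                      start = 0L, end = 1000L, stringsAsFactors = FALSE)
  transcripts <- data.frame(
    tx_id = c("gA.t1", "gA.t2"), gene_id = "gA", ref = "chr1",
    strand = "+", start = 0L, end = 1000L, stringsAsFactors = FALSE)
  exons <- data.frame(
    tx_id = c("gA.t1", "gA.t1", "gA.t2", "gA.t2"), gene_id = "gA",
    ref = "chr1", strand = "+",
    start = c(0L, 600L, 0L, 950L), end = c(400L, 1000L, 400L, 1000L),
    stringsAsFactors = FALSE)
  features <- data.frame(
    tx_id = c("gA.t1", "gA.t1", "gA.t1", "gA.t1", "gA.t2", "gA.t2",
              "gA.t2"),
    gene_id = "gA", ref = "chr1", strand = "+",
    type = c("utr5", "cds", "cds", "utr3", "utr5", "cds", "utr3"),
    start = c(0L, 100L, 600L, 800L, 0L, 100L, 950L),
    end = c(100L, 400L, 800L, 1000L, 100L, 400L, 1000L),
    stringsAsFactors = FALSE)
  rbpatlas:::new_genome_annotation(genes, transcripts, exons, features)
}
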