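iv <- function(start, end, gene = "g1", strand = "+") {
  data.frame(ref = "chr1", strand = strand, start = start, end = end,
             gene_id = gene, stringsAsFactors = FALSE)
}

test_that("overlap statistics match hand-counted intervals", {
  # identical intervals: full coverage
  r <- overlap_sites(iv(10L, 20L), iv(10L, 20L))
  expect_equal(r$coverage_a, 100)
  expect_equal(r$n_pairs, 1L)

  # A = [10,20), B = {[5,13), [18,26)}: covered {10,11,12,18,19} = 50%
  b <- rbind(iv(5L, 13L), iv(18L, 26L))
  r2 <- overlap_sites(iv(10L, 20L), b)
  expect_equal(r2$coverage_a, 50)
  expect_equal(r2$a_overlapping, 1L)
  expect_equal(r2$n_pairs, 2L)

  # disjoint sets, and strand-awareness
  r3 <- overlap_sites(iv(10L, 20L), iv(100L, 120L))
  expect_equal(r3$a_overlapping, 0L)
  expect_equal(r3$coverage_a, 0)
  r4 <- overlap_sites(iv(10L, 20L), iv(10L, 20L, strand = "-"))
  expect_equal(r4$n_pairs, 0L)

  # pair count is symmetric
  set.seed(81)
  sa <- iv(sort(sample(0:500, 20)), NA); sa$end <- sa$start + 10L
  sb <- iv(sort(sample(0:500, 20)), NA); sb$end <- sb$start + 15L
  expect_equal(overlap_sites(sa, sb)$n_pairs,
               overlap_sites(sb, sa)$n_pairs)

  # gene-level partition
  a <- rbind(iv(10L, 20L, "g1"), iv(50L, 60L, "g2"))
  b2 <- rbind(iv(15L, 25L, "g1"), iv(200L, 210L, "g3"))
  r5 <- overlap_sites(a, b2)
  expect_equal(r5$genes$both, "g1")
  expect_equal(r5$genes$a_only, "g2")
  expect_equal(r5$genes$b_only, "g3")
})

test_that("per-3'UTR site counts and the rank test behave as published", {
  mk <- function(genes) {
    data.frame(gene_id = genes, region = "utr3", stringsAsFactors = FALSE)
  }
  # median of {2,2,4} is 2
  a <- mk(rep(c("g1", "g2", "g3"), c(2, 2, 4)))
  b <- mk(rep(c("h1", "h2"), c(3, 4)))
  r <- sites_per_utr(a, b)
  expect_equal(r$median_a, 2)
  expect_equal(unname(r$counts_a[c("g1", "g2", "g3")]), c(2L, 2L, 4L))

  # identical distributions: p near 1
  same <- mk(rep(c("g1", "g2", "g3"), 1:3))
  same2 <- mk(rep(c("h1", "h2", "h3"), 1:3))
  expect_gte(sites_per_utr(same, same2)$p_value, 0.9)

  # U on {1,2} vs {3,4} is 0 (no pair has the first sample larger)
  u <- sites_per_utr(mk(c("g1", "g2", "g2")),
                     mk(rep(c("h1", "h2"), c(3, 4))))
  expect_equal(u$U, 0)
})

test_that("Pearson correlation reproduces hand evaluations and the CI", {
  expect_equal(correlate(1:10, 2 * (1:10))$r, 1)
  expect_equal(correlate(1:10, -3 * (1:10) + 7)$r, -1)
  r <- correlate(c(1, 2, 3), c(1, 2, 4))
  expect_equal(r$r, 0.981980506, tolerance = 1e-8)
  # missing pairs are excluded listwise
  r2 <- correlate(c(1, 2, 3, NA), c(1, 2, 4, 100))
  expect_equal(r2$n, 3L)
  expect_equal(r2$r, r$r)
  # brute-force agreement on random vectors
  set.seed(91)
  for (rep in 1:100) {
    x <- rnorm(sample(4:20, 1))
    y <- rnorm(length(x))
    expect_equal(correlate(x, y)$r, pearson_bruteforce(x, y),
                 tolerance = 1e-12)
  }
})

test_that("k-mer enrichment recovers a planted heptamer", {
  set.seed(111)
  bg <- vapply(1:60, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE,
                 prob = c(.3, .2, .2, .3)), collapse = ""), character(1))
  sites <- vapply(1:100, function(i) {
    fl <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                   replace = TRUE), collapse = "")
    paste0(fl(6), "TATTTAT", fl(6))
  }, character(1))
  enr <- kmer_enrichment(sites, bg, k = 7)
  expect_equal(enr$kmer[1], "UAUUUAU")
  expect_lt(enr$padj[1], 1e-10)

  # sites drawn from the background itself: no signal in >= 95% of runs
  set.seed(112)
  null_ok <- vapply(1:20, function(i) {
    draw <- vapply(1:20, function(j)
      paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE,
                   prob = c(.3, .2, .2, .3)), collapse = ""), character(1))
    min(kmer_enrichment(draw, bg, k = 5)$padj) >= 0.05
  }, logical(1))
  expect_gte(mean(null_ok), 0.95)

  expect_equal(nrow(kmer_enrichment(character(0), bg)), 0L)
})

test_that("the packaged overlapping-gene table holds 40 distinct symbols", {
  expect_equal(table2_gene_count(), 40L)
  # duplicates count once, case-insensitively
  p <- tempfile()
  writeLines(c("Tnf", "tnf", "Ccl3"), p)
  expect_equal(table2_gene_count(p), 2L)
  writeLines(character(0), p)
  expect_equal(table2_gene_count(p), 0L)
})

test_that("atlas records join sites, scores, decay and expression", {
  fx <- fixture_pipeline()
  d1 <- tempfile(); d2 <- tempfile()
  a1 <- build_atlas(fx$pl$sites, fx$pl$scores_utr3, fx$pl$calls,
                    fx$pl$diffexpr, fx$pl$profiles[[1]], d1)
  a2 <- build_atlas(fx$pl$sites, fx$pl$scores_utr3, fx$pl$calls,
                    fx$pl$diffexpr, fx$pl$profiles[[1]], d2)
  # deterministic export
  for (f in basename(unname(a1$paths))) {
    b1 <- readBin(file.path(d1, f), "raw", file.size(file.path(d1, f)))
    b2 <- readBin(file.path(d2, f), "raw", file.size(file.path(d2, f)))
    expect_identical(b1, b2)
  }
  # one record per sited gene; no records for siteless genes
  sited <- unique(stats::na.omit(fx$pl$sites$gene_id))
  expect_setequal(a1$records$gene_id, sited)
  # every record's fields trace to upstream tables
  for (i in seq_len(nrow(a1$records))) {
    rec <- a1$records[i, ]
    expect_equal(rec$n_sites,
                 sum(fx$pl$sites$gene_id == rec$gene_id, na.rm = TRUE))
    cl <- fx$pl$calls[fx$pl$calls$gene_id == rec$gene_id, ]
    if (nrow(cl)) expect_equal(rec$stability_class, cl$class)
  }
  # stub records on request
  a3 <- build_atlas(fx$pl$sites, fx$pl$scores_utr3, fx$pl$calls,
                    fx$pl$diffexpr, fx$pl$profiles[[1]], tempfile(),
                    include_empty = TRUE)
  expect_gt(nrow(a3$records), nrow(a1$records))
})

test_that("score-decay coupling drives the headline correlation", {
  rs <- vapply(c(0.0005, 0.002), function(k) {
    cfg <- sim_config(seed = 23L, n_genes = 40L, n_sites = 25L,
                      n_replicates = 2L, decay_coupling = k,
                      site_region_props = c(intron = 0.2, utr3 = 0.8,
                                            cds = 0))
    pl <- run_pipeline(cfg)
    pl$correlations$score_vs_delta_decay$r
  }, numeric(1))
  expect_true(all(rs > 0))
  expect_gt(rs[2], rs[1])
})
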