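test_that("generated annotation nests exons in transcripts in genes", {
  cfg <- sim_config(seed = 3L, n_genes = 12L)
  sim <- make_annotation(cfg)
  ann <- sim$annotation

  # exhaustive containment
  for (i in seq_len(nrow(ann$exons))) {
    e <- ann$exons[i, ]
    tx <- ann$transcripts[ann$transcripts$tx_id == e$tx_id, ]
    g <- ann$genes[ann$genes$gene_id == e$gene_id, ]
    expect_true(e$start >= tx$start && e$end <= tx$end)
    expect_true(tx$start >= g$start && tx$end <= g$end)
  }
  # sequences consistent with coordinates
  expect_gte(nchar(sim$reference[["chr1"]]), max(ann$genes$end))
  # both strands and at least one multi-isoform gene
  expect_setequal(unique(ann$genes$strand), c("+", "-"))
  expect_gt(max(table(ann$transcripts$gene_id)), 1L)
})

test_that("minimal one-gene annotation builds and derives its intron", {
  cfg <- sim_config(seed = 5L, n_genes = 1L,
                    n_isoforms_per_gene = c(1L, 1L), n_sites = 0L,
                    n_unbound_motifs = 0L)
  sim <- make_annotation(cfg)
  expect_equal(nrow(sim$annotation$genes), 1L)
  introns <- introns_of(sim$annotation)
  # three-exon gene model: two introns
  expect_equal(nrow(introns), 2L)
  ex <- sim$annotation$exons
  expect_true(all(introns$start %in% ex$end & introns$end %in% ex$start))
})

test_that("fixed seed reproduces byte-identical GTF and FASTA", {
  cfg <- sim_config(seed = 11L, n_genes = 8L)
  p1 <- tempfile(); p2 <- tempfile(); f1 <- tempfile(); f2 <- tempfile()
  sim1 <- make_annotation(cfg)
  sim2 <- make_annotation(cfg)
  write_gtf(sim1$annotation, p1); write_gtf(sim2$annotation, p2)
  write_fasta(sim1$reference, f1); write_fasta(sim2$reference, f2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("planted site proportions follow the requested multinomial", {
  cfg <- sim_config(seed = 2L, n_genes = 120L, n_sites = 100L,
                    site_region_props = c(intron = 0.64, utr3 = 0.35,
                                          cds = 0.01))
  sim <- make_annotation(cfg)
  truth <- plant_sites(sim$annotation, sim$reference, cfg)
  tab <- table(factor(truth$sites$region,
                      levels = c("intron", "utr3", "cds")))
  expect_equal(sum(tab), 100L)
  expect_lte(abs(tab[["intron"]] - 64), 5)
  expect_lte(abs(tab[["utr3"]] - 35), 5)
  # every planted site lies inside an annotated region of its gene
  for (i in seq_len(nrow(truth$sites))) {
    s <- truth$sites[i, ]
    g <- sim$annotation$genes[sim$annotation$genes$gene_id == s$gene_id, ]
    expect_true(s$start >= g$start && s$end <= g$end)
  }
  # true slopes are never positive
  expect_true(all(truth$decay$slope_wt <= 0))
  expect_true(all(truth$decay$slope_ko <= 0))
})

test_that("motif contexts honour the paired fraction and hairpin geometry", {
  cfg0 <- sim_config(seed = 4L, n_genes = 20L, n_sites = 10L,
                     p_paired_bound = 0, p_paired_unbound = 0)
  sim <- make_annotation(cfg0)
  truth0 <- plant_sites(sim$annotation, sim$reference, cfg0)
  expect_true(all(truth0$motifs$context == "accessible"))

  cfg1 <- sim_config(seed = 4L, n_genes = 20L, n_sites = 10L,
                     p_paired_bound = 1, p_paired_unbound = 1)
  truth1 <- plant_sites(sim$annotation, sim$reference, cfg1)
  expect_true(all(truth1$motifs$context == "paired"))
  # the motif's reverse complement sits 8 nt downstream in the emitted
  # transcript-sense sequence
  for (i in seq_len(nrow(truth1$motifs))) {
    m <- truth1$motifs[i, ]
    cx <- extract_context(truth1$reference, m$ref, m$strand, m$start,
                          m$end, pad = 30L)
    seq <- cx$seq
    motif <- substr(seq, cx$offset + 1L, cx$offset + 7L)
    expect_identical(motif, m$matched)
    partner <- substr(seq, cx$offset + 16L, cx$offset + 22L)
    expect_identical(partner, rbpatlas:::rna_revcomp(m$matched))
  }
})

test_that("crosslink chemistry follows truncation and conversion settings", {
  # p_trunc = 1: every 5' end is exactly 1 nt downstream of a crosslinked U
  cfg <- sim_config(seed = 6L, n_genes = 10L, n_sites = 4L, p_trunc = 1,
                    background_rate = 0, n_unbound_motifs = 0L)
  sim <- make_annotation(cfg)
  truth <- plant_sites(sim$annotation, sim$reference, cfg)
  aln <- simulate_clip_reads(truth, sim$annotation, cfg, 1L)
  pos0 <- ifelse(aln$strand == "+", aln$start - 1L, aln$end)
  for (i in seq_len(nrow(aln))) {
    base <- substr(truth$reference[[aln$ref[i]]], pos0[i] + 1L, pos0[i] + 1L)
    expected <- if (aln$strand[i] == "+") "T" else "A"  # template-strand T
    expect_identical(base, expected)
  }
  expect_true(all(aln$subs == "."))

  # no sites, no background: empty alignment set
  cfg0 <- sim_config(seed = 6L, n_genes = 5L, n_sites = 0L,
                     n_unbound_motifs = 0L, background_rate = 0)
  sim0 <- make_annotation(cfg0)
  truth0 <- plant_sites(sim0$annotation, sim0$reference, cfg0)
  expect_equal(nrow(simulate_clip_reads(truth0, sim0$annotation, cfg0)), 0L)
})

test_that("T-to-C fraction converges to p_tc on read-through events", {
  cfg <- sim_config(seed = 8L, n_genes = 40L, n_sites = 30L,
                    summit_height_range = c(800L, 1200L), p_trunc = 0.5,
                    p_tc = 0.45, background_rate = 0, n_unbound_motifs = 0L)
  sim <- make_annotation(cfg)
  truth <- plant_sites(sim$annotation, sim$reference, cfg)
  aln <- simulate_clip_reads(truth, sim$annotation, cfg, 1L)
  # truncated reads have their position 0 at a planted crosslink U
  # (summit or its two shoulders); everything else is a read-through
  cx <- unlist(lapply(seq_len(nrow(truth$sites)), function(i) {
    s <- truth$sites[i, ]
    paste(s$ref, s$strand, (s$summit_pos - 1L):(s$summit_pos + 1L))
  }))
  p0 <- ifelse(aln$strand == "+", aln$start - 1L, aln$end)
  is_trunc <- paste(aln$ref, aln$strand, p0) %in% cx
  n_rt <- sum(!is_trunc)
  expect_gte(n_rt, 1e4)
  frac_tc <- sum(aln$subs != ".") / n_rt
  expect_lt(abs(frac_tc - 0.45), 0.02)
})

test_that("decay series obey closed forms and OLS recovers true slopes", {
  cfg <- sim_config(seed = 9L, n_genes = 4L, n_sites = 2L,
                    fpkm_noise_sd = 0)
  sim <- make_annotation(cfg)
  truth <- plant_sites(sim$annotation, sim$reference, cfg)
  # force known slopes: halving at 45 min for WT, flat for KO
  truth$decay$slope_wt[] <- -1 / 45
  truth$decay$slope_ko[] <- 0
  ser <- simulate_decay_series(truth, cfg)
  g <- truth$decay$gene_id[1]
  wt <- ser[ser$gene_id == g & ser$genotype == "WT" & ser$replicate == 1, ]
  wt <- stats::aggregate(wt["fpkm"], wt["actd_min"], sum)
  expect_equal(wt$fpkm[wt$actd_min == 45] / wt$fpkm[wt$actd_min == 0], 0.5,
               tolerance = 1e-12)
  expect_equal(wt$fpkm[wt$actd_min == 90] / wt$fpkm[wt$actd_min == 0], 0.25,
               tolerance = 1e-12)
  ko <- ser[ser$gene_id == g & ser$genotype == "KO" & ser$replicate == 1, ]
  ko <- stats::aggregate(ko["fpkm"], ko["actd_min"], sum)
  expect_equal(length(unique(round(ko$fpkm, 9))), 1L)

  # noisy recovery: mean absolute slope error below 0.004 log2/min
  cfgN <- sim_config(seed = 10L, n_genes = 200L, n_sites = 60L,
                     fpkm_noise_sd = 0.2)
  simN <- make_annotation(cfgN)
  truthN <- plant_sites(simN$annotation, simN$reference, cfgN)
  serN <- simulate_decay_series(truthN, cfgN)
  fits <- fit_decay(serN[serN$genotype == "WT", ])
  truth_slope <- truthN$decay$slope_wt[match(fits$gene_id,
                                             truthN$decay$gene_id)]
  expect_lt(mean(abs(fits$slope - truth_slope)), 0.004)
})

test_that("emitted truth is self-consistent with the crosslink profile", {
  fx <- fixture_pipeline()
  truth <- fx$pl$truth
  prof <- fx$pl$profiles[[1]]
  for (i in seq_len(nrow(truth$sites))) {
    s <- truth$sites[i, ]
    ev <- prof$events
    hit <- ev$ref == s$ref & ev$strand == s$strand &
      ev$pos >= s$start & ev$pos < s$end
    expect_gt(sum(ev$count[hit]), 0)
  }
})
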