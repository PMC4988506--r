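test_that("motif scanning matches IUPAC patterns, overlaps included", {
  hit <- scan_motifs("UAUUUAU", "WAUUUAW")
  expect_equal(hit$start, 0L)
  expect_equal(hit$matched, "UAUUUAU")
  expect_equal(nrow(scan_motifs("GGGGGGG", "WAUUUAW")), 0L)
  # DNA input is normalized to RNA
  expect_equal(scan_motifs("TATTTAT", "WAUUUAW")$matched, "UAUUUAU")
  # overlapping matches are all reported
  over <- scan_motifs("AAUUUAAUUUAA", "WAUUUAW")
  expect_equal(over$start, c(0L, 5L))
  # the HuR pattern accepts its K degeneracy
  expect_equal(nrow(scan_motifs("UUUGUUU", "UUUKUUU")), 1L)
  expect_equal(nrow(scan_motifs("UUUUUUU", "UUUKUUU")), 1L)
  expect_equal(nrow(scan_motifs("UUUAUUU", "UUUKUUU")), 0L)
})

test_that("motif scanning equals the exhaustive window check", {
  iupac_ok <- function(ch, pat) switch(pat, W = ch %in% c("A", "U"),
                                       K = ch %in% c("G", "U"), ch == pat)
  set.seed(21)
  for (rep in 1:25) {
    s <- paste(sample(c("A", "C", "G", "U"), 30, replace = TRUE),
               collapse = "")
    for (pat in c("WAUUUAW", "UUUKUUU")) {
      pc <- strsplit(pat, "")[[1]]
      expected <- which(vapply(1:(30 - 6), function(i) {
        all(vapply(1:7, function(k)
          iupac_ok(substr(s, i + k - 1, i + k - 1), pc[k]), logical(1)))
      }, logical(1))) - 1L
      expect_equal(scan_motifs(s, pat)$start, as.integer(expected))
    }
  }
})

test_that("AU content counts the motif-centred window", {
  expect_equal(au_content("AUAUAUA", 0L, 7L, 7L), 1.0)
  expect_equal(au_content("GCGCGCG", 0L, 7L, 7L), 0.0)
  # 20-nt hand-counted mixed window
  s <- "GGAUUACGUAUUUAUGGCCA"
  expect_equal(au_content(s, 7L, 7L, 21L), 12 / 20)
})

test_that("poly-A has no structure: all stretches fully open", {
  a <- accessibility(strrep("A", 40), W = 75, u = 7)
  expect_true(all(abs(a$p_unpaired - 1) < 1e-12))
  expect_true(all(abs(a$open_energy) < 1e-9))
})

test_that("unknown accessibility backends are refused with a listing", {
  expect_error(accessibility("AAAAAAAA", backend = "nupack"),
               "available backends")
})

test_that("partition function matches exhaustive Boltzmann enumeration", {
  set.seed(31)
  for (rep in 1:30) {
    n <- sample(5:18, 1L)
    s <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
    u <- sample(1:3, 1L)
    if (n < u) next
    oracle <- oracle_unpaired_probs(s, u)
    codes <- match(s, c("A", "C", "G", "U")) - 1L
    res <- rbpatlas:::pf_window(codes, u, -2, -3, -1,
                                rbpatlas:::RT_37C, 3L)
    expect_lt(max(abs(res$unpaired - oracle)), 1e-9)
    # paired + unpaired probabilities sum to 1 at every position
    res1 <- rbpatlas:::pf_window(codes, 1L, -2, -3, -1,
                                 rbpatlas:::RT_37C, 3L)
    expect_lt(max(abs(rowSums(res1$pair_prob) + res1$unpaired - 1)), 1e-9)
  }
})

test_that("a 7-mer is more open in a hairpin loop than inside the stem", {
  # loop placement: GC stem of 10 bp with the A7 heptamer as the loop
  in_loop <- paste0(strrep("G", 10), strrep("A", 7), strrep("C", 10))
  # stem placement: the same heptamer paired against U7
  in_stem <- paste0(strrep("A", 7), strrep("C", 5), strrep("U", 7))
  p_loop <- accessibility(in_loop, W = 75, u = 7)
  p_stem <- accessibility(in_stem, W = 75, u = 7)
  target <- function(prof, start) prof$p_unpaired[prof$start == start]
  expect_gt(target(p_loop, 10L), target(p_stem, 0L))
})

test_that("one-feature LDA scores order like the feature itself", {
  set.seed(41)
  feature <- c(rnorm(30, 2), rnorm(30, 0))
  bound <- rep(c(TRUE, FALSE), each = 30)
  fit <- train_lda(feature, bound)
  expect_equal(order(fit$scores), order(feature))
  expect_gt(mean(fit$scores[bound]), mean(fit$scores[!bound]))
})

test_that("rank AUC reproduces exhaustive pair counting", {
  # perfectly separated
  expect_equal(roc_auc(c(5, 6, 7, 1, 2, 3),
                       c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))$auc, 1)
  # the four-point worked example
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3),
                       c(TRUE, FALSE, TRUE, FALSE))$auc, 0.75)
  # complement identity AUC(s) + AUC(-s) = 1, ties counting 1/2
  set.seed(51)
  for (rep in 1:50) {
    sc <- sample(0:10, 30, replace = TRUE)
    lb <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    if (length(unique(lb)) < 2) next
    expect_equal(roc_auc(sc, lb)$auc + roc_auc(-sc, lb)$auc, 1)
    # exhaustive concordance count with half ties
    pos <- sc[lb]; neg <- sc[!lb]
    conc <- sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))
    expect_equal(roc_auc(sc, lb)$auc, conc / (length(pos) * length(neg)))
  }
  # label permutation: mean AUC near 1/2
  set.seed(61)
  sc <- rnorm(40)
  aucs <- replicate(200, roc_auc(sc, sample(rep(c(TRUE, FALSE), 20)))$auc)
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(71)
  sc <- rnorm(60)
  lb <- sc + rnorm(60) > 0
  expect_equal(roc_auc(sc, lb)$auc,
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                              direction = "<"))))
})

test_that("structure separates planted bound from unbound motifs", {
  fx <- fixture_pipeline()
  m <- fx$pl$truth$motifs
  feats <- motif_features(
    setNames(
      vapply(seq_len(nrow(m)), function(i)
        extract_context(fx$pl$truth$reference, m$ref[i], m$strand[i],
                        m$start[i], m$end[i], pad = 68L)$seq,
        character(1)),
      m$motif_id),
    data.frame(seq_id = m$motif_id[m$bound], start = 68L, end = 75L,
               stringsAsFactors = FALSE))
  central <- feats[feats$start == 68L, ]
  expect_equal(nrow(central), nrow(m))
  bound <- m$bound[match(central$seq_id, m$motif_id)]

  struct_auc <- roc_auc(central$p_unpaired, bound)$auc
  seq_auc <- roc_auc(central$au, bound)$auc
  expect_gt(struct_auc, 0.6)
  expect_gt(struct_auc, seq_auc)
  # flanking AU content is equalized by construction: sequence is blind
  expect_lt(abs(seq_auc - 0.5), 0.15)

  # structure-blind planting: contexts independent of binding
  cfg_blind <- sim_config(seed = 19L, n_genes = 30L, n_sites = 15L,
                          p_paired_bound = 0.5, p_paired_unbound = 0.5)
  sim <- make_annotation(cfg_blind)
  tr <- plant_sites(sim$annotation, sim$reference, cfg_blind)
  mb <- tr$motifs
  pb <- vapply(seq_len(nrow(mb)), function(i) {
    cx <- extract_context(tr$reference, mb$ref[i], mb$strand[i],
                          mb$start[i], mb$end[i], pad = 68L)
    a <- accessibility(cx$seq, W = 75, u = 7)
    a$p_unpaired[a$start == cx$offset]
  }, numeric(1))
  expect_lt(abs(roc_auc(pb, mb$bound)$auc - 0.5), 0.2)
})
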