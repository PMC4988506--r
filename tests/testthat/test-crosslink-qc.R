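toy_aln <- function(ref, strand, start, end, subs = ".") {
  data.frame(ref = ref, strand = strand, start = start, end = end,
             subs = subs, stringsAsFactors = FALSE)
}

test_that("position 0 is one nt upstream of the 5' end on either strand", {
  p <- extract_crosslinks(toy_aln("chr1", "+", 100L, 150L))
  expect_equal(p$events$pos, 99L)
  m <- extract_crosslinks(toy_aln("chr1", "-", 100L, 150L))
  expect_equal(m$events$pos, 150L)

  empty <- extract_crosslinks(toy_aln(character(), character(), integer(),
                                      integer(), character()))
  expect_equal(empty$total, 0L)
  expect_equal(nrow(empty$events), 0L)
})

test_that("crosslink extraction conserves events and rejects bad strands", {
  aln <- rbind(toy_aln("chr1", "+", c(10L, 10L, 20L), c(60L, 60L, 70L)),
               toy_aln("chr1", "*", 5L, 55L))
  p <- extract_crosslinks(aln)
  expect_equal(p$total, 3L)
  expect_equal(sum(p$events$count), 3L)
  expect_equal(p$n_rejected, 1L)
  # negative-coordinate events dropped with a warning
  expect_warning(p0 <- extract_crosslinks(toy_aln("chr1", "+", 0L, 50L)),
                 "negative")
  expect_equal(p0$total, 0L)
})

test_that("T-to-C calling is strand aware and spectra sum to one", {
  aln <- rbind(
    toy_aln("chr1", "+", 100L, 150L, "120:T>C"),
    toy_aln("chr1", "+", 100L, 150L, "130:G>A"),
    toy_aln("chr1", "-", 200L, 250L, "220:A>G"),   # T>C in read space
    toy_aln("chr1", "-", 200L, 250L, "230:T>C")    # A>G in read space
  )
  res <- call_tc_positions(aln)
  expect_equal(res$tc$pos, c(120L, 220L))
  expect_equal(res$tc$count, c(1L, 1L))
  expect_equal(sum(res$spectrum), 1)
  expect_equal(unname(res$spectrum[["T>C"]]), 0.5)
  expect_equal(unname(res$spectrum[["G>A"]]), 0.25)
  expect_equal(unname(res$spectrum[["A>G"]]), 0.25)
})

test_that("simulated conversion rate appears in the substitution spectrum", {
  fx <- fixture_pipeline()
  aln <- simulate_clip_reads(fx$pl$truth, fx$pl$annotation, fx$cfg, 1L)
  res <- call_tc_positions(aln)
  # the generator introduces no other substitution type
  expect_equal(unname(res$spectrum[["T>C"]]), 1)
})

test_that("composition shows pure T at position 0 for pure truncation", {
  cfg <- sim_config(seed = 12L, n_genes = 10L, n_sites = 5L, p_trunc = 1,
                    background_rate = 0, n_unbound_motifs = 0L)
  sim <- make_annotation(cfg)
  truth <- plant_sites(sim$annotation, sim$reference, cfg)
  aln <- simulate_clip_reads(truth, sim$annotation, cfg, 1L)
  comp <- qc_composition(extract_crosslinks(aln), truth$reference)
  expect_equal(unname(comp["0", "T"]), 1.0)
  expect_true(all(abs(rowSums(comp) - 1) < 1e-9))
})

test_that("RNA-seq-like uniform starts show background composition", {
  cfg <- sim_config(seed = 13L, n_genes = 30L, n_sites = 0L,
                    n_unbound_motifs = 0L, background_rate = 0.4)
  sim <- make_annotation(cfg)
  truth <- plant_sites(sim$annotation, sim$reference, cfg)
  aln <- simulate_clip_reads(truth, sim$annotation, cfg, 1L)
  comp <- qc_composition(extract_crosslinks(aln), truth$reference)
  # every offset close to the genomic base composition (A/T .3, C/G .2)
  expect_true(all(abs(comp[, "A"] - 0.3) < 0.05))
  expect_true(all(abs(comp[, "T"] - 0.3) < 0.05))
  expect_true(all(abs(comp[, "C"] - 0.2) < 0.05))
  expect_true(all(abs(comp[, "G"] - 0.2) < 0.05))
})

test_that("termination/T-to-C overlap counts distinct loci", {
  prof <- rbpatlas:::new_crosslink_profile(
    data.frame(ref = "chr1", strand = "+", pos = c(10L, 20L, 30L),
               count = c(5L, 1L, 2L), stringsAsFactors = FALSE), 8L, 0L)
  tc <- data.frame(ref = "chr1", strand = "+", pos = c(10L, 30L, 99L),
                   count = c(1L, 2L, 1L), stringsAsFactors = FALSE)
  expect_equal(termination_tc_overlap(prof, tc), 2 / 3)
  # per-read weighting exposed as an option
  expect_equal(termination_tc_overlap(prof, tc, per_read = TRUE), 7 / 8)
  # degenerate cases
  none <- tc[0, ]
  expect_equal(termination_tc_overlap(prof, none), 0)
  all_tc <- data.frame(ref = "chr1", strand = "+",
                       pos = c(10L, 20L, 30L), count = 1L,
                       stringsAsFactors = FALSE)
  expect_equal(termination_tc_overlap(prof, all_tc), 1)
  # restriction to sites
  sites <- data.frame(ref = "chr1", strand = "+", start = 5L, end = 15L)
  expect_equal(termination_tc_overlap(prof, tc, sites), 1)
})

test_that("within-site overlap exceeds the genome-wide fraction", {
  fx <- fixture_pipeline()
  aln <- simulate_clip_reads(fx$pl$truth, fx$pl$annotation, fx$cfg, 1L)
  prof <- extract_crosslinks(aln)
  tc <- call_tc_positions(aln)$tc
  gw <- termination_tc_overlap(prof, tc)
  ws <- termination_tc_overlap(prof, tc, fx$pl$truth$sites)
  expect_gt(ws, gw)
})

test_that("QC statistics are invariant under genome reverse-complement", {
  fx <- fixture_pipeline()
  aln <- simulate_clip_reads(fx$pl$truth, fx$pl$annotation, fx$cfg, 1L)
  ref <- fx$pl$truth$reference
  L <- nchar(ref[["chr1"]])
  # flip every record onto the reverse-complemented genome
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip_subs <- function(subs) {
    vapply(subs, function(s) {
      if (s == ".") return(".")
      parts <- strsplit(s, ",", fixed = TRUE)[[1]]
      paste(vapply(parts, function(p) {
        m <- regmatches(p, regexec("^(\\d+):([ACGT])>([ACGT])$", p))[[1]]
        sprintf("%d:%s>%s", L - 1L - as.integer(m[2]), comp[[m[3]]],
                comp[[m[4]]])
      }, character(1)), collapse = ",")
    }, character(1), USE.NAMES = FALSE)
  }
  flipped <- data.frame(
    ref = aln$ref, strand = ifelse(aln$strand == "+", "-", "+"),
    start = L - aln$end, end = L - aln$start,
    subs = flip_subs(aln$subs), stringsAsFactors = FALSE)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(ref[["chr1"]])))
  ref_rc <- c(chr1 = rc)

  q1 <- qc_report(aln, ref)
  q2 <- qc_report(flipped, ref_rc)
  expect_equal(q2$composition, q1$composition, tolerance = 1e-12)
  expect_equal(q2$spectrum, q1$spectrum, tolerance = 1e-12)
  expect_equal(q2$overlap_genomewide, q1$overlap_genomewide)
})

test_that("bedGraph round trip preserves the profile", {
  fx <- fixture_pipeline()
  prof <- fx$pl$profiles[[1]]
  prefix <- tempfile()
  paths <- write_bedgraph(prof, prefix)
  back <- read_bedgraph(paths[1], paths[2])
  expect_equal(back$events, prof$events)
})
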