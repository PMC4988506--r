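#' Simulation configuration for the synthetic PAR-iCLIP cohort
#'
#' Bundles and validates every parameter of the synthetic-data generator:
#' gene architecture, planted binding sites, crosslink chemistry, sequencing,
#' and the two-genotype actinomycin-D decay design.  Defaults describe a
#' macrophage-like cohort: sites split roughly 64/35 between introns and
#' 3'UTRs, T-to-C conversion probability 0.45 on read-through, expression
#' sampled at 0/45/90 min after transcription shut-off in three replicates,
#' and TTP-dependent genes whose knockout stabilization is coupled to their
#' per-molecule binding occupancy.
#'
#' @param seed integer RNG seed; every generator draw derives from it.
#' @param n_genes number of genes laid out on the synthetic chromosome.
#' @param n_isoforms_per_gene integer range (min, max) of isoforms per gene.
#'   Two-isoform genes skip the middle exon in the second isoform, creating
#'   regions exonic in one isoform and intronic in the other.
#' @param utr5_len,cds_exon_len,intron_len,utr3_len integer ranges (nt) for
#'   feature lengths.
#' @param intergenic_gap nt between consecutive genes.
#' @param n_sites number of planted binding sites.
#' @param site_region_props named numeric proportions (intron, utr3, cds)
#'   for site placement; must sum to 1.
#' @param summit_height_range range of planted summit heights (crosslink
#'   truncation events at the summit uridine).
#' @param background_rate expected background read 5' ends per nt of gene.
#' @param p_trunc probability a crosslink event truncates reverse
#'   transcription (vs reading through).
#' @param p_tc probability a read-through converts the crosslinked U's
#'   template T to C.
#' @param read_length read length in nt.
#' @param timepoints minutes after actinomycin D addition; strictly
#'   increasing, starting at 0.
#' @param n_replicates biological replicates per condition (also the number
#'   of simulated PAR-iCLIP replicates).
#' @param fpkm_noise_sd log2-scale Gaussian noise SD of the expression series.
#' @param half_life_target,half_life_unstable,half_life_stable half-life
#'   ranges (min) for the binding-free baseline of TTP targets (their
#'   knockout half-life), for TTP-independent unstable genes, and for
#'   stable genes.
#' @param frac_unstable_independent fraction of non-target genes that are
#'   unstable independently of TTP.
#' @param decay_coupling decay rate added per unit binding occupancy in
#'   the wild type (log2/min per occupancy unit):
#'   `slope_WT = slope_KO - decay_coupling * occupancy`; 0 decouples
#'   binding from decay.
#' @param expr_coupling minutes-equivalent coefficient converting a decay
#'   difference into a baseline differential-expression shift.
#' @param n_unbound_motifs decoy ARE motifs planted without binding sites;
#'   defaults to `n_sites`.
#' @param p_paired_bound,p_paired_unbound fraction of bound / unbound motif
#'   contexts embedded in a hairpin stem (paired) rather than an accessible
#'   context.
#' @param lps_h nominal LPS stimulation time (hours) recorded in sample
#'   metadata.
#' @param base_probs named base probabilities (A, C, G, T) of the background
#'   genome.
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 60L,
                       n_isoforms_per_gene = c(1L, 2L),
                       utr5_len = c(80L, 150L),
                       cds_exon_len = c(160L, 300L),
                       intron_len = c(200L, 700L),
                       utr3_len = c(300L, 600L),
                       intergenic_gap = 800L,
                       n_sites = 40L,
                       site_region_props = c(intron = 0.64, utr3 = 0.35,
                                             cds = 0.01),
                       summit_height_range = c(120L, 400L),
                       background_rate = 0.05,
                       p_trunc = 0.7,
                       p_tc = 0.45,
                       read_length = 50L,
                       timepoints = c(0, 45, 90),
                       n_replicates = 3L,
                       fpkm_noise_sd = 0.2,
                       half_life_target = c(150, 400),
                       half_life_unstable = c(30, 90),
                       half_life_stable = c(300, 600),
                       frac_unstable_independent = 0.15,
                       decay_coupling = 0.002,
                       expr_coupling = 60,
                       n_unbound_motifs = NULL,
                       p_paired_bound = 0,
                       p_paired_unbound = 0.8,
                       lps_h = 6,
                       base_probs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    n_isoforms_per_gene = as.integer(n_isoforms_per_gene),
    utr5_len = as.integer(utr5_len), cds_exon_len = as.integer(cds_exon_len),
    intron_len = as.integer(intron_len), utr3_len = as.integer(utr3_len),
    intergenic_gap = as.integer(intergenic_gap),
    n_sites = as.integer(n_sites),
    site_region_props = site_region_props,
    summit_height_range = as.integer(summit_height_range),
    background_rate = background_rate,
    p_trunc = p_trunc, p_tc = p_tc,
    read_length = as.integer(read_length),
    timepoints = as.numeric(timepoints),
    n_replicates = as.integer(n_replicates),
    fpkm_noise_sd = fpkm_noise_sd,
    half_life_target = half_life_target,
    half_life_unstable = half_life_unstable,
    half_life_stable = half_life_stable,
    frac_unstable_independent = frac_unstable_independent,
    decay_coupling = decay_coupling,
    expr_coupling = expr_coupling,
    n_unbound_motifs = as.integer(n_unbound_motifs %||% n_sites),
    p_paired_bound = p_paired_bound,
    p_paired_unbound = p_paired_unbound,
    lps_h = lps_h,
    base_probs = base_probs
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  for (p in c("p_trunc", "p_tc", "frac_unstable_independent",
              "p_paired_bound", "p_paired_unbound")) {
    stopifnot_scalar_prob(cfg[[p]], p)
  }
  len_fields <- c("utr5_len", "cds_exon_len", "intron_len", "utr3_len")
  for (f in len_fields) {
    rng <- cfg[[f]]
    if (length(rng) != 2L || any(rng <= 0) || rng[1] > rng[2]) {
      stop(sprintf("'%s' must be a positive (min, max) range", f),
           call. = FALSE)
    }
  }
  if (cfg$n_genes < 1L || cfg$read_length < 15L || cfg$intergenic_gap < 1L) {
    stop("impossible length constraints in sim_config", call. = FALSE)
  }
  tp <- cfg$timepoints
  if (length(tp) < 2L || tp[1] != 0 || any(diff(tp) <= 0)) {
    stop("timepoints must be strictly increasing and start at 0",
         call. = FALSE)
  }
  if (cfg$fpkm_noise_sd < 0) {
    stop("fpkm_noise_sd must be non-negative", call. = FALSE)
  }
  props <- cfg$site_region_props
  if (is.null(names(props)) ||
      !all(names(props) %in% c("intron", "utr3", "cds", "utr5")) ||
      any(props < 0) || abs(sum(props) - 1) > 1e-6) {
    stop("site_region_props must be named non-negative proportions summing to 1",
         call. = FALSE)
  }
  shr <- cfg$summit_height_range
  if (length(shr) != 2L || shr[1] < 1L || shr[1] > shr[2]) {
    stop("summit_height_range must be a positive (min, max) range",
         call. = FALSE)
  }
  if (cfg$background_rate < 0) {
    stop("background_rate must be non-negative", call. = FALSE)
  }
  bp <- cfg$base_probs
  if (!setequal(names(bp), c("A", "C", "G", "T")) ||
      abs(sum(bp) - 1) > 1e-6 || any(bp < 0)) {
    stop("base_probs must be probabilities named A, C, G, T summing to 1",
         call. = FALSE)
  }
  invisible(cfg)
}
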