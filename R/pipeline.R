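# End-to-end synthetic pipeline: simulate -> crosslink -> call peaks ->
# annotate -> score -> decay -> integrate -> atlas.

#' Run the full pipeline on a synthetic cohort
#'
#' Generates a genome with planted truth, simulates PAR-iCLIP replicates
#' and decay series, calls and filters binding sites, annotates them,
#' computes normalized scores, fits decay, and assembles the atlas with the
#' headline correlations.  Fully deterministic under `config$seed`; when
#' `out_dir` is given the static atlas bundle and a JSON run manifest are
#' written there.
#'
#' @param config a [sim_config()].
#' @param peak_cfg a [peak_config()].
#' @param out_dir optional export directory.
#' @return list with `truth`, `annotation`, `profiles`, `sites`
#'   (consensus-filtered, annotated, replicate 1), `scores_utr3`, `calls`,
#'   `diffexpr`, `correlations` and, when exported, `paths`.
#' @export
run_pipeline <- function(config = sim_config(),
                         peak_cfg = peak_config(seed = config$seed),
                         out_dir = NULL) {
  sim <- make_annotation(config)
  truth <- plant_sites(sim$annotation, sim$reference, config)
  ann <- sim$annotation
  regions <- ann$genes

  profiles <- list()
  site_lists <- list()
  n_rep <- max(2L, config$n_replicates)
  for (r in seq_len(n_rep)) {
    aln <- simulate_clip_reads(truth, ann, config, replicate = r)
    profiles[[r]] <- extract_crosslinks(aln)
    site_lists[[r]] <- call_binding_sites(profiles[[r]], regions, peak_cfg,
                                          replicate = r)
  }
  cons <- consensus_sites(site_lists)
  sites <- cons$per_replicate[[1L]]
  annotated <- annotate_sites(sites, ann)

  expression <- simulate_decay_series(truth, config)
  baseline <- expression[expression$genotype == "WT" &
                           expression$actd_min == 0, , drop = FALSE]
  tx_fpkm <- stats::aggregate(baseline["fpkm"],
                              baseline[c("tx_id", "gene_id")], FUN = mean)

  scores_utr3 <- score_table(annotated, tx_fpkm, ann, region = "utr3")
  calls <- stability_calls(expression)
  diffexpr <- differential_expression(expression)

  j <- merge(scores_utr3, calls, by = "gene_id")
  j <- merge(j, diffexpr, by = "gene_id", all.x = TRUE)
  correlations <- list(
    score_vs_delta_decay = if (nrow(j) >= 3L)
      correlate(j$score, j$delta_slope) else NULL,
    score_vs_delta_expression = if (nrow(j) >= 3L)
      correlate(j$score, j$log2fc) else NULL,
    delta_decay_vs_delta_expression = if (nrow(j) >= 3L)
      correlate(j$delta_slope, j$log2fc) else NULL
  )

  out <- list(truth = truth, annotation = ann, reference = truth$reference,
              profiles = profiles, site_lists = site_lists,
              consensus = cons, sites = annotated,
              expression = expression, tx_fpkm = tx_fpkm,
              scores_utr3 = scores_utr3, calls = calls,
              diffexpr = diffexpr, correlations = correlations)

  if (!is.null(out_dir)) {
    atlas <- build_atlas(annotated, scores_utr3, calls, diffexpr,
                         profiles[[1L]], out_dir)
    manifest <- list(
      package = "rbpatlas",
      version = as.character(utils::packageVersion("rbpatlas")),
      seed = config$seed,
      n_genes = config$n_genes, n_sites = config$n_sites,
      n_replicates = n_rep,
      peak_config = unclass(peak_cfg)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    out$atlas <- atlas$records
    out$paths <- c(atlas$paths,
                   manifest = file.path(out_dir, "manifest.json"))
  }
  out
}
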