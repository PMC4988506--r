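# Two-genotype actinomycin-D decay series generator.

#' Simulate expression/decay tables from planted truth
#'
#' Emits a long-format FPKM table over genotype (WT, KO) x minutes after
#' actinomycin D x replicate, per transcript.  On the log2 scale,
#' `log2 FPKM(t) = log2 FPKM(0) + slope * t + Normal(0, fpkm_noise_sd)`.
#' The knockout baseline of TTP targets is additionally shifted by
#' `expr_coupling * (slope_KO - slope_WT)` log2 units, coupling differential
#' expression to differential decay.
#'
#' @param truth a `planted_truth` from [plant_sites()].
#' @param config a [sim_config()].
#' @return data.frame with columns tx_id, gene_id, genotype, lps_h,
#'   actd_min, replicate, fpkm.
#' @export
simulate_decay_series <- function(truth, config) {
  validate_sim_config(config)
  with_seed(config$seed + 11L, simulate_decay_series_impl(truth, config))
}

simulate_decay_series_impl <- function(truth, config) {
  ex <- truth$expression
  dec <- truth$decay[match(ex$gene_id, truth$decay$gene_id), ]
  grid <- expand.grid(genotype = c("WT", "KO"),
                      actd_min = config$timepoints,
                      replicate = seq_len(config$n_replicates),
                      stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    slope <- if (g$genotype == "WT") dec$slope_wt else dec$slope_ko
    base <- log2(ex$fpkm0_tx)
    if (g$genotype == "KO") {
      base <- base + config$expr_coupling * (dec$slope_ko - dec$slope_wt)
    }
    lfpkm <- base + slope * g$actd_min
    if (config$fpkm_noise_sd > 0) {
      lfpkm <- lfpkm + rnorm(length(lfpkm), 0, config$fpkm_noise_sd)
    }
    out[[i]] <- data.frame(tx_id = ex$tx_id, gene_id = ex$gene_id,
                           genotype = g$genotype, lps_h = config$lps_h,
                           actd_min = g$actd_min, replicate = g$replicate,
                           fpkm = 2 ^ lfpkm, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$tx_id, res$genotype, res$actd_min, res$replicate), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
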