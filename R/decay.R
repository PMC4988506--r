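# Exponential mRNA decay analysis from actinomycin-D time courses.
#
# log2 FPKM is modelled as linear in minutes after transcription shut-off;
# the slope estimates the decay rate and half-life = -1/slope minutes.

#' Fit per-gene exponential decay by ordinary least squares
#'
#' Pools replicates into a single OLS of log2 FPKM on minutes after
#' actinomycin D, per gene and genotype.  Genes with any zero FPKM point
#' get a pseudocount before the log2 transform and are flagged.
#'
#' @param expression long-format data.frame with gene_id, genotype,
#'   actd_min, fpkm (replicates as repeated rows); transcript-level tables
#'   are aggregated to gene level by summing FPKM within a sample first
#'   when `tx_id`/`replicate` columns are present.
#' @param pseudocount added to FPKM when zeros are present (default 0.1).
#' @return data.frame of fits: gene_id, genotype, slope (log2 FPKM/min),
#'   intercept, slope_se, half_life (min; `Inf` when slope >= 0), n_points,
#'   used_pseudocount.  Genes with fewer than 2 distinct timepoints are
#'   skipped.
#' @export
fit_decay <- function(expression, pseudocount = 0.1) {
  expr <- aggregate_gene_fpkm(expression)
  out <- list()
  for (g in unique(expr$gene_id)) {
    for (gt in unique(expr$genotype)) {
      d <- expr[expr$gene_id == g & expr$genotype == gt, , drop = FALSE]
      if (nrow(d) == 0L || length(unique(d$actd_min)) < 2L) next
      flagged <- any(d$fpkm <= 0)
      y <- log2(d$fpkm + if (flagged) pseudocount else 0)
      fit <- lm(y ~ d$actd_min)
      sm <- summary(fit)$coefficients
      b <- unname(coef(fit)[2])
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g, genotype = gt, slope = b,
        intercept = unname(coef(fit)[1]),
        slope_se = if (nrow(sm) >= 2L) sm[2, 2] else NA_real_,
        half_life = half_life(b), n_points = nrow(d),
        used_pseudocount = flagged, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

aggregate_gene_fpkm <- function(expression) {
  if (!("tx_id" %in% names(expression))) return(expression)
  key <- c("gene_id", "genotype", "actd_min",
           intersect(c("lps_h", "replicate"), names(expression)))
  stats::aggregate(expression["fpkm"], expression[key], FUN = sum)
}

#' Half-life from a log2-scale decay slope
#'
#' Solves `2^(b t) = 1/2`: half-life is `-1/b` minutes, infinite for
#' non-negative slopes.  Slopes within numerical noise of zero
#' (`|b| < 1e-12` log2/min, a half-life beyond two million years) are
#' treated as zero.
#'
#' @param slope log2 FPKM per minute.
#' @return half-life in minutes.
#' @export
half_life <- function(slope) {
  ifelse(slope < -1e-12, -1 / slope, Inf)
}

#' Test a genotype difference in decay slope
#'
#' Fits one linear model with a genotype x time interaction; the
#' interaction coefficient is the differential decay
#' `delta_slope = b_KO - b_WT` used in downstream correlations, and its
#' p-value tests whether decay differs between genotypes.
#'
#' @param expression long-format expression for one gene (both genotypes),
#'   as in [fit_decay()].
#' @param reference_genotype genotype treated as baseline (default "WT").
#' @param pseudocount see [fit_decay()].
#' @return list with `delta_slope`, `p_value`, `slope_ref`, `n`.
#' @export
differential_decay <- function(expression, reference_genotype = "WT",
                               pseudocount = 0.1) {
  expr <- aggregate_gene_fpkm(expression)
  gts <- unique(expr$genotype)
  if (length(gts) != 2L) {
    stop("differential_decay needs exactly 2 genotypes", call. = FALSE)
  }
  other <- setdiff(gts, reference_genotype)
  expr$genotype <- factor(expr$genotype,
                          levels = c(reference_genotype, other))
  flagged <- any(expr$fpkm <= 0)
  y <- log2(expr$fpkm + if (flagged) pseudocount else 0)
  fit <- lm(y ~ actd_min * genotype, data = expr)
  sm <- summary(fit)$coefficients
  term <- paste0("actd_min:genotype", other)
  delta <- unname(coef(fit)[term])
  p <- if (term %in% rownames(sm)) sm[term, 4] else NA_real_
  list(delta_slope = delta, p_value = p,
       slope_ref = unname(coef(fit)["actd_min"]), n = nrow(expr))
}

#' Classify gene stability from two-genotype decay fits
#'
#' A gene is `stable` when its wild-type half-life exceeds
#' `half_life_stable_min`; among unstable genes, it is
#' `unstable_TTP_dependent` when the genotype-interaction p-value is below
#' `alpha` and the knockout half-life exceeds the wild-type half-life, and
#' `unstable_TTP_independent` otherwise.
#'
#' @param fit_wt,fit_ko per-genotype rows from [fit_decay()] for one gene.
#' @param interaction_p p-value from [differential_decay()].
#' @param half_life_stable_min stability threshold in minutes (default 180).
#' @param alpha significance level (default 0.05).
#' @return character class.
#' @export
classify_stability <- function(fit_wt, fit_ko, interaction_p,
                               half_life_stable_min = 180, alpha = 0.05) {
  if (fit_wt$half_life > half_life_stable_min) return("stable")
  if (!is.na(interaction_p) && interaction_p < alpha &&
      fit_ko$half_life > fit_wt$half_life) {
    return("unstable_TTP_dependent")
  }
  "unstable_TTP_independent"
}

#' Stability calls for every gene in a two-genotype series
#'
#' @param expression long-format expression table, both genotypes.
#' @param half_life_stable_min,alpha see [classify_stability()].
#' @param reference_genotype baseline genotype.
#' @return data.frame gene_id, class, half_life_wt, half_life_ko,
#'   delta_slope, p_value.
#' @export
stability_calls <- function(expression, half_life_stable_min = 180,
                            alpha = 0.05, reference_genotype = "WT") {
  fits <- fit_decay(expression)
  out <- list()
  for (g in unique(fits$gene_id)) {
    fw <- fits[fits$gene_id == g & fits$genotype == reference_genotype, ]
    fk <- fits[fits$gene_id == g & fits$genotype != reference_genotype, ]
    if (nrow(fw) != 1L || nrow(fk) != 1L) next
    dd <- differential_decay(
      expression[expression$gene_id == g, , drop = FALSE],
      reference_genotype)
    out[[length(out) + 1L]] <- data.frame(
      gene_id = g,
      class = classify_stability(fw, fk, dd$p_value, half_life_stable_min,
                                 alpha),
      half_life_wt = fw$half_life, half_life_ko = fk$half_life,
      delta_slope = dd$delta_slope, p_value = dd$p_value,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Region-category by stability contingency table
#'
#' Cross-tabulates per-gene binding categories (from [gene_categories()])
#' against stability classes, with per-category fractions.
#'
#' @param calls output of [stability_calls()].
#' @param categories output of [gene_categories()].
#' @return list with `counts` (table) and `fractions` (rows sum to 1).
#' @export
decay_summary <- function(calls, categories) {
  m <- merge(categories, calls, by = "gene_id")
  counts <- table(category = m$category, class = m$class)
  fr <- prop.table(counts, margin = 1)
  list(counts = counts, fractions = fr)
}
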