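# Expression-normalized binding scores.
#
# The normalized score of a gene is its total binding-site area divided by
# its (filtered) expression plus a sparse-data correction:
#   score = area / (FPKM_gene + median_FPKM * alpha)
# FPKM_gene sums the FPKMs of transcript isoforms that contain the site in
# their mature mRNA and pass the FPKM >= 10 filter.

#' Fragments per kilobase per million mapped reads
#'
#' @param counts read counts per feature.
#' @param lengths feature lengths in nt.
#' @param library_size total mapped reads.
#' @return numeric FPKM values.
#' @export
compute_fpkm <- function(counts, lengths, library_size) {
  if (any(lengths <= 0) || library_size <= 0) {
    stop("lengths and library_size must be positive", call. = FALSE)
  }
  counts * 1e9 / (lengths * library_size)
}

# Does transcript tx contain the interval [start, end) within its mature
# (exonic) sequence?  For intronic sites the containment test falls back to
# the transcript span, since intronic sequence is absent from mature mRNA.
tx_contains_site <- function(annotation, tx_id, site, intronic) {
  tx <- annotation$transcripts[annotation$transcripts$tx_id == tx_id, ]
  if (nrow(tx) == 0L || tx$ref != site$ref || tx$strand != site$strand) {
    return(FALSE)
  }
  if (intronic) {
    return(site$start >= tx$start && site$end <= tx$end)
  }
  ex <- annotation$exons[annotation$exons$tx_id == tx_id, , drop = FALSE]
  any(ex$start < site$end & ex$end > site$start)
}

#' Expression of the gene carrying a binding site
#'
#' Sums transcript FPKMs over the isoforms that (a) contain the site in
#' their mature mRNA (transcript span for intronic sites) and (b) pass the
#' minimum-FPKM filter.
#'
#' @param tx_fpkm data.frame with tx_id, gene_id, fpkm.
#' @param site one-row site data.frame with ref, strand, start, end,
#'   gene_id and region.
#' @param annotation a `genome_annotation`.
#' @param min_fpkm transcript filter threshold (default 10).
#' @return FPKM_gene (0 when no isoform qualifies).
#' @export
gene_expression <- function(tx_fpkm, site, annotation, min_fpkm = 10) {
  cand <- tx_fpkm[tx_fpkm$gene_id == site$gene_id &
                    tx_fpkm$fpkm >= min_fpkm, , drop = FALSE]
  if (nrow(cand) == 0L) return(0)
  intronic <- identical(site$region, "intron")
  keep <- vapply(cand$tx_id, function(t)
    tx_contains_site(annotation, t, site, intronic), logical(1))
  sum(cand$fpkm[keep])
}

#' Median transcript FPKM within the analysis scope
#'
#' Midpoint convention for even counts (R's default `median`).
#'
#' @param tx_fpkm data.frame with a `fpkm` column.
#' @param min_fpkm only transcripts at or above this FPKM enter the median.
#' @return median FPKM; `NA` when no transcript qualifies.
#' @export
median_fpkm <- function(tx_fpkm, min_fpkm = 10) {
  v <- tx_fpkm$fpkm[tx_fpkm$fpkm >= min_fpkm]
  if (length(v) == 0L) return(NA_real_)
  median(v)
}

#' Expression-normalized binding score
#'
#' `score = area / (fpkm_gene + median_fpkm * alpha)`.  The denominator
#' correction guards against spuriously high scores for weakly expressed
#' genes; `alpha = 0` reduces the score to a plain area/FPKM ratio.
#'
#' @param area total binding-site area (crosslink events).
#' @param fpkm_gene gene expression (see [gene_expression()]).
#' @param median_fpkm sparse-data correction term.
#' @param alpha correction weight (default 1).
#' @return the score; `NA` with a warning when the denominator is zero.
#' @export
normalized_score <- function(area, fpkm_gene, median_fpkm, alpha = 1) {
  if (any(area < 0) || any(fpkm_gene < 0) || any(median_fpkm < 0) ||
      alpha < 0) {
    stop("score arguments must be non-negative", call. = FALSE)
  }
  den <- fpkm_gene + median_fpkm * alpha
  out <- ifelse(den > 0, area / den, NA_real_)
  if (anyNA(out)) {
    warning("zero denominator: score undefined for ", sum(is.na(out)),
            " gene(s); excluded from downstream correlations")
  }
  out
}

#' Per-gene normalized binding score table
#'
#' Aggregates annotated sites by gene (optionally restricted to one region
#' class, e.g. 3'UTR, matching region-restricted correlation analyses),
#' computes FPKM_gene per gene and the normalized score.
#'
#' @param annotated_sites output of [annotate_sites()] with `area` column.
#' @param tx_fpkm data.frame with tx_id, gene_id, fpkm.
#' @param annotation a `genome_annotation`.
#' @param region optional region class to restrict site areas to.
#' @param min_fpkm transcript filter threshold.
#' @param alpha sparse-data correction weight.
#' @return data.frame gene_id, area, fpkm_gene, score.
#' @export
score_table <- function(annotated_sites, tx_fpkm, annotation,
                        region = NULL, min_fpkm = 10, alpha = 1) {
  s <- annotated_sites[!is.na(annotated_sites$gene_id), , drop = FALSE]
  if (!is.null(region)) s <- s[s$region %in% region, , drop = FALSE]
  med <- median_fpkm(tx_fpkm, min_fpkm)
  genes <- unique(s$gene_id)
  rows <- lapply(genes, function(g) {
    sg <- s[s$gene_id == g, , drop = FALSE]
    fg <- max(vapply(seq_len(nrow(sg)), function(i)
      gene_expression(tx_fpkm, sg[i, ], annotation, min_fpkm), numeric(1)))
    data.frame(gene_id = g, area = sum(sg$area), fpkm_gene = fg,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows) %||%
    data.frame(gene_id = character(), area = numeric(),
               fpkm_gene = numeric())
  res$score <- if (nrow(res) > 0L) {
    normalized_score(res$area, res$fpkm_gene, med, alpha)
  } else numeric(0)
  res
}
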