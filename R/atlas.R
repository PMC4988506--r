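# Cross-protein overlap statistics, correlation analytics, k-mer
# enrichment and the static atlas export.

#' Overlap statistics between two binding-site sets
#'
#' Strand-aware interval intersection: counts per set, the site-level
#' partition (overlapping vs non-overlapping sites and overlapping pairs),
#' the gene-level partition when `gene_id` columns are present, and the
#' coverage of each A site by the union of B sites, in percent.
#'
#' @param sites_a,sites_b site data.frames with ref, strand, start, end
#'   and optionally gene_id.
#' @param min_overlap minimum overlapping nucleotides (default 1).
#' @return list of class `overlap_report`: `n_a`, `n_b`, `a_overlapping`,
#'   `b_overlapping`, `a_only`, `b_only`, `n_pairs`, `genes` (list a_only,
#'   b_only, both) and `coverage_a` (percent per A site).
#' @export
overlap_sites <- function(sites_a, sites_b, min_overlap = 1L) {
  gra <- intervals_to_gr(sites_a)
  grb <- intervals_to_gr(sites_b)
  hits <- GenomicRanges::findOverlaps(gra, grb, minoverlap = min_overlap)
  a_hit <- unique(S4Vectors::queryHits(hits))
  b_hit <- unique(S4Vectors::subjectHits(hits))

  cov_a <- numeric(nrow(sites_a))
  if (nrow(sites_a) > 0L) {
    redb <- GenomicRanges::reduce(grb)
    h <- GenomicRanges::findOverlaps(gra, redb)
    if (length(h) > 0L) {
      w <- IRanges::width(GenomicRanges::pintersect(
        gra[S4Vectors::queryHits(h)], redb[S4Vectors::subjectHits(h)]))
      covered <- tapply(w, S4Vectors::queryHits(h), sum)
      cov_a[as.integer(names(covered))] <- as.numeric(covered)
    }
    cov_a <- 100 * cov_a / (sites_a$end - sites_a$start)
  }

  genes <- NULL
  if ("gene_id" %in% names(sites_a) && "gene_id" %in% names(sites_b)) {
    ga <- unique(stats::na.omit(sites_a$gene_id))
    gb <- unique(stats::na.omit(sites_b$gene_id))
    genes <- list(a_only = setdiff(ga, gb), b_only = setdiff(gb, ga),
                  both = intersect(ga, gb))
  }

  structure(list(
    n_a = nrow(sites_a), n_b = nrow(sites_b),
    a_overlapping = length(a_hit), b_overlapping = length(b_hit),
    a_only = nrow(sites_a) - length(a_hit),
    b_only = nrow(sites_b) - length(b_hit),
    n_pairs = length(hits), genes = genes, coverage_a = cov_a
  ), class = "overlap_report")
}

#' Per-3'UTR site-count distributions and rank test between two proteins
#'
#' Counts 3'UTR sites per targeted gene for each protein and compares the
#' distributions with a two-sample Mann-Whitney U test (exact for small
#' tie-free samples, normal approximation with continuity and tie
#' correction otherwise, as provided by [stats::wilcox.test()]).
#'
#' @param annotated_a,annotated_b outputs of [annotate_sites()].
#' @return list with `counts_a`, `counts_b` (named per-gene counts),
#'   `median_a`, `median_b`, `U` and `p_value`.
#' @export
sites_per_utr <- function(annotated_a, annotated_b) {
  cnt <- function(x) {
    x <- x[!is.na(x$gene_id) & x$region == "utr3", , drop = FALSE]
    if (nrow(x) == 0L) return(integer(0))
    tab <- table(x$gene_id)
    setNames(as.integer(tab), names(tab))
  }
  ca <- cnt(annotated_a)
  cb <- cnt(annotated_b)
  wt <- suppressWarnings(wilcox.test(ca, cb))
  list(counts_a = ca, counts_b = cb,
       median_a = median(ca), median_b = median(cb),
       U = unname(wt$statistic), p_value = wt$p.value)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Pairs with missing values in either variable are excluded listwise.
#'
#' @param x,y numeric vectors.
#' @param conf_level confidence level (default 0.95).
#' @return list of class `correlation_report`: `r`, `ci` (length 2), `p_value`,
#'   `n`.
#' @export
correlate <- function(x, y, conf_level = 0.95) {
  ok <- complete.cases(x, y)
  ct <- cor.test(x[ok], y[ok], method = "pearson",
                 conf.level = conf_level)
  structure(list(r = unname(ct$estimate),
                 ci = as.numeric(ct$conf.int),
                 p_value = ct$p.value, n = sum(ok)),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("Pearson's r = %.3f, 95%% CI [%.3f, %.3f], p = %.3g, n = %d\n",
              x$r, x$ci[1], x$ci[2], x$p_value, x$n))
  invisible(x)
}

#' k-mer enrichment of site sequences against an element background
#'
#' Counts all k-mers in the site sequences and compares each observed count
#' with its expectation under a 0-order background estimated from the given
#' element sequences (introns or 3'UTRs).  P-values are binomial upper
#' tails over the number of k-mer windows, Benjamini-Hochberg corrected
#' across all tested k-mers.
#'
#' @param site_seqs character vector of site sequences (DNA or RNA).
#' @param background_seqs character vector of background element sequences.
#' @param k k-mer sizes (default 5:7).
#' @return data.frame kmer (RNA alphabet), k, observed, expected, p_value,
#'   padj, sorted by p-value; zero rows for an empty site set.
#' @export
kmer_enrichment <- function(site_seqs, background_seqs, k = 5:7) {
  empty <- data.frame(kmer = character(), k = integer(),
                      observed = integer(), expected = numeric(),
                      p_value = numeric(), padj = numeric(),
                      stringsAsFactors = FALSE)
  site_seqs <- site_seqs[nchar(site_seqs) > 0]
  if (length(site_seqs) == 0L) return(empty)
  dna <- function(x) Biostrings::DNAStringSet(chartr("Uu", "Tt", toupper(x)))
  sites <- dna(site_seqs)
  bg <- dna(background_seqs)
  base_freq <- colSums(Biostrings::oligonucleotideFrequency(bg, 1L))
  base_p <- base_freq / sum(base_freq)

  out <- list()
  for (kk in k) {
    use <- sites[Biostrings::width(sites) >= kk]
    if (length(use) == 0L) next
    counts <- colSums(Biostrings::oligonucleotideFrequency(use, kk))
    n_win <- sum(Biostrings::width(use) - kk + 1L)
    kmers <- names(counts)
    p_kmer <- vapply(strsplit(kmers, ""), function(b)
      prod(base_p[b]), numeric(1))
    pv <- pbinom(counts - 1L, n_win, p_kmer, lower.tail = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      kmer = chartr("T", "U", kmers), k = kk,
      observed = as.integer(counts), expected = n_win * p_kmer,
      p_value = pv, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty)
  res$padj <- p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value, -res$observed, res$kmer), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Naive differential expression between genotypes at baseline
#'
#' Median-of-ratios normalization across baseline samples followed by the
#' per-gene mean log2 fold change (non-reference over reference genotype)
#' at the first timepoint.  Intended as the built-in stand-in for an
#' external differential-expression table.
#'
#' @param expression long-format expression table (see [fit_decay()]).
#' @param reference_genotype baseline genotype (default "WT").
#' @param pseudocount added before log2.
#' @return data.frame gene_id, log2fc.
#' @export
differential_expression <- function(expression, reference_genotype = "WT",
                                    pseudocount = 0.1) {
  expr <- aggregate_gene_fpkm(expression)
  t0 <- min(expr$actd_min)
  expr <- expr[expr$actd_min == t0, , drop = FALSE]
  expr$sample <- paste(expr$genotype, expr$replicate %||% 1L, sep = "_")
  wide <- stats::reshape(expr[, c("gene_id", "sample", "fpkm")],
                         idvar = "gene_id", timevar = "sample",
                         direction = "wide")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$gene_id
  # median-of-ratios size factors over genes expressed in all samples
  lg <- log(m + pseudocount)
  ref <- rowMeans(lg)
  sf <- exp(apply(lg - ref, 2L, median))
  m <- sweep(m, 2L, sf, "/")
  is_ref <- grepl(paste0("^fpkm\\.", reference_genotype, "_"), colnames(m))
  l2 <- log2(m + pseudocount)
  data.frame(gene_id = rownames(m),
             log2fc = rowMeans(l2[, !is_ref, drop = FALSE]) -
               rowMeans(l2[, is_ref, drop = FALSE]),
             stringsAsFactors = FALSE)
}

#' Distinct gene count of the packaged overlapping-targets fixture
#'
#' Reads the packaged table of genes whose 3'UTRs carry overlapping TTP and
#' HuR binding sites, normalizes whitespace and case, and counts distinct
#' symbols.
#'
#' @param path fixture path; defaults to the packaged table.
#' @return integer count of distinct gene symbols.
#' @export
table2_gene_count <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table2_overlap_genes.tsv",
                        package = "rbpatlas")
  }
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0L && tolower(lines[1]) == "gene_symbol") {
    lines <- lines[-1]
  }
  length(unique(toupper(lines)))
}

#' Assemble and export the binding-site atlas
#'
#' Joins annotated consensus sites, normalized scores, stability calls and
#' differential expression into one record per gene, and writes a
#' deterministic static bundle: atlas TSV, site BED and per-strand
#' crosslink bedGraph tracks.
#'
#' @param annotated_sites annotated consensus sites with `area`, `summit`,
#'   `height`.
#' @param scores output of [score_table()].
#' @param calls output of [stability_calls()].
#' @param diffexpr output of [differential_expression()].
#' @param profile a `crosslink_profile` for the signal tracks.
#' @param out_dir output directory (created if missing).
#' @param include_empty also emit stub records for genes without sites.
#' @return list with `records` (data.frame) and `paths`.
#' @export
build_atlas <- function(annotated_sites, scores, calls, diffexpr, profile,
                        out_dir, include_empty = FALSE) {
  s <- annotated_sites[!is.na(annotated_sites$gene_id), , drop = FALSE]
  genes <- sort(unique(s$gene_id))
  if (include_empty) {
    genes <- sort(unique(c(genes, calls$gene_id)))
  }
  rows <- lapply(genes, function(g) {
    sg <- s[s$gene_id == g, , drop = FALSE]
    sc <- scores[scores$gene_id == g, , drop = FALSE]
    cl <- calls[calls$gene_id == g, , drop = FALSE]
    de <- diffexpr[diffexpr$gene_id == g, , drop = FALSE]
    data.frame(
      gene_id = g, n_sites = nrow(sg),
      regions = paste(sort(unique(sg$region)), collapse = ","),
      total_area = if (nrow(sg)) sum(sg$area) else 0,
      max_height = if (nrow(sg)) max(sg$height) else 0,
      score = if (nrow(sc)) sc$score else NA_real_,
      stability_class = if (nrow(cl)) cl$class else NA_character_,
      half_life_wt = if (nrow(cl)) cl$half_life_wt else NA_real_,
      half_life_ko = if (nrow(cl)) cl$half_life_ko else NA_real_,
      delta_slope = if (nrow(cl)) cl$delta_slope else NA_real_,
      log2fc = if (nrow(de)) de$log2fc else NA_real_,
      stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, rows) %||% data.frame(gene_id = character())

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    atlas = file.path(out_dir, "atlas.tsv"),
    sites = file.path(out_dir, "sites.bed")
  )
  write_tsv(records, paths[["atlas"]])
  write_bed(s[order(s$ref, s$start), , drop = FALSE], paths[["sites"]])
  bg <- write_bedgraph(profile, file.path(out_dir, "crosslinks"))
  paths <- c(paths, setNames(bg, c("bedgraph_plus", "bedgraph_minus")))
  list(records = records, paths = paths)
}
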