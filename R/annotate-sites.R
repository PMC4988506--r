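# Exon-first region classification of binding sites.

gene_exon_union <- function(annotation, gene_id) {
  ex <- annotation$exons[annotation$exons$gene_id == gene_id, , drop = FALSE]
  if (nrow(ex) == 0L) return(NULL)
  GenomicRanges::reduce(intervals_to_gr(ex))
}

overlap_bases <- function(gr1, gr2) {
  if (is.null(gr2) || length(gr2) == 0L) return(0L)
  sum(IRanges::width(GenomicRanges::intersect(gr1, gr2,
                                              ignore.strand = FALSE)))
}

#' Classify one binding site into a transcript region
#'
#' Applies the exon-first rule across all isoforms of the assigned gene: a
#' site is exonic if it overlaps an exon of at least one isoform, and
#' intronic only if it overlaps no exon of any isoform.  Exonic sites are
#' sub-classified with priority 3'UTR > 5'UTR > CDS over the features their
#' bases overlap.  Strand-mismatched overlaps are never assigned; a site
#' overlapping no gene is intergenic.
#'
#' @param site one-row data.frame (or list) with ref, strand, start, end.
#' @param annotation a `genome_annotation`.
#' @return data.frame with gene_id, region (`utr5`, `cds`, `utr3`,
#'   `intron`, `intergenic` or `mixed`), overlap (bases in gene), and flags
#'   `multi_gene` (ambiguous tie, one row per tied gene) and
#'   `straddles_exon_boundary`.
#' @export
classify_region <- function(site, annotation) {
  sgr <- GenomicRanges::GRanges(
    site$ref, IRanges::IRanges(site$start + 1L, site$end), site$strand)
  gn <- annotation$genes
  cand <- gn[gn$ref == site$ref & gn$strand == site$strand &
               gn$start < site$end & gn$end > site$start, , drop = FALSE]
  if (nrow(cand) == 0L) {
    return(data.frame(gene_id = NA_character_, region = "intergenic",
                      overlap = 0L, multi_gene = FALSE,
                      straddles_exon_boundary = FALSE,
                      stringsAsFactors = FALSE))
  }
  ov <- pmin(site$end, cand$end) - pmax(site$start, cand$start)
  best <- which(ov == max(ov))
  rows <- lapply(best, function(b) {
    g <- cand$gene_id[b]
    exu <- gene_exon_union(annotation, g)
    ex_ov <- overlap_bases(sgr, exu)
    width <- site$end - site$start
    if (ex_ov == 0L) {
      region <- "intron"
      straddle <- FALSE
    } else {
      fe <- annotation$features[annotation$features$gene_id == g, ,
                                drop = FALSE]
      sub_ov <- vapply(c("utr3", "utr5", "cds"), function(tp) {
        f <- fe[fe$type == tp, , drop = FALSE]
        if (nrow(f) == 0L) return(0L)
        overlap_bases(sgr, intervals_to_gr(f))
      }, numeric(1))
      region <- if (sub_ov[["utr3"]] > 0) "utr3"
        else if (sub_ov[["utr5"]] > 0) "utr5"
        else if (sub_ov[["cds"]] > 0) "cds"
        else "mixed"
      straddle <- ex_ov < width
    }
    data.frame(gene_id = g, region = region, overlap = ov[b],
               multi_gene = length(best) > 1L,
               straddles_exon_boundary = straddle, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Annotate a table of binding sites
#'
#' Runs [classify_region()] over every site and appends gene and region
#' columns.  Sites tied between two genes are reported once per gene with
#' `multi_gene = TRUE`.
#'
#' @param sites binding-site data.frame with ref, strand, start, end.
#' @param annotation a `genome_annotation`.
#' @param exclude_heterogeneous drop sites in genes whose annotation mixes
#'   3'UTR and intron across isoforms (see [heterogeneous_genes()]).
#' @return annotated site data.frame.
#' @export
annotate_sites <- function(sites, annotation, exclude_heterogeneous = FALSE) {
  out <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    cl <- classify_region(sites[i, ], annotation)
    base <- sites[rep(i, nrow(cl)), , drop = FALSE]
    base$gene_id <- NULL
    out[[i]] <- cbind(base, cl, row.names = NULL)
  }
  res <- do.call(rbind, out)
  if (exclude_heterogeneous) {
    het <- heterogeneous_genes(annotation)
    res <- res[is.na(res$gene_id) | !(res$gene_id %in% het), , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

#' Genes whose isoforms annotate the same bases as both 3'UTR and intron
#'
#' Mirrors the exclusion used in cross-protein overlap analyses: genes
#' containing genomic intervals that are a 3'UTR in one transcript and
#' intronic in another are ambiguous for 3'UTR-restricted comparisons.
#'
#' @param annotation a `genome_annotation`.
#' @return character vector of gene identifiers.
#' @export
heterogeneous_genes <- function(annotation) {
  introns <- introns_of(annotation)
  u3 <- annotation$features[annotation$features$type == "utr3", ,
                            drop = FALSE]
  out <- character(0)
  for (g in unique(annotation$genes$gene_id)) {
    ug <- u3[u3$gene_id == g, , drop = FALSE]
    ig <- introns[introns$gene_id == g, , drop = FALSE]
    if (nrow(ug) == 0L || nrow(ig) == 0L) next
    # 3'UTR of one isoform vs introns of *other* isoforms
    hit <- FALSE
    for (t in unique(ug$tx_id)) {
      u <- ug[ug$tx_id == t, , drop = FALSE]
      io <- ig[ig$tx_id != t, , drop = FALSE]
      if (nrow(io) == 0L) next
      if (overlap_bases(intervals_to_gr(u), intervals_to_gr(io)) > 0L) {
        hit <- TRUE
        break
      }
    }
    if (hit) out <- c(out, g)
  }
  out
}

#' Per-gene binding category from annotated sites
#'
#' @param annotated_sites output of [annotate_sites()].
#' @return data.frame gene_id, category in `utr3_only`, `intron_only`,
#'   `both`, `other`; plus an attribute-free count table is obtainable with
#'   `table(x$category)`.
#' @export
gene_categories <- function(annotated_sites) {
  s <- annotated_sites[!is.na(annotated_sites$gene_id), , drop = FALSE]
  genes <- unique(s$gene_id)
  cat <- vapply(genes, function(g) {
    rg <- s$region[s$gene_id == g]
    has3 <- "utr3" %in% rg
    hasi <- "intron" %in% rg
    if (has3 && hasi) "both"
    else if (has3) "utr3_only"
    else if (hasi) "intron_only"
    else "other"
  }, character(1))
  data.frame(gene_id = genes, category = unname(cat),
             stringsAsFactors = FALSE)
}

#' Write binding sites as BED6
#'
#' 0-based half-open intervals; name is `gene|index`, score is the summit
#' height capped at 1000.
#'
#' @param sites site data.frame with ref, strand, start, end and optionally
#'   gene_id, height.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(sites, path) {
  gene <- if ("gene_id" %in% names(sites)) sites$gene_id else "site"
  gene[is.na(gene)] <- "NA"
  score <- if ("height" %in% names(sites)) pmin(1000, round(sites$height))
    else rep(0L, nrow(sites))
  lines <- sprintf("%s\t%d\t%d\t%s|%d\t%d\t%s", sites$ref, sites$start,
                   sites$end, gene, seq_len(nrow(sites)), score,
                   sites$strand)
  writeLines(lines, path)
  invisible(path)
}
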