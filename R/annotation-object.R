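# The genome_annotation container: genes -> transcripts -> features.
# All coordinates are stored 0-based half-open; GTF I/O converts to and from
# the 1-based closed convention on the fly.

new_genome_annotation <- function(genes, transcripts, exons, features) {
  ann <- list(genes = genes, transcripts = transcripts, exons = exons,
              features = features)
  class(ann) <- "genome_annotation"
  validate_genome_annotation(ann)
  ann
}

validate_genome_annotation <- function(ann) {
  ex <- ann$exons
  tx <- ann$transcripts
  gn <- ann$genes
  if (any(ex$start >= ex$end) || any(tx$start >= tx$end) ||
      any(gn$start >= gn$end)) {
    stop("annotation contains empty or inverted intervals", call. = FALSE)
  }
  txi <- match(ex$tx_id, tx$tx_id)
  if (anyNA(txi) || any(ex$start < tx$start[txi]) ||
      any(ex$end > tx$end[txi])) {
    stop("exon not contained in its transcript span", call. = FALSE)
  }
  gni <- match(tx$gene_id, gn$gene_id)
  if (anyNA(gni) || any(tx$start < gn$start[gni]) ||
      any(tx$end > gn$end[gni])) {
    stop("transcript not contained in its gene span", call. = FALSE)
  }
  invisible(ann)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d genes, %d transcripts, %d exons\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons)))
  invisible(x)
}

#' Derive introns as gaps between consecutive exons of each transcript
#'
#' @param annotation a `genome_annotation`.
#' @return data.frame with columns tx_id, gene_id, ref, strand, start, end
#'   (0-based half-open); transcripts with a single exon contribute no rows.
#' @export
introns_of <- function(annotation) {
  ex <- annotation$exons
  out <- vector("list", nrow(annotation$transcripts))
  for (i in seq_len(nrow(annotation$transcripts))) {
    t <- annotation$transcripts[i, ]
    e <- ex[ex$tx_id == t$tx_id, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) < 2L) next
    out[[i]] <- data.frame(
      tx_id = t$tx_id, gene_id = t$gene_id, ref = t$ref, strand = t$strand,
      start = e$end[-nrow(e)], end = e$start[-1],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(tx_id = character(), gene_id = character(),
                      ref = character(), strand = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  }
  res
}

gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0(key, ' "([^"]*)"'), attrs))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
         character(1))
}

#' Read a GTF file into a `genome_annotation`
#'
#' Accepts ENSEMBL-style GTF with `exon`, `CDS`, `five_prime_utr` and
#' `three_prime_utr` features carrying `gene_id`/`transcript_id` attributes.
#' Gene and transcript spans are taken from `gene`/`transcript` lines when
#' present, otherwise derived as exon envelopes.  1-based closed GTF
#' coordinates are converted to the internal 0-based half-open convention;
#' the conversion is exactly invertible (see [write_gtf()]).
#'
#' @param path GTF file path.
#' @return a `genome_annotation`.
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- idx[which(nf != 9L)[1]]
    stop(sprintf("malformed GTF line %d: expected 9 tab-separated fields, got %d",
                 bad, nf[which(nf != 9L)[1]]), call. = FALSE)
  }
  m <- do.call(rbind, fields)
  starts <- suppressWarnings(as.integer(m[, 4]))
  ends <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(starts) || anyNA(ends)) {
    bad <- idx[which(is.na(starts) | is.na(ends))[1]]
    stop(sprintf("malformed GTF line %d: non-numeric coordinates", bad),
         call. = FALSE)
  }
  df <- data.frame(
    ref = m[, 1], type = m[, 3],
    start = starts - 1L, end = ends,   # to 0-based half-open
    strand = m[, 7], attrs = m[, 9],
    stringsAsFactors = FALSE
  )
  df$gene_id <- gtf_attr(df$attrs, "gene_id")
  df$tx_id <- gtf_attr(df$attrs, "transcript_id")

  type_map <- c(exon = "exon", CDS = "cds", five_prime_utr = "utr5",
                three_prime_utr = "utr3", `5UTR` = "utr5", `3UTR` = "utr3")

  ex <- df[df$type == "exon", , drop = FALSE]
  feat_rows <- df[df$type %in% c("CDS", "five_prime_utr", "three_prime_utr",
                                 "5UTR", "3UTR"), , drop = FALSE]

  tx_rows <- df[df$type == "transcript", , drop = FALSE]
  if (nrow(tx_rows) == 0L) {
    sp <- split(ex, ex$tx_id)
    tx_rows <- do.call(rbind, lapply(sp, function(e) {
      data.frame(ref = e$ref[1], start = min(e$start), end = max(e$end),
                 strand = e$strand[1], gene_id = e$gene_id[1],
                 tx_id = e$tx_id[1], stringsAsFactors = FALSE)
    }))
  }
  gene_rows <- df[df$type == "gene", , drop = FALSE]
  if (nrow(gene_rows) == 0L) {
    sp <- split(tx_rows, tx_rows$gene_id)
    gene_rows <- do.call(rbind, lapply(sp, function(t) {
      data.frame(ref = t$ref[1], start = min(t$start), end = max(t$end),
                 strand = t$strand[1], gene_id = t$gene_id[1],
                 stringsAsFactors = FALSE)
    }))
  }

  genes <- data.frame(gene_id = gene_rows$gene_id, ref = gene_rows$ref,
                      strand = gene_rows$strand, start = gene_rows$start,
                      end = gene_rows$end, stringsAsFactors = FALSE)
  transcripts <- data.frame(tx_id = tx_rows$tx_id, gene_id = tx_rows$gene_id,
                            ref = tx_rows$ref, strand = tx_rows$strand,
                            start = tx_rows$start, end = tx_rows$end,
                            stringsAsFactors = FALSE)
  exons <- data.frame(tx_id = ex$tx_id, gene_id = ex$gene_id, ref = ex$ref,
                      strand = ex$strand, start = ex$start, end = ex$end,
                      stringsAsFactors = FALSE)
  features <- data.frame(tx_id = feat_rows$tx_id, gene_id = feat_rows$gene_id,
                         ref = feat_rows$ref, strand = feat_rows$strand,
                         type = unname(type_map[feat_rows$type]),
                         start = feat_rows$start, end = feat_rows$end,
                         stringsAsFactors = FALSE)
  genes <- genes[order(genes$ref, genes$start, genes$gene_id), ,
                 drop = FALSE]
  rownames(genes) <- rownames(transcripts) <- rownames(exons) <-
    rownames(features) <- NULL
  new_genome_annotation(genes, transcripts, exons, features)
}

#' Write a `genome_annotation` as GTF
#'
#' Internal 0-based half-open coordinates are emitted as GTF 1-based closed;
#' [read_gtf()] recovers the annotation exactly.
#'
#' @param annotation a `genome_annotation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  rev_map <- c(exon = "exon", cds = "CDS", utr5 = "five_prime_utr",
               utr3 = "three_prime_utr")
  fmt <- function(ref, type, start, end, strand, attrs) {
    sprintf("%s\trbpatlas\t%s\t%d\t%d\t.\t%s\t.\t%s",
            ref, type, start + 1L, end, strand, attrs)
  }
  lines <- character(0)
  for (i in seq_len(nrow(annotation$genes))) {
    g <- annotation$genes[i, ]
    lines <- c(lines, fmt(g$ref, "gene", g$start, g$end, g$strand,
                          sprintf('gene_id "%s";', g$gene_id)))
    txs <- annotation$transcripts[annotation$transcripts$gene_id == g$gene_id, ,
                                  drop = FALSE]
    for (j in seq_len(nrow(txs))) {
      t <- txs[j, ]
      at <- sprintf('gene_id "%s"; transcript_id "%s";', g$gene_id, t$tx_id)
      lines <- c(lines, fmt(t$ref, "transcript", t$start, t$end, t$strand, at))
      ex <- annotation$exons[annotation$exons$tx_id == t$tx_id, ,
                             drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      for (k in seq_len(nrow(ex))) {
        lines <- c(lines, fmt(ex$ref[k], "exon", ex$start[k], ex$end[k],
                              t$strand, at))
      }
      fe <- annotation$features[annotation$features$tx_id == t$tx_id, ,
                                drop = FALSE]
      fe <- fe[order(fe$start), , drop = FALSE]
      for (k in seq_len(nrow(fe))) {
        lines <- c(lines, fmt(fe$ref[k], rev_map[[fe$type[k]]], fe$start[k],
                              fe$end[k], t$strand, at))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
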