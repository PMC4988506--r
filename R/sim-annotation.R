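# Synthetic genome and annotation generator.

rand_len <- function(rng, n = 1L) {
  if (rng[1] == rng[2]) rep(rng[1], n) else sample(rng[1]:rng[2], n,
                                                   replace = TRUE)
}

#' Generate a synthetic multi-isoform annotation and matching genome
#'
#' Lays `n_genes` three-exon genes along one synthetic chromosome,
#' alternating strands, each with a 5'UTR, CDS split over the exons and a
#' 3'UTR.  Two-isoform genes add a second isoform that skips the middle
#' exon, so the skipped region is exonic in one isoform and intronic in the
#' other.  The chromosome sequence is drawn from `config$base_probs` and is
#' consistent with all feature coordinates.  All draws derive from
#' `config$seed`; repeated calls are byte-identical.
#'
#' @param config a [sim_config()].
#' @return list with elements `annotation` (a `genome_annotation`) and
#'   `reference` (named character vector of chromosome sequences).
#' @export
make_annotation <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, make_annotation_impl(config))
}

make_annotation_impl <- function(config) {
  margin <- config$read_length + 50L
  cursor <- margin
  genes <- transcripts <- exons <- features <- list()

  for (g in seq_len(config$n_genes)) {
    gene_id <- sprintf("g%03d", g)
    strand <- if (g %% 2L == 1L) "+" else "-"
    n_iso <- rand_len(config$n_isoforms_per_gene)

    # segment lengths in transcript order: utr5, cds1, i1, cds2, i2, cds3, utr3
    u5 <- rand_len(config$utr5_len)
    cds <- rand_len(config$cds_exon_len, 3L)
    itr <- rand_len(config$intron_len, 2L)
    u3 <- rand_len(config$utr3_len)
    seg_len <- c(u5, cds[1], itr[1], cds[2], itr[2], cds[3], u3)
    seg_type <- c("utr5", "cds", "intron", "cds", "intron", "cds", "utr3")
    if (strand == "-") {             # transcript runs right-to-left
      seg_len <- rev(seg_len)
      seg_type <- rev(seg_type)
    }
    seg_end <- cursor + cumsum(seg_len)
    seg_start <- c(cursor, seg_end[-length(seg_end)])
    gstart <- cursor
    gend <- seg_end[length(seg_end)]
    cursor <- gend + config$intergenic_gap

    seg <- data.frame(start = seg_start, end = seg_end, type = seg_type,
                      stringsAsFactors = FALSE)

    genes[[g]] <- data.frame(gene_id = gene_id, ref = "chr1", strand = strand,
                             start = gstart, end = gend,
                             stringsAsFactors = FALSE)

    add_tx <- function(tx_id, keep_middle) {
      seg_k <- seg
      if (!keep_middle) {
        # middle CDS exon becomes intronic for this isoform
        mid <- which(seg_k$type == "cds")[2]
        seg_k$type[mid] <- "intron"
      }
      ex_k <- seg_k[seg_k$type != "intron", , drop = FALSE]
      ex_iv <- merge_adjacent(ex_k$start, ex_k$end)
      transcripts[[length(transcripts) + 1L]] <<- data.frame(
        tx_id = tx_id, gene_id = gene_id, ref = "chr1", strand = strand,
        start = gstart, end = gend, stringsAsFactors = FALSE)
      exons[[length(exons) + 1L]] <<- data.frame(
        tx_id = tx_id, gene_id = gene_id, ref = "chr1", strand = strand,
        start = ex_iv$start, end = ex_iv$end, stringsAsFactors = FALSE)
      features[[length(features) + 1L]] <<- data.frame(
        tx_id = tx_id, gene_id = gene_id, ref = "chr1", strand = strand,
        type = ex_k$type, start = ex_k$start, end = ex_k$end,
        stringsAsFactors = FALSE)
    }
    add_tx(paste0(gene_id, ".t1"), keep_middle = TRUE)
    if (n_iso >= 2L) add_tx(paste0(gene_id, ".t2"), keep_middle = FALSE)
  }

  chrom_len <- cursor + margin
  bases <- names(config$base_probs)
  seqv <- sample(bases, chrom_len, replace = TRUE, prob = config$base_probs)
  reference <- c(chr1 = paste(seqv, collapse = ""))

  ann <- new_genome_annotation(
    do.call(rbind, genes), do.call(rbind, transcripts),
    do.call(rbind, exons), do.call(rbind, features)
  )
  list(annotation = ann, reference = reference)
}

# Merge intervals that touch end-to-start (inputs sorted, non-overlapping).
merge_adjacent <- function(start, end) {
  ks <- ke <- integer(0)
  for (i in seq_along(start)) {
    if (length(ks) > 0L && start[i] == ke[length(ke)]) {
      ke[length(ke)] <- end[i]
    } else {
      ks <- c(ks, start[i]); ke <- c(ke, end[i])
    }
  }
  data.frame(start = ks, end = ke)
}

#' Write reference sequences as FASTA
#'
#' @param reference named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reference, path) {
  dss <- Biostrings::DNAStringSet(reference)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  out <- as.character(dss)
  names(out) <- sub("\\s.*$", "", names(dss))
  out
}
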