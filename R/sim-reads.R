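# PAR-iCLIP read simulation from planted truth.
#
# Crosslink chemistry: a crosslink event at template-strand position x either
# truncates reverse transcription, so the read's 5' end starts 1 nt
# downstream of x in transcript orientation, or reads through, leaving a
# T-to-C transition at x with probability p_tc.  Only template-strand T
# (transcribed U) positions are ever crosslinked.  The planted summit height
# is realized as the exact number of truncation events at the summit U;
# read-through events are added at rate (1 - p_trunc) / p_trunc on top, so
# the realized truncation fraction matches p_trunc.

#' Simulate PAR-iCLIP alignments from planted truth
#'
#' Generates one replicate of crosslink-derived and background reads as an
#' alignment table in the canonical tab dialect (columns `ref`, `strand`,
#' `start`, `end` 0-based half-open, and `subs` as comma-separated
#' `pos:ref>alt` in genome space, `.` when none).
#'
#' @param truth a `planted_truth` from [plant_sites()].
#' @param annotation the matching `genome_annotation`.
#' @param config a [sim_config()].
#' @param replicate integer replicate index; each replicate draws from an
#'   independent seeded substream of `config$seed`.
#' @return data.frame of alignments, deterministically ordered.
#' @export
simulate_clip_reads <- function(truth, annotation, config, replicate = 1L) {
  validate_sim_config(config)
  with_seed(config$seed + 1000L * as.integer(replicate) + 3L,
            simulate_clip_reads_impl(truth, annotation, config))
}

simulate_clip_reads_impl <- function(truth, annotation, config) {
  rl <- config$read_length
  p_trunc <- config$p_trunc
  p_tc <- config$p_tc
  out <- list()

  add <- function(ref, strand, start, end, subs) {
    out[[length(out) + 1L]] <<- data.frame(
      ref = ref, strand = strand, start = as.integer(start),
      end = as.integer(end), subs = subs, stringsAsFactors = FALSE)
  }

  sites <- truth$sites
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    h <- s$summit_height
    # crosslinkable Us at motif offsets 2, 3, 4 (transcript sense); counts
    # shape a summit with two shoulders
    offs <- c(2L, 3L, 4L)
    counts <- c(round(0.25 * h), h, round(0.10 * h))
    for (k in seq_along(offs)) {
      x <- if (s$strand == "+") s$start + offs[k] else s$end - 1L - offs[k]
      n <- counts[k]
      if (n <= 0) next
      n_trunc <- if (p_trunc > 0) n else 0L
      n_rt <- if (p_trunc > 0) round(n * (1 - p_trunc) / p_trunc) else n
      if (n_trunc > 0) {
        if (s$strand == "+") {
          add(s$ref, "+", rep(x + 1L, n_trunc), rep(x + 1L + rl, n_trunc),
              rep(".", n_trunc))
        } else {
          add(s$ref, "-", rep(x - rl, n_trunc), rep(x, n_trunc),
              rep(".", n_trunc))
        }
      }
      if (n_rt > 0) {
        d <- sample(5:(rl - 6L), n_rt, replace = TRUE)
        has_tc <- runif(n_rt) < p_tc
        if (s$strand == "+") {
          st <- x - d
          sub <- ifelse(has_tc, sprintf("%d:T>C", x), ".")
          add(s$ref, "+", st, st + rl, sub)
        } else {
          e5 <- x + d                      # 5' end (highest coordinate)
          sub <- ifelse(has_tc, sprintf("%d:A>G", x), ".")
          add(s$ref, "-", e5 - rl + 1L, e5 + 1L, sub)
        }
      }
    }
  }

  # uniform background reads per gene (no crosslink chemistry)
  if (config$background_rate > 0) {
    gn <- annotation$genes
    for (i in seq_len(nrow(gn))) {
      g <- gn[i, ]
      n_bg <- rpois(1L, config$background_rate * (g$end - g$start))
      if (n_bg == 0L) next
      p5 <- g$start + sample.int(g$end - g$start, n_bg, replace = TRUE) - 1L
      if (g$strand == "+") {
        add(g$ref, "+", p5, p5 + rl, rep(".", n_bg))
      } else {
        add(g$ref, "-", p5 - rl + 1L, p5 + 1L, rep(".", n_bg))
      }
    }
  }

  if (length(out) == 0L) {
    return(data.frame(ref = character(), strand = character(),
                      start = integer(), end = integer(), subs = character(),
                      stringsAsFactors = FALSE))
  }
  aln <- do.call(rbind, out)
  aln <- aln[aln$start >= 0L, , drop = FALSE]
  aln <- aln[order(aln$ref, aln$strand, aln$start, aln$end, aln$subs), ,
             drop = FALSE]
  rownames(aln) <- NULL
  aln
}

#' Write alignments in the canonical tab dialect
#'
#' @param alignments alignment data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(alignments, path) {
  write_tsv(alignments, path)
}

#' Read alignments from the canonical tab dialect
#'
#' @param path file with columns `ref`, `strand`, `start`, `end`, `subs`.
#' @return alignment data.frame.
#' @export
read_alignments <- function(path) {
  aln <- read_tsv(path)
  need <- c("ref", "strand", "start", "end", "subs")
  if (!all(need %in% names(aln))) {
    stop("alignment file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  aln$subs <- as.character(aln$subs)
  aln$subs[is.na(aln$subs) | aln$subs == ""] <- "."
  aln
}

#' Write alignments as minimal SAM
#'
#' Optional interoperability export; the tab dialect remains the canonical
#' exchange format.  Sequences are reconstructed from the reference with the
#' recorded substitutions applied, CIGAR is full-length match.
#'
#' @param alignments alignment data.frame.
#' @param reference named character vector of chromosome sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, reference, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(reference),
                   nchar(reference)))
  recs <- character(nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    a <- alignments[i, ]
    len <- a$end - a$start
    seq <- substr(reference[[a$ref]], a$start + 1L, a$end)
    if (a$subs != ".") {
      for (s in strsplit(a$subs, ",", fixed = TRUE)[[1]]) {
        m <- regmatches(s, regexec("^(\\d+):([ACGTN])>([ACGTN])$", s))[[1]]
        off <- as.integer(m[2]) - a$start
        substr(seq, off + 1L, off + 1L) <- m[4]
      }
    }
    flag <- if (a$strand == "-") 16L else 0L
    recs[i] <- sprintf("r%06d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                       i, flag, a$ref, a$start + 1L, len, seq)
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}
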