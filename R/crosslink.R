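# Crosslink-event extraction and PAR-iCLIP QC diagnostics.

new_crosslink_profile <- function(events, total, n_rejected) {
  structure(list(events = events, total = total, n_rejected = n_rejected),
            class = "crosslink_profile")
}

#' @export
print.crosslink_profile <- function(x, ...) {
  cat(sprintf("crosslink_profile: %d loci, %d events (%d reads rejected)\n",
              nrow(x$events), x$total, x$n_rejected))
  invisible(x)
}

#' Extract crosslink events ("position 0") from alignments
#'
#' Position 0 is the genomic position one nucleotide upstream, in transcript
#' orientation, of a read's 5' end: for a plus-strand read starting at
#' genomic `s` the event falls at `s - 1`; for a minus-strand read with
#' half-open end `e` (whose 5'-most base is `e - 1`) it falls at `e`.
#' Events at negative coordinates are dropped with a warning; reads with an
#' unknown strand are rejected and counted.
#'
#' @param alignments alignment data.frame (see [read_alignments()]).
#' @return a `crosslink_profile`: sparse per-(ref, strand, pos) event counts
#'   plus the total accepted event count and the number of rejected reads.
#' @export
extract_crosslinks <- function(alignments) {
  ok <- alignments$strand %in% c("+", "-")
  n_rejected <- sum(!ok)
  aln <- alignments[ok, , drop = FALSE]
  if (nrow(aln) == 0L) {
    ev <- data.frame(ref = character(), strand = character(),
                     pos = integer(), count = integer(),
                     stringsAsFactors = FALSE)
    return(new_crosslink_profile(ev, 0L, n_rejected))
  }
  pos <- ifelse(aln$strand == "+", aln$start - 1L, aln$end)
  neg <- pos < 0L
  if (any(neg)) {
    warning(sum(neg), " crosslink event(s) at negative coordinates dropped")
    aln <- aln[!neg, , drop = FALSE]
    pos <- pos[!neg]
  }
  if (nrow(aln) == 0L) {
    ev <- data.frame(ref = character(), strand = character(),
                     pos = integer(), count = integer(),
                     stringsAsFactors = FALSE)
    return(new_crosslink_profile(ev, 0L, n_rejected))
  }
  key <- paste(aln$ref, aln$strand, pos, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  ev <- data.frame(
    ref = vapply(parts, `[`, character(1), 1L),
    strand = vapply(parts, `[`, character(1), 2L),
    pos = as.integer(vapply(parts, `[`, character(1), 3L)),
    count = as.integer(tab),
    stringsAsFactors = FALSE
  )
  ev <- ev[order(ev$ref, ev$strand, ev$pos), , drop = FALSE]
  rownames(ev) <- NULL
  new_crosslink_profile(ev, sum(ev$count), n_rejected)
}

#' Count T-to-C transitions at template-T positions
#'
#' Strand-aware: a diagnostic transition is `T>C` in genome space on
#' plus-strand reads and `A>G` in genome space on minus-strand reads (both
#' are T-to-C on the transcribed strand).  All other substitutions are
#' tallied into a read-space 12-type spectrum.
#'
#' @param alignments alignment data.frame.
#' @return list with `tc` (data.frame ref, strand, pos, count of T-to-C
#'   reads) and `spectrum` (named fractions over the 12 substitution types
#'   in read space, summing to 1; empty when no substitutions).
#' @export
call_tc_positions <- function(alignments) {
  bases <- c("A", "C", "G", "T")
  types <- as.vector(outer(bases, bases, function(a, b)
    paste0(a, ">", b)))
  types <- types[substr(types, 1, 1) != substr(types, 3, 3)]
  spectrum <- setNames(numeric(length(types)), sort(types))

  has <- alignments$subs != "." & !is.na(alignments$subs)
  tc_rows <- list()
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in which(has)) {
    a <- alignments[i, ]
    for (s in strsplit(a$subs, ",", fixed = TRUE)[[1]]) {
      m <- regmatches(s, regexec("^(\\d+):([ACGT])>([ACGT])$", s))[[1]]
      if (length(m) != 4L) {
        stop("malformed substitution record: ", s, call. = FALSE)
      }
      pos <- as.integer(m[2]); ref <- m[3]; alt <- m[4]
      # read-space orientation for the spectrum
      if (a$strand == "-") {
        ref_r <- comp[[ref]]; alt_r <- comp[[alt]]
      } else {
        ref_r <- ref; alt_r <- alt
      }
      key <- paste0(ref_r, ">", alt_r)
      spectrum[key] <- spectrum[key] + 1
      is_tc <- (a$strand == "+" && ref == "T" && alt == "C") ||
        (a$strand == "-" && ref == "A" && alt == "G")
      if (is_tc) {
        tc_rows[[length(tc_rows) + 1L]] <- data.frame(
          ref = a$ref, strand = a$strand, pos = pos,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(tc_rows) > 0L) {
    tcdf <- do.call(rbind, tc_rows)
    key <- paste(tcdf$ref, tcdf$strand, tcdf$pos, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    tc <- data.frame(
      ref = vapply(parts, `[`, character(1), 1L),
      strand = vapply(parts, `[`, character(1), 2L),
      pos = as.integer(vapply(parts, `[`, character(1), 3L)),
      count = as.integer(tab), stringsAsFactors = FALSE)
    tc <- tc[order(tc$ref, tc$strand, tc$pos), , drop = FALSE]
    rownames(tc) <- NULL
  } else {
    tc <- data.frame(ref = character(), strand = character(),
                     pos = integer(), count = integer(),
                     stringsAsFactors = FALSE)
  }
  tot <- sum(spectrum)
  if (tot > 0) spectrum <- spectrum / tot
  list(tc = tc, spectrum = spectrum)
}

#' Nucleotide composition around crosslink positions
#'
#' For every crosslink event locus, extracts the transcript-sense base at
#' offsets `-flank .. +flank` around position 0 (reverse complement on the
#' minus strand) and returns per-offset base frequencies weighted by event
#' counts.  Offsets reaching beyond a contig edge are normalized over the
#' available events at that offset.
#'
#' @param profile a `crosslink_profile`.
#' @param reference named character vector of chromosome sequences.
#' @param flank offsets to report on each side of position 0.
#' @return numeric matrix, rows `offset` (-flank..+flank), columns A, C, G,
#'   T (transcript-sense); each row sums to 1.
#' @export
qc_composition <- function(profile, reference, flank = 10L) {
  offs <- -flank:flank
  bases <- c("A", "C", "G", "T")
  m <- matrix(0, nrow = length(offs), ncol = 4L,
              dimnames = list(as.character(offs), bases))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ev <- profile$events
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    chrom <- reference[[e$ref]]
    clen <- nchar(chrom)
    for (k in seq_along(offs)) {
      gpos <- if (e$strand == "+") e$pos + offs[k] else e$pos - offs[k]
      if (gpos < 0L || gpos >= clen) next
      b <- substr(chrom, gpos + 1L, gpos + 1L)
      if (e$strand == "-") b <- comp[[b]]
      if (b %in% bases) m[k, b] <- m[k, b] + e$count
    }
  }
  rs <- rowSums(m)
  rs[rs == 0] <- 1
  sweep(m, 1L, rs, "/")
}

#' Fraction of crosslink loci confirmed by a T-to-C transition
#'
#' Over the distinct position-0 loci of `profile` (optionally restricted to
#' loci inside `sites` intervals), computes the fraction having at least one
#' T-to-C read at the same (ref, strand, position).
#'
#' @param profile a `crosslink_profile`.
#' @param tc_positions the `tc` data.frame from [call_tc_positions()].
#' @param sites optional data.frame with ref, strand, start, end restricting
#'   loci to those inside the intervals.
#' @param per_read count loci weighted by their event counts instead of
#'   once each.
#' @return fraction in `[0, 1]`; `NaN` when there are no loci.
#' @export
termination_tc_overlap <- function(profile, tc_positions, sites = NULL,
                                   per_read = FALSE) {
  ev <- profile$events
  if (!is.null(sites) && nrow(ev) > 0L) {
    keep <- logical(nrow(ev))
    for (i in seq_len(nrow(ev))) {
      keep[i] <- any(sites$ref == ev$ref[i] & sites$strand == ev$strand[i] &
                       sites$start <= ev$pos[i] & ev$pos[i] < sites$end)
    }
    ev <- ev[keep, , drop = FALSE]
  }
  if (nrow(ev) == 0L) return(NaN)
  tc_key <- paste(tc_positions$ref, tc_positions$strand, tc_positions$pos)
  hit <- paste(ev$ref, ev$strand, ev$pos) %in% tc_key
  if (per_read) sum(ev$count[hit]) / sum(ev$count) else mean(hit)
}

#' Assemble the full PAR-iCLIP QC report
#'
#' @param alignments alignment data.frame.
#' @param reference named character vector of chromosome sequences.
#' @param sites optional site intervals for the within-site overlap fraction.
#' @param flank composition flank (nt).
#' @return list with `composition`, `spectrum`, `overlap_genomewide`,
#'   `overlap_in_sites` (NA when `sites` is NULL).
#' @export
qc_report <- function(alignments, reference, sites = NULL, flank = 10L) {
  profile <- extract_crosslinks(alignments)
  tc <- call_tc_positions(alignments)
  list(
    composition = qc_composition(profile, reference, flank),
    spectrum = tc$spectrum,
    overlap_genomewide = termination_tc_overlap(profile, tc$tc),
    overlap_in_sites = if (is.null(sites)) NA_real_ else
      termination_tc_overlap(profile, tc$tc, sites)
  )
}

#' Write a crosslink profile as per-strand bedGraph tracks
#'
#' @param profile a `crosslink_profile`.
#' @param prefix output path prefix; writes `<prefix>_plus.bedgraph` and
#'   `<prefix>_minus.bedgraph`.
#' @return the two paths, invisibly.
#' @export
write_bedgraph <- function(profile, prefix) {
  paths <- c()
  for (s in c("+", "-")) {
    tag <- if (s == "+") "plus" else "minus"
    p <- paste0(prefix, "_", tag, ".bedgraph")
    ev <- profile$events[profile$events$strand == s, , drop = FALSE]
    lines <- sprintf("%s\t%d\t%d\t%d", ev$ref, ev$pos, ev$pos + 1L, ev$count)
    writeLines(lines, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read per-strand bedGraph tracks back into a crosslink profile
#'
#' @param plus_path,minus_path bedGraph files written by [write_bedgraph()].
#' @return a `crosslink_profile`.
#' @export
read_bedgraph <- function(plus_path, minus_path) {
  one <- function(path, strand) {
    lines <- readLines(path)
    if (length(lines) == 0L) {
      return(data.frame(ref = character(), strand = character(),
                        pos = integer(), count = integer(),
                        stringsAsFactors = FALSE))
    }
    m <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
    data.frame(ref = m[, 1], strand = strand, pos = as.integer(m[, 2]),
               count = as.integer(m[, 4]), stringsAsFactors = FALSE)
  }
  ev <- rbind(one(plus_path, "+"), one(minus_path, "-"))
  ev <- ev[order(ev$ref, ev$strand, ev$pos), , drop = FALSE]
  rownames(ev) <- NULL
  new_crosslink_profile(ev, sum(ev$count), 0L)
}
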