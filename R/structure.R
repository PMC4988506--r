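# ARE motif scanning, RNA accessibility and bound/unbound discrimination.

RT_37C <- 0.0019872 * 310.15   # kcal/mol at 37 C

norm_rna <- function(x) chartr("tu", "TU", chartr("T", "U", toupper(x)))

iupac_regex <- c(A = "A", C = "C", G = "G", U = "U", W = "[AU]", K = "[GU]",
                 S = "[CG]", M = "[AC]", R = "[AG]", Y = "[CU]", N = ".")

#' Scan a sequence for ARE motif matches
#'
#' Finds all, possibly overlapping, matches of an IUPAC pattern (default
#' the TTP core `WAUUUAW`; `UUUKUUU` is the HuR-preferred variant).  DNA or
#' RNA input is normalized to RNA.
#'
#' @param sequence character sequence (sense strand).
#' @param pattern IUPAC pattern over A/C/G/U plus W (A/U) and K (G/U).
#' @return data.frame with `start` (0-based), `end` (half-open), `matched`
#'   (RNA 7-mer) and `pattern`.
#' @export
scan_motifs <- function(sequence, pattern = "WAUUUAW") {
  seq <- norm_rna(sequence)
  pat <- norm_rna(pattern)
  chars <- strsplit(pat, "")[[1]]
  if (!all(chars %in% names(iupac_regex))) {
    stop("unsupported IUPAC code in pattern: ", pattern, call. = FALSE)
  }
  rex <- paste0("(?=(", paste(iupac_regex[chars], collapse = ""), "))")
  m <- gregexpr(rex, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(), end = integer(),
                      matched = character(), pattern = character(),
                      stringsAsFactors = FALSE))
  }
  start <- as.integer(m) - 1L
  k <- length(chars)
  data.frame(start = start, end = start + k,
             matched = substring(seq, start + 1L, start + k),
             pattern = pat, stringsAsFactors = FALSE)
}

#' AU content of a window centered on a motif
#'
#' @param sequence character sequence.
#' @param start 0-based motif start.
#' @param width motif width (default 7).
#' @param window total window width centered on the motif midpoint
#'   (default 21); clipped at sequence edges.
#' @return fraction of A/U bases in the window.
#' @export
au_content <- function(sequence, start, width = 7L, window = 21L) {
  seq <- norm_rna(sequence)
  mid <- start + width %/% 2L             # 0-based midpoint
  lo <- max(0L, mid - window %/% 2L)
  hi <- min(nchar(seq), lo + window)
  win <- substr(seq, lo + 1L, hi)
  mean(strsplit(win, "")[[1]] %in% c("A", "U"))
}

#' Accessibility profile: probability that u-nt stretches are unpaired
#'
#' For every stretch start, computes the probability that the `u`-mer
#' beginning there is entirely unpaired under the secondary-structure
#' ensemble, averaged over all sliding windows of width `W` that contain
#' it.  The built-in backend is an exact partition function over
#' non-crossing structures with per-pair energies (GC -3, AU -2, GU -1
#' kcal/mol) and a minimum hairpin loop of 3 nt.  The `viennarna` backend
#' shells out to `RNAplfold` when installed.
#'
#' @param sequence character sequence (DNA or RNA; sense strand).
#' @param W sliding window width (default 75 nt).
#' @param u stretch length (default 7 nt).
#' @param backend `"builtin"` or `"viennarna"`.
#' @param energies named pair energies (kcal/mol): AU, GC, GU.
#' @param min_loop minimum hairpin loop length (nt).
#' @return data.frame of class `accessibility_profile` with `start`
#'   (0-based), `p_unpaired` and `open_energy` (`-RT log p`, kcal/mol).
#' @export
accessibility <- function(sequence, W = 75L, u = 7L, backend = "builtin",
                          energies = c(AU = -2, GC = -3, GU = -1),
                          min_loop = 3L) {
  seq <- norm_rna(sequence)
  n <- nchar(seq)
  if (n < u) stop("sequence length must be >= u", call. = FALSE)
  if (backend == "builtin") {
    codes <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "U")) - 1L
    if (anyNA(codes)) stop("sequence contains non-ACGU characters",
                           call. = FALSE)
    p <- pf_accessibility(codes, as.integer(W), as.integer(u),
                          energies[["AU"]], energies[["GC"]],
                          energies[["GU"]], RT_37C, as.integer(min_loop))
  } else if (backend == "viennarna") {
    p <- rnaplfold_unpaired(seq, W, u)
  } else {
    stop("unknown backend '", backend,
         "'; available backends: builtin, viennarna", call. = FALSE)
  }
  out <- data.frame(start = seq_along(p) - 1L, p_unpaired = p,
                    open_energy = -RT_37C * log(pmax(p, .Machine$double.xmin)))
  class(out) <- c("accessibility_profile", class(out))
  out
}

# External backend: parse RNAplfold's _lunp output (mean unpaired
# probability of stretches of length u ending at each position).
rnaplfold_unpaired <- function(seq, W, u) {
  if (Sys.which("RNAplfold") == "") {
    stop("backend 'viennarna' requires RNAplfold on PATH", call. = FALSE)
  }
  dir <- tempfile("plfold")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  old <- setwd(dir)
  on.exit(setwd(old), add = TRUE, after = FALSE)
  writeLines(c(">q", seq), "in.fa")
  system2("RNAplfold", c("-W", min(W, nchar(seq)), "-u", u, "--auto-id"),
          stdin = "in.fa", stdout = FALSE)
  lunp <- list.files(dir, pattern = "_lunp$", full.names = TRUE)[1]
  tab <- read.delim(lunp, comment.char = "#", header = FALSE, sep = "\t")
  ends <- tab[[1]]
  vals <- suppressWarnings(as.numeric(tab[[u + 1L]]))
  p <- rep(NA_real_, nchar(seq) - u + 1L)
  sel <- ends >= u
  p[ends[sel] - u + 1L] <- vals[sel]
  p
}

#' Extract a transcript-sense RNA subsequence from the genome
#'
#' Returns the RNA sequence of `[start, end)` padded by `pad` nt on each
#' side, reverse-complemented for minus-strand features, clipped at contig
#' edges.
#'
#' @param reference named character vector of chromosome sequences.
#' @param ref,strand,start,end genomic interval (0-based half-open).
#' @param pad padding in nt.
#' @return list with `seq` (RNA) and `offset` (0-based position of `start`
#'   within `seq`, in transcript orientation).
#' @export
extract_context <- function(reference, ref, strand, start, end, pad = 68L) {
  chrom <- reference[[ref]]
  lo <- max(0L, start - pad)
  hi <- min(nchar(chrom), end + pad)
  dna <- substr(chrom, lo + 1L, hi)
  if (strand == "-") {
    dna <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(dna)))
    offset <- hi - end
  } else {
    offset <- start - lo
  }
  list(seq = chartr("T", "U", dna), offset = as.integer(offset))
}

#' One-feature linear discriminant scores for bound vs unbound motifs
#'
#' Fits linear discriminant analysis on a single feature (AU content or
#' accessibility).  With one feature the discriminant reduces to a
#' monotone transform of the feature itself, so downstream ROC analysis is
#' identical to thresholding the feature; the LDA formulation is kept for
#' parity with standard practice.
#'
#' @param feature numeric feature per motif occurrence.
#' @param bound logical labels.
#' @return list with `scores` (higher = more bound-like), and the fitted
#'   `model`.
#' @export
train_lda <- function(feature, bound) {
  stopifnot(length(feature) == length(bound))
  grp <- factor(ifelse(bound, "bound", "unbound"),
                levels = c("unbound", "bound"))
  model <- MASS::lda(x = matrix(feature, ncol = 1L), grouping = grp)
  sc <- stats::predict(model, matrix(feature, ncol = 1L))$x[, 1L]
  # orient so that bound scores are larger
  if (mean(sc[bound]) < mean(sc[!bound])) sc <- -sc
  list(scores = as.numeric(sc), model = model)
}

#' ROC curve and AUC by the rank (Mann-Whitney) formulation
#'
#' AUC equals the probability that a random bound score exceeds a random
#' unbound score, ties counting one half.
#'
#' @param scores numeric classifier scores.
#' @param labels logical (TRUE = positive/bound).
#' @return list with `auc` and `roc` (data.frame fpr, tpr over score
#'   thresholds).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop("need both positive and negative labels", call. = FALSE)
  }
  r <- rank(scores)     # average ranks: ties contribute 1/2
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  roc <- data.frame(
    fpr = c(0, vapply(thr, function(t) sum(scores[!labels] >= t) / n0,
                      numeric(1))),
    tpr = c(0, vapply(thr, function(t) sum(scores[labels] >= t) / n1,
                      numeric(1)))
  )
  list(auc = auc, roc = roc)
}

#' Feature table for bound/unbound motif discrimination
#'
#' Scans motif occurrences in a set of transcript-sense sequences, labels
#' each occurrence bound when it overlaps a binding-site interval given in
#' the same per-sequence coordinates, and attaches AU content and mean
#' opening probability of the motif stretch.
#'
#' @param seqs named character vector of transcript-sense sequences.
#' @param bound_intervals data.frame with seq_id, start, end (0-based
#'   half-open, per-sequence coordinates) of binding sites.
#' @param pattern IUPAC motif pattern.
#' @param W,u accessibility window and stretch length.
#' @param backend accessibility backend.
#' @param au_window AU-content window width.
#' @return data.frame: seq_id, start, end, matched, bound, au,
#'   p_unpaired, open_energy.
#' @export
motif_features <- function(seqs, bound_intervals, pattern = "WAUUUAW",
                           W = 75L, u = 7L, backend = "builtin",
                           au_window = 21L) {
  out <- list()
  for (id in names(seqs)) {
    seq <- seqs[[id]]
    occ <- scan_motifs(seq, pattern)
    if (nrow(occ) == 0L) next
    acc <- accessibility(seq, W = W, u = u, backend = backend)
    bi <- bound_intervals[bound_intervals$seq_id == id, , drop = FALSE]
    occ$seq_id <- id
    occ$bound <- vapply(seq_len(nrow(occ)), function(i)
      any(bi$start < occ$end[i] & bi$end > occ$start[i]), logical(1))
    occ$au <- vapply(occ$start, function(s)
      au_content(seq, s, width = nchar(pattern), window = au_window),
      numeric(1))
    idx <- match(occ$start, acc$start)
    occ$p_unpaired <- acc$p_unpaired[idx]
    occ$open_energy <- acc$open_energy[idx]
    out[[length(out) + 1L]] <- occ
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(start = integer(), end = integer(),
                      matched = character(), pattern = character(),
                      seq_id = character(), bound = logical(),
                      au = numeric(), p_unpaired = numeric(),
                      open_energy = numeric(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}
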