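# Binding-site calling: randomization (modFDR-style) significance within
# gene regions, followed by recursive summit splitting of significant
# clusters and a replicate-consensus filter.

#' Peak-calling configuration
#'
#' Defaults follow the published filtering rules: clusters whose summit
#' pileup is below 100 crosslinks are background; a site is first split
#' where its pileup falls below 30% of the summit, and emerging subsites are
#' recursively split at 10% of their own summits.
#'
#' @param summit_min minimum summit pileup for an emitted site.
#' @param primary_frac first-pass cut fraction of the summit height.
#' @param secondary_frac recursive cut fraction applied to subsites.
#' @param fdr_q FDR threshold for the randomization null.
#' @param n_randomizations uniform redistributions per region.
#' @param seed base seed; each region derives an independent substream from
#'   it, so processing order never changes results.
#' @param min_region_gap positions below the height threshold bridged when
#'   forming candidate clusters.
#' @return a validated list of class `peak_config`.
#' @export
peak_config <- function(summit_min = 100L, primary_frac = 0.30,
                        secondary_frac = 0.10, fdr_q = 0.01,
                        n_randomizations = 100L, seed = 1L,
                        min_region_gap = 1L) {
  cfg <- list(summit_min = as.integer(summit_min),
              primary_frac = primary_frac, secondary_frac = secondary_frac,
              fdr_q = fdr_q, n_randomizations = as.integer(n_randomizations),
              seed = as.integer(seed),
              min_region_gap = as.integer(min_region_gap))
  if (!(cfg$secondary_frac > 0 && cfg$secondary_frac < cfg$primary_frac &&
        cfg$primary_frac < 1)) {
    stop("need 0 < secondary_frac < primary_frac < 1", call. = FALSE)
  }
  if (cfg$summit_min < 1L) stop("summit_min must be >= 1", call. = FALSE)
  if (cfg$fdr_q <= 0 || cfg$fdr_q > 1) stop("fdr_q must be in (0, 1]",
                                            call. = FALSE)
  class(cfg) <- "peak_config"
  cfg
}

#' Summit, height and area of an interval on a crosslink profile
#'
#' @param profile a `crosslink_profile`.
#' @param ref,strand,start,end interval (0-based half-open).
#' @return list with `summit` (position, ties broken to the lowest
#'   coordinate), `height` (max pileup) and `area` (total pileup).
#' @export
site_metrics <- function(profile, ref, strand, start, end) {
  ev <- profile$events
  sel <- ev$ref == ref & ev$strand == strand & ev$pos >= start & ev$pos < end
  ev <- ev[sel, , drop = FALSE]
  if (nrow(ev) == 0L) {
    return(list(summit = as.integer(start), height = 0L, area = 0L))
  }
  ev <- ev[order(ev$pos), , drop = FALSE]
  i <- which.max(ev$count)   # first maximum = lowest coordinate
  list(summit = ev$pos[i], height = ev$count[i], area = sum(ev$count))
}

#' Recursively split a cluster pileup vector into binding sites
#'
#' Finds the summit (maximum pileup, ties to the lowest coordinate);
#' clusters whose summit is below `summit_min` are discarded.  Walking
#' outward from the summit, the cluster is cut at the first position on
#' each side where the pileup drops below `primary_frac` of the summit; the
#' summit-containing segment is emitted.  Each remaining segment is
#' processed recursively with `secondary_frac` of its own summit.  Cut
#' positions belong to neither flanking segment.
#'
#' @param pileup non-negative numeric vector of per-position pileups.
#' @param config a [peak_config()].
#' @return data.frame with 0-based offsets into `pileup`: columns `start`,
#'   `end` (half-open), `summit`, `height`, `area`; zero rows when nothing
#'   survives the summit threshold.
#' @export
split_sites <- function(pileup, config = peak_config()) {
  empty <- data.frame(start = integer(), end = integer(), summit = integer(),
                      height = numeric(), area = numeric())
  if (length(pileup) == 0L) return(empty)
  if (any(pileup < 0)) stop("pileup must be non-negative", call. = FALSE)
  acc <- list()
  rec <- function(lo, hi, frac) {
    if (lo > hi) return(invisible(NULL))
    seg <- pileup[lo:hi]
    S <- max(seg)
    if (S < config$summit_min) return(invisible(NULL))
    s <- lo + which.max(seg) - 1L
    thr <- frac * S
    l <- s
    while (l - 1L >= lo && pileup[l - 1L] >= thr) l <- l - 1L
    r <- s
    while (r + 1L <= hi && pileup[r + 1L] >= thr) r <- r + 1L
    acc[[length(acc) + 1L]] <<- data.frame(
      start = l - 1L, end = r, summit = s - 1L, height = S,
      area = sum(pileup[l:r]))
    if (l - 2L >= lo) rec(lo, l - 2L, config$secondary_frac)
    if (r + 2L <= hi) rec(r + 2L, hi, config$secondary_frac)
    invisible(NULL)
  }
  rec(1L, length(pileup), config$primary_frac)
  if (length(acc) == 0L) return(empty)
  out <- do.call(rbind, acc)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call candidate clusters with a randomization (modFDR-style) null
#'
#' Within each region (gene span), the observed crosslink events are
#' redistributed uniformly at random over the region `n_randomizations`
#' times.  For each pileup height `h`, `FDR(h)` is the mean number of null
#' positions with pileup `>= h` divided by the observed number; the height
#' threshold is the smallest `h` with `FDR(h) <= fdr_q`.  Runs of positions
#' at or above the threshold (bridging gaps up to `min_region_gap`) become
#' candidate clusters.  Each region uses an RNG substream derived from its
#' identifier, so results are independent of processing order.
#'
#' @param profile a `crosslink_profile`.
#' @param regions data.frame with columns gene_id, ref, strand, start, end
#'   (0-based half-open gene spans).
#' @param config a [peak_config()].
#' @return data.frame of clusters: gene_id, ref, strand, start, end,
#'   h_star (height threshold used).
#' @export
modfdr_call <- function(profile, regions, config = peak_config()) {
  out <- list()
  for (i in seq_len(nrow(regions))) {
    rg <- regions[i, ]
    ev <- profile$events
    sel <- ev$ref == rg$ref & ev$strand == rg$strand &
      ev$pos >= rg$start & ev$pos < rg$end
    ev <- ev[sel, , drop = FALSE]
    if (nrow(ev) == 0L) next
    L <- rg$end - rg$start
    N <- sum(ev$count)
    maxh <- max(ev$count)
    obs_ge <- rev(cumsum(rev(tabulate(pmin(ev$count, maxh), nbins = maxh))))

    null_ge <- with_seed(string_seed(rg$gene_id, config$seed), {
      tot <- numeric(maxh)
      for (r in seq_len(config$n_randomizations)) {
        cnt <- tabulate(sample.int(L, N, replace = TRUE), nbins = L)
        cnt <- cnt[cnt > 0L]
        th <- tabulate(pmin(cnt, maxh), nbins = maxh)
        tot <- tot + rev(cumsum(rev(th)))
      }
      tot / config$n_randomizations
    })

    fdr <- ifelse(obs_ge > 0, null_ge / obs_ge, Inf)
    ok <- which(fdr <= config$fdr_q & obs_ge > 0)
    if (length(ok) == 0L) next
    h_star <- min(ok)

    pos <- sort(ev$pos[ev$count >= h_star])
    gap <- diff(pos) - 1L
    brk <- c(0L, cumsum(gap > config$min_region_gap))
    for (cl in split(pos, brk)) {
      out[[length(out) + 1L]] <- data.frame(
        gene_id = rg$gene_id, ref = rg$ref, strand = rg$strand,
        start = min(cl), end = max(cl) + 1L, h_star = h_star,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(gene_id = character(), ref = character(),
                      strand = character(), start = integer(),
                      end = integer(), h_star = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Call and split binding sites on a crosslink profile
#'
#' Runs [modfdr_call()] over the regions, then [split_sites()] on each
#' candidate cluster's pileup vector, mapping offsets back to genomic
#' coordinates.
#'
#' @param profile a `crosslink_profile`.
#' @param regions gene-span data.frame (see [modfdr_call()]).
#' @param config a [peak_config()].
#' @param replicate replicate identifier carried into the site table.
#' @return binding-site data.frame: ref, strand, start, end, summit,
#'   height, area, gene_id, replicate.
#' @export
call_binding_sites <- function(profile, regions, config = peak_config(),
                               replicate = 1L) {
  clusters <- modfdr_call(profile, regions, config)
  out <- list()
  ev <- profile$events
  for (i in seq_len(nrow(clusters))) {
    cl <- clusters[i, ]
    sel <- ev$ref == cl$ref & ev$strand == cl$strand &
      ev$pos >= cl$start & ev$pos < cl$end
    sub <- ev[sel, , drop = FALSE]
    v <- numeric(cl$end - cl$start)
    v[sub$pos - cl$start + 1L] <- sub$count
    sp <- split_sites(v, config)
    if (nrow(sp) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      ref = cl$ref, strand = cl$strand,
      start = cl$start + sp$start, end = cl$start + sp$end,
      summit = cl$start + sp$summit, height = sp$height, area = sp$area,
      gene_id = cl$gene_id, replicate = replicate,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(ref = character(), strand = character(),
                      start = integer(), end = integer(), summit = integer(),
                      height = numeric(), area = numeric(),
                      gene_id = character(), replicate = integer(),
                      stringsAsFactors = FALSE)
  }
  res <- res[order(res$ref, res$strand, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Replicate-consensus filter for binding sites
#'
#' A site is kept if and only if it overlaps (by at least 1 nt, same
#' reference and strand) at least one site in every other replicate.  Kept
#' sites retain their own boundaries; a merged union track of the kept
#' sites is also returned.
#'
#' @param site_lists list (length >= 2) of binding-site data.frames.
#' @return list with `per_replicate` (kept sites per input) and `merged`
#'   (reduced union intervals of all kept sites: ref, strand, start, end).
#' @export
consensus_sites <- function(site_lists) {
  if (length(site_lists) < 2L) {
    stop("consensus requires at least 2 replicates", call. = FALSE)
  }
  grs <- lapply(site_lists, intervals_to_gr)
  kept <- vector("list", length(site_lists))
  for (i in seq_along(site_lists)) {
    keep <- rep(TRUE, nrow(site_lists[[i]]))
    for (j in seq_along(site_lists)) {
      if (i == j) next
      hits <- GenomicRanges::countOverlaps(grs[[i]], grs[[j]],
                                           minoverlap = 1L)
      keep <- keep & hits > 0L
    }
    kept[[i]] <- site_lists[[i]][keep, , drop = FALSE]
    rownames(kept[[i]]) <- NULL
  }
  all_kept <- do.call(rbind, lapply(kept, function(d)
    d[, c("ref", "strand", "start", "end"), drop = FALSE]))
  if (nrow(all_kept) > 0L) {
    red <- GenomicRanges::reduce(intervals_to_gr(all_kept))
    merged <- data.frame(
      ref = as.character(GenomicRanges::seqnames(red)),
      strand = as.character(GenomicRanges::strand(red)),
      start = GenomicRanges::start(red) - 1L,
      end = GenomicRanges::end(red), stringsAsFactors = FALSE)
    merged <- merged[order(merged$ref, merged$strand, merged$start), ,
                     drop = FALSE]
    rownames(merged) <- NULL
  } else {
    merged <- data.frame(ref = character(), strand = character(),
                         start = integer(), end = integer(),
                         stringsAsFactors = FALSE)
  }
  list(per_replicate = kept, merged = merged)
}
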