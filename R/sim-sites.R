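# Planting of binding sites, ARE motif contexts and decay ground truth.

# Planted motif contexts are written over cytosine flanks wide enough that
# every accessibility window (width ACCESS_W) containing the motif lies
# inside the planted context.  Under the pairing-only energy model any A, U
# or G in a window offers the AU-rich motif a pairing partner, so context
# accessibility is controlled solely by the planted stem partner: paired
# contexts add the motif's reverse complement 8 nt downstream, accessible
# contexts add more flank.  AU content of a motif-centred window is
# identical between the two context classes.
MOTIF_LEN <- 7L
ACCESS_W <- 75L                    # folding window the contexts are sized for
CTX_LEFT <- ACCESS_W - MOTIF_LEN   # 68 nt flank left of motif
CTX_RIGHT <- ACCESS_W - MOTIF_LEN  # 8 loop + 7 partner/filler + 53 right
CTX_LEN <- CTX_LEFT + MOTIF_LEN + CTX_RIGHT

sample_motif <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  paste(vapply(chars, function(ch) switch(ch,
    W = sample(c("A", "U"), 1L),
    K = sample(c("G", "U"), 1L),
    ch), character(1)), collapse = "")
}

rna_revcomp <- function(x) {
  chartr("ACGU", "UGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

rand_flank <- function(n) strrep("C", n)

# Transcript-sense motif context (RNA alphabet).  Paired contexts place the
# reverse complement of the motif 8 nt downstream, forming a hairpin whose
# stem contains the motif; accessible contexts fill the same span with
# flank sequence.
make_context <- function(motif, paired) {
  partner <- if (paired) rna_revcomp(motif) else rand_flank(MOTIF_LEN)
  paste0(rand_flank(CTX_LEFT), motif, rand_flank(8L), partner,
         rand_flank(CTX_RIGHT - 15L))
}

#' Plant binding sites, motif contexts and decay truth into a synthetic genome
#'
#' Assigns `config$n_sites` binding sites to introns, 3'UTRs and CDS regions
#' in the requested proportions, writes an ARE heptamer (default `WAUUUAW`)
#' with flanking context into the reference sequence at each site, plants an
#' additional set of unbound decoy motifs in 3'UTRs, and draws per-gene decay
#' truth: wild-type slopes from the configured half-life ranges and knockout
#' slopes stabilized in proportion to each target's binding occupancy
#' (`decay_coupling`).
#'
#' @param annotation a `genome_annotation` from [make_annotation()].
#' @param reference named character vector of chromosome sequences.
#' @param config a [sim_config()].
#' @return list of class `planted_truth` with elements `sites`, `motifs`,
#'   `decay` (per gene x genotype slopes), `expression` (per transcript
#'   baseline FPKM) and the modified `reference`.
#' @export
plant_sites <- function(annotation, reference, config) {
  validate_sim_config(config)
  with_seed(config$seed + 1L, plant_sites_impl(annotation, reference, config))
}

plant_sites_impl <- function(annotation, reference, config) {
  ann <- annotation
  introns <- introns_of(ann)
  # intron placement uses introns of the primary isoform only: those are
  # intronic in every isoform of the synthetic gene models
  introns <- introns[grepl("\\.t1$", introns$tx_id), , drop = FALSE]
  feats <- ann$features[grepl("\\.t1$", ann$features$tx_id), , drop = FALSE]
  utr3 <- feats[feats$type == "utr3", , drop = FALSE]
  cds <- feats[feats$type == "cds", , drop = FALSE]

  pools <- list(intron = introns, utr3 = utr3, cds = cds)
  props <- config$site_region_props
  classes <- sample(names(props), config$n_sites, replace = TRUE,
                    prob = unname(props))
  slots_available <- sum(vapply(pools, function(p)
    sum(pmax(0L, (p$end - p$start - CTX_LEN - 4L) %/% (CTX_LEN + 4L))),
    numeric(1)))
  if (config$n_sites + config$n_unbound_motifs > slots_available) {
    stop("more sites than available regions under the current gene models",
         call. = FALSE)
  }

  occupied <- list()  # per ref: matrix of (start, end)
  no_clash <- function(ref, start, end) {
    occ <- occupied[[ref]]
    if (is.null(occ)) return(TRUE)
    all(end <= occ[, 1] | start >= occ[, 2])
  }
  claim <- function(ref, start, end) {
    occupied[[ref]] <<- rbind(occupied[[ref]], c(start, end))
  }

  place_context <- function(pool_df) {
    # returns a row of pool_df plus a context start, or NULL after misses
    for (try in 1:100) {
      row <- pool_df[sample.int(nrow(pool_df), 1L), ]
      lo <- row$start + 2L
      hi <- row$end - CTX_LEN - 2L
      if (hi <= lo) next
      cstart <- lo + sample.int(hi - lo, 1L) - 1L
      if (no_clash(row$ref, cstart, cstart + CTX_LEN)) {
        claim(row$ref, cstart, cstart + CTX_LEN)
        return(list(row = row, cstart = cstart))
      }
    }
    NULL
  }

  # genomic position of transcript-sense context offset o (0-based)
  ctx_pos <- function(cstart, strand, o) {
    if (strand == "+") cstart + o else cstart + CTX_LEN - 1L - o
  }

  edits <- list()    # reference edits: list(ref, start, dna)
  sites <- list()
  motifs <- list()

  plant_one <- function(region, bound, idx) {
    pool <- pools[[region]]
    if (nrow(pool) == 0L) return(NULL)
    pl <- place_context(pool)
    if (is.null(pl)) {
      stop("more sites than available regions (placement exhausted)",
           call. = FALSE)
    }
    strand <- pl$row$strand
    paired <- runif(1) < (if (bound) config$p_paired_bound
                          else config$p_paired_unbound)
    motif <- sample_motif("WAUUUAW")
    ctx <- make_context(motif, paired)
    dna <- chartr("U", "T", ctx)
    if (strand == "-") {
      dna <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(dna)))
    }
    edits[[length(edits) + 1L]] <<- list(ref = pl$row$ref, start = pl$cstart,
                                         dna = dna)
    mstart_t <- CTX_LEFT                         # motif offset in context
    gpos <- vapply(mstart_t:(mstart_t + MOTIF_LEN - 1L),
                   function(o) ctx_pos(pl$cstart, strand, o), numeric(1))
    mstart <- as.integer(min(gpos))
    motifs[[length(motifs) + 1L]] <<- data.frame(
      motif_id = sprintf("m%04d", idx), gene_id = pl$row$gene_id,
      ref = pl$row$ref, strand = strand,
      start = mstart, end = mstart + MOTIF_LEN,
      context = if (paired) "paired" else "accessible",
      bound = bound, pattern = "WAUUUAW", matched = motif,
      stringsAsFactors = FALSE)
    if (bound) {
      h <- sample(config$summit_height_range[1]:config$summit_height_range[2],
                  1L)
      summit <- as.integer(ctx_pos(pl$cstart, strand, mstart_t + 3L))
      sites[[length(sites) + 1L]] <<- data.frame(
        site_id = sprintf("s%04d", idx), gene_id = pl$row$gene_id,
        ref = pl$row$ref, strand = strand,
        start = mstart, end = mstart + MOTIF_LEN,
        region = region, summit_pos = summit, summit_height = h,
        area_true = h + round(0.25 * h) + round(0.10 * h),
        stringsAsFactors = FALSE)
    }
    invisible(NULL)
  }

  for (i in seq_len(config$n_sites)) plant_one(classes[i], TRUE, i)
  for (i in seq_len(config$n_unbound_motifs)) {
    plant_one("utr3", FALSE, config$n_sites + i)
  }

  for (e in edits) {
    substr(reference[[e$ref]], e$start + 1L, e$start + nchar(e$dna)) <- e$dna
  }

  sites <- do.call(rbind, sites) %||%
    data.frame(site_id = character(), gene_id = character(),
               ref = character(), strand = character(), start = integer(),
               end = integer(), region = character(), summit_pos = integer(),
               summit_height = integer(), area_true = numeric())
  motifs <- do.call(rbind, motifs)

  truth <- list(sites = sites, motifs = motifs)
  truth$decay <- plant_decay_truth(ann, truth, config)
  truth$expression <- plant_expression_truth(ann, truth$decay, config)
  truth$reference <- reference
  class(truth) <- "planted_truth"
  truth
}

# Per-gene decay classes and slopes.  For targets (genes with a bound
# 3'UTR site) binding causes decay: the knockout slope is the gene's
# binding-free baseline (drawn from half_life_target) and the wild-type
# slope adds an occupancy-proportional decay component,
#   slope_WT = slope_KO - decay_coupling * occupancy
# with occupancy = planted site area / baseline expression, so the true
# differential decay equals decay_coupling * occupancy exactly.
plant_decay_truth <- function(ann, truth, config) {
  genes <- ann$genes$gene_id
  fpkm0 <- pmax(1, 2 ^ rnorm(length(genes), mean = log2(30), sd = 1.2))
  names(fpkm0) <- genes
  utr3_sites <- truth$sites[truth$sites$region == "utr3", , drop = FALSE]
  target <- genes %in% utr3_sites$gene_id
  n_other <- sum(!target)
  unst_ind <- rep(FALSE, length(genes))
  unst_ind[!target] <- runif(n_other) < config$frac_unstable_independent

  hl_draw <- function(rng, n) runif(n, rng[1], rng[2])
  slope_wt <- slope_ko <- numeric(length(genes))
  cls <- character(length(genes))
  for (i in seq_along(genes)) {
    if (target[i]) {
      hl <- hl_draw(config$half_life_target, 1L)
      slope_ko[i] <- -1 / hl
      occ <- sum(utr3_sites$area_true[utr3_sites$gene_id == genes[i]]) /
        fpkm0[i]
      slope_wt[i] <- slope_ko[i] - config$decay_coupling * occ
      cls[i] <- "target"
    } else if (unst_ind[i]) {
      hl <- hl_draw(config$half_life_unstable, 1L)
      slope_wt[i] <- slope_ko[i] <- -1 / hl
      cls[i] <- "unstable_independent"
    } else {
      hl <- hl_draw(config$half_life_stable, 1L)
      slope_wt[i] <- slope_ko[i] <- -1 / hl
      cls[i] <- "stable"
    }
  }
  data.frame(gene_id = genes, class = cls, slope_wt = slope_wt,
             slope_ko = slope_ko, fpkm0_gene = unname(fpkm0),
             stringsAsFactors = FALSE)
}

# Split each gene's baseline FPKM across isoforms.
plant_expression_truth <- function(ann, decay, config) {
  tx <- ann$transcripts
  out <- list()
  for (g in seq_len(nrow(decay))) {
    txg <- tx$tx_id[tx$gene_id == decay$gene_id[g]]
    w <- runif(length(txg), 0.5, 1)
    w <- w / sum(w)
    out[[g]] <- data.frame(tx_id = txg, gene_id = decay$gene_id[g],
                           fpkm0_tx = decay$fpkm0_gene[g] * w,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
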