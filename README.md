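# rbpatlas

Builds functionally annotated binding-site atlases for AU-rich-element
(ARE) binding proteins — tristetraprolin (TTP/Zfp36) and HuR (Elavl1) are
the motivating pair — from PAR-iCLIP alignments and actinomycin-D RNA-seq
decay time courses.

In PAR-iCLIP, 4-thiouridine-labelled RNA is UV-crosslinked to the protein
of interest; the crosslink either terminates reverse transcription (the
read's 5' end then starts 1 nt downstream of the crosslinked U, so
"position 0" marks the contact) or leaves a diagnostic T-to-C transition
when the polymerase reads through.  `rbpatlas` implements the analysis
route from such alignments to a site atlas:

* **Crosslink QC** — position-0 extraction, nucleotide composition around
  crosslinks, substitution spectra, and the overlap between termination
  positions and T-to-C transitions, genome-wide and within sites.
* **Peak calling** — a randomization (modFDR-style) null per gene region:
  observed events are uniformly redistributed, `FDR(h)` compares null and
  observed counts of positions with pileup ≥ h, and significant clusters
  are refined by *recursive summit splitting*: clusters whose summit is
  below 100 crosslinks are background; a site is cut where pileup falls
  below 30% of its summit, and emerging subsites are recursively cut at
  10% of their own summits.  A replicate-consensus filter keeps sites
  overlapping at least one site in every other replicate.
* **Annotation** — exon-first region classification across all isoforms
  (a site is exonic if exonic in *any* isoform; exonic sub-classes by
  3'UTR > 5'UTR > CDS priority), per-gene binding categories.
* **Scoring** — expression-normalized binding scores
  `score = area / (FPKM_gene + median FPKM · α)`, where `FPKM_gene` sums
  isoforms containing the site in their mature mRNA with FPKM ≥ 10.
* **Decay** — per-gene OLS of log2 FPKM on minutes after actinomycin D;
  half-life = −1/slope; genotype × time interaction tests for
  TTP-dependent decay; stability classification.
* **Structure classifier** — ARE scanning (`WAUUUAW`, `UUUKUUU`), RNA
  accessibility via a built-in McCaskill-style partition function (75-nt
  sliding windows, 7-nt stretches; exact inside/outside algorithm with a
  simple pair-energy model), one-feature LDA and rank-based ROC/AUC to ask
  whether sequence (AU content) or structure predicts binding.
* **Integration** — TTP/HuR site-overlap statistics, per-3'UTR site-count
  rank tests, k-mer enrichment against element backgrounds, Pearson
  correlations (Fisher-z CIs) of binding score against differential decay
  and expression, and a static atlas export (TSV/BED/bedGraph + manifest).
* **Synthetic data** — a first-class generator that plants binding sites,
  motif contexts (accessible vs hairpin-paired), crosslink chemistry
  (`p_trunc`, `p_tc`), and two-genotype exponential decay with a known
  binding→decay coupling, so every stage is validated against ground
  truth.

## Worked example

```r
library(rbpatlas)

pl <- run_pipeline(sim_config(seed = 1))

table(pl$sites$region)
#> intron   utr3
#>     26     14

head(pl$scores_utr3[order(-pl$scores_utr3$score), ], 3)
#>   gene_id area fpkm_gene     score
#> 4    g014  491   0.00000 23.015454
#> 6    g032  308   0.00000 14.437393
#> 1    g004  301  11.35457  9.208253

table(pl$calls$class)
#>                   stable   unstable_TTP_dependent unstable_TTP_independent
#>                       42                       12                        6

pl$correlations$score_vs_delta_decay
#> Pearson's r = 0.927, 95% CI [0.770, 0.978], p = 5.05e-06, n = 13
```

The default cohort plants 40 sites in 60 genes; all 40 are recovered as
replicate-consensus sites, split 26/14 between introns and 3'UTRs.  The
score table ranks 3'UTR-bound genes by crosslink area per expression unit
(a zero `fpkm_gene` means no isoform passed the FPKM ≥ 10 filter; the
median-FPKM correction keeps the score finite).  Because the generator
couples knockout stabilization to binding occupancy, the normalized score
correlates strongly with differential decay (`r = 0.93` here).

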