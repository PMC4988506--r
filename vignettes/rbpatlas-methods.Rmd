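---
title: "Methods: from crosslink events to a binding-site atlas"
author: "rbpatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from crosslink events to a binding-site atlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbpatlas)
```

`rbpatlas` turns PAR-iCLIP alignments and actinomycin-D RNA-seq time
courses into a functionally annotated atlas of RNA-binding-protein sites.
This vignette explains the models behind each stage, the parameters that
matter, the synthetic cohort used to validate them, and the design
decisions taken where the methodology left genuine choices open.

## Crosslink events and their diagnostics

PAR-iCLIP incorporates 4-thiouridine (4sU) into nascent RNA and
crosslinks it to the protein with 365-nm UV.  During library preparation
the crosslinked nucleotide either terminates reverse transcription — the
cDNA then starts one nucleotide downstream of the crosslinked U — or the
polymerase reads through and tends to misincorporate, leaving a T-to-C
transition at the crosslink.  `extract_crosslinks()` therefore defines
**position 0** of every read as the genomic position one nucleotide
upstream of its 5' end in transcript orientation: `start − 1` for a
plus-strand read, and the half-open `end` coordinate for a minus-strand
read.  The minus-strand convention is our choice (the rule is usually
stated for the plus strand only); it is the exact mirror of the
plus-strand rule, and the QC suite verifies that every statistic is
invariant under reverse-complementing the genome and flipping all reads.

Three diagnostics summarise whether a library behaves like crosslink
data: the nucleotide composition around position 0 (a genuine PAR-iCLIP
library is nearly pure U at offset 0, an RNA-seq control is flat), the
substitution spectrum (T-to-C should dominate), and the fraction of
position-0 loci that carry at least one T-to-C read at the same position.
That fraction is computed over **distinct loci**, not reads, with a
`per_read` option for the alternative; restricted to binding sites it
should exceed the genome-wide value, and on synthetic data (where
background reads carry no crosslink chemistry) it does so by a wide
margin.

## Cluster significance: a randomization null

A binding site is a region with significantly more crosslink pileup than
expected by chance.  `modfdr_call()` implements a randomization null in
the spirit of the modFDR approach: within each gene region the observed
events are redistributed uniformly at random `n_randomizations` times
(default 100); for every height `h`, `FDR(h)` is the mean number of null
positions with pileup at least `h` divided by the observed number; the
height threshold is the smallest `h` with `FDR(h) ≤ q` (default
`q = 0.01`).  Runs of positions at or above the threshold, bridging gaps
up to `min_region_gap` (default 1 nt), become candidate clusters.

The published description fixes neither the number of randomizations nor
the granularity of the null, so both are explicit configuration here, and
the null is *within-gene* (events cannot move across gene boundaries),
which matches the intent of testing a gene's internal signal
concentration.  Each region draws from an RNG substream derived by
hashing its gene identifier, so results are independent of processing
order and of which other regions are present.

## Recursive summit splitting

Crosslink clusters range from a single nucleotide to hundreds of
nucleotides containing several adjacent sites.  `split_sites()` applies
the filtering cascade: the cluster summit (maximum pileup, ties broken to
the lowest coordinate for determinism) must reach `summit_min = 100`
crosslinks, otherwise the cluster is background; walking outward from the
summit, the cluster is cut at the first position on each side where
pileup drops below `primary_frac = 0.30` of the summit; each remaining
segment is then processed recursively, cutting at
`secondary_frac = 0.10` of its *own* summit.  Cut positions belong to
neither flanking segment.  Three readings of the published rule were
possible; we fixed them as: fractions always refer to the current
segment's summit, the 10% rule applies recursively to sub-segments of
sub-segments, and the walk is a 1-nt sliding comparison (no window width
parameter).  An independent brute-force reference implementation (runs of
above-threshold positions over explicit index sets) is part of the test
suite and agrees with the walker on 1,000 random pileup vectors per run.

Replicates are called independently; `consensus_sites()` keeps a site only
if it overlaps (≥ 1 nt, same strand) at least one site in every other
replicate, retaining each replicate's own boundaries and reporting a
merged union track.

## Exon-first annotation

`classify_region()` assigns each site to the overlapping gene (larger
overlap wins; exact ties are reported once per gene and flagged) and
classifies it exon-first across all isoforms: exonic if any isoform has
an exon there, intronic only if no isoform does.  Exonic sites are
sub-classified with priority 3'UTR > 5'UTR > CDS over the features their
bases overlap — the priority is our choice; it resolves junction
straddlers in favour of the functionally salient 3'UTR and such sites are
additionally flagged.  Genes whose isoforms annotate the same bases as
both 3'UTR and intron can be excluded from cross-protein overlap analyses
(`exclude_heterogeneous`), mirroring the exclusion used for
heterogeneously annotated genes in comparative analyses.  Antisense
overlaps are never assigned.

## Expression-normalized binding scores

Crosslink counts conflate binding strength with expression.  The
normalized score of a gene is

```
score = area / (FPKM_gene + median_FPKM * alpha)
```

where `area` is the summed crosslink count over the gene's sites
(3'UTR-restricted for 3'UTR analyses), `FPKM_gene` sums the FPKMs of
transcript isoforms that contain the site within their mature mRNA and
pass the `FPKM ≥ 10` filter, and the median-FPKM term (over transcripts
passing the same filter) is a sparse-data correction preventing
spuriously large scores for weakly expressed genes.  `alpha` defaults
to 1; `alpha = 0` recovers the plain ratio.  Two interpretations were
left open and resolved as follows: "binding site area" is the crosslink
count sum (site width is available as an alternative), and intronic sites
use transcript-span containment, since intronic sequence is absent from
mature mRNA and the mature-mRNA containment rule cannot apply to them.

## Decay fits and stability classes

mRNA decay is modelled as exponential: log2 FPKM is linear in minutes
after actinomycin D, fitted by OLS with replicates pooled into a single
model (maximizing power at three replicates), and half-life is −1/slope
minutes (infinite for non-negative slopes; slopes within 1e−12 of zero
are treated as zero).  Genes with a zero FPKM value get a pseudocount
(default 0.1) and are flagged.  `differential_decay()` fits one model
with a genotype × time interaction; the interaction coefficient *is* the
differential decay `Δslope = b_KO − b_WT` used in all correlation
analyses, and its p-value tests for genotype-dependent decay.

`stability_calls()` classifies each gene: **stable** when the wild-type
half-life exceeds 180 min (the threshold is configuration; 180 min echoes
the half-life bound quoted for a canonically stable transcript), else
**unstable_TTP_dependent** when the interaction is significant
(`α = 0.05`) and the knockout half-life exceeds the wild-type one, else
**unstable_TTP_independent**.  The boundary rule used for the published
stability categories is not stated anywhere; ours is declared, not
inferred.

## Accessibility and the structure-vs-sequence classifier

ARE heptamers are scanned with IUPAC patterns (`WAUUUAW` for TTP,
`UUUKUUU` for HuR; W = A/U, K = G/U), overlapping matches included.
Accessibility of a 7-nt stretch is the probability that the stretch is
entirely unpaired under the secondary-structure ensemble of a 75-nt
sliding window, averaged over all windows containing the stretch (the
windowing detail is unstated in the methodology we follow; averaging over
covering windows is our choice).  Opening energy is `−RT log p`.

The built-in backend is an exact McCaskill-style inside/outside partition
function over non-crossing structures with a deliberately simple energy
model: per-pair energies GC −3, AU −2, GU −1 kcal/mol, minimum hairpin
loop 3 nt, no stacking or loop entropies.  The unpaired-stretch
probability uses the innermost-enclosing-pair decomposition, which the
test suite verifies against exhaustive Boltzmann enumeration of all legal
structures on sequences up to 18 nt (agreement to 1e−9; in practice
machine precision).  An optional `viennarna` backend shells out to
`RNAplfold` for Turner-parameter accessibilities when available; no test
depends on it.  One caveat of the pairing-only model matters for
interpretation: any pairing partner in the window wins over the unpaired
state by a factor of `exp(−E/RT)` ≈ 25 per pair, so AU-rich regions are
essentially always paired somewhere — accessibility contrasts are
meaningful only when the surrounding window controls partner
availability, which the synthetic generator does explicitly (below).

Bound and unbound motif occurrences (unbound = pattern matches in
expressed target 3'UTRs overlapping no consensus site) are compared by
one-dimensional linear discriminants on AU content and on opening
probability.  With one feature, LDA reduces to a monotone transform of
the feature, so the ROC is identical to thresholding the feature; the LDA
formulation is kept for parity with standard practice.  AUC is computed
by the rank (Mann-Whitney) formulation with ties counting one half, and
is cross-checked against an independent ROC implementation.

## Integration analytics

`overlap_sites()` reports strand-aware interval overlaps between two
proteins' site sets: per-set counts, overlapping pairs, gene-level
partitions, and the percent coverage of each site by the union of the
other set's sites.  `sites_per_utr()` compares per-3'UTR site counts with
a Mann-Whitney U test (exact for small tie-free samples, normal
approximation with continuity and tie correction otherwise — the test is
named but not the variant; we use R's standard implementation).
`correlate()` returns Pearson's r with a Fisher-z 95% CI.  K-mer
enrichment (k = 5–7) replaces EM-based motif discovery deliberately: site
sequences are compared against a 0-order background estimated from the
relevant genomic element class (introns or 3'UTRs), with binomial tail
p-values and Benjamini-Hochberg correction.  Differential expression
ships as a naive built-in (median-of-ratios normalization, baseline log2
fold change) and accepts an external per-gene table in its place.
`build_atlas()` joins everything into one record per gene and exports a
deterministic TSV/BED/bedGraph bundle with a JSON manifest.

The exported R functions and `run_pipeline()` are the package's
interface; the pipeline stages (`simulate`, `crosslink`, `callpeaks`,
`annotate`, `score`, `decay`, `structure`, `integrate`, `atlas`)
correspond to the functions documented above and are intended to be
driven from R or Rscript.

## The synthetic cohort

`sim_config()` fixes the study conditions the tests run under; the
defaults are chosen once and describe an activated-macrophage-like
cohort:

* 60 genes on one chromosome, alternating strands, three exons each with
  5'UTR/CDS/3'UTR structure; two-isoform genes skip the middle exon, so
  the same bases are exonic in one isoform and intronic in the other.
* 40 binding sites split intron/3'UTR/CDS = 0.64/0.35/0.01, matching the
  observed region distribution of TTP sites; summit heights 120–400
  crosslinks (the significance floor being 100).
* Crosslink chemistry: `p_tc = 0.45` (T-to-C's observed share of
  substitutions is ~45%); `p_trunc = 0.7` — the true truncation fraction
  is not reported anywhere, so it is a free parameter with a default
  chosen on the iCLIP premise that truncation dominates.  The planted
  summit height is realized as the exact number of truncation events at
  the summit U, with read-throughs added at rate
  `(1 − p_trunc)/p_trunc`, so "height" is a controlled condition rather
  than a binomial outcome.
* Decay: expression is sampled at 0/45/90 min after actinomycin D in
  three replicates per genotype, with log-normal noise (SD 0.2 log2
  units).  Binding causes decay: a target's knockout slope is its
  binding-free baseline (half-life 150–400 min) and its wild-type slope
  adds `decay_coupling × occupancy` (occupancy = planted site area /
  baseline FPKM), so the true differential decay equals
  `decay_coupling × occupancy` exactly and the score-decay correlation
  must grow with the coupling coefficient.  Non-targets are stable
  (half-life 300–600 min) or unstable independently of the protein (15%,
  half-life 30–90 min).  Differential expression is coupled to
  differential decay through `expr_coupling` (60 min-equivalents).
* Motif contexts: each bound site carries a `WAUUUAW` instance; an equal
  number of unbound decoys is planted in 3'UTRs.  Contexts are written
  over cytosine flanks wide enough (68 nt each side) that every 75-nt
  folding window containing the motif stays inside the planted context;
  paired contexts add the motif's reverse complement 8 nt downstream
  (hairpin stem), accessible contexts add more flank.  Under the
  pairing-only energy model this is the *only* way to control
  accessibility — in an A/U-rich flank the motif would always find a
  partner — and it equalizes the AU content of a motif-centred window
  between context classes, so the sequence feature is uninformative by
  construction while the structure feature separates bound from unbound.
  The AU-rich accessible flanks seen in real data are therefore *not*
  emulated; what passing tests show is that the classifier machinery
  ranks genuinely accessible motifs above stem-locked ones, not that the
  energy model reproduces physiological accessibility values.

What the generator does not emulate: sequencing errors beyond the
crosslink transition, PCR duplicates, paired-end reads, isoform-level
expression deconvolution, overdispersed counts, or transcriptional
shutoff artifacts in the decay series.

## Numerical choices and degenerate inputs

Summit ties break to the lowest coordinate; cut positions are excluded
from both flanking segments; empty pileup vectors, event-free regions and
empty site sets return empty results rather than errors; alignments with
unknown strand are rejected and counted; crosslink events at negative
coordinates are dropped with a warning; zero score denominators flag the
gene and exclude it from correlations; slopes within 1e−12 of zero count
as zero for half-life purposes.  Probabilities from the partition
function are exact up to floating-point accumulation (observed error
~1e−15 against enumeration); Boltzmann weights stay far below double
overflow for 75-nt windows under the simple energy model.

## Problem sizes

The validation suite exercises deliberately compact cohorts: the
recovery analysis uses 200 genes with 100 planted sites (summits ≥ 150),
chemistry recovery uses ~4 × 10⁴ read-through events, the partition
function is checked on 100 random sequences up to 18 nt, power analyses
use 100 simulated genes at 3 × 3 design points, and the end-to-end
cohort is the 60-gene default.  These sizes make every property cheap to
re-verify while keeping all estimators comfortably inside their
asymptotic regimes.

## Known limitations

The modFDR null internals (randomization count, null granularity) are
declared rather than reconstructed from the original tool; the
stable/unstable classification rule is ours; the energy model is far
from Turner parameters, so absolute accessibilities are not comparable
to `RNAplfold` output; SAM is emitted but not parsed (the tab dialect is
the canonical alignment exchange format); and the atlas export is a
static file bundle, not a served browser.
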