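---
title: "Methods: comparative genome-content profiling of MAG cohorts"
author: "limnoMAG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative genome-content profiling of MAG cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limnoMAG)
```

# The problem

Metagenome-assembled genomes (MAGs) binned from lake time-series
metagenomes are drafts: typically 50–95% complete, with a few percent
contamination. Comparative questions about such cohorts — which metabolic
pathways a population encodes, whether one lake's populations are richer in
glycoside hydrolases (GHs) than another's, whether a genome carries a
porin–multiheme-cytochrome electron conduit, whether a population persists
or blooms and busts — all require procedures that are explicit about
incompleteness. This vignette documents the models, rules and parameters
`limnoMAG` uses, the choices made where the design was genuinely open, and
what the synthetic validation does and does not establish.

# Tri-state pathway completeness

A pathway definition (`PathwaySet`) is an ordered list of enzyme *steps*;
each step is an OR-group of isofunctional annotation accessions (KO
primarily, COG/pfam/TIGRfam where no KO exists), and a subset of steps is
designated as *signature*: enzymes specific enough to the pathway that
their presence indicates the pathway itself rather than a reaction shared
with other pathways.

Completeness of a pathway in a genome is the fraction of steps with at
least one recovered accession. The reported state is:

* **fraction** — the signature is present in this genome, *or* absent here
  but present in at least `prevalenceThreshold(n)` = ⌈n/3⌉ cohort genomes
  (7 in a 19-genome cohort). The rescue exists because a missing signature
  in a half-complete draft is weak evidence of absence when a third of the
  cohort carries it.
* **zero** (`"0"`) — no step recovered at all.
* **likely absent** (`"(0)"`) — some shared steps present, but the
  signature is missing here and in more than two-thirds of the cohort.

Design choices where the convention leaves room:

* *One-third is a ceiling.* ⌈19/3⌉ = 7 matches the worked 19-genome cohort;
  ceiling is used for all cohort sizes.
* *Multiple signature steps use any-semantics*: the signature counts as
  present if any signature step is recovered. This is the permissive
  reading consistent with the purpose of the rescue (protecting incomplete
  genomes from false absence calls).
* *Pathways with no declared signature* can never be `"(0)"`; they report
  a fraction whenever at least one step is recovered and are flagged
  `no_signature` with a warning, because the absence evidence the tri-state
  convention relies on does not exist for them.
* *Fractions are exact* and only formatted (2 decimals) at serialization;
  whether to bin or round them further is left to presentation code.

Prevalence is computed once per pathway over the fixed cohort, so scoring a
genome never depends on the order genomes are visited. Adding genes to a
genome can only raise its completeness, and removing a genome from the
cohort can only lower prevalence support — both properties are enforced by
tests.

# Family censuses and coding density

`countFamilies()` counts genes per family for a class defined either by an
accession pattern (CAZy `GH<digits>`) or an explicit accession list
(sulfatase = pfam00884; PSCyt). A gene with two annotations in the same
family counts once there; a gene spanning two families counts once per
family but once toward the class total, so chimeric or multi-domain hits do
not inflate totals.

The **coding density** of a class is `100 · k / n` where `k` is the class
gene total and `n` the genome's total gene count. Normalizing by gene count
compensates for genome size and completeness under the assumption that
class members are randomly distributed between the recovered and missing
genome fractions; a subsampling test (50% of genes, 100 replicates) checks
that the estimator is unbiased under exactly that assumption.

The PSCyt class deserves a caveat: the planctomycete-specific cytochrome
and associated domains (PSCyt1–3, PSD1–5) have no universal database
accessions, so the class is an explicit, user-replaceable label list
(`pscytAccessions()`); the default simply names the domains.

Homology-based GH assignment uses two filters: HMM hits at E ≤ 1e−7, and —
for GH109, whose public HMM matches only an unspecific N-terminal domain —
a BLASTP rule of E ≤ 1e−6 plus ≥50% query coverage against reference GH109
proteins, with one acceptance (best E-value) per query locus.

Correlation diagnostics (`profileCorrelation()`) default to Pearson with a
two-sided p-value from the t distribution on n−2 degrees of freedom;
Spearman is exposed because published correlation coefficients of this kind
do not always state the method. Profile clustering defaults to correlation
distance with average linkage (the common choice for family-abundance heat
maps when the method is unstated); Bray–Curtis and complete linkage are
available, genomes are pre-sorted lexically so tie merges are
deterministic, and an all-zero profile under correlation distance is an
error that suggests Bray–Curtis instead.

# Locus detection

All three detectors work on gene-count windows along a contig, not
base-pair windows, making them robust to gene-length variation. Calls never
span contigs; overlapping qualifying windows merge into one maximal call
per locus type.

* **PCC (porin–multiheme cytochrome c)**: an outer-membrane gene with at
  least 20 predicted transmembrane beta strands adjacent (≤2 intervening
  genes) to a predicted periplasmic protein with at least 8 CxxCH
  heme-binding motifs. An extracellular MHC in the same cluster is recorded
  as optional evidence and included in the call span. The heme motif is
  fixed to the canonical c-type CxxCH (configurable); the count threshold
  defaults to ≥8 with an exact-8 option, since "eight conserved sites" can
  be read either way. Transmembrane-strand counts and localizations are
  trusted upstream predictions (beta-barrel and localization predictors run
  before the pipeline) and are never imputed.
* **CUT (carbohydrate utilization)**: ≥1 TonB-dependent receptor, ≥1
  inner-membrane sugar transporter and ≥1 GH within ≤15 consecutive genes.
  The fraction of member GHs predicted extracellular/outer-membrane is
  reported because surface-exposed hydrolases are the functional hallmark.
* **BMC (bacterial microcompartment)**: ≥1 shell-protein gene and ≥1
  fucose- or rhamnose-degradation gene within ≤15 genes.

The window defaults (2 intervening genes for PCC adjacency; 15-gene CUT/BMC
windows) comfortably contain published cluster diagrams of these locus
types, which fit in single contigs of ~6–70 kbp. Role membership is driven
by configurable accession lists (`lociConfig()`); the shipped defaults
cover the common accessions per role and are meant to be adapted to the
annotation source. Motif scanning counts all overlapping windows, `X` is
tolerated in sequences but never matches the anchored C/H positions, and an
empty sequence scans to zero rather than erroring.

# Coverage time series

Coverage arrives as a contig × sample matrix of raw read depths plus sample
metadata (group, date, total mapped bases). The exact normalization chains
used by published studies are often supplementary-only; `limnoMAG`
therefore defines a documented two-step contract:

1. multiply each sample's depths by (reference / sample total mapped
   bases), with the reference fixed to the median sample total — this
   cancels per-sample library-size factors exactly (scaling one sample's
   library and depths jointly leaves its normalized values unchanged);
2. aggregate each genome as the contig-length-weighted mean of its scaled
   contig depths, which makes the genome value invariant under splitting a
   contig at any position.

Each genome's series is restricted to its own lake group's samples, ordered
by date. Summaries are the median, mean and coefficient of variation
(CV% = 100·sd/mean, sample sd with n−1); the CV of an all-zero series is
undefined and flagged rather than zeroed. Classification defaults —
bloom-and-bust iff CV > 150% *and* median < 1.0; persistent iff CV ≤ 150%;
otherwise indeterminate — are calibrated to the qualitative contrast in
published cohort tables, where bloom-and-bust epilimnion populations show
medians near 0 with CVs of 170–580% while persistent bog populations sit
near CV 60–140% with medians above 1. Both knobs are exposed.

Contig curation flags contigs whose temporal pattern does not track the
genome consensus: the reference is the per-sample median over the genome's
contigs, contigs with Pearson r < 0.6 against it are flagged, the reference
is recomputed once without them and all contigs re-evaluated (single pass,
never iterated, so curation is deterministic and auditable). Published
descriptions give no threshold for "correlates well"; r = 0.6 is this
package's declared default. Zero-variance contig series have undefined r
and are flagged with an explicit reason.

# Sequence signatures

Tetranucleotide-frequency (TNF) vectors are computed in non-overlapping
5-kbp windows tiling each contig (the standard fragment size for
composition-based binning displays); a trailing fragment of at least 1 kbp
stands alone, a shorter one merges into the previous window, and contigs
under 1 kbp yield no usable vector. 4-mers are counted with single-base
offset, windows containing `N` skip affected 4-mers, and vectors are
L1-normalized (a window with no valid 4-mer is flagged invalid). The
default is the raw 256-dimensional vector; a canonical 136-dimensional mode
merging reverse-complement pairs is available and makes the signature
strand-independent. Self-organizing-map embedding is out of scope — the
vectors feed any downstream embedding or clustering.

Alignment trimming removes columns whose gap fraction exceeds 30%
(strictly greater, so a column at exactly 30% is retained), preserves row
order, reports removed column indices, and is idempotent.

# The synthetic cohort generator

`generateCohort()` is the validation harness's input source, and its
defaults *are* the study conditions the package targets: 19 genomes in
three groups (8 ME / 3 TE / 8 TH); completeness drawn uniformly from
51–95% and applied as an independent per-gene retention probability; GH
coding densities of ~1% (ME), ~3% (TE) and ~4% (TH) with group-contrasted
family compositions (GH2/GH29/GH78/GH95/GH106 overrepresented in bog
genomes, GH13/GH20/GH33/GH57/GH77 in eutrophic-lake genomes); sulfatase and
PSCyt densities with the PSCyt class enriched in epilimnion genomes; PCC
loci planted only in TH genomes (four of eight), CUT loci in one TE and one
TH genome, BMC loci in seven genomes across groups; and weekly coverage
series of 94 / 45 / 45 samples with bloom-and-bust dynamics (low baseline
0.05, Gaussian peak of amplitude 8 and 10-day width, lognormal noise) for
ME populations versus persistent dynamics (baseline 5, lognormal noise,
CV ≈ 30%) for TE/TH. Gene counts per genome span 1,200–5,600, matching the
cohort's printed range. One integer seed governs everything, with
per-genome substreams derived deterministically, so outputs are
byte-identical across runs.

What the generator deliberately does **not** emulate: real protein folds
(sequences are random amino acids with planted CxxCH motifs and recorded
transmembrane counts), assembly artifacts, chimeric bins, inter-genome
homology, shared marker genes, read-level noise, or correlated (operonic)
gene loss — dropout is independent per gene. Passing recovery tests
therefore shows the *rules* are implemented correctly and are recoverable
under idealized incompleteness; it does not validate upstream annotation,
localization or binning quality on real data.

Validation problem sizes: the multi-seed recovery suites run 100 seeds on a
compact five-genome configuration (2 ME / 1 TE / 2 TH, 800–1,200 genes,
24/20/20 samples) that preserves every group contrast of the default
conditions; exactness checks (planted pathway truth, family counts, locus
precision/recall) run with dropout disabled, where recovery must be
perfect, and oracle-equivalence checks enumerate all presence patterns at
≤5 steps × 6 genomes and scan 1,000 random proteins.

# Degenerate inputs and numerical conventions

* Coordinates are 1-based inclusive throughout (GFF3 convention).
* Missing localizations become `"unknown"`; missing transmembrane counts
  stay `NA`; neither is ever imputed.
* `NA` coverage cells are read as 0 with a warning (absence of mapped
  reads is the natural reading for a depth matrix); negative cells are
  errors.
* Samples with zero total mapped bases are excluded from normalization
  with a warning.
* Duplicate (pathway, step) definition rows merge their OR-groups with a
  warning; a pathway with zero steps is an error.
* All writers emit UTF-8 TSV with a commented header line; fractions are
  rounded only at serialization.

# Limitations

The package consumes upstream annotation, localization and beta-barrel
predictions as trusted inputs and provides no HMM/BLAST execution, no
assembly or binning, no alignment or tree inference, and no cross-assembly
abundance comparison (normalized depths compare samples within a series,
not absolute abundances between lakes). Cross-contig loci are not called.
The default role accession lists are starting points, not a curated
ontology; real analyses should review them against their annotation
pipeline.
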