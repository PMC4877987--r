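---
title: "Differential-coverage binning: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential-coverage binning: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covbinr)
```

## The model

A metagenome assembly mixes scaffolds from every genome in the community.
When the same community is sequenced twice — here, a short-term and a
long-term enrichment of the same reactor — each genome's abundance shifts,
and every scaffold of that genome shifts with it. Scaffold coverage in
sample $t$ is defined as

$$\mathrm{cov}(s, t) = \frac{\text{mapped bases}(s, t)}{\mathrm{len}(s)},$$

so in the plane of $(\log_{10}\mathrm{cov}_{t_1}, \log_{10}\mathrm{cov}_{t_2})$
the scaffolds of one genome form a tight cluster whose spread is set only
by sampling noise (for a scaffold of length $L$ at depth $c$ with reads of
length $r$, the read count is approximately Poisson with mean $cL/r$, so
the relative error shrinks as $1/\sqrt{cL/r}$). Coverage clustering is the
primary binning signal; two orthogonal signals clean up and complete the
bin:

* **Tetranucleotide frequency (TNF).** Genomes carry a compositional
  signature approximately uniform along the chromosome. We count all 4-mers
  in a sliding window of step 1, collapse each with its reverse complement
  (assembled scaffolds have arbitrary strand) to 136 canonical 4-mers, and
  normalise to frequencies summing to 1. Scaffolds recruited by coverage
  are clustered by average-linkage hierarchical clustering of the Euclidean
  distances between TNF vectors; the tree is cut at 0.1 and only the
  cluster with the greatest total scaffold length is kept. Removal events
  are logged with their merge heights.
* **Paired-end links.** Read pairs spanning two scaffolds witness physical
  contiguity. Scaffolds connected to the bin by at least `min_links = 2`
  pairs are re-attached when their coverage is not uniformly below
  one-third of the bin's length-weighted median — deliberately asymmetric,
  because the scaffolds this stage exists to recover (collapsed multi-copy
  regions) have coverage *above* the bin median.

The stage order — coverage selection, TNF refinement, PE rescue — is fixed,
and every inclusion or exclusion is written to a provenance log from which
the member set can be replayed (`replay_provenance()`).

## Quality control, comparison, activity

**Marker QC.** Against a marker set $M$ of single-copy genes (the shipped
sets have the canonical sizes 107 and 35),
completeness $= 100\,|M_\mathrm{found}|/|M|$ and redundancy
$= 100\,|M_{\ge 2\ \mathrm{copies}}|/|M_\mathrm{found}|$. "Duplicated"
counts *markers present in at least two copies*, not extra copies — the
only reading under which all the worked percentage pairs
(4/106 → 3.8, 2/105 → 1.9, 4/107 → 3.7, 3/106 → 2.8) are simultaneously
consistent. Reported percentages are rounded half away from zero to one
decimal; full precision is kept internally. A draft passes at
completeness > 96 % and redundancy < 5 % (both configurable).

**ANI.** Genome A is cut into consecutive 1,020 bp fragments, each aligned
locally against genome B; fragments with identity ≥ 60 % over ≥ 70 % of
their length are retained and ANI is their mean identity, symmetrised over
both directions. Alignment is delegated to NCBI blastn (`-task blastn`,
dusting off) on temporary files: blastn is the field's standard local
aligner, and shelling out to it is both faster and better tested than a
reimplementation of Smith–Waterman would be. Precomputed tabular
alignments can be substituted via `ani_from_hits()`. With no surviving
fragment the result is flagged indeterminate rather than coerced to 0.

**BBH and duplicated genes.** Hits are filtered at bit score ≥ 70,
identity ≥ 30 %, aligned fraction ≥ 0.70 of the query (inclusive
thresholds; "similarity" is read as percent identity); the best hit per
query breaks ties by identity, then lexicographic subject. A pair is
shared iff mutually best. A gene is duplicated iff it has any passing
non-self hit. All three filters are monotone: tightening any threshold can
only shrink the counts, a property the test-suite asserts.

**MRPKM.** $\mathrm{RPKM} = 10^9 c /(L\,N)$ for count $c$, gene length $L$,
library size $N$; $\mathrm{MRPKM} = \mathrm{RPKM}_\mathrm{RNA} /
\mathrm{RPKM}_\mathrm{DNA}$, which cancels $L$ and therefore measures
transcription per gene copy. Genes with zero DNA coverage get an
*undefined* MRPKM carried as `NA` with a `defined` flag — a zero would
conflate "present but silent" with "dosage unknown". Undefined values
propagate through summaries (an undefined gene never counts as
transcribed; an all-undefined group aggregates to flagged `NA`). Gene-group
scores default to the *sum* over homolog copies, with mean available,
because a cluster-level activity spanning several homologs has no single
canonical combination rule.

## The synthetic community

`simulate_community()` generates what the binning model assumes and labels
everything:

* genomes as order-0 (GC-only) base compositions — sufficient to exercise
  the 0.1 TNF cutoff, with an order-3 homopolymer-biased option for harder
  refinement tests;
* scaffolds as an exact tiling (concatenation reconstructs the genome
  byte-for-byte; every scaffold ≥ 1 kb, matching the assembly length
  filter binning inherits);
* mapped-read counts as Poisson with mean
  $\mathrm{cov}\cdot\mathrm{len}/\mathrm{read\_len}$ — the simplest model
  consistent with the coverage definition; over-dispersion can be emulated
  by varying per-genome coverage, but is deliberately not the default;
* markers planted one per set member with controlled dropout and
  duplication, so truth completeness/redundancy follow the same arithmetic
  the QC stage computes;
* intra-genome paired-end links between adjacent scaffolds plus optional
  single cross-genome noise links;
* DNA counts proportional to gene length × genome coverage, RNA counts
  zero for inactive genes and length-proportional for active ones.

`demo_community()` fixes the study conditions used throughout the tests:
four genomes with coverage pairs separated at least five-fold in one
sample — (100, 30), (15, 150), (4, 20), (30, 4) — GC contents
0.54 / 0.65 / 0.40 / 0.54, dropout/duplication patterns giving planted
completeness 99.1 / 98.1 / 100.0 / 99.1 % and redundancy
3.8 / 1.9 / 3.7 / 2.8 %, active-gene fractions 27.8 / 35.4 / 18.1 / 2.8 %,
and two planted contaminant scaffolds sharing the first genome's coverage
pair. Choices the generator had to make itself:

* **Genome length 600 kb, ~6,000 genes each.** Real draft genomes of this
  kind run 3–4 Mb with ~3,000–3,700 genes; simulating full length is
  unnecessary for the binning signal, but the *gene count* controls the
  sampling error of the per-bin transcribed fraction
  ($\sigma \approx \sqrt{p(1-p)/n}$, ≈ 0.6 points at $n \approx 6{,}000$,
  $p \approx 0.3$), so the stand-ins keep a full genome's gene complement
  on a desk-scale sequence. Scaffold lengths are exponential above the
  1 kb floor with mean 15 kb, the order of magnitude of a typical
  metagenome assembly N50 (~20 kb).
* **Contaminant GC 0.20.** Order-0 sequences have weak TNF signatures:
  empirically, the expected TNF distance between order-0 genomes at GC
  0.54 vs 0.30 is ≈ 0.09 — *below* the 0.1 cutoff — while 0.54 vs 0.20 is
  ≈ 0.14 with within-genome distances ≈ 0.016 at 5 kb. An AT-rich
  contaminant (GC ≈ 0.20, as in some low-GC firmicutes) is therefore the
  realistic composition gap at which the refinement stage operates on
  GC-only sequences. Real genomes carry higher-order structure and
  separate more easily; this is a conservatism of the generator, not of
  the method.

What the generator does **not** emulate: sequencing error, chimeric
scaffolds, strain microheterogeneity, GC-dependent coverage bias,
repeat-induced fragmentation, and multi-mapping ambiguity. Passing the
recovery tests therefore demonstrates correctness of the arithmetic and
the recruitment logic under the model's assumptions, not performance on
adversarial real assemblies.

## Numerical choices and degenerate inputs

* Zero coverage is floored at 0.01× before $\log_{10}$ so zeros stay
  representable in selection and plotting; coverage is stored linear.
* Point-in-polygon is boundary-inclusive (even-odd rule plus an explicit
  on-edge test); polygon closing edge is implied.
* TNF refinement: the distance scale behind the 0.1 cutoff is not uniquely
  determined by convention, so the scaling is configurable
  (`fraction` — frequencies summing to 1, the default — `percent`, or
  `zscore`); no numeric equivalence with any particular external
  implementation is claimed. Average linkage is the default (robust to
  single outliers); complete linkage is available. Largest-total-length
  cluster wins, ties broken by scaffold count then smallest scaffold ID.
  A single cluster at the cutoff removes nothing (valid, not an error).
  Windows containing ambiguous bases are skipped.
* `cutree` at an infinite cutoff is special-cased to one cluster.
* SAM ingestion counts primary mapped records only (each read once);
  mapped bases are the reference-consuming CIGAR span. Whether multi-mapped
  reads should count multiply is exposed nowhere — summaries state what
  their mapper wrote, and the TSV route accepts any convention upstream.
* Empty bins report completeness/redundancy 0/0 with a warning; redundancy
  with zero identified markers is 0 by convention.
* An empty coverage selection is an error (with a suggestion to widen the
  region), because silently empty bins propagate confusingly.

## Problem sizes

The shipped tests run the full pipeline on the four-genome community
(~2.4 Mb of sequence, ~150 scaffolds, ~24,000 genes, two samples), ANI on
genomes of 12–30 kb, and oracle comparisons on 100 × 10 kb sequences —
sizes at which the whole suite completes in well under a minute while
every statistical check retains the precision argued above.

## Known limitations

* Two-sample workflows are first-class; the data structures allow more
  samples but selection regions are two-dimensional.
* The shipped marker-set ID lists are placeholders of the canonical sizes
  (107, 35); real accession lists should be supplied for production QC.
* DDH is consumed as an input to species classification, never computed.
* `auto_seed_regions()` automates what is classically done by eye; with
  overlapping coverage clusters manual regions remain the honest choice.
* ANI requires blastn on `PATH`; without it, precomputed alignments must
  be supplied.
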