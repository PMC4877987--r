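# covbinr

Differential-coverage genome binning and transcriptional-activity scoring
for metagenomes, in R.

## The problem

Most microbes in engineered and environmental communities (anaerobic
digesters, enrichment reactors, sediments) have no cultured representative,
so their genomes must be recovered directly from metagenome assemblies.
When the same community is sequenced at two time points (or under two
conditions), scaffolds belonging to one genome share a characteristic pair
of read depths — they cluster in the plane of per-sample coverage. `covbinr`
turns that observation into a tested, replayable pipeline:

1. **Coverage binning.** Coverage of a scaffold is total mapped bases
   divided by scaffold length. Scaffolds are recruited from a region of the
   two-dimensional log10-coverage plot (drawn by hand or auto-seeded from
   density clusters).
2. **Composition refinement.** Canonical tetranucleotide frequency (TNF;
   136 reverse-complement-collapsed 4-mers, frequencies summing to 1) is
   clustered hierarchically; cutting the tree at a Euclidean distance of
   0.1 and keeping the largest cluster removes compositional contaminants.
3. **Paired-end rescue.** Scaffolds linked to the bin by ≥ 2 read pairs are
   re-attached, recovering members excluded by coverage anomalies such as
   multi-copy regions.
4. **Marker QC.** With a set *M* of single-copy marker genes (107 essential
   single-copy genes, or 35 conserved COGs as a cross-check),

   completeness = 100 · |markers identified| / |M|,
   redundancy = 100 · |markers in ≥ 2 copies| / |markers identified|,

   both reported to one decimal; a draft passes at completeness > 96 % and
   redundancy < 5 %.
5. **Genome comparison.** Fragment-based ANI (1,020 bp fragments, ≥ 60 %
   identity and ≥ 70 % fragment coverage retained, mean identity of retained
   fragments; symmetric by default), bidirectional-best-hit shared genes
   (bit score ≥ 70, identity ≥ 30 %, ≥ 70 % query coverage), duplicated-gene
   counts under the same filters, and species delineation at ANI 94 % / DDH
   70 %.
6. **Activity scoring.** RPKM = 10⁹ · count / (gene length · library size),
   computed from the metagenome (RPKM-DNA) and metatranscriptome
   (RPKM-RNA); their ratio MRPKM measures per-gene transcription normalised
   for gene dosage. A gene with zero DNA coverage has *undefined* MRPKM,
   never a silent 0.

A fully labelled synthetic-community generator (genomes → scaffolds →
mapping summaries, planted markers, paired-end links, DNA/RNA counts)
makes every stage testable against known ground truth without any
sequencing data.

## Worked example

```r
library(covbinr)

cm  <- demo_community(seed = 1)           # 4 genomes + 2 contaminant scaffolds
dir <- tempfile("demo"); write_community(cm, dir)
res <- run_pipeline(dir, file.path(dir, "out"))
res$summary
#>   bin_id n_scaffolds total_length_bp completeness_pct redundancy_pct
#> 1  bin_1          37           6e+05             98.1            1.9
#> 2  bin_2          30           6e+05            100.0            3.7
#> 3  bin_3          46           6e+05             99.1            3.8
#> 4  bin_4          39           6e+05             99.1            2.8
#>   abundance_LE_pct abundance_SE_pct genes_transcribed_pct
#> 1             63.8              8.6                  34.8
#> 2              8.5              2.3                  18.6
#> 3             12.7             57.6                  27.7
#> 4              1.7             17.3                   2.4
```

Each row is one recovered bin: its scaffold count and summed length, marker
completeness/redundancy (here equal to the planted truth of the matching
genome), relative abundance (bin reads as % of each sample's library), and
the fraction of its genes with detected transcription. Against the
generator's truth table every bin here has precision = recall = 1.0 for
scaffolds ≥ 5 kb, and the two planted AT-rich contaminant scaffolds were
removed by the TNF stage (see `res$bins$bin_1$provenance`). Species
delineation from a published ANI/DDH pair:

```r
classify_species(79.3, 17.7)
#> <species_call> ANI 79.3%, DDH 17.7% -> different_species
```

## Layout

- `R/` — generator, TNF, coverage, binning, marker QC, comparison,
  transcription, pipeline modules
- `inst/extdata/marker_sets/` — marker-set ID lists (placeholder IDs of the
  canonical sizes; swap in real accessions via `marker_set(path)`)
- `vignettes/differential-coverage-binning.Rmd` — methods and design notes
- `tests/testthat/` — unit, property and acceptance suites
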