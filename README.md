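# viromeflow

Gut metagenomes contain thousands of uncultivated phage genomes, but raw
assembled contigs are not a virome: they must be quality-filtered,
dereplicated into species-level viral operational taxonomic units (vOTUs),
organised into higher ranks, quantified by read recruitment, and only then
analysed as an ecological community. `viromeflow` implements that pipeline
for R users — microbial ecologists and virome bioinformaticians — together
with a synthetic-data generator that produces every input with known ground
truth, so the whole chain is testable on a laptop without downloading any
metagenomes.

## What it computes

**Catalog construction**

- *Contig QC* — terminal-repeat detection (a direct terminal repeat, DTR,
  or inverted terminal repeat, ITR, is the sequence signature of a complete
  phage genome), retention filtering (keep a contig iff completeness ≥ 50,
  viral genes > 0 and viral genes > 3× host genes; or length ≥ 20 kb with
  completeness ≥ 40 and the same gene clauses), and quality tiers
  (complete / high / medium / low).
- *Species-level dereplication* — pairwise ANI computed by combining local
  alignments: ANI = Σᵢ(pidᵢ·lenᵢ)/Σᵢlenᵢ with coverage from merged (union)
  alignment intervals, then CD-HIT-style greedy centroid clustering at the
  MIUViG species criterion: ≥ 95 % ANI over ≥ 85 % of the shorter sequence.
- *Genus/family ranks* — per-pair average amino-acid identity (AAI) over
  best protein hits (E < 1e−5, ≥ 50 % bidirectional coverage), edges kept
  at ≥ 20 % shared genes & ≥ 40 % AAI (genus) or ≥ 10 % & ≥ 20 % (family),
  clustered with an in-package Markov Clustering algorithm (inflation 2.0
  and 1.2 respectively).
- *tANI* — whole-genome "total ANI" (identity discounted by aligned
  fraction) with single-linkage species/genus demarcation at 95 % / 70 %.

**Ecology**

- *Read recruitment* — per-read identity ≥ 90 %, aligned fraction ≥ 75 %,
  and per-genome breadth (covered fraction) ≥ 75 %; abundances relative to
  total sample reads and within-virome composition.
- *Community statistics* — richness, region-wise core viromes at 25/50/75 %
  prevalence, species-accumulation curves (random permutations),
  Bray–Curtis dissimilarity, one-way PERMANOVA (pseudo-F with permutation
  p), principal coordinates analysis, pairwise Wilcoxon / Kruskal–Wallis
  tests, host-taxon aggregation, and a negative binomial richness model
  (`richness ~ breed * diet`).

**Synthetic data** — hierarchically diverged viral lineages (family >
genus > species > variants) by seeded per-base substitution with small
indels; contig decoration (truncation, DTR/ITR, provirus labels, gene
counts); a built-in k-mer-anchored aligner emitting local-alignment
tables; and region-structured read simulation in which the proximal gut is
dominated by Lactobacillaceae-infecting phages and the distal gut by
Lachnospiraceae/Bacteroidaceae/Ruminococcaceae hosts.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data and write tables to `results/`:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

Step 3, for example, dereplicates 120 genomes (40 true species × 3
variants, within-species divergence ~3 %, between-species ≥ 15 %) and
prints:

```
40 species-level vOTUs from 120 genomes (true species: 40)
adjusted Rand index vs truth: 1.000
membership certificate: min ANI 96.63, min shorter-cov 94.01
```

i.e. greedy clustering at 95/85 recovers the planted species exactly, and
every member certifiably exceeds both thresholds against its centroid.
Step 6 closes the loop on the ecology side:

```
PERMANOVA: pseudo-F = 285.025, R2 = 0.882, p = 0.001 (999 permutations)
Lactobacillaceae-phage abundance, proximal 0.027 vs distal 0.000 (Wilcoxon p = 7.6e-09)
NB model (theta = 3.58): breed rate ratio 1.57 (planted 1.5), breed p = 0.00058
```

— the planted proximal/distal host-family niche structure and the planted
breed effect on richness are both recovered.

A minimal in-session example:

```r
library(viromeflow)
ev  <- evolve_lineages(lineage_spec(), seed = 1)
ani <- compute_ani(emit_alignments(ev$genomes), genome_lengths(ev$genomes))
cl  <- greedy_cluster(genome_lengths(ev$genomes), ani)  # 95/85 vOTUs
length(unique(cl$centroid_id))
#> [1] 40
```

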