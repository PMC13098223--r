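---
title: "Methods: vOTU catalog construction and virome ecology"
author: "viromeflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vOTU catalog construction and virome ecology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`viromeflow` turns assembled metagenomic contigs into a species-level vOTU
catalog and analyses the resulting community. This vignette documents the
models and procedures, the tunable parameters and their defaults, the
numerical choices, what the synthetic-data generator does and does not
emulate, and the known limitations. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## Contig quality control

**Terminal repeats.** A complete, circularly permuted phage assembly ends
where it began: its first *k* bases recur as its last *k* bases (a direct
terminal repeat, DTR). Linear genomes of some families instead end in an
inverted terminal repeat (ITR): the prefix equals the reverse complement
of the suffix. `detect_termini()` searches strictly terminal repeats — the
repeat must start at base 1 and end at the final base — and reports the
maximal qualifying length, capped at half the genome so prefix and suffix
stay disjoint. DTR takes precedence over ITR when both qualify (a
palindromic repeat satisfies both). Parameters: `min_repeat_len` (default
20 bp) and `max_mismatches` (default 0), the conventional minimums for
closed-genome calling; both are exposed because the right stringency
depends on assembler error profiles. At these defaults a random 30 kb
sequence has essentially zero probability of a false call (the expected
number of chance 20-mer prefix/suffix matches is ≈ (L/2)·4⁻²⁰ ≈ 10⁻⁸),
which the tests verify empirically over seeded draws, alongside exhaustive
agreement with a brute-force all-*k* scan on genomes ≤ 5 kb. The DTR scan
seeds on the first `min_repeat_len` bases against all admissible suffix
positions and verifies candidates longest-first; the ITR scan exploits the
fact that position *i* must pair with position *L*+1−*i*, reducing the
maximal-*k* search to a cumulative-sum pass. Provirus calls are *not*
detected from sequence: they are trusted from the input QC table, since
provirus boundaries come from host-flank evidence that a repeat scan
cannot see.

**Retention rules.** A contig is kept iff

* completeness ≥ 50, viral genes > 0 and viral genes > 3 × host genes, **or**
* length ≥ 20,000 bp, completeness ≥ 40, viral genes > 0 and
  viral genes > 3 × host genes.

Both inequalities on the gene ratio are strict (`viral == 3 × host`
fails). Contigs with *missing* completeness are rejected rather than
guessed: both rules condition on completeness, and imputing it would
silently change catalog membership. Rejected rows carry the first failed
clause as a machine-readable reason. Retention is monotone: raising the
completeness or viral-gene count of a kept contig can never reject it
(property-tested).

**Tiers.** Kept contigs are tiered: `complete` when termini ∈ {DTR, ITR,
provirus} (a closed-genome signal dominates any completeness estimate),
else `high` (completeness ≥ 90), `medium` (≥ 50), `low` (< 50; such
contigs survive only via the long-contig rule). Boundaries are inclusive.

## Species-level dereplication (ANI at 95/85)

Pairwise ANI is computed *by combining local alignments*: the identity is
the alignment-length-weighted mean of per-alignment percent identities,

ANI(q,t) = Σᵢ pidᵢ·lenᵢ / Σᵢ lenᵢ,

while query and target coverage come from the *merged union* of alignment
intervals on each sequence, so overlapping alignments never double-count
coverage but also never dilute the identity weighting. Coordinates are
converted from the external 1-based inclusive convention to 0-based
half-open exactly once, at the I/O boundary; minus-strand rows are
normalised to ascending target coordinates with a strand flag, and
coverage ignores strand. Self-alignments are excluded from ANI (the
alignment table flags them); pairs absent from the table are treated as
ANI 0 — no transitivity is assumed.

Greedy clustering then mimics CD-HIT: genomes are processed in descending
length order (ties broken by ascending id, which makes the output
invariant to input row order); each genome joins the first existing
centroid with ANI ≥ 95 and coverage of the *shorter* sequence ≥ 85 %,
otherwise it founds a cluster. We enforce coverage of the shorter
sequence — the wording of the MIUViG species criterion — rather than
strict target-coverage semantics; a `coverage = "target"` switch restores
the latter. `certify_clusters()` re-checks every membership post hoc, so a
clustering can always be audited against its own thresholds.

## Genus and family ranks (AAI + MCL), and tANI

**AAI.** Protein hits are filtered at E < 1e−5 with ≥ 50 % query and
subject coverage; within each genome pair the best hit per query protein
is kept (lowest E-value, then highest identity, then lexicographic target
id — a deterministic tie-break). AAI is the unweighted mean identity over
kept hits; the shared-gene fraction uses the *smaller* genome's gene count
as denominator so that fragments remain comparable. Hits are used
unidirectionally with symmetric emission; whether reciprocal-best-hit
filtering would change rank assignments is an open modelling choice we
deliberately left at the simpler reading.

**Rank graphs and MCL.** Edges require ≥ 20 % shared genes and ≥ 40 % AAI
(genus) or ≥ 10 % and ≥ 20 % (family); edge weight is the AAI. Markov
Clustering is implemented in-package: self-loops at each node's maximum
incident weight (1 for isolated nodes), column normalisation, then
alternating expansion (matrix squaring) and inflation (element-wise power,
renormalise), pruning entries < 1e−5, until the matrix changes by < 1e−6
or 100 iterations (non-convergence returns the current interpretation
with a warning). Clusters are the connected components of the limit
matrix's non-zero structure; isolated nodes become singletons. Inflation
2.0 (genus) and 1.2 (family) are the standard granularity settings. The
implementation is cross-checked in the tests against an independent
numpy reference (`inst/oracle/mcl_reference.py`) for exact partition
agreement on planted-partition graphs.

**tANI.** Whole-genome "total ANI" discounts identity by aligned
fraction: `tani = ani × (qcov + tcov)/2 / 100` (a length-symmetric
choice; `method = "min"` gives the conservative alternative). Species and
genus partitions are single-linkage components at 95 % and 70 %; because
the species edge set is a subset of the genus edge set, the species
partition provably refines the genus partition. A caveat the analysis
scripts demonstrate: at 95 %, tANI is *strict* — multiplying ~97 %
identity by a ~95 % aligned fraction already falls below the cut — so it
suits near-complete genomes compared with a sensitive aligner, not
partial-coverage catalogs; that is why species dereplication uses the
ANI + shorter-coverage criterion instead.

## Read recruitment and abundance

Per-read metrics follow read-mapper conventions: identity =
100·(A − NM)/A where A counts CIGAR M/=/X + I + D columns (the
denominator consistent with the NM edit distance; a `"M"`-only switch
exists), and aligned fraction counts read bases in M/=/X/I over the full
read length, so soft-clips count against the read. Reads need identity
≥ 90 and aligned fraction ≥ 75; only mapped primary alignments ever
contribute. Breadth — the fraction of genome positions covered by ≥ 1
*passing* read (read filters apply first) — must reach 75 % or the
genome's count is zeroed; breadth filtering is what suppresses spurious
detections driven by a single conserved region. Abundance is recruited
reads over total sample reads; a within-virome composition matrix
(recruited reads as denominator) is emitted alongside, and the
composition analyses consume the latter. All three filters are monotone:
tightening any threshold can only decrease abundances (property-tested).

## Community statistics

* **Richness** counts vOTUs with abundance strictly > 0 (i.e. after
  breadth filtering); presence everywhere in the package means exactly
  this.
* **Core viromes** compute prevalence within each group only and count
  vOTUs at ≥ 25/50/75 % prevalence.
* **Accumulation curves** average cumulative distinct-vOTU counts over
  random sample orderings (default 1000 permutations); the final value
  equals the total distinct count for every seed, and on disjoint-sample
  fixtures the curve is exactly linear — both are used as test closed
  forms, plus agreement with exact enumeration over all orderings at
  small n.
* **Bray–Curtis**: d = Σ|xᵢ−xⱼ| / Σ(xᵢ+xⱼ); two all-zero samples are
  defined to be at distance 0 (the degenerate 0/0 case).
* **PERMANOVA** (one-way): with squared distances d², SS_total =
  Σ_{i<j} d²/n, SS_within sums within-group pairs divided by group size,
  pseudo-F = (SS_B/(k−1))/(SS_W/(n−k)), R² = SS_B/SS_total, and p is the
  permutation tail probability (1 + #{F* ≥ F})/(1 + n_perm) under free
  label permutation (999 by default, so the minimum attainable p is
  0.001). F and R² agree with `vegan::adonis2` to 1e−10 in the tests;
  the permutation scheme is unstratified, matching the one-factor
  designs used here.
* **PCoA** is classical scaling of the Gower-centred −½d² matrix;
  negative eigenvalues (possible for Bray–Curtis) are reported, and
  coordinates are returned for positive axes only.
* **Rank tests and the richness model** delegate to `stats::wilcox.test`
  / `stats::kruskal.test` (pairwise matrices reported raw and
  Holm-adjusted; Holm is what a significance-letter display should use)
  and `MASS::glm.nb` (log link, ML dispersion, Poisson fallback with a
  warning if the dispersion estimate diverges). These are standard,
  well-tested fits; re-implementing them would add risk without adding
  science.
* An optional prevalence pre-filter (`filter_by_prevalence`, e.g. ≥ 10
  samples) is provided as an explicit step before ordination; it is never
  applied implicitly.

## The synthetic-data generator

The generator is the package's study design, not a test convenience; its
defaults are the conditions under which every claim is evaluated.

* **Lineages**: 4 families × 2 genera × 5 species × 3 variants (120
  genomes of 6–10 kb). Branch substitution rates 0.015 / 0.08 / 0.15 per
  base at species/genus/family rank give ~3 % pairwise divergence within
  species (safely inside the 95 % ANI species criterion) and ~16 %
  between species (safely outside). Indels accompany substitutions at one
  tenth the rate with geometric(0.5) lengths — enough to exercise gap
  handling while keeping the global-alignment oracle tractable. Genome
  lengths are kilobases rather than the tens of kilobases typical of real
  phages purely to keep all-vs-all alignment fast; none of the validated
  properties depend on absolute length.
* **Contigs**: tier design 20/25/45/10 % (complete/high/medium/low);
  within the complete tier, termini are DTR-dominated
  (78.6/20.7/0.7 % DTR/ITR/provirus, the empirical ratio of closed phage
  genomes). Tier-proportion recovery tests use ~50 kb roots so that
  low-completeness contigs can still clear the 20 kb rescue rule.
* **Alignments**: a k-mer-anchored ungapped block aligner (17-mer
  candidate screen, 13-mer seeds grouped by diagonal, one span per
  diagonal with look-ahead extension through isolated mismatches, and
  excision of windows whose local identity collapses to random — those
  are segments where the true alignment sits on another diagonal, e.g.
  between compensating indels). It is not a general aligner: it targets
  pairs above ~70 % identity with short indels, exactly what the
  generator emits, and it exists so the pipeline never shells out to an
  external alignment tool. Pairs below the candidate screen share almost
  no long exact k-mers and are correctly emitted as "no alignment".
* **Communities**: each sample's region selects a host-family mixture
  (proximal: Lactobacillaceae 0.60; distal: Lachnospiraceae 0.35,
  Bacteroidaceae 0.25, Ruminococcaceae 0.20), split across that family's
  vOTUs with gamma noise; viral reads are binomial at the design's viral
  fraction (default 1.5 %, the mapped-fraction scale seen in gut
  metagenomes), placed uniformly with independent per-base substitution
  errors (default 2 %) and exact NM bookkeeping, emitted as primary-only
  SAM with match-only CIGARs (the most common mapper dialect). Non-viral
  reads are counted in totals but not materialised.
* **Richness designs** for the breed × diet model are drawn directly from
  the negative binomial with multiplicative effects.

What the generator does **not** emulate — and hence what green tests do
not establish about real data: assembly chimeras and strain mosaics;
repeat-induced misassembly; GC/coverage biases; read-quality profiles
(no FASTQ qualities); phylogenetically realistic substitution models;
proviruses as sequence context (only as labels); and host-prediction
error, since host labels are generated, not inferred.

## Numerical and design choices

* Interval arithmetic is 0-based half-open internally; conversion happens
  once at parse/write time. Interval merging delegates to IRanges.
* Deterministic tie-breaks everywhere a choice exists (length then id in
  clustering; E-value, identity, then target id in best-hit selection), so
  every pipeline stage is a pure function of its inputs.
* Seeded operations take an explicit `seed` and restore the caller's RNG
  state; generator stages derive decoupled child seeds so adding a stage
  never perturbs another stage's stream.
* The NB recovery study reports the marginal (EMM-style) breed contrast
  exp(β_breed + ½β_interaction) from the `breed * diet` fit — the natural
  "breed rate ratio" when the design is balanced. At the study conditions
  (n = 30 per cell, dispersion 0.3, true ratio 1.5) the probability that
  the point estimate lands in [1.3, 1.7] is ≈ 0.81, so a 100-replicate
  estimate of that rate fluctuates around 0.80 by a few points across
  seeds; this is a property of the planted design's information content,
  not of the estimator.
* Problem sizes in tests and the acceptance script (120-genome catalog,
  3 kb ANI-oracle pairs, 30-node MCL graphs, 16-sample null PERMANOVA
  with 199 permutations × 200 replicates, 40-sample regional designs)
  were chosen so the full validation runs in minutes on one core while
  keeping every statistical check adequately powered.

## Limitations

The built-in aligner substitutes for BLAST-style search only within the
generator's divergence regime; real catalogs should feed externally
computed alignment tables through the same interfaces. PERMANOVA is
one-way and unstratified. tANI's exact definition varies between tools;
ours is documented above and switchable. SAM support is the text subset
needed for recruitment (no BAM). NMDS ordination, geographic mapping and
mixed-effects models are out of scope.
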