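#!/usr/bin/env Rscript
# Step 4 — genus- and family-level clustering: protein-hit tables with
# designed rank structure, per-pair AAI with shared-gene fractions, edge
# thresholding (genus >= 20% shared genes & >= 40% AAI; family >= 10% &
# >= 20%), Markov Clustering at inflation 2.0 / 1.2, and a tANI
# single-linkage clustering at 95% / 70% of the same catalog.

suppressMessages({
  library(viromeflow)
  library(data.table)
})

truth <- fread("results/lineage_truth.tsv")

ph <- simulate_protein_hits(truth, seed = 1003)
fwrite(ph$hits, "results/protein_hits.tsv", sep = "\t")

aai <- compute_aai(ph$hits, ph$gene_counts)
fwrite(aai, "results/aai_pairs.tsv", sep = "\t")
nodes <- names(ph$gene_counts)

for (rank in c("genus", "family")) {
  g <- build_rank_graph(aai, nodes, rank)
  r <- cluster_rank(g)
  lbl <- truth[[paste0(rank, "_id")]][match(names(r$membership),
                                            truth$genome_id)]
  ari <- mclust::adjustedRandIndex(r$membership, lbl)
  message(sprintf("%s-level: %d clusters (true %d), ARI %.3f, %s",
                  rank, r$n_clusters, length(unique(lbl)), ari,
                  if (r$converged) "converged" else "NOT converged"))
  fwrite(data.table(genome_id = names(r$membership),
                    cluster = r$membership),
         sprintf("results/%s_clusters.tsv", rank), sep = "\t")
}

# tANI clustering (whole-genome identity discounted by aligned fraction,
# species/genus at 95%/70%) on a designed set emulating a small order of
# near-complete gut phage genomes with clear rank structure
set.seed(1010)
tani_truth <- data.table(
  genome_id = sprintf("cr%02d", 1:12),
  species_id = rep(sprintf("sp%d", 1:4), each = 3),
  genus_id = rep(c("gen1", "gen2"), each = 6))
pairs <- t(combn(tani_truth$genome_id, 2))
same_sp <- tani_truth$species_id[match(pairs[, 1], tani_truth$genome_id)] ==
  tani_truth$species_id[match(pairs[, 2], tani_truth$genome_id)]
same_gen <- tani_truth$genus_id[match(pairs[, 1], tani_truth$genome_id)] ==
  tani_truth$genus_id[match(pairs[, 2], tani_truth$genome_id)]
tani_tab <- data.table(
  genome_a = pairs[, 1], genome_b = pairs[, 2],
  tani = ifelse(same_sp, runif(nrow(pairs), 95.5, 99),
                ifelse(same_gen, runif(nrow(pairs), 72, 85),
                       runif(nrow(pairs), 30, 55))))
part <- tani_cluster(tani_tab, nodes = tani_truth$genome_id)
fwrite(data.table(genome_id = tani_truth$genome_id,
                  species_cluster = part$species[tani_truth$genome_id],
                  genus_cluster = part$genus[tani_truth$genome_id]),
       "results/tani_clusters.tsv", sep = "\t")
message(sprintf(
  "tANI partitions: %d species (ARI %.2f), %d genera (ARI %.2f)",
  length(unique(part$species)),
  mclust::adjustedRandIndex(part$species[tani_truth$genome_id],
                            tani_truth$species_id),
  length(unique(part$genus)),
  mclust::adjustedRandIndex(part$genus[tani_truth$genome_id],
                            tani_truth$genus_id)))

# note: applying the strict 95% tANI species cut to the k-mer-aligned
# lineage catalog over-fragments (tANI multiplies ~97% identity by a
# ~93-97% aligned fraction), which is why species dereplication above
# uses the ANI + shorter-sequence-coverage criterion instead
ani <- fread("results/lineage_ani.tsv")
tani_real <- compute_tani(ani)
part_real <- tani_cluster(tani_real, nodes = truth$genome_id)
message(sprintf(
  "strict 95%% tANI on the aligned catalog: %d clusters for %d true species",
  length(unique(part_real$species)), length(unique(truth$species_id))))
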