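#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study inputs with known ground truth.
#
# Two genome sets are produced:
#   * a lineage catalog: 40 species (4 families x 2 genera x 5 species),
#     3 sequence variants each, used for ANI/AAI/tANI clustering;
#   * a contig set: 400 larger genomes decorated into contigs with
#     terminal repeats, truncation tiers and gene counts, used for the
#     quality-control step.
# Everything is a pure function of the seeds below; tables and FASTA go
# to results/.

suppressMessages({
  library(viromeflow)
  library(data.table)
})

dir.create("results", showWarnings = FALSE)
set.seed(1001)

message("evolving lineage catalog (40 species x 3 variants) ...")
ev <- evolve_lineages(lineage_spec(), seed = 1001)
write_fasta(ev$genomes, "results/lineage_genomes.fasta")
fwrite(ev$truth, "results/lineage_truth.tsv", sep = "\t")
message("  ", length(ev$genomes), " genomes, ",
        length(unique(ev$truth$species_id)), " true species")

message("decorating 400 contigs with tiers and termini ...")
contig_roots <- Biostrings::DNAStringSet(setNames(
  vapply(1:400, function(i)
    paste0(sample(c("A", "C", "G", "T"), 52000, replace = TRUE),
           collapse = ""), character(1)),
  sprintf("ct%03d", 1:400)))
dec <- decorate_contigs(contig_roots, seed = 1002,
                        contaminated_frac = 0.05)
write_fasta(dec$contigs, "results/contigs.fasta")
write_qc_table(dec$qc, "results/contigs_qc.tsv")
fwrite(dec$truth, "results/contigs_truth.tsv", sep = "\t")
message("  designed tiers: ",
        paste(names(table(dec$truth$tier)), table(dec$truth$tier),
              sep = "=", collapse = ", "))
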