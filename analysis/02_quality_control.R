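#!/usr/bin/env Rscript
# Step 2 — contig quality control: terminal-repeat detection, retention
# filtering (completeness >= 50 with viral-gene dominance, or long
# contigs >= 20 kb at completeness >= 40) and quality-tier assignment.
# Compares the recovered tiers against the generator's design.

suppressMessages({
  library(viromeflow)
  library(data.table)
})

contigs <- read_fasta("results/contigs.fasta")
qc <- read_qc_table("results/contigs_qc.tsv")
truth <- fread("results/contigs_truth.tsv")

res <- qc_catalog(contigs, qc)
fwrite(res$kept, "results/qc_kept.tsv", sep = "\t")
fwrite(res$rejected, "results/qc_rejected.tsv", sep = "\t")

message(nrow(res$kept), " contigs retained, ", nrow(res$rejected),
        " rejected")
message("rejection reasons: ",
        paste(names(table(res$rejected$reason)),
              table(res$rejected$reason), sep = "=", collapse = ", "))

tier_tab <- merge(res$kept[, .(contig_id, tier)],
                  truth[, .(contig_id, design_tier = tier)],
                  by = "contig_id")
agree <- mean(tier_tab$tier == tier_tab$design_tier)
message(sprintf("tier agreement with design on retained contigs: %.1f%%",
                100 * agree))
counts <- res$kept[, .N, by = tier][order(tier)]
fwrite(counts, "results/qc_tier_counts.tsv", sep = "\t")
print(counts)
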