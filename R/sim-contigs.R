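#' Decorate genomes into contigs with a matching QC table
#'
#' Emulates the inputs a completeness estimator would produce for an
#' assembled viral catalog: each genome is assigned a target quality tier;
#' `complete` genomes keep their full length and gain a direct or inverted
#' terminal repeat (or a provirus label, which leaves the sequence
#' untouched — provirus boundaries are a table annotation, not a sequence
#' signature), while the other tiers are truncated to a completeness
#' fraction drawn from the tier's range. Viral/host gene counts are drawn
#' so that contigs pass the gene-ratio retention clauses unless the record
#' is deliberately planted as contaminated.
#'
#' @param genomes Named `DNAStringSet` of full-length genomes.
#' @param seed Integer seed.
#' @param tier_design Named proportions over
#'   `c(complete, high, medium, low)`.
#' @param termini_design Proportions of `DTR`/`ITR`/`provirus` within the
#'   complete tier (defaults follow the empirical ratio of closed phage
#'   genomes, which is strongly DTR-dominated).
#' @param repeat_len_range Terminal-repeat lengths in bp.
#' @param contaminated_frac Fraction of contigs planted with host-gene
#'   contamination (viral genes <= 3 x host genes, so they fail retention).
#' @return A list with `contigs` (named `DNAStringSet`), `qc` (QC table)
#'   and `truth` (per-contig tier/termini/completeness design).
#' @export
decorate_contigs <- function(genomes, seed = 1L,
                             tier_design = c(complete = 0.20, high = 0.25,
                                             medium = 0.45, low = 0.10),
                             termini_design = c(DTR = 0.786, ITR = 0.207,
                                                provirus = 0.007),
                             repeat_len_range = c(25L, 60L),
                             contaminated_frac = 0) {
  genomes <- as_dna(genomes)
  if (abs(sum(tier_design) - 1) > 1e-8)
    stop2("tier_design must sum to 1")
  with_seed(seed, {
    ids <- names(genomes)
    n <- length(ids)
    tier <- sample(names(tier_design), n, replace = TRUE,
                   prob = tier_design)
    termini <- rep("none", n)
    is_complete <- tier == "complete"
    termini[is_complete] <- sample(names(termini_design),
                                   sum(is_complete), replace = TRUE,
                                   prob = termini_design)
    cpl <- numeric(n)
    cpl[tier == "complete"] <- 100
    cpl[tier == "high"] <- runif(sum(tier == "high"), 90, 99.9)
    cpl[tier == "medium"] <- runif(sum(tier == "medium"), 50, 89.9)
    cpl[tier == "low"] <- runif(sum(tier == "low"), 40, 49.9)
    contaminated <- runif(n) < contaminated_frac
    seqs <- character(n)
    for (i in seq_len(n)) {
      s <- as.character(genomes[[ids[i]]])
      if (tier[i] != "complete") {
        keep <- max(1L, round(nchar(s) * cpl[i] / 100))
        start <- sample.int(nchar(s) - keep + 1L, 1L)
        s <- substr(s, start, start + keep - 1L)
      } else if (termini[i] %in% c("DTR", "ITR")) {
        r <- sample(repeat_len_range[1L]:repeat_len_range[2L], 1L)
        rep_seq <- substr(s, 1L, r)
        if (termini[i] == "ITR")
          rep_seq <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(rep_seq)))
        s <- paste0(s, rep_seq)
      }
      seqs[i] <- s
    }
    len <- nchar(seqs)
    viral_genes <- pmax(1L, rpois(n, len / 1500))
    host_genes <- rbinom(n, 1L, 0.15)                 # sparse, ratio passes
    if (any(contaminated)) {
      nc <- sum(contaminated)
      host_genes[contaminated] <- pmax(1L,
                                       ceiling(viral_genes[contaminated] / 3))
    }
    qc <- data.table::data.table(
      contig_id = ids, contig_length = len,
      completeness = round(cpl, 1), contamination = 0,
      viral_genes = viral_genes, host_genes = host_genes,
      termini = data.table::fifelse(termini == "provirus", "provirus",
                                    "none"))
    truth <- data.table::data.table(contig_id = ids, tier = tier,
                                    termini = termini,
                                    completeness = round(cpl, 1),
                                    contaminated = contaminated)
    list(contigs = as_dna(setNames(seqs, ids)), qc = qc, truth = truth)
  })
}
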