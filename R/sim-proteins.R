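#' Simulate protein hit tables with designed rank structure
#'
#' Generates per-genome gene counts and a protein-vs-protein hit table
#' whose shared-gene fractions and identity distributions depend on the
#' lowest shared rank of each genome pair, so that AAI clustering at genus
#' and family thresholds can be validated against known labels. Hits are
#' emitted directly as a hit table (the AAI stage consumes hit tables, not
#' raw proteins), with identities drawn around the rank's design value.
#'
#' @param truth A truth table (`genome_id`, `species_id`, `genus_id`,
#'   `family_id`), e.g. from [evolve_lineages()].
#' @param genes_range Per-genome gene count range.
#' @param frac_shared Named designed shared-gene fractions per rank
#'   (`species`, `genus`, `family`); pairs sharing no rank get no hits.
#' @param mean_identity Named designed mean percent identities per rank.
#' @param sd_identity Per-hit identity standard deviation.
#' @param seed Integer seed.
#' @return A list with `hits` (hit table for [compute_aai()]) and
#'   `gene_counts` (named integer vector).
#' @export
simulate_protein_hits <- function(truth,
                                  genes_range = c(20L, 40L),
                                  frac_shared = c(species = 0.90,
                                                  genus = 0.45,
                                                  family = 0.18),
                                  mean_identity = c(species = 92,
                                                    genus = 55,
                                                    family = 28),
                                  sd_identity = 4,
                                  seed = 1L) {
  tr <- data.table::as.data.table(truth)
  with_seed(seed, {
    ids <- tr$genome_id
    n <- length(ids)
    genes <- setNames(sample(genes_range[1L]:genes_range[2L], n,
                             replace = TRUE), ids)
    rows <- list()
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      rank <- if (tr$species_id[i] == tr$species_id[j]) "species"
      else if (tr$genus_id[i] == tr$genus_id[j]) "genus"
      else if (tr$family_id[i] == tr$family_id[j]) "family"
      else NA_character_
      if (is.na(rank)) next
      a <- ids[i]; b <- ids[j]
      nmin <- min(genes[[a]], genes[[b]])
      n_shared <- rbinom(1L, nmin, frac_shared[[rank]])
      if (n_shared == 0L) next
      smaller <- if (genes[[a]] < genes[[b]] ||
                     (genes[[a]] == genes[[b]] && a <= b)) a else b
      other <- if (smaller == a) b else a
      qp <- sample.int(genes[[smaller]], n_shared)
      tp <- sample.int(genes[[other]], n_shared)
      pid <- pmin(100, pmax(5, stats::rnorm(n_shared,
                                            mean_identity[[rank]],
                                            sd_identity)))
      rows[[length(rows) + 1L]] <- data.table::data.table(
        query_protein = sprintf("%s_p%03d", smaller, qp),
        target_protein = sprintf("%s_p%03d", other, tp),
        query_genome = smaller, target_genome = other,
        pident = pid, qcov = runif(n_shared, 60, 100),
        tcov = runif(n_shared, 60, 100),
        evalue = 10^runif(n_shared, -40, -10))
    }
    hits <- if (length(rows)) data.table::rbindlist(rows)
    else data.table::data.table(
      query_protein = character(), target_protein = character(),
      query_genome = character(), target_genome = character(),
      pident = numeric(), qcov = numeric(), tcov = numeric(),
      evalue = numeric())
    list(hits = hits, gene_counts = genes)
  })
}
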