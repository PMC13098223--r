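test_that("lineage evolution is deterministic and label-consistent", {
  spec <- lineage_spec(n_families = 2L, species_per_genus = 2L,
                       variants_per_species = 2L,
                       genome_len_range = c(2000L, 3000L))
  ev1 <- evolve_lineages(spec, seed = 31)
  ev2 <- evolve_lineages(spec, seed = 31)
  expect_identical(as.character(ev1$genomes), as.character(ev2$genomes))
  expect_identical(ev1$truth, ev2$truth)
  # hierarchy labels are nested
  tr <- ev1$truth
  expect_true(all(startsWith(tr$species_id, tr$genus_id)))
  expect_true(all(startsWith(tr$genus_id, tr$family_id)))
  # byte-identical FASTA across runs
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(ev1$genomes, f1)
  write_fasta(ev2$genomes, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("zero within-species divergence yields identical variants", {
  spec <- lineage_spec(within_species_div = 0, n_families = 1L,
                       genera_per_family = 1L, species_per_genus = 2L,
                       variants_per_species = 3L,
                       genome_len_range = c(1500L, 1500L))
  ev <- evolve_lineages(spec, seed = 32)
  for (sp in unique(ev$truth$species_id)) {
    ids <- ev$truth$genome_id[ev$truth$species_id == sp]
    seqs <- as.character(ev$genomes[ids])
    expect_identical(unique(unname(seqs)), seqs[[1]])
  }
})

test_that("lineage spec validates rank ordering of divergences", {
  expect_error(lineage_spec(within_species_div = 0.2), "increase with rank")
  expect_error(lineage_spec(within_species_div = 0.06,
                            within_genus_div = 0.08), "0.05")
})

test_that("between-species divergence lands at the designed identity", {
  # branch rate 0.079 from a shared root gives ~85% pairwise identity
  set.seed(33)
  ids <- replicate(5, {
    root <- rand_seq(2500)
    a <- mutate_sequence(root, 0.079, indel_rate = 0)
    b <- mutate_sequence(root, 0.079, indel_rate = 0)
    ani_oracle(a, b)
  })
  expect_lt(abs(mean(ids) - 85), 1)
})

test_that("within-species pairs satisfy the 95% ANI species criterion", {
  ev <- evolve_lineages(lineage_spec(n_families = 1L,
                                     genera_per_family = 1L,
                                     species_per_genus = 3L,
                                     genome_len_range = c(2500L, 3500L)),
                        seed = 34)
  tr <- ev$truth
  n_ok <- 0L; n <- 0L
  for (sp in unique(tr$species_id)) {
    ids <- tr$genome_id[tr$species_id == sp]
    for (i in seq_len(length(ids) - 1L)) for (j in (i + 1L):length(ids)) {
      n <- n + 1L
      o <- ani_oracle(as.character(ev$genomes[[ids[i]]]),
                      as.character(ev$genomes[[ids[j]]]))
      if (o >= 95) n_ok <- n_ok + 1L
    }
  }
  expect_identical(n_ok, n)
})

test_that("contig decoration closes the loop with termini detection", {
  set.seed(35)
  genomes <- viromeflow:::as_dna(rand_genomes(60, 30000))
  dec <- decorate_contigs(genomes, seed = 36)
  tr <- dec$truth
  for (i in which(tr$termini %in% c("DTR", "ITR"))) {
    call <- detect_termini(dec$contigs[[tr$contig_id[i]]])
    expect_identical(call$kind, tr$termini[i])
  }
  # truncated contigs keep their designed completeness in the QC table
  expect_equal(dec$qc$completeness, tr$completeness)
  # low-completeness short contigs are later rejected
  short_low <- dec$qc[dec$qc$completeness < 50 &
                        dec$qc$contig_length < 20000]
  if (nrow(short_low)) {
    res <- apply_retention_filters(short_low)
    expect_identical(nrow(res$kept), 0L)
  }
})

test_that("designed tier proportions survive the QC pipeline", {
  set.seed(37)
  genomes <- viromeflow:::as_dna(rand_genomes(600, 52000))
  dec <- decorate_contigs(genomes, seed = 38)
  res <- qc_catalog(dec$contigs, dec$qc)
  got <- prop.table(table(res$kept$tier))
  design <- c(complete = 0.20, high = 0.25, medium = 0.45, low = 0.10)
  for (tier in names(design))
    expect_lt(abs(got[[tier]] - design[[tier]]), 0.06)
})

test_that("contaminated contigs are rejected by the gene-ratio clause", {
  set.seed(39)
  genomes <- viromeflow:::as_dna(rand_genomes(80, 45000))
  dec <- decorate_contigs(genomes, seed = 40, contaminated_frac = 0.3)
  res <- apply_retention_filters(dec$qc)
  bad <- dec$truth$contig_id[dec$truth$contaminated]
  expect_true(all(bad %in% res$rejected$contig_id))
})

test_that("alignment emission handles identical and unrelated pairs", {
  set.seed(41)
  s <- rand_seq(4000)
  ident <- viromeflow:::as_dna(c(a = s, b = s))
  aln <- emit_alignments(ident, mode = "kmer")
  ab <- aln[aln$query_id == "a"]
  expect_identical(nrow(ab), 1L)
  expect_equal(ab$pident, 100)
  expect_identical(ab$qstart, 0L)
  expect_identical(ab$qend, 4000L)

  unrel <- viromeflow:::as_dna(c(a = rand_seq(4000), b = rand_seq(4000)))
  expect_identical(nrow(emit_alignments(unrel, mode = "kmer")), 0L)
})

test_that("oracle-mode alignments agree with kmer mode on ANI", {
  set.seed(42)
  root <- rand_seq(2000)
  g <- viromeflow:::as_dna(c(a = root, b = mutate_sequence(root, 0.03)))
  lens <- genome_lengths(g)
  ani_k <- compute_ani(emit_alignments(g, mode = "kmer"), lens)
  ani_o <- compute_ani(emit_alignments(g, mode = "oracle"), lens)
  expect_lt(abs(ani_k$ani[1] - ani_o$ani[1]), 0.5)
  expect_gt(ani_o$qcov[1], 95)
})

test_that("community simulation is deterministic with exact NM bookkeeping", {
  set.seed(43)
  genomes <- viromeflow:::as_dna(rand_genomes(4, 4000, "v"))
  host <- assign_hosts(names(genomes), seed = 44)
  com1 <- simulate_community(genomes, host, regions = c("ileum", "caeca"),
                             reads_per_sample = 5000L, seed = 45)
  com2 <- simulate_community(genomes, host, regions = c("ileum", "caeca"),
                             reads_per_sample = 5000L, seed = 45)
  expect_identical(com1$sam, com2$sam)
  expect_identical(com1$composition, com2$composition)
  expect_true(all(abs(rowSums(com1$composition) - 1) < 1e-12))

  # zero error rate: every read at identity 100
  com0 <- simulate_community(genomes, host, regions = "feces",
                             reads_per_sample = 5000L, error_rate = 0,
                             seed = 46)
  m <- alignment_metrics(com0$sam[[1]])
  expect_true(all(m$identity == 100))

  # reads materialise to sequences consistent with their NM tags
  reads <- materialise_reads(com0$sam[[1]][1:20], genomes, seed = 47)
  for (i in 1:20) {
    ref <- substr(as.character(genomes[[reads$genome_id[i]]]),
                  reads$pos[i] + 1, reads$pos[i] + reads$read_len[i])
    expect_identical(reads$seq[i], ref)  # NM 0 reads match the reference
  }
})

test_that("community design validates mixtures and regions", {
  expect_error(community_design(proximal = c(Lactobacillaceae = 1,
                                             Lachnospiraceae = 0.5,
                                             Bacteroidaceae = 0,
                                             Ruminococcaceae = 0,
                                             other = 0)), "sum to 1")
  genomes <- viromeflow:::as_dna(rand_genomes(3, 2000, "v"))
  host <- assign_hosts(names(genomes), seed = 48)
  expect_error(simulate_community(genomes, host, regions = "stomach",
                                  seed = 1), "unknown region")
})
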