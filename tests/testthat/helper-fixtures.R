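# shared fixture builders; everything is generated in code

rand_seq <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_genomes <- function(n, len, prefix = "g") {
  setNames(vapply(seq_len(n), function(i) rand_seq(len), character(1L)),
           sprintf("%s%03d", prefix, seq_len(n)))
}

# retention-filter fixture spanning every clause boundary, with truth
# derived by hand from the two rules (see inline notes)
retention_fixture <- function() {
  qc <- data.frame(
    contig_id = sprintf("c%02d", 1:20),
    contig_length = c(15000, 25000, 25000, 15000, 15000, 20000, 19999,
                      20000, 20000, 15000, 25000, 15000, 50000, 15000,
                      15000, 25000, 25000, 15000, 15000, 30000),
    completeness = c(60, 42, 42, 50, 49.9, 49.9, 49.9, 40, 39.9, 60, 45,
                     NA, NA, 100, 100, 44, 44, 50, 50, 95),
    contamination = 0,
    viral_genes = c(10, 5, 6, 1, 5, 5, 5, 1, 10, 0, 0, 10, 20, 7, 6, 7,
                    6, 4, 3, 12),
    host_genes = c(2, 1, 2, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 2, 2, 2, 2, 1,
                   1, 3),
    termini = "none")
  # hand truth: c01 A; c02 B; c03 no (6 = 3x2); c04 A boundary (cpl 50,
  # 1 > 0); c05 no (cpl < 50, len < 20k); c06 B boundary (len 20000);
  # c07 no (19999); c08 B boundary (cpl 40); c09 no (39.9); c10/c11 no
  # viral genes; c12/c13 absent completeness; c14 A (7 > 6); c15 no
  # (6 = 3x2); c16 B (7 > 6); c17 no; c18 A (4 > 3); c19 no (3 = 3x1);
  # c20 A
  kept_truth <- sprintf("c%02d", c(1, 2, 4, 6, 8, 14, 16, 18, 20))
  list(qc = qc, kept_truth = kept_truth)
}

# 30-node, 3-block planted-partition rank graph
planted_partition_graph <- function(seed, n_blocks = 3L, per_block = 10L,
                                    p_in = 0.9, p_out = 0.02) {
  set.seed(seed)
  n <- n_blocks * per_block
  blocks <- rep(seq_len(n_blocks), each = per_block)
  nodes <- sprintf("n%02d", seq_len(n))
  rows <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    p <- if (blocks[i] == blocks[j]) p_in else p_out
    if (runif(1) < p)
      rows[[length(rows) + 1L]] <- data.frame(a = nodes[i], b = nodes[j],
                                              weight = runif(1, 50, 100))
  }
  list(graph = structure(list(nodes = nodes,
                              edges = do.call(rbind, rows),
                              rank = "genus"), class = "rank_graph"),
       blocks = blocks, nodes = nodes)
}

# run the numpy reference MCL on the adjacency of a rank graph
reference_mcl <- function(graph, inflation) {
  nodes <- graph$nodes
  ed <- graph$edges
  M <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  M[cbind(match(ed$a, nodes), match(ed$b, nodes))] <- ed$weight
  M[cbind(match(ed$b, nodes), match(ed$a, nodes))] <- ed$weight
  tf <- tempfile(fileext = ".tsv")
  on.exit(unlink(tf))
  utils::write.table(data.frame(id = nodes, M, check.names = FALSE), tf,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = c("id", nodes))
  script <- system.file("oracle", "mcl_reference.py", package = "viromeflow")
  out <- system2("python", c(script, tf, format(inflation)), stdout = TRUE)
  parts <- strsplit(out, "\t", fixed = TRUE)
  setNames(as.integer(vapply(parts, `[[`, character(1L), 2L)),
           vapply(parts, `[[`, character(1L), 1L))
}

# simulate a single-sample SAM table with designed vOTU proportions
sim_sample_sam <- function(lens, props, n_total, viral_fraction,
                           error_rate = 0.02, read_len = 150L) {
  n_vir <- rbinom(1L, n_total, viral_fraction)
  votu <- sample(names(lens), n_vir, replace = TRUE, prob = props)
  starts <- vapply(votu, function(v)
    sample.int(max(1L, lens[[v]] - read_len + 1L), 1L), integer(1L))
  data.table::data.table(
    read_id = sprintf("r%06d", seq_len(n_vir)), flag = 0L,
    genome_id = votu, pos = starts - 1L,
    cigar = sprintf("%dM", read_len), read_len = read_len,
    nm = rbinom(n_vir, read_len, error_rate), mapped = TRUE,
    primary = TRUE)
}

# proximal/distal community fixture shared by the end-to-end tests
regional_community <- function(seed, n_per_group = 20L,
                               reads_per_sample = 20000L) {
  set.seed(seed)
  genomes <- viromeflow:::as_dna(rand_genomes(24, 5000, "v"))
  host <- assign_hosts(names(genomes), seed = seed + 1L,
                       weights = c(Lactobacillaceae = 0.3,
                                   Lachnospiraceae = 0.25,
                                   Bacteroidaceae = 0.2,
                                   Ruminococcaceae = 0.15, other = 0.1))
  regions <- c(rep(c("crop", "ileum"), n_per_group / 2),
               rep(c("caeca", "feces"), n_per_group / 2))
  com <- simulate_community(genomes, host,
                            community_design(viral_fraction = 0.05),
                            regions, reads_per_sample = reads_per_sample,
                            seed = seed + 2L)
  am <- abundance_matrix(com$sam, genome_lengths(genomes), com$totals,
                         metadata = com$metadata)
  list(genomes = genomes, host = host, com = com, am = am)
}
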