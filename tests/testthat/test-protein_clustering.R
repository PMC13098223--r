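make_hits <- function(qp, tp, qg, tg, pident, evalue = 1e-20, qcov = 90,
                      tcov = 90) {
  data.table::data.table(query_protein = qp, target_protein = tp,
                         query_genome = qg, target_genome = tg,
                         pident = pident, qcov = qcov, tcov = tcov,
                         evalue = evalue)
}

test_that("AAI on fully matching proteomes is 100 with full sharing", {
  hits <- make_hits(sprintf("A_p%d", 1:5), sprintf("B_p%d", 1:5),
                    "A", "B", 100)
  aai <- compute_aai(hits, c(A = 5L, B = 5L))
  expect_equal(aai$aai, 100)
  expect_identical(aai$shared_genes, 5L)
  expect_equal(aai$frac_shared, 1)
})

test_that("AAI hit filters drop weak or shallow hits", {
  weak <- make_hits("A_p1", "B_p1", "A", "B", 80, evalue = 1e-3)
  expect_identical(nrow(compute_aai(weak, c(A = 3L, B = 3L))), 0L)
  shallow <- make_hits("A_p1", "B_p1", "A", "B", 80, qcov = 30)
  expect_identical(nrow(compute_aai(shallow, c(A = 3L, B = 3L))), 0L)
  expect_error(compute_aai(make_hits("A_p1", "B_p1", "A", "Z", 80),
                           c(A = 3L, B = 3L)), "absent from")
})

test_that("best-hit selection keeps one hit per query protein", {
  hits <- rbind(make_hits("A_p1", "B_p1", "A", "B", 70, evalue = 1e-30),
                make_hits("A_p1", "B_p2", "A", "B", 95, evalue = 1e-10),
                make_hits("A_p2", "B_p2", "A", "B", 50, evalue = 1e-20))
  aai <- compute_aai(hits, c(A = 2L, B = 4L))
  # p1 keeps the 1e-30 hit (lower evalue wins over higher identity)
  expect_equal(aai$aai, mean(c(70, 50)))
  expect_identical(aai$shared_genes, 2L)
  expect_equal(aai$frac_shared, 1)
})

test_that("designed proteome sharing and identity are recovered", {
  truth <- data.frame(genome_id = c("g1", "g2"), species_id = "s",
                      genus_id = "g", family_id = "f")
  sim <- simulate_protein_hits(truth, genes_range = c(500L, 500L),
                               frac_shared = c(species = 0.60, genus = 0.4,
                                               family = 0.2),
                               mean_identity = c(species = 45, genus = 30,
                                                 family = 25),
                               sd_identity = 2, seed = 12)
  aai <- compute_aai(sim$hits, sim$gene_counts)
  expect_lt(abs(aai$aai - 45), 2)
  expect_lt(abs(aai$frac_shared - 0.60), 0.05)
})

test_that("rank graphs apply the genus/family edge thresholds", {
  pairs <- data.table::data.table(
    genome_a = c("a", "a", "a"), genome_b = c("b", "c", "d"),
    aai = c(41, 41, 19), shared_genes = c(5L, 5L, 5L),
    frac_shared = c(0.21, 0.19, 0.50),
    n_genes_a = 20L, n_genes_b = 20L)
  nodes <- c("a", "b", "c", "d")
  genus <- build_rank_graph(pairs, nodes, "genus")
  family <- build_rank_graph(pairs, nodes, "family")
  expect_identical(nrow(genus$edges), 1L)        # only (a,b)
  expect_identical(genus$edges$b, "b")
  expect_identical(nrow(family$edges), 2L)       # (a,b) and (a,c)
  empty <- build_rank_graph(pairs[0], nodes, "genus")
  expect_identical(nrow(empty$edges), 0L)
  expect_identical(mcl(empty)$n_clusters, 4L)    # isolated nodes: singletons
})

test_that("MCL separates designed structure and is deterministic", {
  ed <- rbind(expand.grid(a = paste0("x", 1:4), b = paste0("x", 1:4)),
              expand.grid(a = paste0("y", 1:4), b = paste0("y", 1:4)))
  ed <- ed[as.character(ed$a) < as.character(ed$b), ]
  ed$weight <- 100
  ed <- rbind(ed, data.frame(a = "x1", b = "y1", weight = 1))
  g <- structure(list(nodes = c(paste0("x", 1:4), paste0("y", 1:4)),
                      edges = ed, rank = "genus"), class = "rank_graph")
  r1 <- mcl(g, inflation = 2.0)
  expect_identical(r1$n_clusters, 2L)
  expect_identical(unname(r1$membership[1:4]), rep(r1$membership[["x1"]], 4))
  expect_true(r1$converged)
  r2 <- mcl(g, inflation = 2.0)
  expect_identical(r1$membership, r2$membership)
  expect_error(mcl(g, inflation = 1), "inflation")
})

test_that("MCL recovers planted partitions and matches the reference run", {
  pp <- planted_partition_graph(seed = 13)
  r <- mcl(pp$graph, inflation = 2.0)
  expect_gte(mclust::adjustedRandIndex(r$membership, pp$blocks), 0.95)
  ref <- reference_mcl(pp$graph, 2.0)
  expect_equal(mclust::adjustedRandIndex(ref[names(r$membership)],
                                         r$membership), 1)
})

test_that("genus MCL refines the family partition on nested hierarchies", {
  ok <- 0L
  for (s in 1:10) {
    ev <- evolve_lineages(lineage_spec(n_families = 2L,
                                       species_per_genus = 2L,
                                       variants_per_species = 2L),
                          seed = 100 + s)
    ph <- simulate_protein_hits(ev$truth, seed = 200 + s)
    aai <- compute_aai(ph$hits, ph$gene_counts)
    nodes <- names(ph$gene_counts)
    gm <- cluster_rank(build_rank_graph(aai, nodes, "genus"))$membership
    fm <- cluster_rank(build_rank_graph(aai, nodes, "family"))$membership
    # refinement: same genus cluster implies same family cluster
    pairs <- utils::combn(nodes, 2L)
    refines <- all(fm[pairs[1, ]][gm[pairs[1, ]] == gm[pairs[2, ]]] ==
                     fm[pairs[2, ]][gm[pairs[1, ]] == gm[pairs[2, ]]])
    if (refines) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})

test_that("tANI single-linkage clustering respects rank thresholds", {
  tp <- data.table::data.table(genome_a = c("a", "b"),
                               genome_b = c("b", "c"),
                               tani = c(96, 72))
  part <- tani_cluster(tp, nodes = c("a", "b", "c"))
  expect_identical(unname(part$species), c(1, 1, 2))
  expect_identical(unname(part$genus), c(1, 1, 1))
  expect_error(tani_cluster(tp, nodes = c("a", "b", "c"),
                            species_thr = 0), "\\(0, 100\\]")

  # three genomes pairwise >= 95: one species cluster
  tp2 <- data.table::data.table(genome_a = c("a", "a", "b"),
                                genome_b = c("b", "c", "c"), tani = 96)
  expect_identical(unname(tani_cluster(tp2, c("a", "b", "c"))$species),
                   rep(1, 3))
})

test_that("tANI computation discounts ANI by aligned fraction", {
  ap <- data.table::data.table(query_id = "a", target_id = "b", ani = 98,
                               qcov = 90, tcov = 70, n_alignments = 2L)
  expect_equal(compute_tani(ap)$tani, 98 * 0.8)
  expect_equal(compute_tani(ap, method = "min")$tani, 98 * 0.7)
  expect_lte(compute_tani(ap)$tani, ap$ani)
})

test_that("designed rank structure is recovered by tANI clustering", {
  # two species of two variants each in one genus, plus an outgroup genus
  ap <- data.table::rbindlist(list(
    data.table::data.table(query_id = "s1a", target_id = "s1b", ani = 98,
                           qcov = 99, tcov = 99, n_alignments = 1L),
    data.table::data.table(query_id = "s2a", target_id = "s2b", ani = 97,
                           qcov = 98, tcov = 98, n_alignments = 1L),
    data.table::data.table(query_id = "s1a", target_id = "s2a", ani = 88,
                           qcov = 90, tcov = 90, n_alignments = 1L),
    data.table::data.table(query_id = "out", target_id = "s1a", ani = 60,
                           qcov = 40, tcov = 40, n_alignments = 1L)))
  nodes <- c("s1a", "s1b", "s2a", "s2b", "out")
  part <- tani_cluster(compute_tani(ap), nodes)
  expect_identical(unname(part$species[c("s1a", "s1b")]),
                   rep(part$species[["s1a"]], 2))
  expect_false(part$species[["s1a"]] == part$species[["s2a"]])
  expect_identical(unname(part$genus[c("s1a", "s2a")]),
                   rep(part$genus[["s1a"]], 2))
  expect_false(part$genus[["s1a"]] == part$genus[["out"]])
})
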