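#' Average amino-acid identity between genome pairs
#'
#' From a table of protein-vs-protein hits, computes per-genome-pair AAI:
#' hits are filtered (`evalue < 1e-5`, query and target coverage >= 50%),
#' the best hit per query protein within each genome pair is kept (lowest
#' E-value, then highest identity, then lexicographic target id), and AAI
#' is the unweighted mean percent identity over kept hits. The shared-gene
#' fraction uses the smaller of the two genomes' gene counts as
#' denominator, so genome fragments remain comparable.
#'
#' @param hits Protein hit table with columns `query_protein`,
#'   `target_protein`, `query_genome`, `target_genome`, `pident`, `qcov`,
#'   `tcov`, `evalue`.
#' @param gene_counts Named per-genome protein counts covering every genome
#'   in `hits`.
#' @param max_evalue,min_cov Hit filters.
#' @return A `data.table` with one row per unordered genome pair:
#'   `genome_a`, `genome_b` (`a < b`), `aai`, `shared_genes`, `frac_shared`,
#'   `n_genes_a`, `n_genes_b`.
#' @export
compute_aai <- function(hits, gene_counts, max_evalue = 1e-5, min_cov = 50) {
  dt <- data.table::as.data.table(hits)
  need <- c("query_protein", "target_protein", "query_genome",
            "target_genome", "pident", "qcov", "tcov", "evalue")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop2("protein hit table missing column(s) ",
          paste0("'", miss, "'", collapse = ", "))
  unknown <- setdiff(unique(c(dt$query_genome, dt$target_genome)),
                     names(gene_counts))
  if (length(unknown))
    stop2("protein hit references genome '", unknown[1L],
          "' absent from gene_counts")
  dt <- dt[evalue < max_evalue & qcov >= min_cov & tcov >= min_cov &
             query_genome != target_genome]
  if (nrow(dt) == 0L)
    return(data.table::data.table(
      genome_a = character(), genome_b = character(), aai = numeric(),
      shared_genes = integer(), frac_shared = numeric(),
      n_genes_a = integer(), n_genes_b = integer()))
  dt[, `:=`(genome_a = pmin(query_genome, target_genome),
            genome_b = pmax(query_genome, target_genome))]
  # best hit per query protein within each unordered pair
  data.table::setorder(dt, genome_a, genome_b, query_protein, evalue,
                       -pident, target_protein)
  best <- dt[, .SD[1L], by = .(genome_a, genome_b, query_protein)]
  out <- best[, {
    na <- gene_counts[[genome_a[1L]]]
    nb <- gene_counts[[genome_b[1L]]]
    smaller <- if (na < nb || (na == nb && genome_a[1L] <= genome_b[1L]))
      genome_a[1L] else genome_b[1L]
    shared <- length(unique(query_protein[query_genome == smaller]))
    list(aai = mean(pident), shared_genes = shared,
         frac_shared = shared / min(na, nb),
         n_genes_a = na, n_genes_b = nb)
  }, by = .(genome_a, genome_b)]
  out[shared_genes >= 1L][]
}

RANK_THRESHOLDS <- list(genus = c(frac = 0.20, aai = 40),
                        family = c(frac = 0.10, aai = 20))

#' Build a thresholded AAI graph at genus or family rank
#'
#' Keeps edges meeting the rank's demarcation thresholds: genus requires
#' >= 20% shared genes and >= 40% AAI; family relaxes to >= 10% shared
#' genes and >= 20% AAI. Edge weight is the AAI.
#'
#' @param pairs Output of [compute_aai()].
#' @param nodes Character vector of genome ids (graph keeps isolated nodes).
#' @param rank `"genus"` or `"family"`.
#' @return A `rank_graph` list with `nodes`, `edges` (`a`, `b`, `weight`)
#'   and `rank`.
#' @export
build_rank_graph <- function(pairs, nodes, rank = c("genus", "family")) {
  rank <- match.arg(rank)
  thr <- RANK_THRESHOLDS[[rank]]
  dt <- data.table::as.data.table(pairs)
  edges <- dt[frac_shared >= thr[["frac"]] & aai >= thr[["aai"]],
              .(a = genome_a, b = genome_b, weight = aai)]
  structure(list(nodes = nodes, edges = edges[], rank = rank),
            class = "rank_graph")
}

#' Total-ANI (tANI) for genome pairs
#'
#' Discounts ANI by the aligned genome fraction:
#' `tani = ani * (qcov + tcov) / 2 / 100` (default, length-symmetric), or
#' `ani * min(qcov, tcov) / 100` with `method = "min"`. Two near-identical
#' genomes aligned over their whole lengths score near their ANI; a
#' high-identity alignment covering a small fraction of the genomes scores
#' low, which is what makes tANI usable for whole-genome species/genus
#' demarcation.
#'
#' @param ani_pairs ANI table ([compute_ani()] layout).
#' @param method `"mean"` (default) or `"min"` aligned-fraction weighting.
#' @return The table with a `tani` column added.
#' @export
compute_tani <- function(ani_pairs, method = c("mean", "min")) {
  method <- match.arg(method)
  dt <- data.table::as.data.table(ani_pairs)
  frac <- if (method == "mean") (dt$qcov + dt$tcov) / 2
  else pmin(dt$qcov, dt$tcov)
  dt[, tani := ani * frac / 100]
  dt[]
}

#' Single-linkage tANI clustering at species and genus rank
#'
#' Clusters genomes as the connected components of the graph whose edges
#' are pairs with `tani >=` the rank threshold (95 for species, 70 for
#' genus by default). Because species edges are a subset of genus edges,
#' the species partition always refines the genus partition.
#'
#' @param tani_pairs Output of [compute_tani()].
#' @param nodes Character vector of genome ids.
#' @param species_thr,genus_thr Percent thresholds in `(0, 100]`.
#' @return A list with `species` and `genus`: named integer membership
#'   vectors over `nodes`.
#' @export
tani_cluster <- function(tani_pairs, nodes, species_thr = 95,
                         genus_thr = 70) {
  for (thr in c(species_thr, genus_thr))
    if (!is.numeric(thr) || thr <= 0 || thr > 100)
      stop2("tANI thresholds must lie in (0, 100]")
  dt <- data.table::as.data.table(tani_pairs)
  # tolerate either compute_ani-style or compute_aai-style column names
  if (!"genome_a" %in% names(dt) && all(c("query_id", "target_id") %in%
                                        names(dt)))
    data.table::setnames(dt, c("query_id", "target_id"),
                         c("genome_a", "genome_b"))
  part <- function(thr) {
    e <- dt[tani >= thr & genome_a != genome_b, .(genome_a, genome_b)]
    g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                       vertices = data.frame(name = nodes))
    igraph::components(g)$membership
  }
  list(species = part(species_thr), genus = part(genus_thr))
}
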