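HOST_FAMILIES <- c("Lactobacillaceae", "Lachnospiraceae", "Bacteroidaceae",
                   "Ruminococcaceae", "other")

#' Region-structured community design
#'
#' Host-family mixture weights per gut-region group, emulating the niche
#' structure of the chicken gut: the proximal gut (crop to ileum) is
#' dominated by phages of Lactobacillaceae, while the distal gut (caeca,
#' colorectum, feces) is spread over Lachnospiraceae, Bacteroidaceae and
#' Ruminococcaceae hosts.
#'
#' @param proximal,distal Named mixture weights over the host families
#'   (must each sum to 1).
#' @param viral_fraction Expected fraction of a sample's reads that are
#'   viral (the mapped-read fraction the design plants).
#' @param dispersion Gamma noise shape on per-vOTU weights (smaller =
#'   noisier samples).
#' @return A `community_design` list.
#' @export
community_design <- function(proximal = c(Lactobacillaceae = 0.60,
                                          Lachnospiraceae = 0.10,
                                          Bacteroidaceae = 0.10,
                                          Ruminococcaceae = 0.10,
                                          other = 0.10),
                             distal = c(Lactobacillaceae = 0.10,
                                        Lachnospiraceae = 0.35,
                                        Bacteroidaceae = 0.25,
                                        Ruminococcaceae = 0.20,
                                        other = 0.10),
                             viral_fraction = 0.015,
                             dispersion = 2) {
  for (w in list(proximal, distal)) {
    if (abs(sum(w) - 1) > 1e-8) stop2("mixture weights must sum to 1")
    if (!setequal(names(w), HOST_FAMILIES))
      stop2("mixture weights must be named by the host families: ",
            paste(HOST_FAMILIES, collapse = ", "))
  }
  structure(list(proximal = proximal, distal = distal,
                 viral_fraction = viral_fraction, dispersion = dispersion),
            class = "community_design")
}

PROXIMAL_REGIONS <- c("crop", "duodenum", "jejunum", "ileum")
DISTAL_REGIONS <- c("caeca", "colorectum", "feces")

#' Assign host families to a genome catalog
#'
#' @param genome_ids Character vector of genome ids.
#' @param seed Integer seed.
#' @param weights Family assignment proportions (default uniform).
#' @return A host table (`genome_id`, `host_family`, `host_genus`).
#' @export
assign_hosts <- function(genome_ids, seed = 1L, weights = NULL) {
  with_seed(seed, {
    fam <- if (is.null(weights))
      sample(HOST_FAMILIES, length(genome_ids), replace = TRUE)
    else sample(names(weights), length(genome_ids), replace = TRUE,
                prob = weights)
    data.table::data.table(
      genome_id = genome_ids, host_family = fam,
      host_genus = paste0(substr(fam, 1L, 4L), "_genus"))
  })
}

#' Simulate region-structured samples of recruited reads
#'
#' For each sample: the region picks the proximal or distal host-family
#' mixture; per-vOTU weights are the family weight split over that
#' family's vOTUs with multiplicative gamma noise; the number of viral
#' reads is binomial at the design's viral fraction; reads are placed
#' uniformly along their genome with independent per-base substitution
#' errors and emitted as mapped primary SAM records (match-only CIGARs
#' with an exact NM tag). Non-viral reads are counted in the totals but
#' not emitted as records.
#'
#' @param genomes Named `DNAStringSet` catalog.
#' @param host_table Host table from [assign_hosts()].
#' @param design A [community_design()].
#' @param regions Per-sample region labels (one sample per element).
#' @param reads_per_sample,read_len,error_rate Read model.
#' @param seed Integer seed.
#' @return A list with `sam` (named list of SAM tables), `metadata`,
#'   `totals`, `composition` (samples x vOTU true within-virome weights)
#'   and `host_table`.
#' @export
simulate_community <- function(genomes, host_table, design = community_design(),
                               regions, reads_per_sample = 50000L,
                               read_len = 150L, error_rate = 0.02,
                               seed = 1L) {
  genomes <- as_dna(genomes)
  stopifnot(inherits(design, "community_design"))
  bad <- setdiff(regions, GUT_REGIONS)
  if (length(bad)) stop2("unknown region '", bad[1L], "'")
  host <- data.table::as.data.table(host_table)
  ids <- names(genomes)
  if (!all(ids %in% host$genome_id))
    stop2("host_table must cover every genome")
  fam <- setNames(host$host_family, host$genome_id)[ids]
  lens <- genome_lengths(genomes)
  chr <- as.character(genomes)
  with_seed(seed, {
    n_samples <- length(regions)
    sample_ids <- sprintf("S%03d", seq_len(n_samples))
    sam <- vector("list", n_samples)
    comp <- matrix(0, n_samples, length(ids),
                   dimnames = list(sample_ids, ids))
    for (si in seq_len(n_samples)) {
      mix <- if (regions[si] %in% PROXIMAL_REGIONS) design$proximal
      else design$distal
      w <- mix[fam]
      w[is.na(w)] <- 0
      per_fam <- table(fam)
      w <- w / as.numeric(per_fam[fam])            # split family weight
      w <- w * rgamma(length(w), shape = design$dispersion,
                      rate = design$dispersion)    # sample-level noise
      w <- w / sum(w)
      comp[si, ] <- w
      n_viral <- rbinom(1L, reads_per_sample, design$viral_fraction)
      if (n_viral == 0L) { sam[[si]] <- empty_sam_table(); next }
      votu <- sample(ids, n_viral, replace = TRUE, prob = w)
      starts <- vapply(votu, function(v)
        sample.int(max(1L, lens[[v]] - read_len + 1L), 1L), integer(1L))
      nm <- rbinom(n_viral, read_len, error_rate)
      sam[[si]] <- data.table::data.table(
        read_id = sprintf("%s_r%06d", sample_ids[si], seq_len(n_viral)),
        flag = 0L, genome_id = votu, pos = starts - 1L,
        cigar = sprintf("%dM", read_len), read_len = read_len,
        nm = nm, mapped = TRUE, primary = TRUE)
    }
    names(sam) <- sample_ids
    list(sam = sam,
         metadata = data.table::data.table(
           sample_id = sample_ids, region = regions,
           country = "synthetic",
           group = data.table::fifelse(regions %in% PROXIMAL_REGIONS,
                                       "proximal", "distal")),
         totals = setNames(rep(as.integer(reads_per_sample), n_samples),
                           sample_ids),
         composition = comp,
         host_table = host)
  })
}

#' Extract read sequences for simulated alignments
#'
#' Materialises read sequences (with the planted substitution errors) for
#' a simulated SAM table, for writing full SAM text. Error positions are
#' drawn fresh, consistent in number with each read's NM tag.
#'
#' @param sam A simulated SAM table.
#' @param genomes The catalog used for simulation.
#' @param seed Integer seed.
#' @return The table with a `seq` column added.
#' @export
materialise_reads <- function(sam, genomes, seed = 1L) {
  genomes <- as_dna(genomes)
  chr <- as.character(genomes)
  dt <- data.table::copy(data.table::as.data.table(sam))
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    seqs <- character(nrow(dt))
    for (i in seq_len(nrow(dt))) {
      s <- substr(chr[[dt$genome_id[i]]], dt$pos[i] + 1L,
                  dt$pos[i] + dt$read_len[i])
      if (dt$nm[i] > 0L) {
        x <- strsplit(s, "", fixed = TRUE)[[1L]]
        at <- sample.int(length(x), min(dt$nm[i], length(x)))
        x[at] <- vapply(x[at], function(b) sample(setdiff(bases, b), 1L),
                        character(1L))
        s <- paste0(x, collapse = "")
      }
      seqs[i] <- s
    }
    dt[, seq := seqs]
    dt[]
  })
}

#' Simulate a richness design for the breed x diet model
#'
#' Negative-binomial per-sample richness counts with multiplicative breed,
#' diet and interaction effects on the mean.
#'
#' @param n_per_group Samples per breed x diet cell.
#' @param base_mean Mean richness of the reference cell.
#' @param rr_breed,rr_diet,rr_interaction Rate ratios.
#' @param dispersion NB dispersion (`size` parameter of [stats::rnbinom]
#'   is `1/dispersion`).
#' @param seed Integer seed.
#' @return A `data.table` with `richness`, `breed`, `diet`.
#' @export
simulate_richness_design <- function(n_per_group = 30L, base_mean = 120,
                                     rr_breed = 1.5, rr_diet = 1,
                                     rr_interaction = 1, dispersion = 0.3,
                                     seed = 1L) {
  with_seed(seed, {
    grid <- expand.grid(breed = c("LB", "LSL"), diet = c("ctrl", "supp"),
                        stringsAsFactors = FALSE)
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      mu <- base_mean *
        ifelse(grid$breed[i] == "LSL", rr_breed, 1) *
        ifelse(grid$diet[i] == "supp", rr_diet, 1) *
        ifelse(grid$breed[i] == "LSL" && grid$diet[i] == "supp",
               rr_interaction, 1)
      data.table::data.table(
        richness = rnbinom(n_per_group, size = 1 / dispersion, mu = mu),
        breed = grid$breed[i], diet = grid$diet[i])
    })
    data.table::rbindlist(rows)
  })
}
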