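#' Specification of a synthetic viral lineage hierarchy
#'
#' Defines a three-rank hierarchy (family > genus > species) with several
#' sequence variants per species. Divergence values are per-base
#' substitution rates applied along each branch; small indels accompany
#' substitutions at one tenth of the substitution rate. Defaults produce
#' 40 species (4 families x 2 genera x 5 species) with 3 variants each:
#' within-species branches at 1.5% divergence (about 3% pairwise, so true
#' species comfortably satisfy the 95% ANI species criterion) and
#' between-species branches at 8% (about 16% pairwise, well past the
#' species boundary).
#'
#' @param n_families,genera_per_family,species_per_genus,variants_per_species
#'   Hierarchy shape.
#' @param within_species_div,within_genus_div,within_family_div Per-branch
#'   substitution rates; must increase with rank and
#'   `within_species_div <= 0.05`.
#' @param genome_len_range Root genome length range in bp.
#' @return A `lineage_spec` list.
#' @export
lineage_spec <- function(n_families = 4L, genera_per_family = 2L,
                         species_per_genus = 5L, variants_per_species = 3L,
                         within_species_div = 0.015,
                         within_genus_div = 0.08,
                         within_family_div = 0.15,
                         genome_len_range = c(6000L, 10000L)) {
  if (!(within_species_div < within_genus_div &&
        within_genus_div < within_family_div))
    stop2("divergence must increase with rank: species < genus < family")
  if (within_species_div > 0.05)
    stop2("within_species_div must be <= 0.05 so true species satisfy the ",
          "95% ANI criterion")
  structure(list(n_families = n_families,
                 genera_per_family = genera_per_family,
                 species_per_genus = species_per_genus,
                 variants_per_species = variants_per_species,
                 within_species_div = within_species_div,
                 within_genus_div = within_genus_div,
                 within_family_div = within_family_div,
                 genome_len_range = as.integer(genome_len_range)),
            class = "lineage_spec")
}

#' Mutate a sequence by substitutions and small indels
#'
#' Substitutions occur independently per base at `sub_rate` (always to a
#' different base); indels occur at `indel_rate` per base with
#' geometric(0.5) lengths (mean 2) and equal insertion/deletion odds.
#'
#' @param seq A single character sequence.
#' @param sub_rate Per-base substitution probability.
#' @param indel_rate Per-base indel probability (default `sub_rate / 10`).
#' @return The mutated character sequence.
#' @export
mutate_sequence <- function(seq, sub_rate, indel_rate = sub_rate / 10) {
  bases <- c("A", "C", "G", "T")
  x <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(x)
  sub_at <- which(runif(n) < sub_rate)
  if (length(sub_at)) {
    cur <- x[sub_at]
    new <- vapply(cur, function(b) sample(setdiff(bases, b), 1L),
                  character(1L))
    x[sub_at] <- new
  }
  if (indel_rate > 0) {
    ind_at <- which(runif(n) < indel_rate)
    if (length(ind_at)) {
      # apply right-to-left so earlier positions stay valid
      for (p in rev(sort(ind_at))) {
        len <- rgeom(1L, 0.5) + 1L
        if (runif(1L) < 0.5) {                       # insertion after p
          ins <- sample(bases, len, replace = TRUE)
          x <- append(x, ins, after = p)
        } else {                                     # deletion from p
          drop <- p:min(length(x), p + len - 1L)
          x <- x[-drop]
        }
      }
    }
  }
  paste0(x, collapse = "")
}

random_genome <- function(len) {
  paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Evolve a hierarchy of viral lineages with known ground truth
#'
#' Draws one random root genome per family, then derives genus roots,
#' species roots and per-species variants by seeded mutation along the
#' hierarchy. Output is a pure function of `(spec, seed)`.
#'
#' @param spec A [lineage_spec()].
#' @param seed Integer seed.
#' @return A list with `genomes` (named `DNAStringSet`) and `truth`
#'   (`data.table` with `genome_id`, `species_id`, `genus_id`, `family_id`).
#' @export
evolve_lineages <- function(spec = lineage_spec(), seed = 1L) {
  stopifnot(inherits(spec, "lineage_spec"))
  with_seed(seed, {
    seqs <- character(0)
    truth <- list()
    for (f in seq_len(spec$n_families)) {
      fam_id <- sprintf("F%02d", f)
      fam_len <- sample(spec$genome_len_range[1L]:spec$genome_len_range[2L],
                        1L)
      fam_root <- random_genome(fam_len)
      for (g in seq_len(spec$genera_per_family)) {
        gen_id <- sprintf("%sG%02d", fam_id, g)
        gen_root <- mutate_sequence(fam_root, spec$within_family_div)
        for (s in seq_len(spec$species_per_genus)) {
          sp_id <- sprintf("%sS%02d", gen_id, s)
          sp_root <- mutate_sequence(gen_root, spec$within_genus_div)
          for (v in seq_len(spec$variants_per_species)) {
            vid <- sprintf("%s_v%d", sp_id, v)
            seqs[[vid]] <- mutate_sequence(sp_root, spec$within_species_div)
            truth[[vid]] <- data.frame(genome_id = vid, species_id = sp_id,
                                       genus_id = gen_id, family_id = fam_id)
          }
        }
      }
    }
    list(genomes = as_dna(seqs),
         truth = data.table::rbindlist(truth))
  })
}
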