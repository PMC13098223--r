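#' Per-read alignment identity and aligned fraction
#'
#' Computes the two read-level filter metrics used in read recruitment:
#' * identity = `100 * (alignment_columns - NM) / alignment_columns`, where
#'   alignment columns are CIGAR `M/=/X + I + D` (consistent with the NM
#'   edit distance, which counts mismatches and indel bases);
#' * aligned fraction = `100 * (read bases in M/=/X/I) / read_len`, i.e.
#'   soft-clipped bases count against the read.
#'
#' @param sam A SAM table ([read_sam()] layout); only mapped primary rows
#'   are admitted.
#' @param identity_denominator `"MID"` (default, edit-distance-consistent)
#'   or `"M"` (aligned match columns only).
#' @return The table with `identity` and `aligned_fraction` columns added.
#' @export
alignment_metrics <- function(sam, identity_denominator = c("MID", "M")) {
  identity_denominator <- match.arg(identity_denominator)
  dt <- data.table::as.data.table(sam)
  if (any(!dt$mapped | !dt$primary))
    stop2("alignment_metrics expects mapped primary alignments only")
  if (anyNA(dt$nm))
    stop2("missing NM tag for read '", dt$read_id[is.na(dt$nm)][1L], "'")
  ops <- cigar_op_sums(dt$cigar)
  denom <- if (identity_denominator == "MID")
    ops$aln_m + ops$ins + ops$del else ops$aln_m
  dt[, identity := 100 * (denom - nm) / denom]
  dt[, aligned_fraction := 100 * (ops$aln_m + ops$ins) / read_len]
  dt[]
}

#' Recruit reads to genomes under identity, aligned-fraction and breadth
#' filters
#'
#' One sample's read recruitment: mapped primary alignments are filtered by
#' read identity and aligned fraction, per-genome breadth (fraction of
#' genome positions covered by at least one passing read) is computed from
#' merged reference intervals, and genomes below the breadth threshold have
#' their counts zeroed — breadth filtering suppresses spurious detections
#' from conserved-region hits. Abundance is recruited reads over the
#' sample's total read count.
#'
#' @param sam A SAM table for one sample.
#' @param lengths Named genome lengths.
#' @param total_reads Total quality-controlled reads in the sample.
#' @param min_identity,min_aligned,min_breadth Percent thresholds
#'   (defaults 90 / 75 / 75).
#' @return A `data.table` with per-genome `reads`, `breadth`, `abundance`
#'   (fraction of total reads) for every genome in `lengths`.
#' @export
recruit <- function(sam, lengths, total_reads, min_identity = 90,
                    min_aligned = 75, min_breadth = 75) {
  if (total_reads <= 0) stop2("total_reads must be positive")
  dt <- data.table::as.data.table(sam)
  dt <- dt[mapped & primary]
  if (nrow(dt)) {
    unknown <- setdiff(unique(dt$genome_id), names(lengths))
    if (length(unknown))
      stop2("alignment references genome '", unknown[1L],
            "' absent from the length table")
    dt <- alignment_metrics(dt)
    dt <- dt[identity >= min_identity & aligned_fraction >= min_aligned]
  }
  out <- data.table::data.table(genome_id = names(lengths),
                                reads = 0L, breadth = 0)
  if (nrow(dt)) {
    ops <- cigar_op_sums(dt$cigar)
    dt[, ref_end := pos + ops$ref]
    per <- dt[, .(reads = .N,
                  breadth = 100 * covered_length(pos, ref_end) /
                    lengths[[genome_id[1L]]]),
              by = genome_id]
    out[per, `:=`(reads = i.reads, breadth = i.breadth), on = "genome_id"]
  }
  out[breadth < min_breadth, reads := 0L]
  out[, abundance := reads / total_reads]
  out[]
}

#' Assemble an abundance matrix over samples
#'
#' Runs [recruit()] per sample and assembles a samples x genomes abundance
#' object carrying read counts, abundances relative to total sample reads,
#' within-virome composition (counts over recruited reads), breadth, totals
#' and optional sample metadata.
#'
#' @param sam_list Named list of per-sample SAM tables.
#' @param lengths Named genome lengths.
#' @param totals Named per-sample total read counts.
#' @param metadata Optional metadata table with a `sample_id` column.
#' @param ... Thresholds passed to [recruit()].
#' @return An `abundance_matrix` list with matrices `counts`, `rel_abund`,
#'   `composition`, `breadth` (rows = samples), `totals`, `metadata`.
#' @export
abundance_matrix <- function(sam_list, lengths, totals, metadata = NULL,
                             ...) {
  samples <- names(sam_list)
  if (is.null(samples) || any(!nzchar(samples)))
    stop2("sam_list must be named by sample")
  if (!all(samples %in% names(totals)))
    stop2("totals missing for sample '",
          setdiff(samples, names(totals))[1L], "'")
  per <- lapply(samples, function(s)
    recruit(sam_list[[s]], lengths, totals[[s]], ...))
  counts <- do.call(rbind, lapply(per, function(p) p$reads))
  breadth <- do.call(rbind, lapply(per, function(p) p$breadth))
  dimnames(counts) <- dimnames(breadth) <- list(samples, names(lengths))
  tot <- as.numeric(totals[samples])
  rec <- rowSums(counts)
  comp <- counts / ifelse(rec > 0, rec, 1)
  structure(list(counts = counts,
                 rel_abund = counts / tot,
                 composition = comp,
                 breadth = breadth,
                 totals = setNames(tot, samples),
                 metadata = if (!is.null(metadata))
                   data.table::as.data.table(metadata) else NULL),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("abundance_matrix:", nrow(x$counts), "samples x", ncol(x$counts),
      "genomes\n")
  cat("  recruited reads:", sum(x$counts), "of", sum(x$totals),
      sprintf("(%.3f%%)\n", 100 * sum(x$counts) / sum(x$totals)))
  invisible(x)
}

#' Per-sample mapped read fraction
#'
#' Percent of each sample's reads recruited to the catalog, with optional
#' group mean and standard deviation (e.g. by gut region).
#'
#' @param am An `abundance_matrix`.
#' @param groups Optional per-sample group labels (same order as samples).
#' @return A named numeric vector of percentages; when `groups` is given, a
#'   list with `per_sample` and a `by_group` summary table.
#' @export
mapped_fraction <- function(am, groups = NULL) {
  stopifnot(inherits(am, "abundance_matrix"))
  if (any(am$totals <= 0)) stop2("sample with zero total reads")
  per <- 100 * rowSums(am$counts) / am$totals
  if (is.null(groups)) return(per)
  tab <- data.table::data.table(group = groups, mapped = per)
  list(per_sample = per,
       by_group = tab[, .(mean = mean(mapped), sd = sd(mapped), n = .N),
                      by = group][])
}
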