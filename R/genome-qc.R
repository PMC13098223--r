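#' Detect direct or inverted terminal repeats
#'
#' Searches for a strictly terminal repeat: a direct terminal repeat (DTR)
#' when the first `k` bases equal the last `k` bases in the same orientation,
#' or an inverted terminal repeat (ITR) when the first `k` bases equal the
#' reverse complement of the last `k` bases, for some
#' `k >= min_repeat_len` with at most `max_mismatches` mismatching positions.
#' The repeat must start at the first base and end at the last base; the
#' reported `repeat_length` is the maximal qualifying `k` (capped at half the
#' genome length so prefix and suffix stay disjoint). DTR takes precedence
#' over ITR when both qualify. Terminal repeats are the sequence signature of
#' complete circularly-permuted (DTR) or linear (ITR) phage genomes.
#'
#' @param genome A `DNAString`, single-record `DNAStringSet`, or character
#'   sequence.
#' @param min_repeat_len Minimum repeat length in bp (default 20, the
#'   conventional minimum for DTR calling).
#' @param max_mismatches Maximum mismatching positions within the repeat
#'   (default 0).
#' @return A list with `kind` (`"DTR"`, `"ITR"` or `"none"`),
#'   `repeat_length`, `mismatches`, and `detectable` (`FALSE` when the
#'   sequence is too short for the search to apply).
#' @export
detect_termini <- function(genome, min_repeat_len = 20L, max_mismatches = 0L) {
  s <- single_sequence(genome)
  L <- nchar(s)
  if (L <= 2L * min_repeat_len)
    return(list(kind = "none", repeat_length = 0L, mismatches = 0L,
                detectable = FALSE))
  raw <- charToRaw(s)
  kmax <- L %/% 2L
  dtr <- dtr_scan(raw, L, min_repeat_len, max_mismatches, kmax)
  if (!is.null(dtr))
    return(list(kind = "DTR", repeat_length = dtr$k, mismatches = dtr$mm,
                detectable = TRUE))
  itr <- itr_scan(raw, L, min_repeat_len, max_mismatches, kmax)
  if (!is.null(itr))
    return(list(kind = "ITR", repeat_length = itr$k, mismatches = itr$mm,
                detectable = TRUE))
  list(kind = "none", repeat_length = 0L, mismatches = 0L, detectable = TRUE)
}

# DTR: prefix_k == suffix_k. Seed-scan the first min_repeat_len bases over
# all admissible suffix start positions, then verify full repeats.
dtr_scan <- function(raw, L, min_len, max_mm, kmax) {
  starts <- (L - kmax + 1L):(L - min_len + 1L)   # suffix starts; k = L-j+1
  mm_seed <- integer(length(starts))
  for (i in seq_len(min_len)) {
    mm_seed <- mm_seed + as.integer(raw[starts + i - 1L] != raw[i])
  }
  cand <- starts[mm_seed <= max_mm]
  if (length(cand) == 0L) return(NULL)
  best <- NULL
  for (j in sort(cand)) {                        # smallest j = largest k first
    k <- L - j + 1L
    mm <- sum(raw[seq_len(k)] != raw[j:L])
    if (mm <= max_mm) { best <- list(k = k, mm = as.integer(mm)); break }
  }
  best
}

# ITR: prefix_k == revcomp(suffix_k), i.e. base i pairs with base L+1-i.
# Position-wise complement test makes the maximal k a cumulative-sum scan.
itr_scan <- function(raw, L, min_len, max_mm, kmax) {
  comp <- comp_raw(raw[L:(L - kmax + 1L)])       # complement of reversed tail
  mism <- cumsum(as.integer(raw[seq_len(kmax)] != comp))
  ok <- which(mism <= max_mm)
  ok <- ok[ok >= min_len]
  if (length(ok) == 0L) return(NULL)
  k <- max(ok)
  list(k = k, mm = as.integer(mism[k]))
}

comp_raw <- function(raw) {
  map <- raw(256)
  map[as.integer(charToRaw("A")) + 1L] <- charToRaw("T")
  map[as.integer(charToRaw("T")) + 1L] <- charToRaw("A")
  map[as.integer(charToRaw("C")) + 1L] <- charToRaw("G")
  map[as.integer(charToRaw("G")) + 1L] <- charToRaw("C")
  map[as.integer(charToRaw("N")) + 1L] <- charToRaw("N")
  map[as.integer(raw) + 1L]
}

single_sequence <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    if (length(genome) != 1L) stop2("expected a single sequence")
    return(as.character(genome[[1L]]))
  }
  if (methods::is(genome, "DNAString")) return(as.character(genome))
  if (is.character(genome) && length(genome) == 1L) return(toupper(genome))
  stop2("expected a single DNA sequence")
}

#' Apply contig retention filters
#'
#' A contig is retained if it satisfies either rule:
#' * RULE A: completeness >= 50, viral genes > 0, viral genes > 3 x host genes;
#' * RULE B: length >= 20,000 bp, completeness >= 40, viral genes > 0,
#'   viral genes > 3 x host genes (rescues long, slightly less complete
#'   contigs).
#'
#' Contigs with missing completeness are rejected: both rules condition on
#' completeness and guessing a value would silently change the catalog.
#' Rejected contigs carry the first failed clause as a `reason`.
#'
#' @param qc A QC table ([read_qc_table()] layout).
#' @return A list with `kept` and `rejected` (`rejected` gains `reason` and
#'   both gain `rule`, the rule that admitted the contig or `NA`).
#' @export
apply_retention_filters <- function(qc) {
  dt <- data.table::as.data.table(qc)
  validate_qc_table(dt)
  cpl <- dt$completeness
  has_cpl <- !is.na(cpl)
  viral_ok <- dt$viral_genes > 0L
  ratio_ok <- dt$viral_genes > 3L * dt$host_genes
  rule_a <- has_cpl & cpl >= 50 & viral_ok & ratio_ok
  rule_b <- has_cpl & dt$contig_length >= 20000L & cpl >= 40 &
    viral_ok & ratio_ok
  keep <- rule_a | rule_b
  rsn <- rep(NA_character_, nrow(dt))
  rsn[!keep & !has_cpl] <- "completeness_absent"
  left <- !keep & has_cpl
  rsn[left & !viral_ok] <- "no_viral_genes"
  left <- left & viral_ok
  rsn[left & !ratio_ok] <- "viral_genes_not_3x_host_genes"
  left <- left & ratio_ok
  rsn[left & dt$contig_length >= 20000L] <- "completeness_below_40"
  rsn[left & dt$contig_length < 20000L] <-
    "completeness_below_50_and_contig_below_20kb"
  dt[, rule := data.table::fifelse(rule_a, "A",
                                   data.table::fifelse(rule_b, "B",
                                                       NA_character_))]
  rej <- dt[!keep]
  rej[, reason := rsn[!keep]]
  list(kept = dt[keep], rejected = rej)
}

#' Assign genome quality tiers
#'
#' Tiers retained contigs: `complete` when termini are `DTR`, `ITR` or
#' `provirus` (a closed-genome signal dominates the completeness estimate),
#' else `high` when completeness >= 90, `medium` when >= 50, else `low`.
#'
#' @param qc A QC table of retained contigs (completeness must be present).
#' @return The table with a `tier` column added.
#' @export
assign_quality_tier <- function(qc) {
  dt <- data.table::as.data.table(qc)
  if (anyNA(dt$completeness))
    stop2("absent completeness in tier assignment (contig '",
          dt$contig_id[is.na(dt$completeness)][1L],
          "'); run apply_retention_filters() first")
  dt[, tier := data.table::fifelse(
    termini %in% c("DTR", "ITR", "provirus"), "complete",
    data.table::fifelse(completeness >= 90, "high",
                        data.table::fifelse(completeness >= 50, "medium",
                                            "low")))]
  dt[]
}

#' Quality-control a contig catalog end to end
#'
#' Detects terminal repeats on the sequences, reconciles them with the QC
#' table (provirus calls are trusted from the table, DTR/ITR come from the
#' sequence scan), applies the retention filters and assigns quality tiers.
#'
#' @param genomes Named `DNAStringSet` of contig sequences.
#' @param qc QC table covering the same contig ids.
#' @param min_repeat_len,max_mismatches Passed to [detect_termini()].
#' @return A list with `kept` (tiered QC table) and `rejected`.
#' @export
qc_catalog <- function(genomes, qc, min_repeat_len = 20L,
                       max_mismatches = 0L) {
  genomes <- as_dna(genomes)
  dt <- data.table::as.data.table(qc)
  missing <- setdiff(dt$contig_id, names(genomes))
  if (length(missing))
    stop2("contig '", missing[1L], "' has no sequence")
  detected <- vapply(dt$contig_id, function(id) {
    detect_termini(genomes[[id]], min_repeat_len, max_mismatches)$kind
  }, character(1L))
  dt[, termini := data.table::fifelse(termini == "provirus", "provirus",
                                      detected)]
  res <- apply_retention_filters(dt)
  res$kept <- assign_quality_tier(res$kept)
  res
}
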