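# Alignment emission for synthetic genome sets: either the built-in
# k-mer-anchored ungapped aligner (fast, no external tools) or a
# global-alignment oracle split into gapless blocks. Both produce rows in
# the internal local-alignment layout (0-based half-open coordinates).

#' Global-alignment identity oracle for a genome pair
#'
#' Needleman-Wunsch global alignment (via [Biostrings::pairwiseAlignment])
#' reported as percent identity over the aligned columns, i.e.
#' `matches / (matches + mismatches)`. Gap columns are excluded from the
#' denominator so the value measures the same quantity as a
#' merged-local-alignment ANI: nucleotide identity where the two sequences
#' align.
#'
#' @param q,t Character sequences or `DNAString`s.
#' @return Percent identity in `[0, 100]`.
#' @export
ani_oracle <- function(q, t) {
  aln <- Biostrings::pairwiseAlignment(single_sequence(q),
                                       single_sequence(t), type = "global")
  m <- Biostrings::nmatch(aln)
  100 * m / (m + Biostrings::nmismatch(aln))
}

# shared-kmer candidate pairs over a genome set (inverted k-mer index)
kmer_candidate_pairs <- function(genomes, k = 17L, min_share = 0.05) {
  genomes <- as_dna(genomes)
  ids <- names(genomes)
  km <- lapply(ids, function(id) {
    s <- as.character(genomes[[id]])
    L <- nchar(s)
    if (L < k) return(character(0))
    unique(substring(s, 1:(L - k + 1L), k:L))
  })
  names(km) <- ids
  idx <- data.table::data.table(
    kmer = unlist(km, use.names = FALSE),
    gid = rep(ids, lengths(km)))
  pairs <- merge(idx, idx, by = "kmer", allow.cartesian = TRUE)
  pairs <- pairs[gid.x < gid.y, .(n_shared = .N), by = .(gid.x, gid.y)]
  if (nrow(pairs) == 0L)
    return(data.table::data.table(a = character(), b = character()))
  nk <- lengths(km)
  pairs[, share := n_shared / pmin(nk[gid.x], nk[gid.y])]
  pairs[share >= min_share, .(a = gid.x, b = gid.y)]
}

# k-mer anchored ungapped block alignment of one ordered pair (q query).
# Seeds on exact k-mers are grouped by diagonal; each diagonal contributes
# one span from its first to its last seed, extended outward while bases
# match. Within a span, windows whose local identity collapses to random
# (>= `bad_mm` mismatches in `window` bases) mark segments where the true
# alignment has shifted to another diagonal (e.g. between compensating
# indels); the span is split there and the bad segment discarded, so block
# identities count genuine substitutions but not misaligned sequence.
# Not a general aligner: intended for pairs above ~70% identity with
# short indels, which is what the lineage generator produces.
align_pair_kmer <- function(qid, tid, qseq, tseq, k = 13L, min_block = 50L,
                            min_pident = 70, window = 20L, bad_mm = 10L) {
  qL <- nchar(qseq); tL <- nchar(tseq)
  qraw <- charToRaw(qseq); traw <- charToRaw(tseq)
  qk <- substring(qseq, 1:(qL - k + 1L), k:qL)
  tk <- substring(tseq, 1:(tL - k + 1L), k:tL)
  tdt <- data.table::data.table(kmer = tk, tpos = seq_along(tk))
  qdt <- data.table::data.table(kmer = qk, qpos = seq_along(qk))
  hits <- merge(qdt, tdt, by = "kmer", allow.cartesian = TRUE)
  if (nrow(hits) == 0L) return(NULL)
  hits[, diag := qpos - tpos]
  # drop sparse diagonals (spurious repeat hits)
  hits <- hits[, if (.N >= 2L) .SD, by = diag]
  if (nrow(hits) == 0L) return(NULL)
  spans <- hits[, .(qs = min(qpos), qe = max(qpos) + k - 1L), by = diag]
  rows <- list()
  for (i in seq_len(nrow(spans))) {
    d <- spans$diag[i]
    qs <- spans$qs[i]; qe <- spans$qe[i]
    # extend outward; isolated mismatches are absorbed when the look-ahead
    # window still matches well, so edge substitutions are counted rather
    # than silently excluded (which would bias identity upward)
    repeat {
      while (qe < qL && qe - d < tL && qraw[qe + 1L] == traw[qe - d + 1L])
        qe <- qe + 1L
      la <- min(10L, qL - qe, tL - (qe - d))
      if (la < 4L) break
      mmw <- sum(qraw[(qe + 1L):(qe + la)] !=
                   traw[(qe - d + 1L):(qe - d + la)])
      if (mmw <= la %/% 3L) qe <- qe + la else break
    }
    repeat {
      while (qs > 1L && qs - d > 1L && qraw[qs - 1L] == traw[qs - d - 1L])
        qs <- qs - 1L
      la <- min(10L, qs - 1L, qs - d - 1L)
      if (la < 4L) break
      mmw <- sum(qraw[(qs - la):(qs - 1L)] !=
                   traw[(qs - d - la):(qs - d - 1L)])
      if (mmw <= la %/% 3L) qs <- qs - la else break
    }
    mism <- qraw[qs:qe] != traw[(qs - d):(qe - d)]
    n <- length(mism)
    good <- rep(TRUE, n)
    if (n >= window) {
      wsum <- cumsum(as.integer(mism))
      wsum <- wsum[window:n] - c(0L, wsum[seq_len(n - window)])
      bad_win <- which(wsum >= bad_mm)       # window starting at this offset
      for (b in bad_win) good[b:(b + window - 1L)] <- FALSE
    }
    r <- rle(good)
    stops <- cumsum(r$lengths)
    starts <- c(1L, head(stops, -1L) + 1L)
    for (j in which(r$values)) {
      bs <- qs + starts[j] - 1L; be <- qs + stops[j] - 1L
      len <- be - bs + 1L
      if (len < min_block) next
      mm <- sum(mism[starts[j]:stops[j]])
      pid <- 100 * (len - mm) / len
      if (pid < min_pident) next
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = qid, target_id = tid, pident = pid, aln_len = len,
        mismatches = mm, gap_opens = 0L,
        qstart = bs - 1L, qend = be,
        tstart = bs - d - 1L, tend = be - d,
        evalue = 0, bitscore = 2 * len, strand = "+", self = FALSE)
    }
  }
  if (length(rows) == 0L) return(NULL)
  out <- data.table::rbindlist(rows)
  # keep each query position in at most one block: greedily drop blocks
  # whose query interval is largely inside an already-kept longer block
  data.table::setorder(out, -aln_len)
  kept <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!kept[i]) next
    if (i < nrow(out)) for (j in (i + 1L):nrow(out)) {
      if (!kept[j]) next
      ov <- min(out$qend[i], out$qend[j]) - max(out$qstart[i], out$qstart[j])
      if (ov > 0.5 * out$aln_len[j]) kept[j] <- FALSE
    }
  }
  out[kept]
}

# global-alignment oracle split into gapless blocks
align_pair_oracle <- function(qid, tid, qseq, tseq, min_block = 30L) {
  aln <- Biostrings::pairwiseAlignment(qseq, tseq, type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  gap <- pa == "-" | sa == "-"
  qpos <- cumsum(pa != "-")
  tpos <- cumsum(sa != "-")
  run <- cumsum(c(TRUE, diff(gap) != 0L))
  rows <- list()
  for (r in unique(run[!gap])) {
    idx <- which(run == r)
    len <- length(idx)
    if (len < min_block) next
    mm <- sum(pa[idx] != sa[idx])
    rows[[length(rows) + 1L]] <- data.frame(
      query_id = qid, target_id = tid, pident = 100 * (len - mm) / len,
      aln_len = len, mismatches = mm, gap_opens = 0L,
      qstart = qpos[idx[1L]] - 1L, qend = qpos[idx[len]],
      tstart = tpos[idx[1L]] - 1L, tend = tpos[idx[len]],
      evalue = 0, bitscore = 2 * len, strand = "+", self = FALSE)
  }
  if (length(rows) == 0L) return(NULL)
  data.table::rbindlist(rows)
}

#' Emit a local-alignment table for a synthetic genome set
#'
#' Generates all-vs-all local alignments for genome pairs that share enough
#' exact k-mers to be plausibly related (pairs below roughly 70% identity
#' share almost no long exact k-mers and are skipped). Two engines are
#' available: `"kmer"`, the built-in anchored ungapped aligner, and
#' `"oracle"`, a Needleman-Wunsch global alignment split into gapless
#' blocks. Each unordered pair is aligned once and emitted in both
#' directions.
#'
#' @param genomes Named `DNAStringSet` (tractable sizes: hundreds of
#'   genomes of tens of kb).
#' @param mode `"kmer"` (default) or `"oracle"`.
#' @param min_share Minimum shared-k-mer fraction (of the smaller k-mer
#'   set) for a pair to be aligned.
#' @return A `data.table` in the internal local-alignment layout.
#' @export
emit_alignments <- function(genomes, mode = c("kmer", "oracle"),
                            min_share = 0.05) {
  mode <- match.arg(mode)
  genomes <- as_dna(genomes)
  cand <- kmer_candidate_pairs(genomes, min_share = min_share)
  out <- list()
  if (nrow(cand)) {
    chr <- as.character(genomes)
    for (i in seq_len(nrow(cand))) {
      a <- cand$a[i]; b <- cand$b[i]
      rows <- if (mode == "kmer")
        align_pair_kmer(a, b, chr[[a]], chr[[b]])
      else align_pair_oracle(a, b, chr[[a]], chr[[b]])
      if (is.null(rows)) next
      rev_rows <- data.table::copy(rows)
      data.table::setnames(rev_rows,
                           c("query_id", "target_id", "qstart", "qend",
                             "tstart", "tend"),
                           c("target_id", "query_id", "tstart", "tend",
                             "qstart", "qend"))
      data.table::setcolorder(rev_rows, names(rows))
      out[[length(out) + 1L]] <- rows
      out[[length(out) + 1L]] <- rev_rows
    }
  }
  if (length(out) == 0L) return(empty_alignment_table())
  data.table::rbindlist(out)
}
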