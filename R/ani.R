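#' Merged-local-alignment ANI for one ordered genome pair
#'
#' Combines all local alignments between a query and a target genome:
#' the average nucleotide identity (ANI) is the alignment-length-weighted
#' mean of the per-alignment percent identities, while query and target
#' coverage are computed from the merged (union, not sum) alignment
#' intervals on each sequence. Overlapping alignments are merged only for
#' coverage, never for identity weighting.
#'
#' @param aln Alignment rows ([read_alignment_table()] layout) sharing one
#'   `(query_id, target_id)` pair; self rows are not admitted.
#' @param qlen,tlen Query and target lengths in bp.
#' @return A one-row `data.frame` with `query_id`, `target_id`, `ani`,
#'   `qcov`, `tcov`, `n_alignments`, or `NULL` for an empty alignment set
#'   (the pair is then treated as ANI 0 downstream).
#' @export
pair_ani <- function(aln, qlen, tlen) {
  dt <- data.table::as.data.table(aln)
  if (nrow(dt) == 0L) return(NULL)
  if (length(unique(dt$query_id)) != 1L || length(unique(dt$target_id)) != 1L)
    stop2("pair_ani expects alignments of a single ordered pair")
  if (dt$query_id[1L] == dt$target_id[1L])
    stop2("self-alignments are excluded from ANI")
  data.frame(
    query_id = dt$query_id[1L], target_id = dt$target_id[1L],
    ani = sum(dt$pident * dt$aln_len) / sum(dt$aln_len),
    qcov = 100 * covered_length(dt$qstart, dt$qend) / qlen,
    tcov = 100 * covered_length(dt$tstart, dt$tend) / tlen,
    n_alignments = nrow(dt))
}

#' Pairwise ANI table from a local-alignment table
#'
#' Applies [pair_ani()] to every ordered `(query, target)` pair in an
#' alignment table. Self-alignments are dropped.
#'
#' @param aln Alignment table ([read_alignment_table()] layout).
#' @param lengths Named genome lengths covering every id in `aln`.
#' @return A `data.table` of per-pair ANI records.
#' @export
compute_ani <- function(aln, lengths) {
  dt <- data.table::as.data.table(aln)
  dt <- dt[query_id != target_id]
  if (nrow(dt) == 0L)
    return(data.table::data.table(
      query_id = character(), target_id = character(), ani = numeric(),
      qcov = numeric(), tcov = numeric(), n_alignments = integer()))
  unknown <- setdiff(unique(c(dt$query_id, dt$target_id)), names(lengths))
  if (length(unknown))
    stop2("alignment references unknown genome id '", unknown[1L], "'")
  out <- dt[, {
    ql <- lengths[[query_id[1L]]]
    tl <- lengths[[target_id[1L]]]
    list(ani = sum(pident * aln_len) / sum(aln_len),
         qcov = 100 * covered_length(qstart, qend) / ql,
         tcov = 100 * covered_length(tstart, tend) / tl,
         n_alignments = .N)
  }, by = .(query_id, target_id)]
  out[]
}

#' Greedy centroid clustering into species-level vOTUs
#'
#' CD-HIT-like clustering: genomes are processed in descending length order
#' (length ties broken by ascending id); each genome joins the first
#' already-founded centroid to which it has `ani >= min_ani`, coverage of
#' the shorter of the two sequences `>= min_tcov`, and its own (query)
#' coverage `>= min_qcov`; otherwise it founds a new cluster. The defaults
#' encode the MIUViG species criterion: 95% ANI over 85% of the shorter
#' sequence.
#'
#' @param lengths Named genome lengths (defines the genome set).
#' @param ani_pairs ANI table from [compute_ani()]; pairs absent from the
#'   table are treated as ANI 0 (no transitivity is assumed).
#' @param min_ani,min_tcov,min_qcov Thresholds in percent.
#' @param coverage Either `"shorter"` (default; threshold applies to the
#'   shorter sequence of the pair) or `"target"` (strict target-coverage
#'   semantics, the centroid being the target).
#' @return A `data.table` with columns `centroid_id`, `member_id`; clusters
#'   partition the genome set and every centroid is the longest member.
#' @export
greedy_cluster <- function(lengths, ani_pairs, min_ani = 95, min_tcov = 85,
                           min_qcov = 0, coverage = c("shorter", "target")) {
  coverage <- match.arg(coverage)
  pairs <- data.table::as.data.table(ani_pairs)
  if (nrow(pairs)) {
    unknown <- setdiff(unique(c(pairs$query_id, pairs$target_id)),
                       names(lengths))
    if (length(unknown))
      stop2("ANI pair references unknown genome id '", unknown[1L], "'")
  }
  ids <- names(lengths)
  ord <- order(-as.numeric(lengths), ids)
  ids <- ids[ord]
  lut <- new.env(parent = emptyenv())
  if (nrow(pairs)) {
    for (i in seq_len(nrow(pairs)))
      assign(paste0(pairs$query_id[i], "\r", pairs$target_id[i]),
             c(pairs$ani[i], pairs$qcov[i], pairs$tcov[i]), envir = lut)
  }
  look <- function(q, t) {
    v <- mget(paste0(q, "\r", t), envir = lut, ifnotfound = list(NULL))[[1L]]
    v
  }
  centroids <- character(0)
  assign_to <- character(0)
  for (g in ids) {
    joined <- NA_character_
    for (cen in centroids) {
      rec <- look(g, cen)   # g as query, centroid as target
      if (!is.null(rec)) {
        ani <- rec[1L]; qcov <- rec[2L]; tcov <- rec[3L]
      } else {
        rec2 <- look(cen, g)
        if (is.null(rec2)) next
        ani <- rec2[1L]; qcov <- rec2[3L]; tcov <- rec2[2L]
      }
      cov_thr <- if (coverage == "target") tcov
      else if (lengths[[g]] <= lengths[[cen]]) qcov else tcov
      if (ani >= min_ani && cov_thr >= min_tcov && qcov >= min_qcov) {
        joined <- cen
        break
      }
    }
    if (is.na(joined)) {
      centroids <- c(centroids, g)
      assign_to <- c(assign_to, g)
    } else {
      assign_to <- c(assign_to, joined)
    }
  }
  data.table::data.table(centroid_id = assign_to, member_id = ids)
}

#' Certify a greedy clustering against its thresholds
#'
#' Post-hoc check that every non-centroid member meets the ANI and
#' shorter-sequence coverage thresholds with respect to its centroid.
#'
#' @param clusters Output of [greedy_cluster()].
#' @param lengths,ani_pairs As in [greedy_cluster()].
#' @return A `data.table` with per-member `ani` and `cov_shorter`.
#' @export
certify_clusters <- function(clusters, lengths, ani_pairs) {
  cl <- data.table::as.data.table(clusters)
  pairs <- data.table::as.data.table(ani_pairs)
  mem <- cl[centroid_id != member_id]
  if (nrow(mem) == 0L)
    return(data.table::data.table(centroid_id = character(),
                                  member_id = character(), ani = numeric(),
                                  cov_shorter = numeric()))
  rows <- lapply(seq_len(nrow(mem)), function(i) {
    g <- mem$member_id[i]; cen <- mem$centroid_id[i]
    rec <- pairs[query_id == g & target_id == cen]
    if (nrow(rec)) {
      shorter_cov <- if (lengths[[g]] <= lengths[[cen]]) rec$qcov[1L]
      else rec$tcov[1L]
      return(data.frame(centroid_id = cen, member_id = g, ani = rec$ani[1L],
                        cov_shorter = shorter_cov))
    }
    rec <- pairs[query_id == cen & target_id == g]
    if (nrow(rec)) {
      shorter_cov <- if (lengths[[g]] <= lengths[[cen]]) rec$tcov[1L]
      else rec$qcov[1L]
      return(data.frame(centroid_id = cen, member_id = g, ani = rec$ani[1L],
                        cov_shorter = shorter_cov))
    }
    data.frame(centroid_id = cen, member_id = g, ani = 0,
               cov_shorter = 0)
  })
  data.table::rbindlist(rows)
}

#' Species-level overlap between two genome catalogs
#'
#' Clusters the union of two catalogs at the species thresholds and counts
#' clusters containing members of both catalogs ("shared") or of one only.
#'
#' @param lengths_a,lengths_b Named genome lengths of each catalog; ids must
#'   not collide across catalogs.
#' @param ani_pairs ANI table over the union.
#' @param ... Passed to [greedy_cluster()].
#' @return A list with `shared`, `unique_a`, `unique_b`, and the underlying
#'   `clusters` table.
#' @export
cross_catalog_overlap <- function(lengths_a, lengths_b, ani_pairs, ...) {
  coll <- intersect(names(lengths_a), names(lengths_b))
  if (length(coll))
    stop2("genome id '", coll[1L], "' occurs in both catalogs; prefix the ",
          "ids of one catalog before comparing")
  lengths <- c(lengths_a, lengths_b)
  cl <- greedy_cluster(lengths, ani_pairs, ...)
  cl[, catalog := data.table::fifelse(member_id %in% names(lengths_a),
                                      "a", "b")]
  per <- cl[, .(has_a = any(catalog == "a"), has_b = any(catalog == "b")),
            by = centroid_id]
  list(shared = sum(per$has_a & per$has_b),
       unique_a = sum(per$has_a & !per$has_b),
       unique_b = sum(per$has_b & !per$has_a),
       clusters = cl[])
}
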