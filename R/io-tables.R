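ALN_COLS <- c("query_id", "target_id", "pident", "aln_len", "mismatches",
              "gap_opens", "qstart", "qend", "tstart", "tend",
              "evalue", "bitscore")

GUT_REGIONS <- c("crop", "duodenum", "jejunum", "ileum", "caeca",
                 "colorectum", "feces")

TERMINI_LEVELS <- c("DTR", "ITR", "provirus", "none")

#' Read a 12-column tabular local-alignment file
#'
#' Reads the standard 12-column tab-separated local-alignment dialect
#' (query, target, percent identity, alignment length, mismatches, gap opens,
#' query start/end, target start/end, E-value, bit score). External
#' coordinates are 1-based inclusive; they are converted exactly once here to
#' 0-based half-open intervals, the convention used by all internal interval
#' arithmetic. Minus-strand rows (target start > end) are normalised to
#' ascending target coordinates with `strand = "-"`. Self-alignments are
#' retained and flagged in the `self` column.
#'
#' @param path Path to a tab-separated alignment table (no header).
#' @return A `data.table` with columns `query_id`, `target_id`, `pident`,
#'   `aln_len`, `mismatches`, `gap_opens`, `qstart`, `qend`, `tstart`, `tend`
#'   (0-based half-open), `evalue`, `bitscore`, `strand`, `self`.
#' @export
read_alignment_table <- function(path) {
  if (!file.exists(path)) stop2("alignment table not found: ", path)
  nf <- tryCatch(utils::count.fields(path, sep = "\t", quote = "",
                                     comment.char = ""),
                 error = function(e) integer(0))
  if (length(nf) == 0L) return(empty_alignment_table())
  bad <- which(nf != 12L)
  if (length(bad))
    stop2("alignment table parse error at row ", bad[1L], ": expected 12 ",
          "tab-separated columns, found ", nf[bad[1L]])
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = ALN_COLS,
                          colClasses = list(character = 1:2))
  num_cols <- ALN_COLS[3:12]
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(dt[[cc]]))
    if (anyNA(v) && !anyNA(dt[[cc]]))
      stop2("non-numeric value in column '", cc, "'")
    data.table::set(dt, j = cc, value = v)
  }
  if (any(dt$qstart > dt$qend))
    stop2("alignment table: qstart > qend at row ",
          which(dt$qstart > dt$qend)[1L])
  if (any(dt$aln_len < 1L)) stop2("alignment length < 1")
  if (any(dt$pident < 0 | dt$pident > 100))
    stop2("pident outside [0, 100]")
  minus <- dt$tstart > dt$tend
  ts <- ifelse(minus, dt$tend, dt$tstart)
  te <- ifelse(minus, dt$tstart, dt$tend)
  dt[, `:=`(strand = ifelse(minus, "-", "+"),
            self = query_id == target_id,
            qstart = as.integer(qstart - 1L), qend = as.integer(qend),
            tstart = as.integer(ts - 1L), tend = as.integer(te))]
  dt[]
}

empty_alignment_table <- function() {
  dt <- data.table::data.table(
    query_id = character(), target_id = character(), pident = numeric(),
    aln_len = numeric(), mismatches = numeric(), gap_opens = numeric(),
    qstart = integer(), qend = integer(), tstart = integer(),
    tend = integer(), evalue = numeric(), bitscore = numeric(),
    strand = character(), self = logical())
  dt
}

#' Write a local-alignment table in the 12-column dialect
#'
#' Inverse of [read_alignment_table()]: converts internal 0-based half-open
#' coordinates back to 1-based inclusive and restores minus-strand target
#' orientation.
#'
#' @param aln A table as returned by [read_alignment_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_table <- function(aln, path) {
  dt <- data.table::as.data.table(aln)
  minus <- dt$strand == "-"
  out <- dt[, .(query_id, target_id, pident, aln_len, mismatches, gap_opens,
                qstart = qstart + 1L, qend = qend,
                tstart = ifelse(minus, tend, tstart + 1L),
                tend = ifelse(minus, tstart + 1L, tend),
                evalue, bitscore)]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

QC_REQUIRED <- c("contig_id", "contig_length", "completeness",
                 "contamination", "viral_genes", "host_genes", "termini")

#' Read a per-contig quality-control table
#'
#' Reads a header-carrying TSV in the quality-summary dialect produced by
#' completeness estimators: one row per contig with estimated completeness,
#' contamination, viral and host gene counts and a termini call. Missing
#' completeness values (`NA`) are kept as missing, never coerced to zero.
#'
#' @param path Path to a TSV with columns `contig_id`, `contig_length`,
#'   `completeness`, `contamination`, `viral_genes`, `host_genes`, `termini`.
#' @return A `data.table`, one row per contig.
#' @export
read_qc_table <- function(path) {
  if (!file.exists(path)) stop2("QC table not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("NA", ""))
  miss <- setdiff(QC_REQUIRED, names(dt))
  if (length(miss))
    stop2("QC table schema error: missing required column(s) ",
          paste0("'", miss, "'", collapse = ", "))
  validate_qc_table(dt)
  dt[]
}

validate_qc_table <- function(dt) {
  if (anyDuplicated(dt$contig_id))
    stop2("QC table: duplicate contig_id '",
          dt$contig_id[duplicated(dt$contig_id)][1L], "'")
  cpl <- dt$completeness
  if (any(!is.na(cpl) & (cpl < 0 | cpl > 100)))
    stop2("QC table: completeness outside [0, 100] for contig '",
          dt$contig_id[which(!is.na(cpl) & (cpl < 0 | cpl > 100))[1L]], "'")
  if (any(dt$viral_genes < 0, na.rm = TRUE) ||
      any(dt$host_genes < 0, na.rm = TRUE))
    stop2("QC table: negative gene counts")
  bad_t <- !dt$termini %in% TERMINI_LEVELS
  if (any(bad_t))
    stop2("QC table: unknown termini value '", dt$termini[bad_t][1L],
          "' (expected one of ", paste(TERMINI_LEVELS, collapse = ", "), ")")
  invisible(dt)
}

#' Write a per-contig quality-control table
#' @param qc A QC table ([read_qc_table()] layout).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_table <- function(qc, path) {
  data.table::fwrite(data.table::as.data.table(qc), path, sep = "\t",
                     na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a sample-metadata table
#'
#' Reads a TSV with one row per sample. `region` must come from the
#' seven-level gut-region vocabulary (`crop`, `duodenum`, `jejunum`, `ileum`,
#' `caeca`, `colorectum`, `feces`). Optional fields (`breed`, `diet`, `sex`)
#' are kept as `NA` when absent; they are never silently filled.
#'
#' @param path Path to a TSV with at least `sample_id`, `region`, `country`.
#' @return A `data.table`, one row per sample.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop2("metadata table not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("NA", ""))
  miss <- setdiff(c("sample_id", "region", "country"), names(dt))
  if (length(miss))
    stop2("metadata schema error: missing required column(s) ",
          paste0("'", miss, "'", collapse = ", "))
  if (anyDuplicated(dt$sample_id))
    stop2("metadata: duplicate sample_id")
  bad <- !dt$region %in% GUT_REGIONS
  if (any(bad))
    stop2("metadata: unknown region '", dt$region[bad][1L],
          "' (expected one of ", paste(GUT_REGIONS, collapse = ", "), ")")
  dt[]
}

#' Read a vOTU host-prediction table
#'
#' One best-score host prediction per genome: columns `genome_id`,
#' `host_family`, `host_genus` (either may be `NA` for unassigned genomes).
#'
#' @param path Path to a TSV.
#' @return A `data.table`.
#' @export
read_host_table <- function(path) {
  if (!file.exists(path)) stop2("host table not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("NA", ""))
  miss <- setdiff(c("genome_id", "host_family", "host_genus"), names(dt))
  if (length(miss))
    stop2("host table schema error: missing required column(s) ",
          paste0("'", miss, "'", collapse = ", "))
  if (anyDuplicated(dt$genome_id))
    stop2("host table: duplicate genome_id (one best prediction per genome)")
  dt[]
}
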