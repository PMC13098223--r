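#' Read a text SAM file (read-recruitment subset)
#'
#' Parses the SAM subset used for read recruitment: `QNAME`, `FLAG`, `RNAME`,
#' `POS`, `CIGAR`, `SEQ` length and the `NM:i` edit-distance tag. Header
#' lines (`@...`) are skipped. Reference positions are converted to 0-based
#' at this boundary. `mapped` and `primary` flags are decoded from `FLAG`
#' (bits 0x4, 0x100, 0x800).
#'
#' @param path Path to a SAM text file.
#' @return A `data.table` with columns `read_id`, `flag`, `genome_id`,
#'   `pos` (0-based), `cigar`, `read_len`, `nm` (`NA` when the tag is
#'   absent), `mapped`, `primary`.
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop2("SAM file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0L) return(empty_sam_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield < 11L))
    stop2("SAM parse error at alignment line ", which(nfield < 11L)[1L],
          ": fewer than 11 mandatory fields")
  get <- function(i) vapply(fields, `[[`, character(1L), i)
  nm <- vapply(fields, function(f) {
    tags <- f[-(1:11)]
    hit <- tags[startsWith(tags, "NM:i:")]
    if (length(hit)) as.integer(sub("NM:i:", "", hit[1L], fixed = TRUE))
    else NA_integer_
  }, integer(1L))
  seqf <- get(10L)
  cig <- get(6L)
  read_len <- ifelse(seqf == "*", NA_integer_, nchar(seqf))
  # fall back to CIGAR-derived length when SEQ is omitted
  no_seq <- is.na(read_len) & cig != "*"
  if (any(no_seq))
    read_len[no_seq] <- vapply(cig[no_seq], cigar_read_length, integer(1L))
  flag <- as.integer(get(2L))
  dt <- data.table::data.table(
    read_id = get(1L),
    flag = flag,
    genome_id = get(3L),
    pos = as.integer(get(4L)) - 1L,
    cigar = cig,
    read_len = as.integer(read_len),
    nm = nm,
    mapped = bitwAnd(flag, 4L) == 0L,
    primary = bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L)
  dt[]
}

empty_sam_table <- function() {
  data.table::data.table(
    read_id = character(), flag = integer(), genome_id = character(),
    pos = integer(), cigar = character(), read_len = integer(),
    nm = integer(), mapped = logical(), primary = logical())
}

#' Write a SAM subset table to a text SAM file
#'
#' @param sam A table in the [read_sam()] layout; an optional `seq` column
#'   supplies read sequences (otherwise `SEQ` is written as `*`).
#' @param path Output path.
#' @param genome_lengths Named lengths for the `@SQ` header lines.
#' @return `path`, invisibly.
#' @export
write_sam <- function(sam, path, genome_lengths = NULL) {
  dt <- data.table::as.data.table(sam)
  hdr <- "@HD\tVN:1.6\tSO:unsorted"
  if (!is.null(genome_lengths))
    hdr <- c(hdr, sprintf("@SQ\tSN:%s\tLN:%d", names(genome_lengths),
                          as.integer(genome_lengths)))
  seqf <- if ("seq" %in% names(dt)) dt$seq else rep("*", nrow(dt))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*%s",
                  dt$read_id, dt$flag, dt$genome_id, dt$pos + 1L,
                  ifelse(dt$mapped, 60L, 0L), dt$cigar, seqf,
                  ifelse(is.na(dt$nm), "", sprintf("\tNM:i:%d", dt$nm)))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# --- CIGAR helpers -----------------------------------------------------------

cigar_split <- function(cigar) {
  if (cigar == "*") return(list(len = integer(0), op = character(0)))
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1L]]
  toks <- regmatches(cigar, list(m))[[1L]]
  if (sum(attr(m, "match.length")) != nchar(cigar))
    stop2("malformed CIGAR '", cigar, "'")
  list(len = as.integer(sub("[MIDNSHP=X]$", "", toks)),
       op = sub("^\\d+", "", toks))
}

# bases of the read consumed by the CIGAR (M/I/S/=/X)
cigar_read_length <- function(cigar) {
  cs <- cigar_split(cigar)
  as.integer(sum(cs$len[cs$op %in% c("M", "I", "S", "=", "X")]))
}

# reference span consumed by the CIGAR (M/D/N/=/X)
cigar_ref_length <- function(cigar) {
  cs <- cigar_split(cigar)
  as.integer(sum(cs$len[cs$op %in% c("M", "D", "N", "=", "X")]))
}

# vectorised per-op sums over a cigar vector, returned as a data.table
cigar_op_sums <- function(cigars) {
  u <- unique(cigars)
  res <- lapply(u, function(cg) {
    cs <- cigar_split(cg)
    c(aln_m = sum(cs$len[cs$op %in% c("M", "=", "X")]),
      ins = sum(cs$len[cs$op == "I"]),
      del = sum(cs$len[cs$op %in% c("D", "N")]),
      ref = sum(cs$len[cs$op %in% c("M", "D", "N", "=", "X")]))
  })
  tab <- data.table::as.data.table(do.call(rbind, res))
  tab[, cigar := u]
  tab[match(cigars, tab$cigar)]
}
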