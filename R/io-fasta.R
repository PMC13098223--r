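#' Read a multi-record FASTA file of genome sequences
#'
#' Parses a (wrapped or unwrapped) FASTA file into a [Biostrings::DNAStringSet].
#' Sequence ids are the first whitespace-delimited token of each header.
#' Lowercase bases are normalised to uppercase; only `A`, `C`, `G`, `T`, `N`
#' are admitted. Duplicate ids, empty sequences and malformed headers are
#' rejected with an error naming the offending line.
#'
#' @param path Path to a FASTA file.
#' @return A named `DNAStringSet`; names are unique record ids.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop2("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop2("empty FASTA file: ", path)
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L])
    stop2("FASTA parse error at line 1: expected '>' header, got '",
          substr(lines[1L], 1L, 30L), "'")
  hdr_idx <- which(is_hdr)
  ids <- vapply(lines[hdr_idx], function(h) {
    id <- strsplit(sub("^>", "", h), "[ \t]")[[1L]][1L]
    if (is.na(id) || !nzchar(id)) "" else id
  }, character(1L), USE.NAMES = FALSE)
  bad_hdr <- which(!nzchar(ids))
  if (length(bad_hdr))
    stop2("FASTA parse error at line ", hdr_idx[bad_hdr[1L]],
          ": header has no id")
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stop2("duplicate FASTA id '", dup, "' (ids must be unique)")
  }
  ends <- c(hdr_idx[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr_idx), function(i) {
    if (ends[i] < hdr_idx[i] + 1L) return("")
    paste0(lines[(hdr_idx[i] + 1L):ends[i]], collapse = "")
  }, character(1L))
  empty <- which(!nzchar(seqs))
  if (length(empty))
    stop2("FASTA parse error at line ", hdr_idx[empty[1L]],
          ": record '", ids[empty[1L]], "' has an empty sequence")
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop2("record '", ids[which(bad)[1L]],
          "' contains characters outside {A,C,G,T,N}")
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  x
}

#' Write genome sequences to FASTA
#'
#' @param x A named `DNAStringSet` or named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 80L) {
  x <- as_dna(x)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop2("all records must be named")
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

# coerce character vectors / DNAStringSet uniformly
as_dna <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (is.character(x)) {
    y <- Biostrings::DNAStringSet(toupper(x))
    names(y) <- names(x)
    return(y)
  }
  stop2("expected a DNAStringSet or named character vector")
}

#' Genome lengths of a sequence collection
#'
#' @param genomes A named `DNAStringSet` or named character vector.
#' @return Named integer vector of lengths in bp.
#' @export
genome_lengths <- function(genomes) {
  genomes <- as_dna(genomes)
  setNames(Biostrings::width(genomes), names(genomes))
}

#' @importFrom methods is
NULL
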