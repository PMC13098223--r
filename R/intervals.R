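#' Merge 0-based half-open intervals on one sequence
#'
#' Combines possibly overlapping intervals into a disjoint sorted set and
#' reports the total number of covered positions. This is the primitive
#' behind "combining the local alignments" for coverage: merged, not summed,
#' so overlapping alignments are not double-counted.
#'
#' @param starts,ends Integer vectors of equal length; each interval is
#'   `[start, end)` with `0 <= start < end`.
#' @return A list with `intervals` (two-column matrix `start`, `end`) and
#'   `covered` (total covered length).
#' @export
merge_intervals <- function(starts, ends) {
  if (length(starts) != length(ends))
    stop2("starts and ends must have equal length")
  if (length(starts) == 0L)
    return(list(intervals = cbind(start = integer(0), end = integer(0)),
                covered = 0L))
  if (any(starts < 0)) stop2("negative interval start")
  if (any(starts >= ends)) stop2("inverted or empty interval (start >= end)")
  ir <- IRanges::reduce(IRanges::IRanges(start = starts + 1L, end = ends))
  list(intervals = cbind(start = IRanges::start(ir) - 1L,
                         end = IRanges::end(ir)),
       covered = sum(IRanges::width(ir)))
}

# covered length only (hot path)
covered_length <- function(starts, ends) {
  if (length(starts) == 0L) return(0L)
  sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(start = starts + 1L, end = ends))))
}
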