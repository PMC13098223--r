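# independent brute-force oracles, deliberately written with plain string
# and vector operations, not via the package's code paths

revcomp_chr <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste0(rev(map[strsplit(s, "")[[1L]]]), collapse = "")
}

# exhaustive terminal-repeat scan: every k from min_len to floor(L/2)
brute_termini <- function(s, min_len = 20L, max_mm = 0L) {
  L <- nchar(s)
  if (L <= 2L * min_len)
    return(list(kind = "none", repeat_length = 0L))
  x <- strsplit(s, "")[[1L]]
  rc <- strsplit(revcomp_chr(s), "")[[1L]]
  best_dtr <- 0L
  best_itr <- 0L
  for (k in seq(min_len, L %/% 2L)) {
    if (sum(x[1:k] != x[(L - k + 1L):L]) <= max_mm) best_dtr <- k
    # prefix vs revcomp(suffix): revcomp(suffix_k) = first k of revcomp(s)
    if (sum(x[1:k] != rc[1:k]) <= max_mm) best_itr <- k
  }
  if (best_dtr > 0L) list(kind = "DTR", repeat_length = best_dtr)
  else if (best_itr > 0L) list(kind = "ITR", repeat_length = best_itr)
  else list(kind = "none", repeat_length = 0L)
}

# per-base bitmap coverage of 0-based half-open intervals
bitmap_covered <- function(starts, ends, len) {
  hit <- logical(len)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) hit[(starts[i] + 1L):ends[i]] <- TRUE
  }
  sum(hit)
}

# exact expected accumulation curve by enumerating all sample orders
exact_accumulation <- function(pres) {
  n <- nrow(pres)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  all_orders <- perms(seq_len(n))
  curves <- vapply(all_orders, function(o) {
    seen <- rep(FALSE, ncol(pres))
    vapply(seq_len(n), function(k) {
      seen <<- seen | pres[o[k], ]
      sum(seen)
    }, numeric(1L))
  }, numeric(n))
  rowMeans(curves)
}
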