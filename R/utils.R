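#' @importFrom data.table data.table as.data.table setDT setnames := .N .SD
#' @importFrom stats rbinom rpois runif rnbinom rgeom sd setNames quantile
#' @importFrom utils head tail
NULL

# run expr under a temporary seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

# deterministic child seeds so independent generator stages do not share streams
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + 1013904223L + 69069L * as.integer(k)) %% 2147483647L
}
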