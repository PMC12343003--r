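# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state so
# generators behave as pure functions of (config, seed).
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Row-normalize a dense matrix to unit L2 norm; errors on all-zero rows.
row_unit <- function(m, what = "profile") {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0))
    stopf("undefined similarity for zero %s (rows: %s)", what,
          paste(head(rownames(m)[nrm == 0], 5), collapse = ", "))
  m / nrm
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
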