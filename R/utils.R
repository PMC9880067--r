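# shared internal helpers

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Run `code` under a temporary RNG seed, restoring (or removing) the global
# .Random.seed afterwards so no function leaks RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stopf("'seed' must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# first line decides: tab-separated unless it contains commas and no tabs
sniff_sep <- function(path) {
  l1 <- readLines(path, n = 1L)
  if (!length(l1)) stopf("'%s' is empty", path)
  if (grepl("\t", l1)) "\t" else if (grepl(",", l1)) "," else "\t"
}

row_var <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1L)
}
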