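#' @keywords internal
"_PACKAGE"

abort_empty <- function(what) {
  stop(sprintf("empty input: %s has no usable rows", what), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` with a local RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic locale-independent ordering (C byte order for characters).
order_radix <- function(...) order(..., method = "radix")

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)
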