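# Seed scoping: package functions that take a `seed` argument draw from a
# private stream and restore the caller's RNG state afterwards.
.seed_set <- function(seed) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  invisible(old)
}

.seed_restore <- function(old) {
  if (is.null(old)) {
    if (!is.null(get0(".Random.seed", envir = globalenv())))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
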