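# internal helpers: seeded evaluation and deterministic per-sequence seeds

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Polynomial string hash folded into [0, 2^31 - 2]; used to derive an
# independent, reproducible sub-seed from (global seed, id string, index).
# All arithmetic stays below 2^53 so the result is exact in doubles.
hash_seed <- function(seed, id = "", index = 0L) {
  mod <- 2^31 - 1
  h <- (as.numeric(seed) %% mod)
  bytes <- c(utf8ToInt(as.character(id)), 255L,
             as.integer(index) %% 256L, as.integer(index) %/% 256L)
  for (b in bytes) h <- (h * 131 + b) %% mod
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
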