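# internal helpers shared across modules

# run `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so simulation code never perturbs
# the user's stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# deterministic 32-bit substream seed from a master seed and an index
derive_seed <- function(master, i) {
  m <- as.numeric(master) %% 2147483647
  as.integer((m * 48271 + i * 16807) %% 2147483647)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == round(x)
}

stop_param <- function(...) stop(..., call. = FALSE)

clamp8 <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  storage.mode(x) <- "integer"
  x
}
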