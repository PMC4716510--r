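# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# seed = NULL means: use (and advance) the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# round-half-up to `digits` decimals (base round() is round-half-even)
round_half_up <- function(x, digits = 0L) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical (sorted) storage of an unphased allele pair, elementwise over
# vectors; NA-safe (a missing genotype keeps NA in both slots)
canon_pair <- function(a, b) {
  swap <- !is.na(a) & !is.na(b) & a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  list(a = a, b = b)
}
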