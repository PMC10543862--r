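# Internal helpers: condition constructors and seed hygiene.

cochloc_error <- function(message, class) {
  stop(errorCondition(message, class = c(class, "cochloc_error")))
}

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never clobbers user RNG.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a per-unit child seed < 2^31 from a base seed and an index.
child_seed <- function(seed, index, stream = 0L) {
  (as.numeric(seed) * 7919 + as.numeric(index) * 104729 +
     as.numeric(stream) * 15485863) %% 2147483647
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
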