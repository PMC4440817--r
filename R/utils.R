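clamp01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic derivation of substream seeds from a run seed. Knuth-style
# multiplicative mix reduced mod 2^31 - 1 so results stay valid R integer
# seeds. Distinct stream indices give well-separated seeds.
mix_seed <- function(seed, stream) {
  s <- (as.double(seed) %% 2147483647) + 1
  v <- (s * 48271 + as.double(stream) * 2654435.0) %% 2147483647
  as.integer(v)
}

# Minimal named RNG substreams built on R's global .Random.seed. A stream
# set holds one saved RNG state per stream; `with_stream()` evaluates an
# expression under a stream and saves the advanced state back, so draws in
# one mechanism never shift another's.
make_streams <- function(seeds) {
  old <- get0(".Random.seed", envir = globalenv())
  states <- lapply(seeds, function(s) {
    set.seed(s)
    get(".Random.seed", envir = globalenv())
  })
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  names(states) <- names(seeds)
  states
}

with_stream <- function(streams, name, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  assign(".Random.seed", streams[[name]], envir = globalenv())
  value <- force(expr)
  streams[[name]] <- get(".Random.seed", envir = globalenv())
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  list(value = value, streams = streams)
}
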