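# Internal helpers: seeded streams and small numerics.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed_ <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible integer sub-seed from a base seed and string labels.
# Keeps every derived seed in the 32-bit range. A small multiplicative string
# hash is enough here: streams only need to be distinct and stable.
derive_seed <- function(seed, ...) {
  labels <- paste(c(...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(labels)) h <- (h * 131 + ch) %% 2147480009
  as.integer((as.numeric(seed) * 48271 + h) %% 2147480009)
}

# month lengths of the no-leap calendar used by the generator
month_of_doy <- function(doy) {
  ends <- cumsum(c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31))
  findInterval(doy - 1, c(0, ends[-12])) |> pmin(12L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
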