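# Internal helpers: seeded substreams, array plumbing, validation.

# Derive a reproducible 31-bit sub-seed from a base seed and a stream name,
# so independent pieces of the pipeline never share a random stream. All
# intermediate products stay below 2^53 so the modular arithmetic is exact
# in doubles, even for seeds that are themselves sub-seeds.
sub_seed <- function(seed, stream) {
  h <- 0
  for (ch in utf8ToInt(as.character(stream))) h <- (h * 131 + ch) %% 2147483647
  x <- abs(as.numeric(seed)) %% 2147483647
  x <- (x * 48271) %% 2147483647          # Lehmer step: 48271 * 2^31 < 2^53
  x <- ((x + h) * 48271) %% 2147483647
  as.integer(x)
}

# Evaluate expr with the global RNG temporarily seeded; restores prior state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Ensure (H, W, C) -> (H, W, C, 1); pass 4-d through.
as_batch <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("expected a 3-d or 4-d array")
  x
}

stopifnot_prob <- function(x, what = "x") {
  if (anyNA(x) || min(x) < 0 || max(x) > 1)
    stop(sprintf("%s must contain probabilities in [0, 1]", what))
  invisible(TRUE)
}

# Reflection-pad an (H, W, C) array on the bottom/right to at least (h, w).
reflect_pad_hw <- function(x, h, w) {
  d <- dim(x)
  if (d[1] >= h && d[2] >= w) return(x)
  ridx <- reflect_index(d[1], max(h, d[1]))
  cidx <- reflect_index(d[2], max(w, d[2]))
  if (length(d) == 3L) x[ridx, cidx, , drop = FALSE] else x[ridx, cidx]
}

# Index vector 1..n extended to length m by boundary reflection (abcb|a...).
reflect_index <- function(n, m) {
  if (m <= n) return(seq_len(m))
  if (n == 1L) return(rep(1L, m))
  period <- c(seq_len(n), seq(n - 1L, 2L))
  period[((seq_len(m) - 1L) %% length(period)) + 1L]
}
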