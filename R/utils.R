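# Internal helpers shared across modules.

# Deterministic polynomial string hash (hex), used to fingerprint typing
# tables so feature grids can refuse parameters/decoys typed differently.
str_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  code <- utf8ToInt(x)
  h <- 0
  mod <- 2^31 - 1 # Mersenne prime; doubles hold exact integers well below 2^53
  for (chunk in split(code, ceiling(seq_along(code) / 512))) {
    for (v in chunk) h <- (h * 131 + v) %% mod
  }
  sprintf("%08x", as.integer(h))
}

# n1 x n2 Euclidean cross-distance matrix between coordinate matrices.
cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Sum `vals` into an accumulator of length n by 1-based integer index.
accumulate_by_index <- function(vals, idx, n) {
  out <- numeric(n)
  s <- rowsum(vals, idx)
  out[as.integer(rownames(s))] <- s
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
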