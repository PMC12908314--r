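# Internal helpers shared across modules.

# Signal a classed error so callers can condition on failure mode.
abort <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "cooccurnet_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical unordered pair index for m items: lexicographic (i, j), i < j.
canonical_pairs <- function(m) {
  if (m < 2L) abort("cooccurnet_bad_argument", "need at least 2 taxa to form pairs")
  t(combn(seq_len(m), 2L))
}

# Deterministic per-replicate substream seed derived from (root seed, replicate).
# Keeps values in (0, 2^31) so they are valid R integer seeds, and lets B/P be
# extended without disturbing earlier replicates.
substream_seed <- function(seed, r) {
  s <- (abs(as.double(seed)) %% 2147483647) + 1
  as.integer((s * 48271 + as.double(r) * 30011) %% 2147483629) + 1L
}

# Star annotation rule used in correlation heatmaps: ** for p < 0.01,
# * for 0.01 <= p < 0.05, empty otherwise.
stars_from_p <- function(p) {
  out <- character(length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[is.na(p)] <- NA_character_
  out
}

# All permutations of 1..n as an n! x n integer matrix (cached; n <= 9).
all_permutations <- function(n) {
  key <- paste0("perm", n)
  hit <- .cooccurnet_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (n > 9L) abort("cooccurnet_bad_argument", "exact enumeration supported only for n <= 9")
  build <- function(k) {
    if (k == 1L) return(matrix(1L, 1L, 1L))
    sub <- build(k - 1L)
    out <- vector("list", k)
    for (first in seq_len(k)) {
      rest <- seq_len(k)[-first]
      out[[first]] <- cbind(first, matrix(rest[sub], nrow(sub), k - 1L))
    }
    do.call(rbind, out)
  }
  res <- build(as.integer(n))
  .cooccurnet_cache[[key]] <- res
  res
}
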