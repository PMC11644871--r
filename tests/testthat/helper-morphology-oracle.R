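# Independent set-definition oracles for binary morphology, operating on a
# matrix whose columns are all masks of a fixed small shape (vectorized
# over masks, but written directly from the definitions; shares no code
# with the implementation).
oracle_erode_cols <- function(M, nr, nc, off) {
  out <- matrix(FALSE, nrow(M), ncol(M))
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    px <- i + (j - 1L) * nr
    acc <- rep(TRUE, ncol(M))
    for (t in seq_len(nrow(off))) {
      si <- i + off[t, 1L]; sj <- j + off[t, 2L]
      acc <- if (si < 1L || si > nr || sj < 1L || sj > nc)
        rep(FALSE, ncol(M))
      else acc & M[si + (sj - 1L) * nr, ]
    }
    out[px, ] <- acc
  }
  out
}

oracle_dilate_cols <- function(M, nr, nc, off) {
  out <- matrix(FALSE, nrow(M), ncol(M))
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    px <- i + (j - 1L) * nr
    acc <- rep(FALSE, ncol(M))
    for (t in seq_len(nrow(off))) {
      si <- i - off[t, 1L]; sj <- j - off[t, 2L]
      if (si >= 1L && si <= nr && sj >= 1L && sj <= nc)
        acc <- acc | M[si + (sj - 1L) * nr, ]
    }
    out[px, ] <- acc
  }
  out
}
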