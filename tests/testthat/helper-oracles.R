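# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (double loops, no shared code with the implementation)
# so they can arbitrate correctness.

rand_raw <- function(h, w, seed) {
  set.seed(seed)
  gray_image(matrix(sample(0:255, h * w, replace = TRUE), h, w), "raw")
}

# EME by an explicit double loop over non-overlapping blocks
eme_brute <- function(x, bh = 3L, bw = 3L, eps = 1) {
  if (is_gray_image(x)) x <- pixels(x)
  nbr <- nrow(x) %/% bh
  nbc <- ncol(x) %/% bw
  vals <- numeric(0)
  for (i in seq_len(nbr)) {
    for (j in seq_len(nbc)) {
      blk <- x[((i - 1) * bh + 1):(i * bh), ((j - 1) * bw + 1):(j * bw)]
      mx <- max(blk); mn <- min(blk)
      vals <- c(vals, if (mx < eps) 0 else 20 * log10(mx / max(mn, eps)))
    }
  }
  mean(vals)
}

# Wang-Bovik index by an explicit sliding-window loop
iqi_brute <- function(x, y, w = 8L) {
  if (is_gray_image(x)) x <- pixels(x)
  if (is_gray_image(y)) y <- pixels(y)
  qs <- numeric(0)
  for (i in seq_len(nrow(x) - w + 1)) {
    for (j in seq_len(ncol(x) - w + 1)) {
      a <- as.vector(x[i:(i + w - 1), j:(j + w - 1)])
      b <- as.vector(y[i:(i + w - 1), j:(j + w - 1)])
      ma <- mean(a); mb <- mean(b)
      va <- mean(a^2) - ma^2; vb <- mean(b^2) - mb^2
      cab <- mean(a * b) - ma * mb
      den <- (va + vb) * (ma^2 + mb^2)
      if (abs(den) > 1e-12) qs <- c(qs, 4 * cab * ma * mb / den)
    }
  }
  mean(qs)
}

# Per-tile renormalize -> sigmoid -> restore chain, one tile at a time
scurve_local_brute <- function(x, p, k) {
  h <- nrow(x); w <- ncol(x)
  row_tile <- ceiling(seq_len(h) / h * k)
  col_tile <- ceiling(seq_len(w) / w * k)
  out <- x
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      ri <- which(row_tile == i); ci <- which(col_tile == j)
      blk <- x[ri, ci, drop = FALSE]
      lo <- min(blk); hi <- max(blk)
      if (hi > lo) {
        s <- scurve_value((blk - lo) / (hi - lo), p)
        out[ri, ci] <- lo + s * (hi - lo)
      }
    }
  }
  out
}
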