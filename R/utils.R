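# Internal numeric helpers shared across modules.

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream. `seed = NULL` leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Squared Euclidean distances between rows of `a` (n x d) and rows of `b`
# (m x d); returns n x m. Clamped at 0 against round-off.
pairwise_sqdist <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  d2 <- -2 * tcrossprod(a, b)
  d2 <- d2 + rowSums(a^2)                 # recycles down rows
  d2 <- sweep(d2, 2, rowSums(b^2), "+")
  d2[d2 < 0] <- 0
  d2
}

# k nearest columns for every row of a distance matrix. The stable radix
# sort breaks distance ties by column position, so results are fully
# deterministic for a fixed column order (and our containers keep cells in
# a fixed id order). Returns an integer index matrix nrow(d) x k.
knn_cols <- function(d, k, col_ids = colnames(d)) {
  stopifnot(k >= 1, k <= ncol(d))
  idx <- matrix(0L, nrow(d), k)
  for (i in seq_len(nrow(d))) {
    ord <- order(d[i, ], method = "radix")
    idx[i, ] <- ord[seq_len(k)]
  }
  rownames(idx) <- rownames(d)
  idx
}

row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(0, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

# Center and unit-scale rows; zero-variance rows become all-zero.
scale_rows <- function(x) {
  m <- rowMeans(x)
  s <- sqrt(row_vars(x))
  s[s == 0] <- 1
  (x - m) / s
}

# Column-standardize (across rows) for fast Pearson via crossprod.
# Zero-variance columns become all-NA so the caller can detect them.
standardize_cols <- function(x) {
  n <- nrow(x)
  m <- colMeans(x)
  xc <- sweep(x, 2, m)
  s <- sqrt(colSums(xc^2) / (n - 1))
  bad <- s == 0 | !is.finite(s)
  s[bad] <- 1
  z <- sweep(xc, 2, s, "/")
  if (any(bad)) z[, bad] <- NA_real_
  z
}

`%||%` <- function(a, b) if (is.null(a)) b else a
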