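# Independent affine-gap alignment oracle: a straightforward three-matrix
# DP written from the recurrence, scores only. A gap of length k costs
# open + k * ext. Kept deliberately separate from the package's aligner.

oracle_align_score <- function(a, b, sub, open, ext, local = TRUE) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a)
  m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (local) {
    M[, 1] <- 0
    M[1, ] <- 0
  } else {
    if (n > 0) for (i in 2:(n + 1)) X[i, 1] <- -open - ext * (i - 1)
    if (m > 0) for (j in 2:(m + 1)) Y[1, j] <- -open - ext * (j - 1)
  }
  best <- 0
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      s <- sub[a[i - 1], b[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      if (local) M[i, j] <- max(M[i, j], 0)
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
      if (local && M[i, j] > best) best <- M[i, j]
    }
  }
  if (local) best else max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

oracle_sub_matrix <- function() {
  sc <- align_scoring()
  sc$sub
}
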