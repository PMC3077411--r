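# Independent oracles: deliberately naive scalar/brute-force
# implementations that never share code with the package internals.

# log-entropy weights computed entry-by-entry with scalar loops
oracle_log_entropy <- function(f) {
  n <- ncol(f)
  w <- matrix(0, nrow(f), ncol(f), dimnames = dimnames(f))
  g <- numeric(nrow(f))
  for (i in seq_len(nrow(f))) {
    tot <- sum(f[i, ])
    ent <- 0
    for (j in seq_len(n)) {
      if (f[i, j] > 0) {
        p <- f[i, j] / tot
        ent <- ent + p * log2(p)
      }
    }
    g[i] <- 1 + ent / log2(n)
    for (j in seq_len(n)) w[i, j] <- g[i] * log2(1 + f[i, j])
  }
  list(weights = w, global = g)
}

# hypergeometric enrichment tail by direct pmf summation from lchoose
# (independent of phyper's algorithm)
oracle_fisher_tail <- function(k, m, K, M) {
  t <- k + K
  hi <- min(m, t)
  if (k > hi) return(0)
  i <- k:hi
  valid <- (t - i) <= M & (t - i) >= 0
  sum(exp(lchoose(m, i[valid]) + lchoose(M, t - i[valid]) -
          lchoose(m + M, t)))
}

# direct cosine of the columns of a weight matrix
oracle_cosine_matrix <- function(w) {
  n <- ncol(w)
  s <- matrix(0, n, n, dimnames = list(colnames(w), colnames(w)))
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      s[a, b] <- sum(w[, a] * w[, b]) /
        sqrt(sum(w[, a]^2) * sum(w[, b]^2))
    }
  }
  s
}

# brute-force pair enumeration for edge counting
oracle_count_edges <- function(genes, sim_mat, threshold) {
  genes <- unique(genes)
  m <- 0; k <- 0
  for (a in seq_along(genes)) {
    for (b in seq_along(genes)) {
      if (a < b) {
        m <- m + 1
        if (sim_mat[genes[a], genes[b]] > threshold) k <- k + 1
      }
    }
  }
  list(m = m, k_above = k)
}

# a classed similarity matrix built directly from a symmetric matrix
as_similarity <- function(mat) {
  diag(mat) <- 1
  structure(mat, class = c("similarity_matrix", class(mat)),
            fingerprint = "test")
}
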