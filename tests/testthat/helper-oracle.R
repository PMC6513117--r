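# Brute-force modularity oracle: enumerate every set partition of n units
# (restricted growth strings) and score each one directly from the
# definition. Independent of the optimizer's code path.

all_partitions <- function(n) {
  parts <- list(1L)
  if (n == 1) return(parts)
  for (i in 2:n) {
    new <- vector("list", 0L)
    for (p in parts) {
      m <- max(p)
      for (v in seq_len(m + 1L)) new[[length(new) + 1L]] <- c(p, v)
    }
    parts <- new
  }
  parts
}

brute_force_q <- function(B, labels, c_norm = nrow(B)) {
  sum(B[outer(labels, labels, "==")]) / c_norm
}

brute_force_best <- function(B, c_norm = nrow(B)) {
  parts <- all_partitions(nrow(B))
  qs <- vapply(parts, function(p) brute_force_q(B, p, c_norm), numeric(1))
  list(q = max(qs), labels = parts[[which.max(qs)]])
}

# Random positive-semidefinite low-rank matrix of the kind the spectral
# filter produces (sum of a few lambda v v' terms with orthonormal v).
random_filtered_matrix <- function(n, rank, seed) {
  set.seed(seed)
  V <- qr.Q(qr(matrix(stats::rnorm(n * rank), n, rank)))
  lam <- sort(stats::runif(rank, 0.5, 2) * n / 4, decreasing = TRUE)
  B <- V %*% (lam * t(V))
  (B + t(B)) / 2
}
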