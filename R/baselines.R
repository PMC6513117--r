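# Comparison methods: threshold-network projection with standard graph
# community detection, and signed modularity with an independent-entry null.

#' Project a correlation matrix onto an unweighted graph
#'
#' Edge `(i, j)` iff `C_ij > threshold`, `i != j` — the standard (and
#' threshold-dependent) first step of network-based functional connectivity.
#'
#' @param C A `correlation_matrix` or plain symmetric matrix.
#' @param threshold Threshold in `[-1, 1]`.
#' @return An [igraph::graph] with `N` vertices named by unit id.
#' @export
threshold_project <- function(C, threshold) {
  M <- if (inherits(C, "correlation_matrix")) C$values else as.matrix(C)
  stopifnot(threshold >= -1, threshold <= 1)
  A <- (M > threshold) * 1
  diag(A) <- 0
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

#' Threshold sweep with graph community detection
#'
#' For each threshold: project the matrix onto a graph, run standard
#' Newman-Girvan modularity (Louvain) community detection, and record
#' `S` = fraction of units in the largest connected component and
#' `M` = (number of communities)/N, counting isolated units as singleton
#' communities. On dense all-positive matrices the `S` curve collapses from
#' 1 to 1/N with no multi-community plateau — there is no good threshold.
#'
#' @param C A `correlation_matrix` or plain symmetric matrix.
#' @param thresholds Ascending thresholds, default `seq(0, 1, by = 0.025)`.
#' @param seed Integer seed for the graph community detection.
#' @return A tibble of class `threshold_sweep` with columns `threshold`,
#'   `S`, `M`, `n_communities` and a list-column `partition` of per-threshold
#'   membership vectors.
#' @export
threshold_sweep <- function(C, thresholds = seq(0, 1, by = 0.025), seed = 1) {
  M <- if (inherits(C, "correlation_matrix")) C$values else as.matrix(C)
  stopifnot(!is.unsorted(thresholds))
  n <- nrow(M)
  rows <- purrr::map_dfr(seq_along(thresholds), function(k) {
    g <- threshold_project(M, thresholds[k])
    memb <- with_seed(fan_seed(seed, k), {
      igraph::membership(igraph::cluster_louvain(g))
    })
    comp <- igraph::components(g)
    tibble::tibble(threshold = thresholds[k],
                   S = max(comp$csize) / n,
                   M = length(unique(memb)) / n,
                   n_communities = length(unique(memb)),
                   partition = list(as.integer(memb)))
  })
  class(rows) <- c("threshold_sweep", class(rows))
  rows
}

#' Signed-modularity baseline (independent-entry null)
#'
#' Splits the correlation matrix into positive and negative parts
#' `W+ = max(C, 0)`, `W- = max(-C, 0)` (zero diagonal) and optimizes the
#' asymmetric signed modularity
#' `Q* = Q+/v+ - Q-/(v+ + v-)`, where `Q+-` uses the configuration-model
#' null `s_i s_j / v` with strengths `s_i = sum_j W_ij` and `v = sum_ij W_ij`.
#' Because this null assumes independent matrix entries, mutually
#' anticorrelated groups riding on a strong common trend tend to be merged
#' (the merging bias the spectral null avoids).
#'
#' @param C A `correlation_matrix` or plain symmetric matrix.
#' @param seed Integer seed.
#' @param n_restarts Optimizer restarts, default 100.
#' @return A `funsig_partition` (always flagged significant; this baseline
#'   has no significance filter).
#' @export
signed_modularity_partition <- function(C, seed = 1, n_restarts = 100) {
  M <- if (inherits(C, "correlation_matrix")) C$values else as.matrix(C)
  ids <- rownames(M) %||% paste0("unit_", seq_len(nrow(M)))
  W <- M
  diag(W) <- 0
  Wp <- pmax(W, 0)
  Wn <- pmax(-W, 0)
  sp <- rowSums(Wp); vp <- sum(sp)
  sn <- rowSums(Wn); vn <- sum(sn)
  if (vp == 0) stop_funsig("no positive weights: signed modularity undefined", "funsig_input_error")
  B <- (Wp - outer(sp, sp) / vp) / vp
  if (vn > 0) B <- B - (Wn - outer(sn, sn) / vn) / (vp + vn)
  dimnames(B) <- list(ids, ids)
  res <- louvain_dense(B, as.integer(n_restarts), as.integer(seed), 1e-12)
  new_partition(res$labels, modularity = res$q_raw, significant = TRUE,
                unit_ids = ids, seed = seed)
}

#' Write a threshold sweep as CSV
#'
#' @param sweep A `threshold_sweep`.
#' @param path Output path (columns `threshold`, `S`, `M`, `n_communities`).
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  readr::write_csv(dplyr::select(tibble::as_tibble(sweep), -"partition"), path)
  invisible(path)
}
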