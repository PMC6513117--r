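#' Modularity matrix of a filtered correlation matrix
#'
#' The modularity objective for correlation matrices is
#' `Q(sigma) = (1/c_norm) * sum_ij [C_ij - <C_ij>] delta(sigma_i, sigma_j)`,
#' where the null expectation `<C>` comprises the random-bulk and global-mode
#' eigencomponents, so `C - <C>` is exactly the structural (filtered) matrix.
#' `c_norm` is the total sum of the original correlation matrix when
#' positive, otherwise `N`; any positive constant leaves the optimum
#' unchanged, this choice keeps scores comparable across samples.
#'
#' @param filt A `filtered_decomposition` (or a plain symmetric matrix, used
#'   as-is).
#' @param C The original `correlation_matrix`, used only for `c_norm`;
#'   when omitted `c_norm` falls back to `N`.
#' @return A `modularity_matrix` with fields `B`, `c_norm`, `unit_ids`, and
#'   `significant` (FALSE when the structural set was empty so `B = 0`).
#' @export
modularity_matrix <- function(filt, C = NULL) {
  if (inherits(filt, "filtered_decomposition")) {
    B <- filt$C_filtered
    ids <- filt$unit_ids
    significant <- length(filt$classification$structural) > 0
  } else {
    B <- as.matrix(filt)
    ids <- rownames(B) %||% paste0("unit_", seq_len(nrow(B)))
    significant <- any(B != 0)
  }
  c_norm <- if (!is.null(C)) {
    s <- sum(if (inherits(C, "correlation_matrix")) C$values else C)
    if (s > 0) s else nrow(B)
  } else nrow(B)
  structure(list(B = B, c_norm = c_norm, unit_ids = ids,
                 significant = significant),
            class = "modularity_matrix")
}

as_mod_matrix <- function(B, c_norm = NULL) {
  if (inherits(B, "modularity_matrix")) return(B)
  if (inherits(B, "filtered_decomposition")) return(modularity_matrix(B))
  mm <- modularity_matrix(as.matrix(B))
  if (!is.null(c_norm)) mm$c_norm <- c_norm
  mm
}

new_partition <- function(labels, modularity, significant, unit_ids, seed = NA_integer_) {
  labels <- as.integer(labels)
  names(labels) <- unit_ids
  structure(list(labels = labels,
                 n_modules = length(unique(labels)),
                 modularity = modularity,
                 significant = significant,
                 seed = seed),
            class = "funsig_partition")
}

#' @export
print.funsig_partition <- function(x, ...) {
  cat(sprintf("<funsig_partition> %d modules, Q = %.4g%s\n",
              x$n_modules, x$modularity,
              if (!x$significant) " (no significant structure)" else ""))
  invisible(x)
}

#' Tidy a partition into a unit-module table
#'
#' @param x A `funsig_partition`.
#' @param ... Unused.
#' @return A tibble with columns `unit_id`, `module`.
#' @export
tidy.funsig_partition <- function(x, ...) {
  tibble::tibble(unit_id = names(x$labels), module = unname(x$labels))
}

#' One-line summary of a partition
#'
#' @param x A `funsig_partition`.
#' @param ... Unused.
#' @return A one-row tibble with `n_modules`, `modularity`, `significant`.
#' @export
glance.funsig_partition <- function(x, ...) {
  tibble::tibble(n_modules = x$n_modules, modularity = x$modularity,
                 significant = x$significant)
}

#' Modularity score of a partition
#'
#' `(1/c_norm) * sum_{i,j} B_ij [sigma_i == sigma_j]` over all ordered pairs
#' including `i = j` (the diagonal term is constant across partitions and is
#' kept for score reproducibility).
#'
#' @param B A `modularity_matrix` (or plain matrix; then `c_norm` applies).
#' @param partition A `funsig_partition` or an integer label vector.
#' @param c_norm Normalization when `B` is a plain matrix (default `N`).
#' @return The modularity score, a real number.
#' @export
modularity_score <- function(B, partition, c_norm = NULL) {
  mm <- as_mod_matrix(B, c_norm)
  lab <- if (inherits(partition, "funsig_partition")) partition$labels else as.integer(partition)
  stopifnot(length(lab) == nrow(mm$B))
  same <- outer(lab, lab, "==")
  sum(mm$B[same]) / mm$c_norm
}

#' Optimize the correlation-matrix modularity
#'
#' Greedy optimization of the signed modularity on a dense matrix: randomized
#' single-node moves (including isolation into a new module) alternated with
#' exhaustive pairwise module merges, iterated to convergence, over
#' `n_restarts` random restarts (best score wins). Merge-stability of the
#' returned optimum guarantees that every between-module block sum of `B` is
#' non-positive, i.e. modules are overall positively correlated internally
#' and negatively correlated across. The number of modules is not set a
#' priori; it emerges from the optimization.
#'
#' @param B A `modularity_matrix`, `filtered_decomposition`, or plain
#'   symmetric matrix.
#' @param seed Integer seed for the randomized sweep orders.
#' @param n_restarts Number of random restarts, default 100.
#' @param c_norm Normalization when `B` is a plain matrix.
#' @return A `funsig_partition`. When `B` is the zero matrix (empty
#'   structural set) a single-module partition with `significant = FALSE` is
#'   returned.
#' @export
optimize_partition <- function(B, seed = 1, n_restarts = 100, c_norm = NULL) {
  mm <- as_mod_matrix(B, c_norm)
  n <- nrow(mm$B)
  if (!mm$significant || all(mm$B == 0)) {
    return(new_partition(rep(1L, n), modularity = 0, significant = FALSE,
                         unit_ids = mm$unit_ids, seed = seed))
  }
  res <- louvain_dense(mm$B, as.integer(n_restarts), as.integer(seed), 1e-12)
  new_partition(res$labels, modularity = res$q_raw / mm$c_norm,
                significant = TRUE, unit_ids = mm$unit_ids, seed = seed)
}

#' Co-classification frequencies over repeated optimization runs
#'
#' Runs the optimizer `n_runs` times with seeds `base_seed .. base_seed +
#' n_runs - 1` (one restart each, so run-to-run variability is visible) and
#' records for every unit pair the fraction of runs in which the two units
#' share a module — the likelihood matrix of the partition ensemble.
#'
#' @param B As in [optimize_partition()].
#' @param n_runs Number of runs, default 100.
#' @param base_seed First seed.
#' @param n_restarts Restarts per run, default 1.
#' @param c_norm Normalization when `B` is a plain matrix.
#' @return A `coclassification` with fields `F` (`N x N`, entries in [0, 1],
#'   unit diagonal), `n_runs`, `unit_ids`.
#' @export
co_classification <- function(B, n_runs = 100, base_seed = 1, n_restarts = 1,
                              c_norm = NULL) {
  stopifnot(n_runs >= 1)
  mm <- as_mod_matrix(B, c_norm)
  n <- nrow(mm$B)
  acc <- matrix(0, n, n)
  for (r in seq_len(n_runs)) {
    p <- optimize_partition(mm, seed = base_seed + r - 1L, n_restarts = n_restarts)
    acc <- acc + outer(p$labels, p$labels, "==")
  }
  F <- acc / n_runs
  dimnames(F) <- list(mm$unit_ids, mm$unit_ids)
  structure(list(F = F, n_runs = n_runs, unit_ids = mm$unit_ids),
            class = "coclassification")
}

#' @export
print.coclassification <- function(x, ...) {
  cat(sprintf("<coclassification> %d units over %d runs\n", nrow(x$F), x$n_runs))
  invisible(x)
}

#' Consensus partition from a co-classification matrix
#'
#' Optimizes the shifted co-classification matrix `F - tau` as a modularity
#' objective and iterates (re-running the optimizer ensemble on each new
#' consensus matrix) until the co-classification of the consensus runs is
#' binary, i.e. all runs agree.
#'
#' @param F A `coclassification` or a plain frequency matrix.
#' @param tau Shift threshold in (0, 1), default 0.5: pairs co-assigned more
#'   often than `tau` attract, the rest repel.
#' @param n_runs Optimizer runs per consensus iteration, default 20.
#' @param seed Integer seed.
#' @param max_iter Maximum consensus iterations before failing, default 50.
#' @return A `funsig_partition`.
#' @export
consensus_partition <- function(F, tau = 0.5, n_runs = 20, seed = 1,
                                max_iter = 50) {
  mat <- if (inherits(F, "coclassification")) F$F else as.matrix(F)
  ids <- rownames(mat) %||% paste0("unit_", seq_len(nrow(mat)))
  cur <- mat
  for (it in seq_len(max_iter)) {
    D <- cur - tau
    dimnames(D) <- list(ids, ids)
    cc <- co_classification(modularity_matrix(D), n_runs = n_runs,
                            base_seed = fan_seed(seed, it), n_restarts = 1)
    if (all(cc$F %in% c(0, 1))) {
      p <- optimize_partition(modularity_matrix(D), seed = fan_seed(seed, it),
                              n_restarts = 1)
      p$modularity <- NA_real_
      return(p)
    }
    cur <- cc$F
  }
  stop_funsig(sprintf("consensus did not converge in %d iterations (last matrix had %d non-binary entries)",
                      max_iter, sum(!(cur %in% c(0, 1)))),
              "funsig_convergence_error")
}

#' Write a partition as a two-column TSV
#'
#' @param partition A `funsig_partition`.
#' @param path Output path (columns `unit_id`, `module_id`).
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  df <- tidy(partition)
  names(df) <- c("unit_id", "module_id")
  readr::write_tsv(df, path)
  invisible(path)
}
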