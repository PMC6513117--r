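# Signature statistics: within/between residual-correlation distributions,
# contrast ratios, and community signals.

#' Signature statistics of a partition
#'
#' The "residual correlations" are the off-diagonal entries of the filtered
#' matrix (trend- and noise-free dependencies). For each module the report
#' gives the mean residual correlation and the within contrast ratio
#' `delta = N- / N+` (count of negative over positive entries; a pure module
#' has delta = 0); for each module pair, the mean between-residual and the
#' between contrast ratio `delta = N+ / N-`. Zero denominators yield `Inf`
#' with `contrast_defined = FALSE`; singleton modules have no within
#' statistics and are flagged.
#'
#' @param filt A `filtered_decomposition` (or plain matrix of residuals).
#' @param partition A `funsig_partition` or label vector over the same units.
#' @return A `signature_report`: list with tibbles `within` (`module`,
#'   `n_units`, `mean_residual`, `n_pos`, `n_neg`, `contrast_ratio`,
#'   `contrast_defined`, list-column `entries`) and `between` (`module_a`,
#'   `module_b`, same statistics).
#' @export
signature_stats <- function(filt, partition) {
  B <- if (inherits(filt, "filtered_decomposition")) filt$C_filtered else as.matrix(filt)
  lab <- if (inherits(partition, "funsig_partition")) partition$labels else as.integer(partition)
  stopifnot(length(lab) == nrow(B))
  mods <- sort(unique(lab))

  within <- purrr::map_dfr(mods, function(m) {
    idx <- which(lab == m)
    if (length(idx) < 2) {
      return(tibble::tibble(module = m, n_units = length(idx),
                            mean_residual = NA_real_, n_pos = NA_integer_,
                            n_neg = NA_integer_, contrast_ratio = NA_real_,
                            contrast_defined = FALSE, entries = list(numeric(0))))
    }
    sub <- B[idx, idx]
    e <- sub[upper.tri(sub)]
    np <- sum(e > 0); nn <- sum(e < 0)
    tibble::tibble(module = m, n_units = length(idx), mean_residual = mean(e),
                   n_pos = np, n_neg = nn,
                   contrast_ratio = if (np > 0) nn / np else Inf,
                   contrast_defined = np > 0,
                   entries = list(e))
  })

  pairs <- if (length(mods) > 1) utils::combn(mods, 2, simplify = FALSE) else list()
  between <- purrr::map_dfr(pairs, function(pr) {
    e <- as.vector(B[lab == pr[1], lab == pr[2], drop = FALSE])
    np <- sum(e > 0); nn <- sum(e < 0)
    tibble::tibble(module_a = pr[1], module_b = pr[2], mean_residual = mean(e),
                   n_pos = np, n_neg = nn,
                   contrast_ratio = if (nn > 0) np / nn else Inf,
                   contrast_defined = nn > 0,
                   entries = list(e))
  })
  structure(list(within = within, between = between, n_modules = length(mods)),
            class = "signature_report")
}

#' @export
print.signature_report <- function(x, ...) {
  cat(sprintf("<signature_report> %d module(s)\n", x$n_modules))
  print(dplyr::select(x$within, -"entries"))
  if (nrow(x$between)) print(dplyr::select(x$between, -"entries"))
  invisible(x)
}

#' Tidy a signature report
#'
#' @param x A `signature_report`.
#' @param ... Unused.
#' @return A tibble pooling within and between statistics with a `scope`
#'   column (`"within"` / `"between"`), without the raw entry samples.
#' @export
tidy.signature_report <- function(x, ...) {
  w <- dplyr::mutate(dplyr::select(x$within, -"entries"),
                     scope = "within", module_a = .data$module,
                     module_b = .data$module)
  w <- dplyr::select(w, -"module", -"n_units")
  b <- dplyr::mutate(dplyr::select(x$between, -"entries"), scope = "between")
  dplyr::bind_rows(w, b)[, c("scope", "module_a", "module_b", "mean_residual",
                             "n_pos", "n_neg", "contrast_ratio", "contrast_defined")]
}

#' Mean activity signal of each community
#'
#' Arithmetic mean over each module's unit series, plus the whole-system
#' mean (the global signal, labelled module `"global"`).
#'
#' @param rec An `activity_recording`.
#' @param partition A `funsig_partition` or label vector.
#' @return A tibble with columns `module` (character), `time`, `value`.
#' @export
community_signals <- function(rec, partition) {
  lab <- if (inherits(partition, "funsig_partition")) partition$labels else as.integer(partition)
  stopifnot(length(lab) == nrow(rec$values))
  sig <- purrr::map_dfr(sort(unique(lab)), function(m) {
    tibble::tibble(module = as.character(m), time = rec$time_stamps,
                   value = colMeans(rec$values[lab == m, , drop = FALSE]))
  })
  dplyr::bind_rows(sig,
                   tibble::tibble(module = "global", time = rec$time_stamps,
                                  value = colMeans(rec$values)))
}

#' Residual community signals after global-signal subtraction
#'
#' Each unit series is standardized (so bright units do not dominate), the
#' mean standardized series (global signal) is subtracted, and module means
#' are taken. The size-weighted sum of the residual signals is the zero
#' series, so with two equal modules the residuals are exact negatives —
#' the anti-correlation that the global trend obscured.
#'
#' @param rec An `activity_recording`.
#' @param partition A `funsig_partition` or label vector.
#' @return A tibble with columns `module` (integer), `time`, `value`.
#' @export
residual_signals <- function(rec, partition) {
  lab <- if (inherits(partition, "funsig_partition")) partition$labels else as.integer(partition)
  stopifnot(length(lab) == nrow(rec$values))
  Z <- t(scale(t(rec$values)))
  global <- colMeans(Z)
  R <- sweep(Z, 2, global)
  purrr::map_dfr(sort(unique(lab)), function(m) {
    tibble::tibble(module = m, time = rec$time_stamps,
                   value = colMeans(R[lab == m, , drop = FALSE]))
  })
}
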