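#' Detect the functional signature of a recording
#'
#' The full pipeline: Pearson correlation; eigendecomposition; Wishart null
#' bounds — global-mode corrected when a global mode is present (`auto`
#' decides via the sign-uniformity of the leading eigenvector, see
#' [detect_global_mode()]); classification of the spectrum into global /
#' structural / random; reconstruction of the filtered matrix from the
#' structural eigencomponents; modularity optimization on the filtered
#' matrix. Applying the global-mode correction when no shared trend exists
#' would discard a genuine structure direction, which is why `auto` is the
#' default rather than always treating the largest eigenvalue as a trend.
#'
#' @param rec An `activity_recording` or a precomputed `correlation_matrix`.
#' @param null_model `"auto"` (default), `"corrected"` or `"uncorrected"`.
#' @param n_restarts Optimizer restarts, default 100.
#' @param seed Integer seed for the optimizer.
#' @param min_sign_fraction Sign-uniformity threshold for `auto`.
#' @return A `funsig_result` bundling `correlation`, `eigen`, `bounds`,
#'   `classification`, `filtered`, `modularity` (the objective matrix) and
#'   `partition`. When the structural set is empty the partition is a single
#'   module flagged `significant = FALSE`.
#' @export
detect_signature <- function(rec, null_model = c("auto", "corrected", "uncorrected"),
                             n_restarts = 100, seed = 1, min_sign_fraction = 0.9) {
  null_model <- match.arg(null_model)
  C <- if (inherits(rec, "correlation_matrix")) rec else pearson_correlation(rec)
  eig <- spectral_decompose(C)
  global <- switch(null_model,
                   auto = detect_global_mode(eig, min_sign_fraction),
                   corrected = TRUE,
                   uncorrected = FALSE)
  bounds <- if (global) {
    corrected_bounds(C$n_units, C$n_timepoints, eig$values[1])
  } else {
    wishart_bounds(C$n_units, C$n_timepoints)
  }
  cls <- classify_eigenvalues(eig, bounds)
  filt <- filter_matrix(eig, cls)
  mm <- modularity_matrix(filt, C)
  part <- optimize_partition(mm, seed = seed, n_restarts = n_restarts)
  structure(list(correlation = C, eigen = eig, bounds = bounds,
                 classification = cls, filtered = filt, modularity = mm,
                 partition = part, global_mode = global,
                 null_model = null_model, seed = seed),
            class = "funsig_result")
}

#' @export
print.funsig_result <- function(x, ...) {
  cat(sprintf("<funsig_result> N = %d, T = %d | %s null | %d structural eigenvalue(s) | %d module(s)%s\n",
              x$correlation$n_units, x$correlation$n_timepoints,
              if (x$bounds$corrected) "corrected" else "uncorrected",
              length(x$classification$structural),
              x$partition$n_modules,
              if (!x$partition$significant) " (no significant structure)" else ""))
  invisible(x)
}

#' Tidy a signature result into a unit table
#'
#' @param x A `funsig_result`.
#' @param ... Unused.
#' @return A tibble with `unit_id`, `module`.
#' @export
tidy.funsig_result <- function(x, ...) tidy(x$partition)

#' One-row summary of a signature result
#'
#' @param x A `funsig_result`.
#' @param ... Unused.
#' @return A tibble with dimensions, null-model bounds, structural count,
#'   module count, modularity and significance.
#' @export
glance.funsig_result <- function(x, ...) {
  tibble::tibble(n_units = x$correlation$n_units,
                 n_timepoints = x$correlation$n_timepoints,
                 q_ratio = x$bounds$Q,
                 global_mode = x$global_mode,
                 lambda_max = x$eigen$values[1],
                 lambda_plus = x$bounds$lambda_plus,
                 n_structural = length(x$classification$structural),
                 n_modules = x$partition$n_modules,
                 modularity = x$partition$modularity,
                 significant = x$partition$significant)
}
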