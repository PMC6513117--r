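#' Eigendecomposition of a correlation matrix
#'
#' Full symmetric eigendecomposition with eigenvalues in descending order and
#' a deterministic eigenvector sign convention (the largest-magnitude
#' component of each eigenvector is positive), so repeated runs and
#' serialized outputs are bit-stable.
#'
#' @param C A `correlation_matrix` or a symmetric numeric matrix.
#' @param tol Symmetry tolerance.
#' @return An object of class `spectral_decomposition` with fields `values`
#'   (descending eigenvalues), `vectors` (orthonormal columns), `n_units`,
#'   `n_timepoints`, `unit_ids`.
#' @export
spectral_decompose <- function(C, tol = 1e-10) {
  if (inherits(C, "correlation_matrix")) {
    M <- C$values; n_t <- C$n_timepoints; ids <- C$unit_ids
  } else {
    M <- as.matrix(C); n_t <- NA_integer_
    ids <- rownames(M) %||% paste0("unit_", seq_len(nrow(M)))
  }
  if (max(abs(M - t(M))) > tol) {
    stop_funsig("matrix is not symmetric within tolerance", "funsig_input_error")
  }
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  V <- e$vectors
  for (k in seq_len(ncol(V))) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  structure(list(values = e$values, vectors = V,
                 n_units = nrow(M), n_timepoints = n_t, unit_ids = ids),
            class = "spectral_decomposition")
}

#' @export
print.spectral_decomposition <- function(x, ...) {
  cat(sprintf("<spectral_decomposition> N = %d, lambda_max = %.4g\n",
              x$n_units, x$values[1]))
  invisible(x)
}

new_bounds <- function(lambda_minus, lambda_plus, lambda_max, Q, N, T, corrected) {
  structure(list(lambda_minus = max(lambda_minus, 0), lambda_plus = lambda_plus,
                 lambda_max = lambda_max, Q = Q, N = as.integer(N),
                 T = as.integer(T), corrected = corrected),
            class = "rmt_bounds")
}

#' Marchenko-Pastur bounds of the Wishart null
#'
#' Edges of the random bulk of the correlation spectrum of `N` independent
#' noise series of length `T`: `lambda_pm = (1 +/- 1/sqrt(Q))^2` with
#' `Q = T/N`. For `T <= N` the lower edge is floored at 0 (rank deficiency)
#' with a warning.
#'
#' @param N,T Number of units and of time points.
#' @return An `rmt_bounds` object with `corrected = FALSE`.
#' @export
wishart_bounds <- function(N, T) {
  if (N <= 0 || T <= 0) stop_funsig("N and T must be positive", "funsig_input_error")
  Q <- T / N
  if (Q <= 1) {
    warning(sprintf("Q = T/N = %.3g <= 1: spectrum is rank-deficient, lower edge floored at 0", Q),
            call. = FALSE)
  }
  new_bounds((1 - 1 / sqrt(Q))^2, (1 + 1 / sqrt(Q))^2,
             lambda_max = 0, Q = Q, N = N, T = T, corrected = FALSE)
}

#' Global-mode-corrected Wishart bounds
#'
#' When a global trend occupies the largest eigenvalue `lambda_max`, only the
#' remaining variance feeds the random bulk, which is therefore left-shifted:
#' `lambda_pm = (1 - lambda_max/N) * (1 +/- 1/sqrt(Q))^2`. The higher the
#' global mode, the lower the upper edge, so structure hiding below the
#' uncorrected edge can be unveiled.
#'
#' @param N,T Number of units and of time points.
#' @param lambda_max Largest empirical eigenvalue, in `[0, N)`.
#' @return An `rmt_bounds` object with `corrected = TRUE`.
#' @export
corrected_bounds <- function(N, T, lambda_max) {
  if (N <= 0 || T <= 0) stop_funsig("N and T must be positive", "funsig_input_error")
  if (lambda_max < 0 || lambda_max >= N) {
    stop_funsig("lambda_max must lie in [0, N): the global mode cannot exceed the total variance",
                "funsig_input_error")
  }
  Q <- T / N
  if (Q <= 1) {
    warning(sprintf("Q = T/N = %.3g <= 1: spectrum is rank-deficient, lower edge floored at 0", Q),
            call. = FALSE)
  }
  m <- 1 - lambda_max / N
  new_bounds(m * (1 - 1 / sqrt(Q))^2, m * (1 + 1 / sqrt(Q))^2,
             lambda_max = lambda_max, Q = Q, N = N, T = T, corrected = TRUE)
}

#' @export
print.rmt_bounds <- function(x, ...) {
  cat(sprintf("<rmt_bounds%s> lambda- = %.4g, lambda+ = %.4g (Q = %.3g%s)\n",
              if (x$corrected) ", global-mode corrected" else "",
              x$lambda_minus, x$lambda_plus, x$Q,
              if (x$corrected) sprintf(", lambda_max = %.4g", x$lambda_max) else ""))
  invisible(x)
}

#' Null eigenvalue density of the (corrected) Wishart model
#'
#' Density of the random bulk:
#' `rho(l) = Q * sqrt((lambda+ - l)(l - lambda-)) / (2 * pi * l * m)` on
#' `[lambda-, lambda+]` with `m = 1 - lambda_max/N` (1 when uncorrected), and
#' 0 outside. The correction is a pure dilation of the Marchenko-Pastur bulk,
#' so the bulk integrates to 1; the global mode itself is a separate point
#' mass of weight `1/N` at `lambda_max`, not included here.
#'
#' @param bounds An `rmt_bounds` object.
#' @param lambda Numeric vector of evaluation points.
#' @return Density values, same length as `lambda`.
#' @export
null_density <- function(bounds, lambda) {
  stopifnot(inherits(bounds, "rmt_bounds"))
  m <- if (bounds$corrected) 1 - bounds$lambda_max / bounds$N else 1
  lm <- bounds$lambda_minus; lp <- bounds$lambda_plus
  out <- numeric(length(lambda))
  ok <- lambda > max(lm, 0) & lambda < lp
  out[ok] <- bounds$Q * sqrt((lp - lambda[ok]) * (lambda[ok] - lm)) /
    (2 * pi * lambda[ok] * m)
  out
}

#' Is a global mode present in the spectrum?
#'
#' A shared trend loads every unit with the same sign, so its eigenvector is
#' sign-uniform (a Perron-like direction); genuine phase-contrast structure
#' produces mixed signs. The leading eigenvector is called a global mode when
#' at least `min_sign_fraction` of its components share one sign.
#'
#' @param eig A `spectral_decomposition`.
#' @param min_sign_fraction Majority-sign fraction above which the leading
#'   eigenvector counts as a global mode (default 0.9).
#' @return Logical scalar.
#' @export
detect_global_mode <- function(eig, min_sign_fraction = 0.9) {
  stopifnot(inherits(eig, "spectral_decomposition"))
  v <- eig$vectors[, 1]
  max(mean(v > 0), mean(v < 0)) >= min_sign_fraction
}

#' Classify eigenvalues against the null bounds
#'
#' Under the corrected null (a global mode is present) the largest eigenvalue
#' is the global mode and the structural set is the open range
#' `(lambda+, lambda_max)`; under the uncorrected null nothing is assigned to
#' a global mode and every eigenvalue above `lambda+` is structural. The
#' rest is the random bulk. Eigenvalues exactly at the edge (within `tol`)
#' are classified random.
#'
#' @param eig A `spectral_decomposition`.
#' @param bounds An `rmt_bounds` from the same `(N, T)`; when
#'   `bounds$corrected`, `bounds$lambda_max` must equal the largest
#'   eigenvalue of `eig`.
#' @param tol Edge tolerance, default 1e-12.
#' @return An `eigen_classification` with integer index fields `global`,
#'   `structural`, `random` partitioning `1..N`.
#' @export
classify_eigenvalues <- function(eig, bounds, tol = 1e-12) {
  stopifnot(inherits(eig, "spectral_decomposition"), inherits(bounds, "rmt_bounds"))
  lam <- eig$values
  if (bounds$corrected) {
    if (abs(bounds$lambda_max - lam[1]) > 1e-6 * max(1, abs(lam[1]))) {
      stop_funsig("bounds$lambda_max does not match the spectrum's largest eigenvalue",
                  "funsig_input_error")
    }
    global <- 1L
    structural <- which(lam > bounds$lambda_plus + tol & lam < lam[1] - tol)
    structural <- setdiff(structural, global)
  } else {
    global <- integer(0)
    structural <- which(lam > bounds$lambda_plus + tol)
  }
  rnd <- setdiff(seq_along(lam), c(global, structural))
  structure(list(global = as.integer(global),
                 structural = as.integer(structural),
                 random = as.integer(rnd),
                 n = length(lam)),
            class = "eigen_classification")
}

#' @export
print.eigen_classification <- function(x, ...) {
  cat(sprintf("<eigen_classification> %d global, %d structural, %d random\n",
              length(x$global), length(x$structural), length(x$random)))
  invisible(x)
}

#' Split a correlation matrix into structural, global and random components
#'
#' Reconstructs each eigencomponent over its index set:
#' `C_filtered = sum over structural of lambda_i v_i v_i'`, and analogously
#' `C_global` and `C_random`; the three add back to the original matrix.
#' `C_filtered` is the trend- and noise-filtered matrix that carries the
#' statistically significant modular information.
#'
#' @param eig A `spectral_decomposition`.
#' @param cls An `eigen_classification` for the same spectrum.
#' @return A `filtered_decomposition` with matrices `C_filtered`, `C_global`,
#'   `C_random`, the `classification`, and `unit_ids`.
#' @export
filter_matrix <- function(eig, cls) {
  stopifnot(inherits(eig, "spectral_decomposition"),
            inherits(cls, "eigen_classification"),
            cls$n == eig$n_units)
  comp <- function(idx) {
    if (length(idx) == 0) {
      matrix(0, eig$n_units, eig$n_units,
             dimnames = list(eig$unit_ids, eig$unit_ids))
    } else {
      V <- eig$vectors[, idx, drop = FALSE]
      M <- V %*% (eig$values[idx] * t(V))
      dimnames(M) <- list(eig$unit_ids, eig$unit_ids)
      (M + t(M)) / 2
    }
  }
  structure(list(C_filtered = comp(cls$structural),
                 C_global = comp(cls$global),
                 C_random = comp(cls$random),
                 classification = cls,
                 eigenvalues = eig$values,
                 n_units = eig$n_units,
                 n_timepoints = eig$n_timepoints,
                 unit_ids = eig$unit_ids),
            class = "filtered_decomposition")
}

#' @export
print.filtered_decomposition <- function(x, ...) {
  cat(sprintf("<filtered_decomposition> N = %d, structural rank = %d\n",
              x$n_units, length(x$classification$structural)))
  invisible(x)
}

#' Tidy a spectral decomposition into an eigenvalue table
#'
#' @param x A `spectral_decomposition`.
#' @param bounds Optional `rmt_bounds`; when given, a `component` column
#'   (global/structural/random) is added from [classify_eigenvalues()].
#' @param ... Unused.
#' @return A tibble with columns `index`, `eigenvalue` (and `component`).
#' @export
tidy.spectral_decomposition <- function(x, bounds = NULL, ...) {
  out <- tibble::tibble(index = seq_along(x$values), eigenvalue = x$values)
  if (!is.null(bounds)) {
    cls <- classify_eigenvalues(x, bounds)
    comp <- rep("random", cls$n)
    comp[cls$structural] <- "structural"
    comp[cls$global] <- "global"
    out$component <- comp
  }
  out
}

#' Serialize a filtered decomposition to a directory
#'
#' Writes `eigenvalues.csv`, `classification.json` and
#' `filtered_matrix.csv` (unit ids as header).
#'
#' @param filt A `filtered_decomposition`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_filtered <- function(filt, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tibble::tibble(index = seq_along(filt$eigenvalues),
                                  eigenvalue = filt$eigenvalues),
                   file.path(dir, "eigenvalues.csv"))
  jsonlite::write_json(filt$classification[c("global", "structural", "random")],
                       file.path(dir, "classification.json"), digits = NA)
  df <- tibble::as_tibble(filt$C_filtered, .name_repair = "minimal")
  names(df) <- filt$unit_ids
  df <- dplyr::bind_cols(tibble::tibble(unit_id = filt$unit_ids), df)
  readr::write_csv(df, file.path(dir, "filtered_matrix.csv"))
  invisible(dir)
}
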