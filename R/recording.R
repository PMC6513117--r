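#' Construct an activity recording
#'
#' Container for a multivariate activity recording: `N` unit time series of
#' common length `T`, e.g. hourly single-cell bioluminescence traces.
#' Units with any missing value are dropped with a warning so that the
#' Wishart null model's `(N, T)` stays well defined.
#'
#' @param values Numeric `N x T` matrix, rows = units, columns = time points.
#' @param unit_ids Character vector of `N` unit identifiers. Defaults to row
#'   names or `unit_1 ... unit_N`.
#' @param time_stamps Strictly increasing numeric vector of `T` time stamps
#'   (hours). Defaults to `0, dt, 2*dt, ...`.
#' @param sampling_interval Sampling interval in hours; inferred from
#'   `time_stamps` when omitted.
#' @param coords Optional data frame with columns `unit_id`, `x`, `y` giving
#'   image-plane unit positions, used only for back-mapping modules.
#' @return An object of class `activity_recording`.
#' @export
activity_recording <- function(values, unit_ids = NULL, time_stamps = NULL,
                               sampling_interval = NULL, coords = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(unit_ids)) {
    unit_ids <- rownames(values) %||% paste0("unit_", seq_len(nrow(values)))
  }
  stopifnot(length(unit_ids) == nrow(values))

  bad <- !apply(values, 1, function(r) all(is.finite(r)))
  if (any(bad)) {
    warning(sprintf("dropping %d unit(s) with missing values: %s",
                    sum(bad), paste(utils::head(unit_ids[bad], 5), collapse = ", ")),
            call. = FALSE)
    values <- values[!bad, , drop = FALSE]
    unit_ids <- unit_ids[!bad]
  }
  if (nrow(values) < 2) stop_funsig("a recording needs at least 2 units", "funsig_input_error")
  if (ncol(values) < 3) stop_funsig("a recording needs at least 3 time points", "funsig_input_error")

  if (is.null(time_stamps)) {
    dt <- sampling_interval %||% 1
    time_stamps <- (seq_len(ncol(values)) - 1) * dt
  }
  stopifnot(length(time_stamps) == ncol(values))
  if (any(diff(time_stamps) <= 0)) {
    stop_funsig("time stamps must be strictly increasing", "funsig_input_error")
  }
  sampling_interval <- sampling_interval %||% stats::median(diff(time_stamps))

  rownames(values) <- unit_ids
  structure(list(values = values,
                 unit_ids = as.character(unit_ids),
                 time_stamps = as.numeric(time_stamps),
                 sampling_interval = sampling_interval,
                 coords = coords),
            class = "activity_recording")
}

#' @export
print.activity_recording <- function(x, ...) {
  cat(sprintf("<activity_recording> %d units x %d time points (dt = %g h)\n",
              nrow(x$values), ncol(x$values), x$sampling_interval))
  invisible(x)
}

#' @export
dim.activity_recording <- function(x) dim(x$values)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an activity recording into long format
#'
#' @param x An `activity_recording`.
#' @param ... Unused.
#' @return A tibble with columns `unit_id`, `time`, `value`.
#' @export
tidy.activity_recording <- function(x, ...) {
  tibble::tibble(unit_id = rep(x$unit_ids, times = ncol(x$values)),
                 time = rep(x$time_stamps, each = nrow(x$values)),
                 value = as.vector(x$values))
}

#' Load an activity recording from a delimited text file
#'
#' Expected layout: rows = units, first column = unit id, remaining columns =
#' time points, header row = time stamps (in hours). With `transpose = TRUE`
#' the file holds rows = time points (first column = time stamps, header =
#' unit ids) and is transposed on load.
#'
#' @param path File path.
#' @param delim Field delimiter, default `","`.
#' @param transpose Is the file stored time-by-unit instead of unit-by-time?
#' @param sampling_interval Override for the sampling interval (hours).
#' @param coords_path Optional path to a sidecar CSV with columns
#'   `unit_id,x,y`.
#' @return An [activity_recording()].
#' @export
load_recording <- function(path, delim = ",", transpose = FALSE,
                           sampling_interval = NULL, coords_path = NULL) {
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  if (ncol(df) < 2) stop_funsig("file must have an id column plus data columns", "funsig_parse_error")
  ids <- df[[1]]
  num <- suppressWarnings(
    vapply(df[-1], function(col) as.numeric(col), numeric(nrow(df)))
  )
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(df))
  raw_chr <- as.matrix(df[-1])
  bad <- is.na(num) & !is.na(raw_chr) & raw_chr != "NaN" & toupper(raw_chr) != "NA"
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop_funsig(sprintf("non-numeric cell at row %d, column %d ('%s')",
                        idx[1], idx[2] + 1L, raw_chr[bad][1]),
                "funsig_parse_error")
  }
  header <- suppressWarnings(as.numeric(names(df)[-1]))

  if (transpose) {
    values <- t(num)
    unit_ids <- names(df)[-1]
    time_stamps <- suppressWarnings(as.numeric(ids))
    if (anyNA(time_stamps)) time_stamps <- NULL
  } else {
    values <- num
    unit_ids <- ids
    time_stamps <- if (anyNA(header)) NULL else header
  }

  coords <- NULL
  if (!is.null(coords_path)) {
    coords <- readr::read_csv(coords_path, show_col_types = FALSE)
    stopifnot(all(c("unit_id", "x", "y") %in% names(coords)))
  }
  activity_recording(values, unit_ids = unit_ids, time_stamps = time_stamps,
                     sampling_interval = sampling_interval, coords = coords)
}

#' Write a recording to a delimited text file
#'
#' Inverse of [load_recording()] (unit-by-time layout).
#'
#' @param rec An `activity_recording`.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, delim = ",") {
  df <- tibble::as_tibble(rec$values, .name_repair = "minimal")
  names(df) <- as.character(rec$time_stamps)
  df <- dplyr::bind_cols(tibble::tibble(unit_id = rec$unit_ids), df)
  readr::write_delim(df, path, delim = delim)
  invisible(path)
}

#' Keep units with sustained circadian rhythmicity
#'
#' A unit passes when it shows at least `min_cycles` peaks whose mean
#' inter-peak interval lies in `period_range` (hours). Peaks are local maxima,
#' optionally after moving-average smoothing (off by default; raw and
#' smoothed traces give equivalent downstream results on rhythmic data).
#'
#' @param rec An `activity_recording` with time stamps in hours.
#' @param min_cycles Minimum number of detected peaks, default 3.
#' @param period_range Admissible mean peak interval (hours), default
#'   `c(20, 28)` — the circadian range.
#' @param smooth_window Moving-average window in samples (0 = no smoothing).
#' @return The filtered recording; the per-unit report is attached as
#'   attribute `"qc"` and retrievable with [qc_report()].
#' @export
circadian_qc <- function(rec, min_cycles = 3, period_range = c(20, 28),
                         smooth_window = 0) {
  stopifnot(inherits(rec, "activity_recording"))
  report <- purrr::map_dfr(seq_along(rec$unit_ids), function(i) {
    y <- rec$values[i, ]
    if (smooth_window > 1) {
      y <- stats::filter(y, rep(1 / smooth_window, smooth_window), sides = 2)
      keep <- !is.na(y)
      y <- y[keep]; tt <- rec$time_stamps[keep]
    } else tt <- rec$time_stamps
    pk <- if (stats::sd(y) == 0) NULL else pracma::findpeaks(as.numeric(y))
    n_peaks <- if (is.null(pk)) 0L else nrow(pk)
    mean_int <- if (n_peaks >= 2) mean(diff(tt[pk[, 2]])) else NA_real_
    tibble::tibble(unit_id = rec$unit_ids[i], n_peaks = n_peaks,
                   mean_interval = mean_int,
                   pass = n_peaks >= min_cycles && !is.na(mean_int) &&
                          mean_int >= period_range[1] && mean_int <= period_range[2])
  })
  if (!any(report$pass)) {
    stop_funsig("no rhythmic units: every unit failed circadian QC", "funsig_qc_error")
  }
  if (sum(report$pass) < 2) {
    stop_funsig("fewer than 2 rhythmic units after circadian QC", "funsig_qc_error")
  }
  keep <- report$pass
  out <- activity_recording(rec$values[keep, , drop = FALSE],
                            unit_ids = rec$unit_ids[keep],
                            time_stamps = rec$time_stamps,
                            sampling_interval = rec$sampling_interval,
                            coords = rec$coords)
  attr(out, "qc") <- report
  out
}

#' Retrieve the per-unit QC report of a filtered recording
#'
#' @param rec A recording returned by [circadian_qc()].
#' @return A tibble with columns `unit_id`, `n_peaks`, `mean_interval`,
#'   `pass`, or `NULL` when no QC was run.
#' @export
qc_report <- function(rec) attr(rec, "qc")

#' Pearson correlation matrix of a recording
#'
#' Standard product-moment correlations between all unit pairs. The matrix,
#' not the raw series, is the method's sufficient statistic: any common
#' permutation of time points across all units leaves it unchanged, which is
#' why arbitrary temporal modulation of a shared trend can be handled at the
#' spectral level.
#'
#' @param rec An `activity_recording` or a numeric unit-by-time matrix.
#' @return An object of class `correlation_matrix` with fields `values`
#'   (`N x N`), `n_units`, `n_timepoints`, `unit_ids`.
#' @export
pearson_correlation <- function(rec) {
  if (inherits(rec, "activity_recording")) {
    values <- rec$values
    ids <- rec$unit_ids
  } else {
    values <- as.matrix(rec)
    ids <- rownames(values) %||% paste0("unit_", seq_len(nrow(values)))
  }
  sds <- apply(values, 1, stats::sd)
  if (any(sds == 0)) {
    stop_funsig(sprintf("zero-variance unit(s): %s (apply QC first)",
                        paste(utils::head(ids[sds == 0], 5), collapse = ", ")),
                "funsig_input_error")
  }
  C <- stats::cor(t(values))
  C <- (C + t(C)) / 2
  diag(C) <- 1
  dimnames(C) <- list(ids, ids)
  structure(list(values = C, n_units = nrow(C), n_timepoints = ncol(values),
                 unit_ids = ids),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d units, T = %d\n", x$n_units, x$n_timepoints))
  invisible(x)
}

#' Write a correlation matrix as CSV with a unit id header
#'
#' @param C A `correlation_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_correlation <- function(C, path) {
  df <- tibble::as_tibble(C$values, .name_repair = "minimal")
  names(df) <- C$unit_ids
  df <- dplyr::bind_cols(tibble::tibble(unit_id = C$unit_ids), df)
  readr::write_csv(df, path)
  invisible(path)
}
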