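#' Recursive (hierarchical) module detection
#'
#' Runs the full pipeline, then recurses into each detected module by
#' restricting the ORIGINAL time series to the module's units, recomputing
#' the correlation matrix, re-deriving null bounds from the submatrix's own
#' `(N', T)` and largest eigenvalue, and re-optimizing. Recursion stops when
#' a module's structural set is empty, the module is smaller than
#' `min_module_size`, or `max_depth` is reached. Within a module the shared
#' oscillation acts as that submatrix's global mode, so sub-structure is
#' resolved relative to it.
#'
#' @param rec An `activity_recording`.
#' @param max_depth Maximum recursion depth (1 = flat pipeline).
#' @param min_module_size Do not split modules smaller than this (default 10;
#'   small modules make further partitions unreliable).
#' @param seed Integer seed.
#' @param n_restarts Optimizer restarts per node.
#' @param null_model Null-model variant passed to [detect_signature()].
#' @return A `funsig_hierarchy` node: list with `partition`, `result`,
#'   `depth`, `unit_ids` and `children` (list of child nodes, possibly
#'   empty), where children partition the parent module's units.
#' @export
detect_hierarchy <- function(rec, max_depth = 2, min_module_size = 10,
                             seed = 1, n_restarts = 100, null_model = "auto") {
  stopifnot(max_depth >= 1)
  build <- function(r, depth, stage) {
    res <- detect_signature(r, null_model = null_model, n_restarts = n_restarts,
                            seed = fan_seed(seed, stage))
    node <- structure(list(partition = res$partition, result = res,
                           depth = depth, unit_ids = r$unit_ids,
                           children = list()),
                      class = "funsig_hierarchy")
    if (depth >= max_depth || !res$partition$significant) return(node)
    labs <- res$partition$labels
    for (m in sort(unique(labs))) {
      idx <- which(labs == m)
      if (length(idx) < min_module_size) next
      sub <- activity_recording(r$values[idx, , drop = FALSE],
                                unit_ids = r$unit_ids[idx],
                                time_stamps = r$time_stamps,
                                sampling_interval = r$sampling_interval)
      child <- build(sub, depth + 1, stage * 31 + m)
      if (child$partition$significant && child$partition$n_modules > 1) {
        node$children[[length(node$children) + 1]] <- child
      }
    }
    node
  }
  build(rec, 1L, 1L)
}

#' @export
print.funsig_hierarchy <- function(x, ...) {
  cat(sprintf("<funsig_hierarchy> depth %d: %d module(s)%s, %d child node(s)\n",
              x$depth, x$partition$n_modules,
              if (!x$partition$significant) " (not significant)" else "",
              length(x$children)))
  invisible(x)
}

#' Tidy a hierarchy into a unit table with one column per depth
#'
#' @param x A `funsig_hierarchy`.
#' @param ... Unused.
#' @return A tibble with `unit_id` and columns `level_1 .. level_d`; deeper
#'   labels are nested within shallower ones (NA where recursion stopped).
#' @export
tidy.funsig_hierarchy <- function(x, ...) {
  out <- tibble::tibble(unit_id = x$unit_ids,
                        level_1 = unname(x$partition$labels))
  walk <- function(node, prefix) {
    for (child in node$children) {
      lvl <- paste0("level_", child$depth)
      if (!lvl %in% names(out)) out[[lvl]] <<- NA_integer_
      ids <- child$unit_ids
      # child labels offset so they stay unique across sibling modules
      base <- max(out[[lvl]], 0L, na.rm = TRUE)
      out[[lvl]][match(ids, out$unit_id)] <<- base + unname(child$partition$labels)
      walk(child, prefix + 1)
    }
  }
  walk(x, 0)
  out
}

#' Serialize a hierarchy as nested JSON
#'
#' @param x A `funsig_hierarchy`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(x, path) {
  strip <- function(node) {
    list(depth = node$depth,
         n_modules = node$partition$n_modules,
         significant = node$partition$significant,
         modularity = node$partition$modularity,
         labels = as.list(stats::setNames(unname(node$partition$labels),
                                          names(node$partition$labels))),
         children = lapply(node$children, strip))
  }
  jsonlite::write_json(strip(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
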