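# Reproducible end-to-end runs with artifacts and a replayable manifest.
# A single run seed fans out deterministically to per-stage seeds (see
# fan_seed()), so partial re-runs reuse identical stage seeds.

write_manifest <- function(dir, manifest) {
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Generate and write a synthetic benchmark fixture
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory: writes `recording.csv`,
#'   `ground_truth.tsv`, `config.json`.
#' @param nested Optional sub-group phase separation; when given,
#'   [generate_nested_groups()] is used.
#' @return The generated list (recording + truth), invisibly.
#' @export
run_synth <- function(config, out_dir, nested = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- if (is.null(nested)) generate_grouped_oscillators(config)
         else generate_nested_groups(config, nested)
  write_recording(gen$recording, file.path(out_dir, "recording.csv"))
  write_ground_truth(gen$truth, out_dir)
  invisible(gen)
}

#' Run the detection pipeline and write all artifacts
#'
#' Writes `correlation.csv`, the filtered decomposition
#' (`eigenvalues.csv`, `classification.json`, `filtered_matrix.csv`),
#' `bounds.json`, `partition.tsv`, `signature.csv` and a replayable
#' `manifest.json`. Outputs contain no timestamps, so identical config and
#' seed give byte-identical files.
#'
#' @param input An `activity_recording`, `correlation_matrix`, or a path to
#'   a delimited recording readable by [load_recording()].
#' @param out_dir Output directory.
#' @param qc Apply [circadian_qc()] first?
#' @param null_model,n_restarts,seed Passed to [detect_signature()].
#' @param ... Further arguments for [load_recording()] or [circadian_qc()].
#' @return The `funsig_result`, invisibly.
#' @export
run_detect <- function(input, out_dir, qc = FALSE,
                       null_model = "auto", n_restarts = 100, seed = 1, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rec <- if (is.character(input)) load_recording(input, ...) else input
  if (qc && inherits(rec, "activity_recording")) rec <- circadian_qc(rec)
  res <- detect_signature(rec, null_model = null_model,
                          n_restarts = n_restarts, seed = fan_seed(seed, 1))
  write_correlation(res$correlation, file.path(out_dir, "correlation.csv"))
  write_filtered(res$filtered, out_dir)
  jsonlite::write_json(res$bounds[c("lambda_minus", "lambda_plus", "lambda_max",
                                    "Q", "N", "T", "corrected")],
                       file.path(out_dir, "bounds.json"),
                       auto_unbox = TRUE, digits = NA)
  write_partition(res$partition, file.path(out_dir, "partition.tsv"))
  if (res$partition$significant) {
    readr::write_csv(tidy(signature_stats(res$filtered, res$partition)),
                     file.path(out_dir, "signature.csv"))
  }
  write_manifest(out_dir, c(
    list(command = "detect", input = if (is.character(input)) input else "in-memory",
         qc = qc, null_model = null_model, n_restarts = n_restarts,
         seed = seed, stage_seed = fan_seed(seed, 1),
         package_version = as.character(utils::packageVersion("funsig"))),
    as.list(glance(res))))
  invisible(res)
}

#' Run a baseline method and write its artifacts
#'
#' `method = "threshold"` writes the S/M sweep (`sweep.csv`);
#' `method = "signed"` writes the signed-modularity partition
#' (`partition.tsv`). When ground-truth labels are supplied the manifest
#' records the adjusted Rand index against them.
#'
#' @param input As in [run_detect()].
#' @param method `"threshold"` or `"signed"`.
#' @param out_dir Output directory.
#' @param truth Optional `ground_truth` or label vector for ARI reporting.
#' @param thresholds Thresholds for the sweep.
#' @param n_restarts,seed Optimizer settings for the signed baseline.
#' @param ... Further arguments for [load_recording()].
#' @return The sweep tibble or partition, invisibly.
#' @export
run_baseline <- function(input, method = c("threshold", "signed"), out_dir,
                         truth = NULL, thresholds = seq(0, 1, by = 0.025),
                         n_restarts = 100, seed = 1, ...) {
  method <- match.arg(method)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rec <- if (is.character(input)) load_recording(input, ...) else input
  C <- if (inherits(rec, "correlation_matrix")) rec else pearson_correlation(rec)
  truth_labels <- if (inherits(truth, "ground_truth")) truth$labels else truth
  manifest <- list(command = "baseline", method = method, seed = seed,
                   package_version = as.character(utils::packageVersion("funsig")))
  if (method == "threshold") {
    out <- threshold_sweep(C, thresholds = thresholds, seed = fan_seed(seed, 1))
    write_sweep(out, file.path(out_dir, "sweep.csv"))
  } else {
    out <- signed_modularity_partition(C, seed = fan_seed(seed, 1),
                                       n_restarts = n_restarts)
    write_partition(out, file.path(out_dir, "partition.tsv"))
    manifest$n_modules <- out$n_modules
    if (!is.null(truth_labels)) {
      manifest$ari <- adjusted_rand_index(out$labels, truth_labels)
    }
  }
  write_manifest(out_dir, manifest)
  invisible(out)
}

#' Run hierarchical detection and write the nested partition
#'
#' @param input As in [run_detect()].
#' @param out_dir Output directory: `hierarchy.json`, `levels.tsv`,
#'   `manifest.json`.
#' @param max_depth,min_module_size,seed,n_restarts Passed to
#'   [detect_hierarchy()].
#' @param ... Further arguments for [load_recording()].
#' @return The `funsig_hierarchy`, invisibly.
#' @export
run_hierarchy <- function(input, out_dir, max_depth = 2, min_module_size = 10,
                          seed = 1, n_restarts = 100, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rec <- if (is.character(input)) load_recording(input, ...) else input
  h <- detect_hierarchy(rec, max_depth = max_depth,
                        min_module_size = min_module_size,
                        seed = seed, n_restarts = n_restarts)
  write_hierarchy(h, file.path(out_dir, "hierarchy.json"))
  readr::write_tsv(tidy(h), file.path(out_dir, "levels.tsv"))
  write_manifest(out_dir, list(command = "hierarchy", max_depth = max_depth,
                               min_module_size = min_module_size, seed = seed,
                               package_version = as.character(utils::packageVersion("funsig"))))
  invisible(h)
}
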