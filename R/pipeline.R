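#' Run the full profiling pipeline over several LC-MS runs
#'
#' Executes, per run: peak picking, deisotoping, feature detection with
#' noise-list capture; then retention-time alignment of every run onto the
#' first (the reference), aggregation into the peptide profile matrix with
#' redundancy collapse and noise rescue, and (optionally) two-group
#' statistics. When `out_dir` is given, the profile matrix (Table-1 layout),
#' the presence histogram, per-run feature/noise lists, and any statistics
#' are written there as tab-separated text.
#'
#' @param runs List of `ms_run` objects, or character paths to mzML/mzXML
#'   files (read at MS level 1). The first run is the alignment reference.
#' @param ppm Mass window in ppm (deisotoping, linking, matrix matching).
#' @param time_window_s Retention-time window in seconds for the matrix.
#' @param min_scans Consecutive-scan requirement for features.
#' @param charges Charge states considered.
#' @param min_snr,min_score Peak-picking and envelope thresholds.
#' @param align Whether to fit and apply the drift model (skipped with fewer
#'   than 2 runs or, with a warning, when anchors are insufficient).
#' @param groups Optional list `list(a = idx, b = idx)` of run indices for
#'   two-group statistics.
#' @param n_rounds,seed Randomization-baseline settings (used when `groups`
#'   is given).
#' @param out_dir Optional output directory.
#' @return List with `matrix` (a `profile_matrix`), `histogram`, `per_run`
#'   (features/noise), `models` (fitted `rt_model`s, reference first = NULL),
#'   and, when `groups` is given, `stats` (`group_profile` result) and
#'   `baseline`.
#' @export
run_pipeline <- function(runs, ppm = 10, time_window_s = 300,
                         min_scans = 4L, charges = c(2L, 3L, 4L, 5L),
                         min_snr = 3, min_score = 0.7, align = TRUE,
                         groups = NULL, n_rounds = 10L, seed = 1L,
                         out_dir = NULL) {
  if (!length(runs)) stop("need at least one run")
  if (is.character(runs)) {
    missing_f <- runs[!file.exists(runs)]
    if (length(missing_f)) {
      stop("input file(s) not found: ", paste(missing_f, collapse = ", "))
    }
    runs <- lapply(runs, read_run)
  }
  ids <- vapply(runs, `[[`, character(1), "run_id")
  if (anyDuplicated(ids)) ids <- make.unique(ids)

  per_run <- lapply(runs, detect_features, charges = charges, ppm_tol = ppm,
                    min_scans = min_scans, min_snr = min_snr,
                    min_score = min_score)
  names(per_run) <- ids

  models <- vector("list", length(runs))
  if (align && length(runs) >= 2L) {
    ref <- per_run[[1L]]$features
    for (k in seq_along(runs)[-1L]) {
      model <- tryCatch({
        pairs <- collect_anchor_pairs(ref, per_run[[k]]$features,
                                      ppm_tol = ppm)
        fit_rt_model(pairs)
      }, error = function(e) {
        warning("run ", ids[k], ": alignment skipped (",
                conditionMessage(e), ")")
        NULL
      })
      if (!is.null(model)) {
        per_run[[k]]$features <- apply_alignment(per_run[[k]]$features, model)
        per_run[[k]]$noise <- apply_alignment(per_run[[k]]$noise, model)
        models[[k]] <- model
      }
    }
  }

  pm <- build_matrix(per_run, ppm = ppm, time_window_s = time_window_s)
  hist <- presence_histogram(pm)

  out <- list(matrix = pm, histogram = hist, per_run = per_run,
              models = models)
  if (!is.null(groups)) {
    out$stats <- group_profile(pm, groups$a, groups$b)
    out$baseline <- randomization_baseline(pm, length(groups$a),
                                           length(groups$b),
                                           n_rounds = n_rounds, seed = seed)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_profile_matrix(pm, file.path(out_dir, "profile_matrix.tsv"))
    utils::write.table(
      data.frame(n_samples = names(hist), n_rows = as.integer(hist)),
      file.path(out_dir, "presence_histogram.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    for (k in seq_along(per_run)) {
      utils::write.table(per_run[[k]]$features[
        setdiff(names(per_run[[k]]$features), "per_charge")],
        file.path(out_dir, paste0("features_", ids[k], ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(per_run[[k]]$noise,
        file.path(out_dir, paste0("noise_", ids[k], ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(out$stats)) {
      utils::write.table(out$stats$results,
        file.path(out_dir, "group_stats.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out
}
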