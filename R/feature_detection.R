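#' Link per-scan mono-isotopic ions into elution traces
#'
#' Ions of equal charge whose MH+ agree within `ppm_tol` in consecutive MS1
#' scans are chained. A chain qualifies as a trace when its gap-free streak
#' spans at least `min_consecutive` consecutive MS1 scans; once qualified, a
#' chain may extend across single-scan gaps (keeps tailing peaks whole).
#' Shorter chains are returned as short traces (the noise list). Each ion
#' joins at most one chain: the nearest-MH match wins, ties go to the higher
#' intensity.
#'
#' @param per_scan_ions List (one element per MS1 scan, in retention-time
#'   order) of ion data frames as returned by [deisotope_scan()].
#' @param ppm_tol Mass tolerance in ppm for chaining.
#' @param min_consecutive Minimum gap-free streak length (scans).
#' @return List with `traces` and `short_traces`; each element is a list of
#'   data frames (columns `mh`, `z`, `intensity`, `scan_id`, `rt`, plus a
#'   `scan_index` column giving the MS1 scan position).
#' @export
link_ions <- function(per_scan_ions, ppm_tol = 10, min_consecutive = 4L) {
  chains <- list()   # each: list(rows = df, last_idx, streak, best_streak)
  open <- integer(0) # indices of chains still extendable
  for (s in seq_along(per_scan_ions)) {
    ions <- per_scan_ions[[s]]
    if (is.null(ions) || !nrow(ions)) ions <- NULL
    taken <- if (is.null(ions)) logical(0) else logical(nrow(ions))
    still_open <- integer(0)
    for (ci in open) {
      ch <- chains[[ci]]
      gap <- s - ch$last_idx
      allowed <- gap == 1L || (gap == 2L && ch$best_streak >= min_consecutive)
      if (gap <= 2L) {
        if (allowed && !is.null(ions)) {
          last_mh <- ch$rows$mh[nrow(ch$rows)]
          cand <- which(!taken & ions$z == ch$rows$z[1L] &
                          abs(ions$mh - last_mh) <= ppm_tol * 1e-6 * last_mh)
          if (length(cand)) {
            d <- abs(ions$mh[cand] - last_mh)
            cand <- cand[order(d, -ions$intensity[cand])]
            j <- cand[1L]
            taken[j] <- TRUE
            row <- ions[j, , drop = FALSE]
            row$scan_index <- s
            ch$rows <- rbind(ch$rows, row)
            ch$streak <- if (gap == 1L) ch$streak + 1L else 1L
            ch$best_streak <- max(ch$best_streak, ch$streak)
            ch$last_idx <- s
            chains[[ci]] <- ch
          }
        }
        still_open <- c(still_open, ci)
      }
    }
    # unmatched ions start new chains
    if (!is.null(ions)) {
      for (j in which(!taken)) {
        row <- ions[j, , drop = FALSE]
        row$scan_index <- s
        chains[[length(chains) + 1L]] <- list(rows = row, last_idx = s,
                                              streak = 1L, best_streak = 1L)
        still_open <- c(still_open, length(chains))
      }
    }
    open <- still_open
  }
  qual <- vapply(chains, function(ch) ch$best_streak >= min_consecutive,
                 logical(1))
  rows <- lapply(chains, function(ch) { r <- ch$rows; rownames(r) <- NULL; r })
  list(traces = rows[qual], short_traces = rows[!qual])
}

#' Consolidate one elution trace into a feature
#'
#' The feature's intensity is the apex of the mono-isotope intensity over
#' the elution profile; the apex retention time is where that maximum occurs
#' (first maximum on ties). The feature MH+ is the intensity-weighted mean of
#' the member MH+ values.
#'
#' @param trace One trace data frame from [link_ions()].
#' @return One-row data frame with columns `mh`, `rt_apex`, `intensity`, `z`,
#'   `n_scans`, `scan_first`, `scan_last`.
#' @export
trace_to_feature <- function(trace) {
  i <- which.max(trace$intensity)
  data.frame(
    mh = sum(trace$mh * trace$intensity) / sum(trace$intensity),
    rt_apex = trace$rt[i],
    intensity = trace$intensity[i],
    z = trace$z[1L],
    n_scans = nrow(trace),
    scan_first = min(trace$scan_id),
    scan_last = max(trace$scan_id)
  )
}

#' Consolidate a short trace into a noise-list entry
#' @param trace One short-trace data frame from [link_ions()].
#' @return One-row data frame with columns `mh`, `z`, `intensity`, `rt`,
#'   `n_scans`.
#' @export
short_trace_to_noise <- function(trace) {
  i <- which.max(trace$intensity)
  data.frame(
    mh = sum(trace$mh * trace$intensity) / sum(trace$intensity),
    z = trace$z[1L],
    intensity = trace$intensity[i],
    rt = trace$rt[i],
    n_scans = nrow(trace)
  )
}

#' Combine charge states of the same peptide into one feature
#'
#' Features whose MH+ values agree within `ppm_tol`, whose apex retention
#' times differ by at most `time_tol_s`, and whose charges differ are merged.
#' The combined intensity is the sum of the per-charge apex intensities (set
#' `combine = "max"` to keep the largest apex instead); the apex retention
#' time is that of the most intense charge state.
#'
#' @param features Data frame from [trace_to_feature()] rows.
#' @param ppm_tol Mass tolerance in ppm.
#' @param time_tol_s Apex retention-time tolerance in seconds.
#' @param combine `"sum"` (default) or `"max"`.
#' @return Data frame with columns `mh`, `rt_apex`, `intensity`, `charges`
#'   (comma-separated), `per_charge` (list of named apex vectors), `n_scans`.
#' @export
merge_charge_states <- function(features, ppm_tol = 10, time_tol_s = 60,
                                combine = c("sum", "max")) {
  combine <- match.arg(combine)
  n <- nrow(features)
  empty <- data.frame(mh = numeric(), rt_apex = numeric(),
                      intensity = numeric(), charges = character(),
                      n_scans = integer())
  if (!n) { empty$per_charge <- list(); return(empty) }
  used <- logical(n)
  ord <- order(-features$intensity, features$mh)
  out <- vector("list", 0L)
  for (i in ord) {
    if (used[i]) next
    used[i] <- TRUE
    grp <- i
    cand <- which(!used &
                    abs(features$mh - features$mh[i]) <=
                      ppm_tol * 1e-6 * features$mh[i] &
                    abs(features$rt_apex - features$rt_apex[i]) <= time_tol_s &
                    features$z != features$z[i])
    if (length(cand)) {
      # at most one partner per distinct charge; nearest mh wins
      for (zz in unique(features$z[cand])) {
        cz <- cand[features$z[cand] == zz]
        j <- cz[which.min(abs(features$mh[cz] - features$mh[i]))]
        grp <- c(grp, j)
        used[j] <- TRUE
      }
    }
    per <- features$intensity[grp]
    names(per) <- as.character(features$z[grp])
    apex_of <- grp[which.max(per)]
    out[[length(out) + 1L]] <- data.frame(
      mh = sum(features$mh[grp] * per) / sum(per),
      rt_apex = features$rt_apex[apex_of],
      intensity = if (combine == "sum") sum(per) else max(per),
      charges = paste(sort(unique(features$z[grp])), collapse = ","),
      n_scans = max(features$n_scans[grp])
    )
    out[[length(out)]]$per_charge <- list(per)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$mh, res$rt_apex), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Detect features and noise ions in one run
#'
#' Full per-run stage: centroid every MS1 scan, deisotope, link ions over
#' elution time, split qualifying traces from short ones, and combine charge
#' states. Short traces become the run's noise list, kept for rescue when the
#' profile matrix is built.
#'
#' @param run An `ms_run`.
#' @param charges Charge states considered by the deisotoper.
#' @param ppm_tol Mass tolerance in ppm (deisotoping and linking).
#' @param min_scans Consecutive-scan requirement for a feature.
#' @param min_snr,min_score Peak-picking and envelope-score thresholds.
#' @param charge_time_tol_s Apex-time tolerance for charge-state merging.
#' @return List with `features` (merged data frame) and `noise` (data frame
#'   of noise ions).
#' @export
detect_features <- function(run, charges = c(2L, 3L, 4L, 5L), ppm_tol = 10,
                            min_scans = 4L, min_snr = 3, min_score = 0.7,
                            charge_time_tol_s = 60) {
  ms1 <- Filter(function(s) s$ms_level == 1L, run$spectra)
  per_scan <- lapply(ms1, function(sp) {
    deisotope_scan(centroid_spectrum(sp, min_snr = min_snr),
                   charges = charges, ppm_tol = ppm_tol,
                   min_score = min_score)
  })
  linked <- link_ions(per_scan, ppm_tol = ppm_tol,
                      min_consecutive = min_scans)
  feats <- if (length(linked$traces)) {
    do.call(rbind, lapply(linked$traces, trace_to_feature))
  } else {
    data.frame(mh = numeric(), rt_apex = numeric(), intensity = numeric(),
               z = integer(), n_scans = integer(), scan_first = integer(),
               scan_last = integer())
  }
  noise <- if (length(linked$short_traces)) {
    do.call(rbind, lapply(linked$short_traces, short_trace_to_noise))
  } else {
    data.frame(mh = numeric(), z = integer(), intensity = numeric(),
               rt = numeric(), n_scans = integer())
  }
  list(features = merge_charge_states(feats, ppm_tol = ppm_tol,
                                      time_tol_s = charge_time_tol_s),
       noise = noise)
}
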