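#' Internal constructor for a profile matrix
#'
#' Presence flags and total counts are always derived from the intensities
#' (presence = intensity > 0), so the two can never disagree.
#' @noRd
new_profile_matrix <- function(sample_ids, mh, rt_ref, intensities,
                               mass_window_ppm, time_window_s) {
  intensities <- as.matrix(intensities)
  colnames(intensities) <- sample_ids
  o <- order(mh, rt_ref)
  intensities <- intensities[o, , drop = FALSE]
  presence <- (intensities > 0) * 1L
  structure(list(
    sample_ids = sample_ids,
    mh = mh[o], rt_ref = rt_ref[o],
    intensities = intensities,
    presence = presence,
    total_count = as.integer(rowSums(presence)),
    mass_window_ppm = mass_window_ppm,
    time_window_s = time_window_s
  ), class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix: %d rows x %d samples (%s)>\n",
              length(x$mh), length(x$sample_ids),
              paste(x$sample_ids, collapse = ", ")))
  invisible(x)
}

#' Rolling redundancy collapse of repeated detections of one mass
#'
#' A tailing peptide can be re-detected minutes after its apex. Detections of
#' the same mass are grouped with a rolling rule: the first retention time
#' opens a group; each next detection within `time_window_s` of the group's
#' LAST member joins it and the reference point moves to that detection;
#' otherwise a new group starts. One group becomes one matrix row, so a peak
#' smearing for much longer than the window still collapses to a single row.
#' The group's reference time is the retention time of its most intense
#' member.
#'
#' @param detections Data frame with columns `rt` and `intensity`, all of one
#'   mass (within the mass window), sorted by ascending `rt`.
#' @param time_window_s Rolling window in seconds.
#' @return Integer vector of group ids, one per detection (1, 2, ...).
#' @export
#' @examples
#' d <- data.frame(rt = c(100, 350, 560, 900), intensity = 1)
#' collapse_repeat_detections(d, 300)  # 1 1 1 2
collapse_repeat_detections <- function(detections, time_window_s) {
  rt <- detections$rt
  stopifnot(!is.unsorted(rt))
  g <- integer(length(rt))
  if (!length(rt)) return(g)
  g[1L] <- 1L
  for (i in seq_along(rt)[-1L]) {
    g[i] <- if (rt[i] - rt[i - 1L] <= time_window_s) g[i - 1L] else
      g[i - 1L] + 1L
  }
  g
}

#' Build the peptide profile matrix from aligned runs
#'
#' Aggregation proceeds in four steps: (a) rows are seeded from the union of
#' per-run features, matched across runs greedily by descending intensity
#' within the mass and time windows (matched features are consumed; ties go
#' to the smaller mass difference); (b) rows of the same mass are passed
#' through the rolling redundancy collapse ([collapse_repeat_detections()]),
#' merged rows keeping each sample's apex intensity; (c) every remaining
#' empty cell is searched for in that run's noise list within the same
#' windows and filled with the noise ion's apex intensity when found
#' (rescue); (d) remaining cells stay 0. Presence flags and per-row totals
#' follow from the intensities.
#'
#' @param runs Named list, one element per sample, each a list with elements
#'   `features` (data frame with `mh`, `rt_apex`, `intensity`) and `noise`
#'   (data frame with `mh`, `rt`, `intensity`; may be empty), already
#'   RT-aligned.
#' @param ppm Mass window in ppm.
#' @param time_window_s Retention-time window in seconds (default 5 min).
#' @return A `profile_matrix`.
#' @export
build_matrix <- function(runs, ppm = 10, time_window_s = 300) {
  if (!length(runs)) stop("empty input: need at least one run")
  ids <- names(runs)
  if (is.null(ids)) ids <- as.character(seq_along(runs))
  ns <- length(runs)

  pool <- do.call(rbind, lapply(seq_along(runs), function(k) {
    f <- runs[[k]]$features
    if (is.null(f) || !nrow(f)) return(NULL)
    data.frame(sample = k, mh = f$mh, rt = f$rt_apex,
               intensity = f$intensity)
  }))
  if (is.null(pool) || !nrow(pool)) stop("empty input: no features in any run")

  # (a) greedy cross-run matching by descending intensity
  used <- logical(nrow(pool))
  ord <- order(-pool$intensity, pool$mh)
  seed_rows <- list()
  for (i in ord) {
    if (used[i]) next
    used[i] <- TRUE
    cells <- numeric(ns)
    cells[pool$sample[i]] <- pool$intensity[i]
    for (k in seq_len(ns)[-pool$sample[i]]) {
      cand <- which(!used & pool$sample == k &
                      abs(pool$mh - pool$mh[i]) <= ppm * 1e-6 * pool$mh[i] &
                      abs(pool$rt - pool$rt[i]) <= time_window_s)
      if (length(cand)) {
        j <- cand[which.min(abs(pool$mh[cand] - pool$mh[i]))]
        used[j] <- TRUE
        cells[k] <- pool$intensity[j]
      }
    }
    seed_rows[[length(seed_rows) + 1L]] <-
      list(mh = pool$mh[i], rt = pool$rt[i],
           intensity = pool$intensity[i], cells = cells)
  }

  mh <- vapply(seed_rows, `[[`, numeric(1), "mh")
  rt <- vapply(seed_rows, `[[`, numeric(1), "rt")
  apex <- vapply(seed_rows, `[[`, numeric(1), "intensity")
  cells <- do.call(rbind, lapply(seed_rows, `[[`, "cells"))

  # (b) redundancy collapse within mass groups
  o <- order(mh, rt)
  mh <- mh[o]; rt <- rt[o]; apex <- apex[o]
  cells <- cells[o, , drop = FALSE]
  mgrp <- cumsum(c(1L, (diff(mh) > ppm * 1e-6 * mh[-length(mh)]) * 1L))
  out_mh <- numeric(0); out_rt <- numeric(0)
  out_cells <- NULL
  for (g in split(seq_along(mh), mgrp)) {
    g <- g[order(rt[g])]
    sub <- data.frame(rt = rt[g], intensity = apex[g])
    gid <- collapse_repeat_detections(sub, time_window_s)
    for (u in unique(gid)) {
      m <- g[gid == u]
      best <- m[which.max(apex[m])]
      merged <- apply(cells[m, , drop = FALSE], 2L, max)
      out_mh <- c(out_mh, sum(mh[m] * apex[m]) / sum(apex[m]))
      out_rt <- c(out_rt, rt[best])
      out_cells <- rbind(out_cells, merged)
    }
  }

  # (c) noise-list rescue of empty cells
  noise_used <- lapply(runs, function(r) {
    nz <- r$noise
    if (is.null(nz)) nz <- data.frame(mh = numeric(), rt = numeric(),
                                      intensity = numeric())
    list(df = nz, used = logical(nrow(nz)))
  })
  row_order <- order(out_mh, out_rt)
  for (ri in row_order) {
    for (k in which(out_cells[ri, ] == 0)) {
      nd <- noise_used[[k]]
      if (!nrow(nd$df)) next
      cand <- which(!nd$used &
                      abs(nd$df$mh - out_mh[ri]) <= ppm * 1e-6 * out_mh[ri] &
                      abs(nd$df$rt - out_rt[ri]) <= time_window_s)
      if (length(cand)) {
        j <- cand[order(abs(nd$df$mh[cand] - out_mh[ri]),
                        -nd$df$intensity[cand])][1L]
        out_cells[ri, k] <- nd$df$intensity[j]
        noise_used[[k]]$used[j] <- TRUE
      }
    }
  }

  new_profile_matrix(sample_ids = ids, mh = out_mh, rt_ref = out_rt,
                     intensities = out_cells,
                     mass_window_ppm = ppm, time_window_s = time_window_s)
}

#' Replicate-presence histogram of a profile matrix
#'
#' Counts how many rows were detected in exactly 1, 2, ..., N samples.
#'
#' @param matrix A `profile_matrix`.
#' @return Named integer vector; names are the presence counts `1..N`, values
#'   the number of rows. Sums to the number of rows.
#' @export
presence_histogram <- function(matrix) {
  ns <- length(matrix$sample_ids)
  counts <- tabulate(matrix$total_count, nbins = ns)
  stats::setNames(as.integer(counts), seq_len(ns))
}
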