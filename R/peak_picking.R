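#' Estimate the noise level of an MS1 spectrum
#'
#' The noise level is the median of the nonzero intensities times `factor`.
#' A spectrum with no nonzero intensity has noise level 0.
#'
#' @param spectrum An `ms_spectrum` (see [ms_spectrum()]).
#' @param factor Multiplier applied to the median.
#' @return Noise level in the spectrum's intensity units.
#' @export
estimate_noise <- function(spectrum, factor = 1) {
  i <- spectrum$intensity[spectrum$intensity > 0]
  if (!length(i)) return(0)
  stats::median(i) * factor
}

#' Centroid an MS1 spectrum
#'
#' For profile-mode data, local maxima above `min_snr` times the noise level
#' become peaks; the centroid m/z is the intensity-weighted mean over the
#' maximum plus/minus `k` profile points and the reported intensity is the
#' apex value. Already-centroided spectra pass through with only the
#' signal-to-noise filter applied. Peaks with identical m/z are merged by
#' summing intensities.
#'
#' @param spectrum An `ms_spectrum`.
#' @param min_snr Minimum signal-to-noise ratio for a peak to be kept.
#' @param noise_factor Passed to [estimate_noise()].
#' @param k Half-width, in profile points, of the centroiding window.
#' @return A `centroid_scan`: list with `scan_id`, `rt`, `peaks` (data frame
#'   `mz`, `intensity`, sorted by `mz`) and `noise_level`.
#' @export
centroid_spectrum <- function(spectrum, min_snr = 3, noise_factor = 1, k = 2L) {
  noise <- estimate_noise(spectrum, noise_factor)
  thr <- min_snr * noise
  mz <- spectrum$mz
  int <- spectrum$intensity
  if (isTRUE(spectrum$centroided)) {
    keep <- int > 0 & int >= thr
    pk <- data.frame(mz = mz[keep], intensity = int[keep])
  } else {
    n <- length(int)
    pk <- data.frame(mz = numeric(), intensity = numeric())
    if (n >= 3L) {
      is_max <- c(FALSE, int[2:(n - 1)] > int[1:(n - 2)] &
                         int[2:(n - 1)] >= int[3:n], FALSE)
      apex <- which(is_max & int > 0 & int >= thr)
      if (length(apex)) {
        cmz <- vapply(apex, function(i) {
          w <- max(1L, i - k):min(n, i + k)
          sum(mz[w] * int[w]) / sum(int[w])
        }, numeric(1))
        pk <- data.frame(mz = cmz, intensity = int[apex])
      }
    }
  }
  if (nrow(pk)) {
    pk <- pk[order(pk$mz), , drop = FALSE]
    if (anyDuplicated(pk$mz)) {
      agg <- rowsum(pk$intensity, group = pk$mz)
      pk <- data.frame(mz = as.numeric(rownames(agg)), intensity = agg[, 1L])
    }
    rownames(pk) <- NULL
  }
  structure(list(scan_id = spectrum$scan_id, rt = spectrum$rt, peaks = pk,
                 noise_level = noise),
            class = "centroid_scan")
}
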