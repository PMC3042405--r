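# shared fixture builders (all data generated in code, fixed seeds per test)

# profile matrix directly from an intensity matrix (rows x samples)
make_pm <- function(intensities, mh = NULL, rt = NULL) {
  intensities <- as.matrix(intensities)
  n <- nrow(intensities)
  if (is.null(mh)) mh <- 1000 + seq_len(n)
  if (is.null(rt)) rt <- 100 * seq_len(n)
  peparray:::new_profile_matrix(
    sample_ids = as.character(seq_len(ncol(intensities))),
    mh = mh, rt_ref = rt, intensities = intensities,
    mass_window_ppm = 10, time_window_s = 300)
}

# centroid scan holding one or more averagine isotope envelopes
make_envelope_scan <- function(mono_mz, z, apex, n_iso = 4, scan_id = 1,
                               rt = 100, extra_mz = numeric(),
                               extra_int = numeric()) {
  k <- mass_constants()
  mz <- c(); int <- c()
  for (i in seq_along(mono_mz)) {
    env <- averagine_envelope((mono_mz[i] - k$proton) * z[i], n_iso)
    mz <- c(mz, mono_mz[i] + (0:(n_iso - 1)) * k$isotope_spacing / z[i])
    int <- c(int, apex[i] * env)
  }
  mz <- c(mz, extra_mz); int <- c(int, extra_int)
  o <- order(mz)
  structure(list(scan_id = scan_id, rt = rt,
                 peaks = data.frame(mz = mz[o], intensity = int[o]),
                 noise_level = 0),
            class = "centroid_scan")
}

# per-scan ion lists: one ion of mass mh at the given scan positions
ion_rows <- function(scans, mh, z = 2L, intensity = 100, rt = scans * 2) {
  out <- vector("list", max(scans))
  for (i in seq_along(scans)) {
    s <- scans[i]
    out[[s]] <- rbind(out[[s]],
                      data.frame(mh = mh, z = z, intensity = intensity[
                        ((i - 1) %% length(intensity)) + 1],
                        scan_id = s, rt = rt[i]))
  }
  out
}

# a small feature table
feat_df <- function(mh, rt, intensity = rep(1000, length(mh)),
                    z = rep(2L, length(mh))) {
  n <- length(mh)
  data.frame(mh = mh, rt_apex = rt, intensity = intensity, z = z,
             n_scans = rep(5L, n), scan_first = rep(1L, n),
             scan_last = rep(5L, n))
}
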