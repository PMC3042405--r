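#' Simulation configuration for synthetic LC-MS1 runs
#'
#' Defaults emulate a 2-hour Orbitrap-like gradient: 1 MS1 scan per second,
#' 2 ppm mass jitter, 10% multiplicative replicate intensity noise, 25
#' random noise peaks per scan (uniform in m/z over the acquisition window,
#' exponential intensity with mean 50), and an inter-run retention-time
#' drift of 60 s at the dead time decaying with rate 5e-4 1/s.
#'
#' @param gradient_s Gradient length in seconds.
#' @param scan_interval_s Time between MS1 scans in seconds.
#' @param mz_jitter_ppm Per-peak Gaussian m/z jitter (ppm, 1 sd).
#' @param intensity_cv Multiplicative replicate intensity noise (fractional
#'   CV).
#' @param noise_peaks_per_scan Random noise peaks added to each scan.
#' @param noise_mean Mean of the exponential noise-peak intensity.
#' @param mz_range Acquisition m/z window.
#' @param drift_A,drift_c,drift_tm Inter-run drift parameters (see
#'   [rt_model()]).
#' @param dropout Per-replicate, per-peptide dropout probability.
#' @param seed Integer seed; required for every simulation.
#' @return A `sim_config` list.
#' @export
sim_config <- function(gradient_s = 7200, scan_interval_s = 1,
                       mz_jitter_ppm = 2, intensity_cv = 0.1,
                       noise_peaks_per_scan = 25L, noise_mean = 50,
                       mz_range = c(400, 1600),
                       drift_A = 60, drift_c = 5e-4, drift_tm = 120,
                       dropout = 0, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(gradient_s > 0, scan_interval_s > 0, mz_jitter_ppm >= 0,
            intensity_cv >= 0, noise_peaks_per_scan >= 0, dropout >= 0,
            dropout < 1)
  structure(list(gradient_s = gradient_s, scan_interval_s = scan_interval_s,
                 mz_jitter_ppm = mz_jitter_ppm, intensity_cv = intensity_cv,
                 noise_peaks_per_scan = as.integer(noise_peaks_per_scan),
                 noise_mean = noise_mean, mz_range = mz_range,
                 drift_A = drift_A, drift_c = drift_c, drift_tm = drift_tm,
                 dropout = dropout, seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw a random peptide table for simulation
#'
#' Peptides get MH+ masses uniform over `mh_range`, lognormal apex
#' intensities, elution centers uniform over the usable gradient, Gaussian
#' elution widths of 8-15 s, and charge states 2 and 3 with random weights.
#' A fraction can be given an exponential tail to emulate smearing peaks.
#'
#' @param n Number of peptides.
#' @param config A `sim_config` (provides gradient length and the seed
#'   offset).
#' @param mh_range MH+ range in Da.
#' @param apex_meanlog,apex_sdlog Lognormal apex-intensity parameters.
#' @param frac_tailing Fraction of peptides given an exponential tail.
#' @param tail_tau_s Tail time constant in seconds for tailing peptides.
#' @return Data frame with columns `peptide_id`, `mh`, `charges`,
#'   `charge_weights`, `apex_intensity`, `rt_center`, `rt_sigma`,
#'   `tailing_tau`.
#' @export
synth_peptides <- function(n, config, mh_range = c(900, 2400),
                           apex_meanlog = log(2e4), apex_sdlog = 0.8,
                           frac_tailing = 0, tail_tau_s = 120) {
  set.seed(config$seed + 1L)
  margin <- 60
  rt_lo <- config$drift_tm + margin
  rt_hi <- config$gradient_s - margin
  if (rt_hi <= rt_lo) {  # short gradients (small test runs)
    rt_lo <- 0.2 * config$gradient_s
    rt_hi <- 0.8 * config$gradient_s
  }
  w2 <- stats::runif(n, 0.3, 0.7)
  data.frame(
    peptide_id = seq_len(n),
    mh = stats::runif(n, mh_range[1L], mh_range[2L]),
    charges = "2,3",
    charge_weights = sprintf("%.3f,%.3f", w2, 1 - w2),
    apex_intensity = stats::rlnorm(n, apex_meanlog, apex_sdlog),
    rt_center = stats::runif(n, rt_lo, rt_hi),
    rt_sigma = stats::runif(n, 8, 15),
    tailing_tau = ifelse(stats::runif(n) < frac_tailing, tail_tau_s, 0)
  )
}

# elution profile over scan times, normalized to max 1; EMG tail if tau > 0
.elution_shape <- function(t, center, sigma, tau) {
  if (tau <= 0) return(exp(-0.5 * ((t - center) / sigma)^2))
  # exponentially modified Gaussian; erfc via pnorm
  erfc <- function(x) 2 * stats::pnorm(-x * sqrt(2))
  arg <- sigma^2 / (2 * tau^2) - (t - center) / tau
  arg <- pmin(arg, 700)  # overflow guard
  h <- exp(arg) * erfc((sigma / tau - (t - center) / sigma) / sqrt(2))
  h / max(h)
}

.parse_num_list <- function(s) as.numeric(strsplit(s, ",")[[1L]])

#' Simulate one LC-MS1 run
#'
#' Each peptide contributes, per charge state, an isotope envelope (averagine
#' abundances, spacing 1.0033548/z Da) scaled by its elution profile --
#' Gaussian, or exponentially modified Gaussian for tailing peptides -- at
#' every scan within 5 sigma (plus 8 tail time constants) of its center.
#' Per-peak ppm jitter and per-scan random noise peaks are added. All
#' randomness is governed by `seed`; the same seed reproduces the run
#' bit for bit.
#'
#' @param peptides Peptide table as from [synth_peptides()].
#' @param config A `sim_config`.
#' @param seed Integer seed (defaults to `config$seed`).
#' @param rt_shift_fun Optional function(rt) -> shifted rt applied to
#'   elution centers (used for inter-run drift).
#' @param intensity_factor Per-peptide multiplicative factors (replicate
#'   noise, fold changes); recycled.
#' @param run_id Identifier for the resulting run.
#' @return List with `run` (an `ms_run`) and `truth` (data frame of injected
#'   peptides: `peptide_id`, `mh`, `charges`, `rt_center`, `apex`).
#' @export
simulate_run <- function(peptides, config, seed = config$seed,
                         rt_shift_fun = identity,
                         intensity_factor = 1, run_id = "sim") {
  set.seed(seed)
  n_iso <- 4L
  k <- mass_constants()
  scan_t <- seq(0, config$gradient_s, by = config$scan_interval_s)
  n_scans <- length(scan_t)
  fac <- rep_len(intensity_factor, nrow(peptides))

  scan_mz <- vector("list", n_scans)
  scan_int <- vector("list", n_scans)

  if (nrow(peptides)) {
    for (pi in seq_len(nrow(peptides))) {
      p <- peptides[pi, ]
      if (fac[pi] <= 0) next
      center <- rt_shift_fun(p$rt_center)
      span <- 5 * p$rt_sigma + 8 * p$tailing_tau
      sel <- which(scan_t >= center - 5 * p$rt_sigma &
                     scan_t <= center + span)
      if (!length(sel)) next
      shape <- .elution_shape(scan_t[sel], center, p$rt_sigma, p$tailing_tau)
      zs <- as.integer(.parse_num_list(p$charges))
      wz <- .parse_num_list(p$charge_weights)
      wz <- wz / max(wz)
      env <- averagine_envelope(p$mh - k$proton, n_iso)
      for (ci in seq_along(zs)) {
        z <- zs[ci]
        mono <- mz_from_mh(p$mh, z)
        mzs <- mono + (0:(n_iso - 1L)) * k$isotope_spacing / z
        if (mzs[1L] < config$mz_range[1L] || mzs[1L] > config$mz_range[2L])
          next
        base <- p$apex_intensity * fac[pi] * wz[ci]
        for (si in seq_along(sel)) {
          ints <- base * shape[si] * env
          keep <- ints >= 1
          if (!any(keep)) next
          jit <- mzs[keep] *
            (1 + stats::rnorm(sum(keep)) * config$mz_jitter_ppm * 1e-6)
          s <- sel[si]
          scan_mz[[s]] <- c(scan_mz[[s]], jit)
          scan_int[[s]] <- c(scan_int[[s]], ints[keep])
        }
      }
    }
  }

  spectra <- vector("list", n_scans)
  for (s in seq_len(n_scans)) {
    mzv <- scan_mz[[s]]; inv <- scan_int[[s]]
    if (config$noise_peaks_per_scan > 0L) {
      nm <- stats::runif(config$noise_peaks_per_scan, config$mz_range[1L],
                         config$mz_range[2L])
      ni <- stats::rexp(config$noise_peaks_per_scan, 1 / config$noise_mean)
      mzv <- c(mzv, nm); inv <- c(inv, ni)
    }
    if (is.null(mzv)) { mzv <- numeric(0); inv <- numeric(0) }
    spectra[[s]] <- ms_spectrum(scan_id = s, rt = scan_t[s], mz = mzv,
                                intensity = inv, ms_level = 1L,
                                centroided = TRUE)
  }
  truth <- if (nrow(peptides)) {
    data.frame(peptide_id = peptides$peptide_id, mh = peptides$mh,
               charges = peptides$charges,
               rt_center = vapply(peptides$rt_center, rt_shift_fun,
                                  numeric(1)),
               apex = peptides$apex_intensity * fac)
  } else {
    data.frame(peptide_id = integer(), mh = numeric(), charges = character(),
               rt_center = numeric(), apex = numeric())
  }
  list(run = ms_run(run_id, spectra, gradient_length = config$gradient_s),
       truth = truth)
}

#' Simulate technical replicates of one sample
#'
#' Replicate 1 is the reference; each later replicate r is shifted by
#' (r - 1) times the configured drift law and receives independent
#' multiplicative intensity noise with the configured CV (lognormal with
#' matched CV) and optional dropout.
#'
#' @param peptides Peptide table.
#' @param n_reps Number of replicates.
#' @param config A `sim_config`.
#' @return List with `runs` (list of `ms_run`) and `truth` (reference truth
#'   table).
#' @export
simulate_replicates <- function(peptides, n_reps, config) {
  model <- rt_model(config$drift_A, config$drift_c, config$drift_tm)
  sdlog <- sqrt(log(1 + config$intensity_cv^2))
  runs <- vector("list", n_reps)
  truth <- NULL
  for (r in seq_len(n_reps)) {
    rep_seed <- config$seed + 1000L * r
    set.seed(rep_seed)
    fac <- if (config$intensity_cv > 0) {
      stats::rlnorm(nrow(peptides), -sdlog^2 / 2, sdlog)
    } else rep(1, nrow(peptides))
    if (config$dropout > 0) {
      fac[stats::runif(nrow(peptides)) < config$dropout] <- 0
    }
    shift <- if (r == 1L) identity else
      function(t) t + (r - 1L) * predict_dt(model, t)
    sim <- simulate_run(peptides, config, seed = rep_seed,
                        rt_shift_fun = shift, intensity_factor = fac,
                        run_id = paste0("rep", r))
    runs[[r]] <- sim$run
    if (r == 1L) truth <- sim$truth
  }
  list(runs = runs, truth = truth)
}

#' Simulate a two-group study with known differential peptides
#'
#' All samples share one peptide table; a fraction of peptides has its
#' intensity multiplied by `fold_change` in group B. The truth table flags
#' the differential peptides.
#'
#' @param n_per_group Samples per group.
#' @param n_peptides Number of peptides.
#' @param frac_differential Fraction of peptides changed in group B.
#' @param fold_change Multiplicative change applied in group B.
#' @param config A `sim_config`.
#' @return List with `runs` (2 * n_per_group `ms_run`s, group A first),
#'   `labels` (group letter per run), `truth` (peptide table with a
#'   `differential` flag).
#' @export
simulate_two_group_study <- function(n_per_group, n_peptides,
                                     frac_differential, fold_change,
                                     config) {
  peptides <- synth_peptides(n_peptides, config)
  set.seed(config$seed + 2L)
  n_diff <- round(frac_differential * n_peptides)
  diff_ids <- sort(sample.int(n_peptides, n_diff))
  sdlog <- sqrt(log(1 + config$intensity_cv^2))
  runs <- list(); labels <- character(0)
  for (g in c("A", "B")) {
    for (i in seq_len(n_per_group)) {
      s <- config$seed + 10000L * (g == "B") + 100L * i
      set.seed(s)
      fac <- if (config$intensity_cv > 0) {
        stats::rlnorm(n_peptides, -sdlog^2 / 2, sdlog)
      } else rep(1, n_peptides)
      if (g == "B") fac[diff_ids] <- fac[diff_ids] * fold_change
      sim <- simulate_run(peptides, config, seed = s,
                          intensity_factor = fac,
                          run_id = paste0(g, i))
      runs[[length(runs) + 1L]] <- sim$run
      labels <- c(labels, g)
    }
  }
  truth <- peptides
  truth$differential <- truth$peptide_id %in% diff_ids
  list(runs = runs, labels = labels, truth = truth)
}
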