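test_that("a simulated run survives an mzML write/read round trip", {
  cfg <- sim_config(gradient_s = 20, scan_interval_s = 2,
                    noise_peaks_per_scan = 5L, mz_jitter_ppm = 0, seed = 3)
  peps <- data.frame(peptide_id = 1L, mh = 1200.5, charges = "2,3",
                     charge_weights = "0.6,0.4", apex_intensity = 5e4,
                     rt_center = 10, rt_sigma = 4, tailing_tau = 0)
  sim <- simulate_run(peps, cfg)
  path <- withr::local_tempfile(fileext = ".mzML")
  write_run_mzml(sim$run, path)
  back <- read_run(path, ms_level_filter = 1)
  expect_length(back$spectra, length(sim$run$spectra))
  for (i in seq_along(back$spectra)) {
    expect_equal(back$spectra[[i]]$rt, sim$run$spectra[[i]]$rt)
    expect_equal(back$spectra[[i]]$mz, sim$run$spectra[[i]]$mz,
                 tolerance = 1e-9)
    expect_equal(back$spectra[[i]]$intensity,
                 sim$run$spectra[[i]]$intensity, tolerance = 1e-6)
  }
})

test_that("the MS-level filter keeps only the requested level", {
  s1 <- ms_spectrum(1, 10, mz = c(500, 501), intensity = c(10, 20),
                    ms_level = 1)
  s2 <- ms_spectrum(2, 11, mz = c(200, 300), intensity = c(5, 5),
                    ms_level = 2)
  s3 <- ms_spectrum(3, 12, mz = c(502, 503), intensity = c(7, 8),
                    ms_level = 1)
  path <- withr::local_tempfile(fileext = ".mzML")
  write_run_mzml(ms_run("mixed", list(s1, s2, s3)), path)
  ms1 <- read_run(path, ms_level_filter = 1)
  expect_length(ms1$spectra, 2)
  expect_true(all(vapply(ms1$spectra, `[[`, integer(1), "ms_level") == 1L))
  all_levels <- read_run(path, ms_level_filter = NULL)
  expect_length(all_levels$spectra, 3)
  expect_error(read_run(path, ms_level_filter = 3), "no spectra")
})

test_that("a truncated file raises a parse error instead of a silent
           truncation", {
  s1 <- ms_spectrum(1, 10, mz = c(500, 501), intensity = c(10, 20))
  path <- withr::local_tempfile(fileext = ".mzML")
  write_run_mzml(ms_run("t", list(s1)), path)
  txt <- readLines(path)
  bad <- withr::local_tempfile(fileext = ".mzML")
  writeLines(txt[1:(length(txt) - 5)], bad)  # drop closing tags
  expect_error(read_run(bad), "parse error")
  expect_error(read_run("/nonexistent/file.mzML"), "not found")
})

test_that("MGF precursor blocks are parsed, flagged and validated", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c(
    "BEGIN IONS",
    "TITLE=scan 100",
    "PEPMASS=872.03 12345.6",
    "CHARGE=2+",
    "100.1 5", "200.2 10",
    "END IONS",
    "",
    "BEGIN IONS",
    "TITLE=scan 101",
    "PEPMASS=650.37",
    "300.0 2",
    "END IONS"
  ), path)
  rec <- read_mgf_precursors(path)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$mz, c(872.03, 650.37))
  expect_equal(rec$z, c(2L, NA_integer_))
  expect_equal(rec$charge_missing, c(FALSE, TRUE))
  expect_equal(rec$scan_ref, c("scan 100", "scan 101"))

  empty <- withr::local_tempfile(fileext = ".mgf")
  writeLines(character(0), empty)
  expect_equal(nrow(read_mgf_precursors(empty)), 0)

  bad <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "PEPMASS=500.1", "CHARGE=2+"), bad)  # no END
  expect_error(read_mgf_precursors(bad), "block")
})

test_that("profile matrix files round-trip and carry the printed column
           layout", {
  runs <- list(
    s1 = list(features = feat_df(c(1239.638, 1500.2), c(6675.558, 900)),
              noise = NULL),
    s2 = list(features = feat_df(1500.2004, 901), noise = NULL),
    s3 = list(features = feat_df(c(1239.6383, 1500.1998), c(6675.0, 899)),
              noise = NULL)
  )
  pm <- build_matrix(runs, ppm = 10, time_window_s = 300)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_matrix(pm, path)
  hdr <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_equal(hdr, c("MH+", "time (s)",
                      paste("Peak intensity in sample", c("s1", "s2", "s3")),
                      paste("Peptide present in sample", c("s1", "s2", "s3")),
                      "Total count of peptides"))
  back <- read_profile_matrix(path)
  expect_equal(back$mh, pm$mh)
  expect_equal(back$rt_ref, pm$rt_ref)
  expect_equal(unname(back$intensities), unname(pm$intensities))
  expect_equal(back$presence, pm$presence, ignore_attr = TRUE)
  expect_equal(back$total_count, pm$total_count)
})

test_that("a 100-row synthetic profile matrix round-trips exactly", {
  set.seed(5)
  ints <- matrix(round(rlnorm(300, log(1e4), 1)), ncol = 3)
  ints[sample(300, 40)] <- 0
  pm <- make_pm(ints, mh = sort(runif(100, 900, 2400)),
                rt = runif(100, 100, 7000))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_matrix(pm, path)
  back <- read_profile_matrix(path)
  expect_equal(back$mh, pm$mh)
  expect_equal(unname(back$intensities), unname(pm$intensities))
  expect_equal(back$total_count, pm$total_count)

  broken <- withr::local_tempfile(fileext = ".tsv")
  tab <- read.delim(path, check.names = FALSE)
  write.table(tab[-3], broken, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_profile_matrix(broken), "layout")
})

test_that("comparison matrix files round-trip with all-zero grid rows kept", {
  grid <- make_grid(1741, 1744, 20)
  cm <- build_comparison_matrix(
    grid,
    sources = list(
      listA = data.frame(mass = c(1741.7447, 1743.0563),
                         intensity = c(30698, 4248221)),
      listB = data.frame(mass = 1741.7447, intensity = 73185)),
    ms2_triggered = 1741.7447)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_comparison_matrix(cm, path)
  back <- read_comparison_matrix(path)
  expect_equal(length(back$grid$masses), length(grid$masses))
  expect_equal(back$cells, cm$cells, tolerance = 1e-12)
  expect_equal(back$ms2_triggered, cm$ms2_triggered)
  # all-zero rows are written, not dropped
  expect_true(any(rowSums(back$cells) == 0))
  hdr <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_equal(hdr[1:3], c("Mass MH+", "ms2 triggered", "ms2 sequenced"))
})
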