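test_that("theoretical MH+ of tryptic IgG kappa peptides match printed values", {
  # printed to 5 decimals; residue masses are exact elemental sums, so
  # agreement is asserted to the printed precision
  printed <- c(DSTYSLSSTLTLSK = 1502.75844,
               VDNALQSGNSQESVTEQDSK = 2135.96873,
               TVAAPSVFIFPPSDEQLK = 1946.02696,
               SGTASVVCLLNNFYPREAK = 2069.04844)
  for (s in names(printed)) {
    expect_lt(abs(peptide_mh(s) - printed[[s]]), 1e-5)
  }
})

test_that("peptide_mh handles single residues, oxidation and bad input", {
  # G = glycine residue + water + proton
  expect_equal(peptide_mh("G"), 57.021464 + 18.0105646 + 1.0072765,
               tolerance = 1e-6)
  expect_equal(peptide_mh("PEPTIDEM", n_oxidations = 1) -
                 peptide_mh("PEPTIDEM"), 15.9994)
  expect_error(peptide_mh("PEPTIDEX"), "X")
  expect_error(peptide_mh("ABZ"), "Z")
})

test_that("mh_from_mz deconvolutes charge and inverts exactly", {
  expect_equal(mh_from_mz(1234.5, 1), 1234.5)
  expect_equal(mh_from_mz(872.03, 2), 2 * 872.03 - 1.0072765)
  expect_equal(mh_from_mz(581.690, 3), 3 * 581.690 - 2 * 1.0072765)
  expect_error(mh_from_mz(500, 0), "charge")
  set.seed(1)
  mh <- runif(50, 600, 4000)
  for (z in 1:5) {
    expect_equal(mh_from_mz(mz_from_mh(mh, z), z), mh)
  }
})

test_that("averagine envelope is M0-dominated for light masses and matches a
           brute-force convolution oracle at 1742 Da", {
  light <- averagine_envelope(100, 5)
  expect_equal(light[1], 1)
  expect_true(all(diff(light) < 0))

  # oracle: polynomial expansion by repeated per-atom convolution over the
  # rounded averagine formula
  units <- 1742 / 111.1254
  counts <- round(c(C = 4.9384, H = 7.7583, N = 1.3577, O = 1.4773,
                    S = 0.0417) * units)
  abund <- list(C = c(0.9893, 0.0107), H = c(0.999885, 0.000115),
                N = c(0.99636, 0.00364), O = c(0.99757, 0.00038, 0.00205),
                S = c(0.9499, 0.0075, 0.0425, 0.0001))
  poly <- 1
  for (el in names(counts)) {
    for (i in seq_len(counts[[el]])) {
      nn <- length(poly) + length(abund[[el]]) - 1L
      acc <- numeric(nn)
      for (j in seq_along(abund[[el]])) {
        acc[j:(j + length(poly) - 1L)] <-
          acc[j:(j + length(poly) - 1L)] + abund[[el]][j] * poly
      }
      poly <- acc[1:min(nn, 8L)]  # truncate far tail
    }
  }
  oracle_ratio <- poly[2] / poly[1]
  env <- averagine_envelope(1742, 4)
  expect_equal(env[2] / env[1], oracle_ratio, tolerance = 0.05)
})

test_that("M1/M0 grows monotonically with peptide mass", {
  masses <- seq(500, 4000, by = 250)
  ratios <- vapply(masses, function(m) {
    e <- averagine_envelope(m, 2); e[2] / e[1]
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("a triply charged envelope is found with the right charge and mono m/z", {
  scan <- make_envelope_scan(581.690, 3, 4.2e6)
  cl <- find_isotope_clusters(scan, charges = c(2, 3))
  expect_length(cl, 1)
  expect_equal(cl[[1]]$z, 3)
  expect_equal(cl[[1]]$mono_mz, 581.690)
  # restricting to z = 2 leaves the 0.334 Da spacing unmatched
  expect_length(find_isotope_clusters(scan, charges = 2), 0)
})

test_that("cluster_to_ion applies the MH+ deconvolution and keeps the apex", {
  scan <- make_envelope_scan(581.690, 3, 4.2e6, rt = 321, scan_id = 17)
  cl <- find_isotope_clusters(scan, charges = c(2, 3))
  ion <- cluster_to_ion(cl[[1]], scan)
  expect_equal(ion$mh, 3 * 581.690 - 2 * 1.0072765, tolerance = 1e-9)
  expect_equal(ion$intensity, 4.2e6)
  expect_equal(ion$rt, 321)
  expect_equal(ion$scan_id, 17)
})

test_that("when clusters overlap, the higher-intensity seed consumes the shared
           peak deterministically", {
  # hand-built crossing: a strong z=2 ladder from 600.0 whose M2 position
  # (601.0034) coincides with the M1 position of a weak z=3 ladder from
  # 600.66895; the shared peak can complete either envelope
  d <- mass_constants()$isotope_spacing
  mz <- c(600.0, 600.0 + d / 2, 600.66895, 600.66895 + d / 3,
          600.0 + 3 * d / 2, 600.66895 + 2 * d / 3)
  int <- c(1e6, 6.5e5, 1.5e5, 2.6e5, 8e4, 5e4)
  o <- order(mz)
  scan <- structure(list(scan_id = 1, rt = 1,
                         peaks = data.frame(mz = mz[o], intensity = int[o]),
                         noise_level = 0), class = "centroid_scan")
  cl <- find_isotope_clusters(scan, charges = c(2, 3))
  # hand enumeration of the greedy rule: the 1e6 seed builds the z=2 cluster
  # first and consumes the shared 601.0034 peak; the weak z=3 seed then finds
  # its M1 position consumed, leaving a broken ladder that cannot form a
  # second cluster through the shared peak
  shared <- 600.66895 + d / 3
  strong <- cl[[which.min(vapply(cl, `[[`, numeric(1), "mono_mz"))]]
  expect_equal(strong$z, 2)
  expect_equal(strong$mono_mz, 600.0)
  expect_true(any(abs(strong$member_mz - shared) < 1e-9))
  others <- setdiff(seq_along(cl), which.min(vapply(cl, `[[`, numeric(1),
                                                    "mono_mz")))
  for (i in others) {
    expect_false(any(abs(cl[[i]]$member_mz - shared) < 1e-9))
  }
  # rerun is bit-identical (deterministic greedy)
  expect_identical(cl, find_isotope_clusters(scan, charges = c(2, 3)))
})

test_that("no peak is double-counted across clusters", {
  set.seed(7)
  for (trial in 1:5) {
    monos <- sort(runif(6, 500, 900))
    scan <- make_envelope_scan(monos, sample(2:3, 6, TRUE),
                               10^runif(6, 4, 6))
    cl <- find_isotope_clusters(scan, charges = c(2, 3))
    member_sum <- sum(unlist(lapply(cl, `[[`, "member_intensity")))
    expect_lte(member_sum, sum(scan$peaks$intensity) + 1e-9)
  }
})

test_that("well-separated synthetic envelopes are all recovered with true charge", {
  set.seed(13)
  monos <- seq(500, 1100, by = 40) + runif(16, 0, 5)
  zs <- rep(c(2L, 3L), 8)
  scan <- make_envelope_scan(monos, zs, rep(1e5, 16))
  cl <- find_isotope_clusters(scan, charges = c(2, 3))
  expect_length(cl, 16)
  got <- cl[order(vapply(cl, `[[`, numeric(1), "mono_mz"))]
  expect_equal(vapply(got, `[[`, numeric(1), "z"), as.numeric(zs))
  expect_equal(vapply(got, `[[`, numeric(1), "mono_mz"), monos,
               tolerance = 1e-9)
})
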