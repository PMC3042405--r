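#' Deconvolute an m/z value to the protonated monoisotopic mass MH+
#'
#' An ion observed at `mz` with charge `z` carries `z` protons; removing
#' `z - 1` of them gives the singly protonated mass:
#' MH+ = z * mz - (z - 1) * proton.
#'
#' @param mz Observed mass-over-charge (Da/charge).
#' @param z Integer charge state, >= 1.
#' @return MH+ in Da.
#' @export
#' @examples
#' mh_from_mz(872.03, 2)   # 1743.0527
#' mh_from_mz(581.69, 3)   # 1743.0555
mh_from_mz <- function(mz, z) {
  if (any(z < 1)) stop("charge z must be >= 1")
  z * mz - (z - 1) * mass_constants()$proton
}

#' Inverse of [mh_from_mz()]: expected m/z of MH+ at charge z
#'
#' @inheritParams mh_from_mz
#' @param mh Protonated monoisotopic mass (Da).
#' @return m/z in Da/charge.
#' @export
mz_from_mh <- function(mh, z) {
  if (any(z < 1)) stop("charge z must be >= 1")
  (mh + (z - 1) * mass_constants()$proton) / z
}

# distribution of total neutron shift for n atoms of one element;
# props[1] is the light isotope, props[k] the (k-1)-neutron isotope
.iso_dist_element <- function(props, n, kmax) {
  out <- numeric(kmax + 1L)
  nheavy <- length(props) - 1L
  if (n == 0L || nheavy == 0L) {
    out[1L] <- 1
    return(out)
  }
  # enumerate counts of each heavy isotope; shifts beyond kmax are truncated
  rec <- function(iso, left, shift, logp, coef_n) {
    if (iso > nheavy) {
      out[shift + 1L] <<- out[shift + 1L] + exp(logp + left * log(props[1L]))
      return(invisible())
    }
    maxc <- if (props[iso + 1L] > 0) min(left, (kmax - shift) %/% iso) else 0L
    for (cnt in 0:maxc) {
      lp <- logp + lchoose(coef_n, cnt) + cnt * log(max(props[iso + 1L], .Machine$double.xmin))
      if (cnt > 0 && props[iso + 1L] == 0) next
      rec(iso + 1L, left - cnt, shift + iso * cnt, lp, coef_n - cnt)
    }
  }
  # lchoose over remaining atoms: multinomial coefficient built incrementally
  rec(1L, n, 0L, 0, n)
  out / sum(out)
}

.ELEMENT_ABUNDANCE <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0.0001)
)

# averagine composition per 111.1254 Da of peptide
.AVERAGINE_UNIT <- c(C = 4.9384, H = 7.7583, N = 1.3577, O = 1.4773, S = 0.0417)
.AVERAGINE_MASS <- 111.1254

#' Expected isotopic intensity envelope of a peptide-like molecule
#'
#' Predicts the relative abundances of the first `n_isotopes` members of an
#' isotopic cluster for a peptide of the given neutral mass, using the
#' averagine model: the mass is converted to an average elemental composition
#' (C 4.9384, H 7.7583, N 1.3577, O 1.4773, S 0.0417 per 111.1254 Da, counts
#' rounded), whose isotope distribution is obtained by convolving the
#' per-element isotope distributions.
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (> 0).
#' @param n_isotopes Number of envelope members to return.
#' @return Numeric vector of length `n_isotopes`, normalized to max = 1.
#' @export
#' @examples
#' averagine_envelope(1742, 4)
averagine_envelope <- function(neutral_mass, n_isotopes = 6L) {
  stopifnot(neutral_mass > 0, n_isotopes >= 1)
  units <- neutral_mass / .AVERAGINE_MASS
  counts <- pmax(round(.AVERAGINE_UNIT * units), 0)
  kmax <- n_isotopes - 1L
  env <- c(1, rep(0, kmax))
  for (el in names(counts)) {
    d <- .iso_dist_element(.ELEMENT_ABUNDANCE[[el]], as.integer(counts[[el]]), kmax)
    env <- sapply(0:kmax, function(k) sum(env[1:(k + 1L)] * d[(k + 1L):1L]))
  }
  env / max(env)
}

#' Find isotopic clusters in a centroided scan and assign charge states
#'
#' Greedy, intensity-descending seeding: the most intense unassigned peak
#' seeds a candidate cluster; for each candidate charge the isotope ladder
#' (spacing 1.0033548/z Da) is walked down to locate the mono-isotope and up
#' to collect members within the ppm tolerance. Observed member intensities
#' are scored against the averagine envelope by normalized dot product; the
#' best-scoring charge is accepted when the score reaches `min_score` and the
#' cluster has at least two members. Accepted members are consumed and cannot
#' join later clusters. Ties between equally intense seeds are broken by
#' lower m/z; equal scores go to the lower charge.
#'
#' @param scan A `centroid_scan` (see [centroid_spectrum()]).
#' @param charges Integer charge states to consider. The default excludes
#'   singly charged ions; pass `1:5` to include them.
#' @param ppm_tol Position tolerance in ppm for isotope members.
#' @param min_score Minimum envelope score in `[0, 1]`.
#' @param max_isotopes Maximum envelope members collected per cluster.
#' @return List of clusters, each a list with `z`, `mono_mz`, `member_mz`,
#'   `member_intensity`, `envelope_score`.
#' @export
find_isotope_clusters <- function(scan, charges = c(2L, 3L, 4L, 5L),
                                  ppm_tol = 10, min_score = 0.7,
                                  max_isotopes = 6L) {
  pk <- scan$peaks
  n <- nrow(pk)
  if (is.null(n) || n < 2L) return(list())
  mz <- pk$mz
  int <- pk$intensity
  delta <- mass_constants()$isotope_spacing
  proton <- mass_constants()$proton
  consumed <- logical(n)
  charges <- sort(unique(as.integer(charges)))

  # nearest unconsumed peak to target within tol, -1 if none
  near <- function(target, tol) {
    i <- findInterval(target, mz)
    best <- -1L; bestd <- tol
    for (j in c(i, i + 1L)) {
      if (j >= 1L && j <= n && !consumed[j]) {
        d <- abs(mz[j] - target)
        if (d <= bestd) { bestd <- d; best <- j }
      }
    }
    best
  }

  seed_order <- order(-int, mz)
  clusters <- list()
  for (s in seed_order) {
    if (consumed[s]) next
    best <- NULL
    for (z in charges) {
      step <- delta / z
      tol <- ppm_tol * 1e-6 * mz[s]
      # walk down to the mono-isotope
      mono <- s
      repeat {
        j <- near(mz[mono] - step, tol)
        if (j < 0L || j == mono) break
        mono <- j
      }
      # walk up collecting members
      members <- mono
      cur <- mono
      while (length(members) < max_isotopes) {
        j <- near(mz[cur] + step, tol)
        if (j < 0L || j == cur) break
        members <- c(members, j)
        cur <- j
      }
      if (length(members) < 2L || !(s %in% members)) next
      obs <- int[members]
      env <- averagine_envelope((mz[mono] - proton) * z, length(members))
      score <- sum(obs * env) / sqrt(sum(obs^2) * sum(env^2))
      if (score >= min_score && (is.null(best) || score > best$envelope_score)) {
        best <- list(z = z, mono_mz = mz[mono], member_idx = members,
                     member_mz = mz[members], member_intensity = obs,
                     envelope_score = score)
      }
    }
    if (!is.null(best)) {
      consumed[best$member_idx] <- TRUE
      best$member_idx <- NULL
      clusters[[length(clusters) + 1L]] <- best
    }
  }
  clusters
}

#' Convert an isotopic cluster to a mono-isotopic ion record
#'
#' The quantity of record is the mono-isotope: its m/z is deconvoluted to MH+
#' and its centroid intensity becomes the ion's apex intensity.
#'
#' @param cluster A cluster from [find_isotope_clusters()].
#' @param scan The `centroid_scan` the cluster was found in (provides scan id
#'   and retention time).
#' @return One-row data frame with columns `mh`, `z`, `intensity`, `scan_id`,
#'   `rt`.
#' @export
cluster_to_ion <- function(cluster, scan) {
  data.frame(
    mh = mh_from_mz(cluster$mono_mz, cluster$z),
    z = cluster$z,
    intensity = cluster$member_intensity[1L],
    scan_id = scan$scan_id,
    rt = scan$rt
  )
}

#' Deisotope one centroided scan to mono-isotopic ions
#'
#' Convenience wrapper: [find_isotope_clusters()] followed by
#' [cluster_to_ion()] for every accepted cluster.
#'
#' @inheritParams find_isotope_clusters
#' @return Data frame of ions (possibly 0 rows) with columns `mh`, `z`,
#'   `intensity`, `scan_id`, `rt`.
#' @export
deisotope_scan <- function(scan, charges = c(2L, 3L, 4L, 5L), ppm_tol = 10,
                           min_score = 0.7, max_isotopes = 6L) {
  cl <- find_isotope_clusters(scan, charges, ppm_tol, min_score, max_isotopes)
  if (!length(cl)) {
    return(data.frame(mh = numeric(), z = integer(), intensity = numeric(),
                      scan_id = integer(), rt = numeric()))
  }
  do.call(rbind, lapply(cl, cluster_to_ion, scan = scan))
}

#' Theoretical protonated monoisotopic peptide mass
#'
#' Sums monoisotopic residue masses over the sequence and adds one water
#' (terminal H and OH) and one proton, plus any methionine oxidations
#' (+15.9994 Da each).
#'
#' @param sequence Peptide sequence in standard one-letter code.
#' @param n_oxidations Number of oxidized methionines.
#' @return MH+ in Da.
#' @export
#' @examples
#' peptide_mh("DSTYSLSSTLTLSK")  # 1502.75845
peptide_mh <- function(sequence, n_oxidations = 0L) {
  aa <- strsplit(toupper(sequence), "")[[1L]]
  bad <- setdiff(aa, names(.RESIDUE_MASS))
  if (length(bad)) {
    stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "))
  }
  k <- mass_constants()
  sum(.RESIDUE_MASS[aa]) + k$water + k$proton + n_oxidations * k$oxidation_m
}
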