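#' Construct a single MS spectrum
#'
#' @param scan_id Integer scan number (>= 1).
#' @param rt Retention time in seconds.
#' @param mz Numeric vector of m/z values; sorted increasing on construction.
#' @param intensity Nonnegative intensities, same length as `mz`.
#' @param ms_level 1 for full scans, 2 for fragmentation scans.
#' @param centroided Whether the arrays are already centroided.
#' @return An `ms_spectrum` object.
#' @export
ms_spectrum <- function(scan_id, rt, mz, intensity, ms_level = 1L,
                        centroided = TRUE) {
  stopifnot(length(mz) == length(intensity), all(intensity >= 0), rt >= 0)
  o <- order(mz)
  structure(list(scan_id = as.integer(scan_id), rt = as.numeric(rt),
                 ms_level = as.integer(ms_level), mz = mz[o],
                 intensity = intensity[o], centroided = isTRUE(centroided)),
            class = "ms_spectrum")
}

#' Construct an LC-MS run from spectra
#'
#' @param run_id Run identifier.
#' @param spectra List of `ms_spectrum`; sorted by retention time.
#' @param gradient_length Optional gradient length in seconds.
#' @return An `ms_run` object.
#' @export
ms_run <- function(run_id, spectra, gradient_length = NA_real_) {
  rts <- vapply(spectra, `[[`, numeric(1), "rt")
  spectra <- spectra[order(rts)]
  structure(list(run_id = run_id, spectra = spectra,
                 gradient_length = gradient_length),
            class = "ms_run")
}

#' @export
print.ms_run <- function(x, ...) {
  lv <- vapply(x$spectra, `[[`, integer(1), "ms_level")
  cat(sprintf("<ms_run '%s': %d spectra (%d MS1, %d MS2)>\n", x$run_id,
              length(x$spectra), sum(lv == 1L), sum(lv == 2L)))
  invisible(x)
}

#' Read an LC-MS run from an mzML or mzXML file
#'
#' Parsing is delegated to mzR (proteowizard). Because that backend silently
#' tolerates files truncated before their closing tags, the file is first
#' checked for XML well-formedness; a malformed file raises a parse error
#' that names the last scan successfully declared, rather than returning a
#' silently truncated run. Retention times are exposed in seconds.
#'
#' @param path Path to an mzML or mzXML file.
#' @param ms_level_filter Keep only spectra of this MS level (`NULL` keeps
#'   all). Default 1 (profiling works on full scans).
#' @return An `ms_run`.
#' @export
read_run <- function(path, ms_level_filter = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  ok <- tryCatch({ xml2::read_xml(path); TRUE }, error = function(e) e)
  if (!isTRUE(ok)) {
    txt <- readLines(path, warn = FALSE)
    scans <- regmatches(txt, regexpr('scan=[0-9]+|num="[0-9]+"', txt))
    last <- if (length(scans)) utils::tail(scans, 1) else "none"
    stop(sprintf("parse error in '%s' (last scan declaration seen: %s): %s",
                 path, last, conditionMessage(ok)))
  }
  fh <- tryCatch(mzR::openMSfile(path),
                 error = function(e) stop("parse error in '", path, "': ",
                                          conditionMessage(e)))
  on.exit(mzR::close(fh), add = TRUE)
  hd <- mzR::header(fh)
  keep <- if (is.null(ms_level_filter)) seq_len(nrow(hd)) else
    which(hd$msLevel == ms_level_filter)
  if (!length(keep)) {
    stop("no spectra", if (!is.null(ms_level_filter))
      paste0(" at MS level ", ms_level_filter), " in '", path, "'")
  }
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)
  spectra <- lapply(keep, function(i) {
    m <- pk[[i]]
    ms_spectrum(scan_id = hd$acquisitionNum[i], rt = hd$retentionTime[i],
                mz = m[, 1L], intensity = m[, 2L], ms_level = hd$msLevel[i],
                centroided = isTRUE(hd$centroided[i]))
  })
  ms_run(run_id = sub("\\.(mzML|mzXML)$", "", basename(path),
                      ignore.case = TRUE),
         spectra = spectra)
}

#' Write an LC-MS run as mzML
#'
#' Thin wrapper around `mzR::writeMSData()`, used mainly to materialize
#' simulated runs for round-trip and pipeline tests.
#'
#' @param run An `ms_run`.
#' @param path Output path (`.mzML`).
#' @return `path`, invisibly.
#' @export
write_run_mzml <- function(run, path) {
  ns <- length(run$spectra)
  stopifnot(ns >= 1L)
  pks <- lapply(run$spectra, function(s)
    cbind(mz = s$mz, intensity = s$intensity))
  na <- rep(NA_real_, ns)
  hd <- data.frame(
    seqNum = seq_len(ns),
    acquisitionNum = vapply(run$spectra, `[[`, integer(1), "scan_id"),
    msLevel = vapply(run$spectra, `[[`, integer(1), "ms_level"),
    polarity = rep(1L, ns),
    peaksCount = vapply(pks, nrow, integer(1)),
    totIonCurrent = vapply(run$spectra, function(s) sum(s$intensity), numeric(1)),
    retentionTime = vapply(run$spectra, `[[`, numeric(1), "rt"),
    basePeakMZ = vapply(run$spectra, function(s)
      if (length(s$mz)) s$mz[which.max(s$intensity)] else 0, numeric(1)),
    basePeakIntensity = vapply(run$spectra, function(s)
      if (length(s$intensity)) max(s$intensity) else 0, numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(run$spectra, function(s)
      if (length(s$mz)) min(s$mz) else 0, numeric(1)),
    highMZ = vapply(run$spectra, function(s)
      if (length(s$mz)) max(s$mz) else 0, numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = sprintf("scan=%d",
                         vapply(run$spectra, `[[`, integer(1), "scan_id")),
    centroided = vapply(run$spectra, `[[`, logical(1), "centroided"),
    ionMobilityDriftTime = na,
    isolationWindowTargetMZ = na, isolationWindowLowerOffset = na,
    isolationWindowUpperOffset = na,
    scanWindowLowerLimit = na, scanWindowUpperLimit = na
  )
  mzR::writeMSData(pks, file = path, header = hd, outformat = "mzml")
  invisible(path)
}

#' Read precursor records from a Mascot generic file (MGF)
#'
#' Each `BEGIN IONS`/`END IONS` block yields one record with the precursor
#' m/z (first PEPMASS token), charge (from CHARGE, e.g. `2+`), and scan
#' reference (TITLE or SCANS). Blocks without a CHARGE line get `z = NA` and
#' are flagged.
#'
#' @param path Path to an MGF file.
#' @return Data frame with columns `mz`, `z`, `scan_ref`, `identified`,
#'   `charge_missing`; zero rows for an empty file.
#' @export
read_mgf_precursors <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  empty <- data.frame(mz = numeric(), z = integer(), scan_ref = character(),
                      identified = logical(), charge_missing = logical())
  if (!length(lines)) return(empty)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins)) {
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS (block ",
         length(ends) + 1L, ")")
  }
  if (!length(begins)) return(empty)
  recs <- lapply(seq_along(begins), function(b) {
    blk <- lines[(begins[b] + 1L):(ends[b] - 1L)]
    getval <- function(key) {
      hit <- grep(paste0("^", key, "="), blk, value = TRUE)
      if (length(hit)) sub(paste0("^", key, "="), "", hit[1L]) else NA_character_
    }
    pep <- getval("PEPMASS")
    if (is.na(pep)) stop("malformed MGF block ", b, ": missing PEPMASS")
    mz <- suppressWarnings(as.numeric(strsplit(pep, "[ \t]+")[[1L]][1L]))
    if (is.na(mz)) stop("malformed MGF block ", b, ": unparseable PEPMASS")
    ch <- getval("CHARGE")
    z <- if (is.na(ch)) NA_integer_ else
      suppressWarnings(as.integer(sub("^([0-9]+)[+-]?$", "\\1", ch)))
    ref <- getval("TITLE")
    if (is.na(ref)) ref <- getval("SCANS")
    data.frame(mz = mz, z = z,
               scan_ref = if (is.na(ref)) paste0("block", b) else ref,
               identified = FALSE, charge_missing = is.na(ch))
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

.pm_colnames <- function(sample_ids) {
  c("MH+", "time (s)",
    paste("Peak intensity in sample", sample_ids),
    paste("Peptide present in sample", sample_ids),
    "Total count of peptides")
}

#' Write a peptide profile matrix as tab-separated text
#'
#' Column layout: MH+, time (s), one peak-intensity column per sample, one
#' 0/1 presence column per sample, and the total count of samples the
#' peptide was detected in. Missing cells are written as 0.
#'
#' @param matrix A `profile_matrix` (see [build_matrix()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "profile_matrix"))
  df <- cbind(
    data.frame(mh = matrix$mh, rt = matrix$rt_ref, check.names = FALSE),
    as.data.frame(matrix$intensities),
    as.data.frame(matrix$presence),
    data.frame(total = matrix$total_count)
  )
  names(df) <- .pm_colnames(matrix$sample_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a peptide profile matrix written by [write_profile_matrix()]
#'
#' @param path Path to the tab-separated file.
#' @return A `profile_matrix`.
#' @export
read_profile_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, fileEncoding = "UTF-8")
  nc <- ncol(df)
  if (nc < 5L || (nc - 3L) %% 2L != 0L) {
    stop("layout error: expected 3 + 2*n_samples columns, got ", nc)
  }
  ns <- (nc - 3L) %/% 2L
  icols <- 2L + seq_len(ns)
  pcols <- 2L + ns + seq_len(ns)
  ids <- sub("^Peak intensity in sample ", "", names(df)[icols])
  expected <- .pm_colnames(ids)
  if (!identical(names(df), expected)) {
    stop("layout error: column headers do not match the profile-matrix layout")
  }
  new_profile_matrix(
    sample_ids = ids,
    mh = df[[1L]], rt_ref = df[[2L]],
    intensities = as.matrix(df[icols]),
    mass_window_ppm = NA_real_, time_window_s = NA_real_
  )
}

.cm_colnames <- function(sources) {
  c("Mass MH+", "ms2 triggered", "ms2 sequenced", sources)
}

#' Write a comparison matrix as tab-separated text
#'
#' Column layout: grid mass MH+, binary ms2-triggered, binary ms2-sequenced,
#' then one summed-intensity column per source list. All grid rows are
#' written, including all-zero ones.
#'
#' @param cm A `comparison_matrix` (see [build_comparison_matrix()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "comparison_matrix"))
  df <- cbind(
    data.frame(mass = cm$grid$masses, t = cm$ms2_triggered,
               s = cm$ms2_identified, check.names = FALSE),
    as.data.frame(cm$cells)
  )
  names(df) <- .cm_colnames(cm$sources)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a comparison matrix written by [write_comparison_matrix()]
#'
#' @param path Path to the tab-separated file.
#' @return A `comparison_matrix`. The grid is reconstructed from the mass
#'   column (its bounds and the constant neighbor ratio).
#' @export
read_comparison_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 4L) stop("layout error: expected >= 4 columns, got ", ncol(df))
  if (!identical(names(df)[1:3], .cm_colnames(character())[1:3])) {
    stop("layout error: column headers do not match the comparison-matrix layout")
  }
  masses <- df[[1L]]
  step_ppm <- (masses[2L] / masses[1L] - 1) * 1e6
  grid <- structure(list(lo = masses[1L], hi = masses[length(masses)],
                         step_ppm = step_ppm, masses = masses),
                    class = "mass_grid")
  sources <- names(df)[-(1:3)]
  cells <- as.matrix(df[-(1:3)])
  dimnames(cells) <- list(NULL, sources)
  structure(list(grid = grid, sources = sources, cells = cells,
                 ms2_triggered = as.integer(df[[2L]]),
                 ms2_identified = as.integer(df[[3L]])),
            class = "comparison_matrix")
}
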