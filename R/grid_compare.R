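#' Build a fixed-ppm reference mass grid
#'
#' The grid starts at `lo`; each successive mass is the previous one
#' multiplied by `1 + step_ppm * 1e-6`. Generation stops at the first mass
#' that reaches or exceeds `hi`, and that terminal mass IS included. Under
#' this endpoint convention the grid size is
#' `floor(log(hi/lo) / log(1 + step_ppm*1e-6)) + 2`; the default 1600-2400 Da
#' range at 20 ppm yields 20,275 grid masses.
#'
#' @param lo,hi Mass range bounds in Da (`lo < hi`).
#' @param step_ppm Spacing between neighboring grid masses in ppm.
#' @return A `mass_grid`: list with `lo`, `hi`, `step_ppm`, `masses`.
#' @export
#' @examples
#' length(make_grid()$masses)  # 20275
make_grid <- function(lo = 1600, hi = 2400, step_ppm = 20) {
  if (lo >= hi) stop("domain error: lo must be < hi")
  if (step_ppm <= 0) stop("domain error: step_ppm must be > 0")
  r <- 1 + step_ppm * 1e-6
  n <- floor(log(hi / lo) / log(r)) + 2
  masses <- cumprod(c(lo, rep(r, n - 1L)))
  structure(list(lo = lo, hi = hi, step_ppm = step_ppm, masses = masses),
            class = "mass_grid")
}

#' @export
print.mass_grid <- function(x, ...) {
  cat(sprintf("<mass_grid: %d masses, %.6g-%.6g Da, %g ppm spacing>\n",
              length(x$masses), x$lo, x$hi, x$step_ppm))
  invisible(x)
}

# index of the nearest grid mass for each input mass (NA when out of range)
.grid_index <- function(masses, grid, tol_ppm) {
  gm <- grid$masses
  n <- length(gm)
  lo_ok <- gm[1L] * (1 - tol_ppm * 1e-6)
  hi_ok <- gm[n] * (1 + tol_ppm * 1e-6)
  idx <- rep(NA_integer_, length(masses))
  inr <- masses >= lo_ok & masses <= hi_ok
  if (any(inr)) {
    k <- findInterval(masses[inr], gm, all.inside = TRUE)
    up <- abs(gm[k + 1L] - masses[inr]) < abs(gm[k] - masses[inr])
    idx[inr] <- k + up
  }
  idx
}

#' Project a mass-intensity list onto a reference grid
#'
#' Each input mass is assigned to its single nearest grid point (guaranteed
#' within the matching tolerance when the grid spacing equals twice the
#' tolerance); masses colliding on one grid point have their intensities
#' summed. Inputs outside the grid range (plus tolerance) are ignored and
#' counted.
#'
#' @param masses Input masses (Da).
#' @param intensities Matching intensities (default all 1, for binary lists).
#' @param grid A `mass_grid`.
#' @param tol_ppm Matching window in ppm.
#' @return Numeric vector of summed intensities, one per grid mass, with
#'   attribute `n_ignored` (number of out-of-range inputs).
#' @export
project_onto_grid <- function(masses, intensities = rep(1, length(masses)),
                              grid, tol_ppm = 10) {
  stopifnot(length(masses) == length(intensities))
  col <- numeric(length(grid$masses))
  idx <- .grid_index(masses, grid, tol_ppm)
  ok <- !is.na(idx)
  if (any(ok)) {
    agg <- rowsum(intensities[ok], group = idx[ok])
    col[as.integer(rownames(agg))] <- agg[, 1L]
  }
  attr(col, "n_ignored") <- sum(!ok)
  col
}

#' Assemble a comparison matrix from several mass lists
#'
#' Every source list is projected onto the grid; MS2-triggered and
#' MS2-identified mass lists become binary indicator columns.
#'
#' @param grid A `mass_grid`.
#' @param sources Named list; each element a data frame (or list) with
#'   `mass` and `intensity`.
#' @param ms2_triggered,ms2_identified Optional numeric vectors of MH+
#'   masses.
#' @param tol_ppm Matching window in ppm.
#' @return A `comparison_matrix`: list with `grid`, `sources`, `cells`
#'   (grid x source intensity matrix), `ms2_triggered`, `ms2_identified`.
#' @export
build_comparison_matrix <- function(grid, sources, ms2_triggered = NULL,
                                    ms2_identified = NULL, tol_ppm = 10) {
  stopifnot(length(sources) >= 1L, !is.null(names(sources)))
  cells <- vapply(sources, function(s)
    project_onto_grid(s$mass, s$intensity, grid, tol_ppm),
    numeric(length(grid$masses)))
  binary <- function(m) {
    if (is.null(m)) return(integer(length(grid$masses)))
    as.integer(project_onto_grid(m, grid = grid, tol_ppm = tol_ppm) > 0)
  }
  structure(list(grid = grid, sources = names(sources), cells = cells,
                 ms2_triggered = binary(ms2_triggered),
                 ms2_identified = binary(ms2_identified)),
            class = "comparison_matrix")
}

#' @export
print.comparison_matrix <- function(x, ...) {
  cat(sprintf("<comparison_matrix: %d grid masses x %d sources (%s)>\n",
              length(x$grid$masses), length(x$sources),
              paste(x$sources, collapse = ", ")))
  invisible(x)
}

#' Pairwise overlap of two sources in a comparison matrix
#'
#' @param cm A `comparison_matrix`.
#' @param source_a,source_b Source names.
#' @return Named integer vector `n_a`, `n_b`, `n_both`: grid points nonzero
#'   in A, in B, and in both.
#' @export
pairwise_overlap <- function(cm, source_a, source_b) {
  a <- cm$cells[, source_a] > 0
  b <- cm$cells[, source_b] > 0
  c(n_a = sum(a), n_b = sum(b), n_both = sum(a & b))
}

#' K-way Venn membership counts over comparison-matrix sources
#'
#' Every grid point nonzero in at least one of the chosen sources is counted
#' in exactly one membership pattern (the set of sources it appears in); the
#' patterns partition the occupied grid points.
#'
#' @param cm A `comparison_matrix`.
#' @param sources Source names (default: all).
#' @return Named integer vector; names are membership patterns like
#'   `"A+B"`, values the number of grid points.
#' @export
venn_counts <- function(cm, sources = cm$sources) {
  pres <- cm$cells[, sources, drop = FALSE] > 0
  occ <- rowSums(pres) > 0
  if (!any(occ)) return(stats::setNames(integer(0), character(0)))
  pat <- apply(pres[occ, , drop = FALSE], 1L, function(r)
    paste(sources[r], collapse = "+"))
  tab <- table(pat)
  stats::setNames(as.integer(tab), names(tab))
}

#' Grid-point multiplicity and window-edge split diagnostics
#'
#' Reports how many grid points were matched by 1, 2, 3, ... input masses,
#' and how many input masses lie close enough to TWO grid points (within
#' `tol_ppm` of both, possible at window edges since the grid spacing is
#' twice the tolerance) that different tools could bin them differently.
#'
#' @param masses Input masses (Da).
#' @param grid A `mass_grid`.
#' @param tol_ppm Matching window in ppm.
#' @return List with `multiplicity` (named integer vector: multiplicity ->
#'   number of grid points) and `n_split` (inputs within tolerance of two
#'   grid points).
#' @export
split_multiplicity_report <- function(masses, grid, tol_ppm = 10) {
  idx <- .grid_index(masses, grid, tol_ppm)
  ok <- !is.na(idx)
  if (!any(ok)) return(list(multiplicity = stats::setNames(integer(0),
                                                           character(0)),
                            n_split = 0L))
  mult <- table(table(idx[ok]))
  gm <- grid$masses
  second_ok <- vapply(which(ok), function(i) {
    k <- idx[i]
    neigh <- c(if (k > 1L) gm[k - 1L], if (k < length(gm)) gm[k + 1L])
    any(abs(neigh - masses[i]) <= tol_ppm * 1e-6 * masses[i])
  }, logical(1))
  list(multiplicity = stats::setNames(as.integer(mult), names(mult)),
       n_split = sum(second_ok))
}
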