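#' Replicate coefficients of variation of a profile matrix
#'
#' For every row present in all samples (optionally all rows with >= 2
#' observations), the CV is 100 * sd / mean of the replicate intensities
#' (sample standard deviation, n-1 denominator). The relative intensity
#' log10(I / Imax) uses the row mean and the largest row mean in the matrix,
#' so the most intense peptide sits at 0 and everything else below.
#'
#' @param matrix A `profile_matrix` with >= 2 samples.
#' @param require_full_presence If `TRUE` (default) only rows detected in
#'   every sample enter; otherwise zeros are dropped per row and rows with
#'   >= 2 nonzero intensities are used.
#' @return Data frame with columns `mh`, `rel_log_intensity` (<= 0), `cv`
#'   (percent).
#' @export
replicate_cv <- function(matrix, require_full_presence = TRUE) {
  ns <- length(matrix$sample_ids)
  if (ns < 2L) stop("need at least 2 samples to compute replicate CVs")
  keep <- if (require_full_presence) matrix$total_count == ns else
    matrix$total_count >= 2L
  idx <- which(keep)
  if (!length(idx)) {
    return(data.frame(mh = numeric(), rel_log_intensity = numeric(),
                      cv = numeric()))
  }
  stats_row <- t(vapply(idx, function(i) {
    v <- matrix$intensities[i, ]
    if (!require_full_presence) v <- v[v > 0]
    c(mean(v), stats::sd(v))
  }, numeric(2)))
  mn <- stats_row[, 1L]
  data.frame(mh = matrix$mh[idx],
             rel_log_intensity = log10(mn / max(mn)),
             cv = 100 * stats_row[, 2L] / mn)
}

#' Median CV per relative-intensity bin
#'
#' Bins the [replicate_cv()] records over `[min, 0]` in steps of `bin_width`
#' log10 units and reports the median CV per populated bin; empty bins are
#' absent from the output, not zero.
#'
#' @param records Data frame from [replicate_cv()].
#' @param bin_width Bin width in log10 units.
#' @return Data frame with columns `bin_lo`, `bin_hi`, `median_cv`, `n`.
#' @export
cv_vs_intensity_profile <- function(records, bin_width = 0.5) {
  if (!nrow(records)) {
    return(data.frame(bin_lo = numeric(), bin_hi = numeric(),
                      median_cv = numeric(), n = integer()))
  }
  lo <- floor(min(records$rel_log_intensity) / bin_width) * bin_width
  br <- seq(lo, 0, by = bin_width)
  if (br[length(br)] < 0) br <- c(br, 0)
  bin <- cut(records$rel_log_intensity, br, include.lowest = TRUE)
  keep <- !is.na(bin)
  agg <- tapply(records$cv[keep], bin[keep], stats::median)
  cnt <- tapply(rep(1L, sum(keep)), bin[keep], sum)
  pop <- which(!is.na(agg))
  data.frame(bin_lo = br[pop], bin_hi = br[pop + 1L],
             median_cv = as.numeric(agg[pop]), n = as.integer(cnt[pop]))
}

#' Two-sided Wilcoxon-Mann-Whitney test with direction
#'
#' For small samples (m + n <= `exact_limit`) the two-sided p-value is
#' computed by exact enumeration of the rank-sum statistic over all
#' C(m+n, m) group assignments, using midranks for ties; otherwise the
#' normal approximation with tie correction and continuity correction is
#' used. The direction reports which group's intensities predominate (larger
#' mean rank).
#'
#' @param xs,ys Numeric intensity vectors of groups A and B (non-empty).
#' @param exact_limit Largest m + n for exact enumeration.
#' @return List with `p` (in (0, 1]) and `direction` (`"A"`, `"B"` or
#'   `"tie"`).
#' @export
#' @examples
#' wmw_test(c(1, 2, 3), c(4, 5, 6))$p  # 0.1
wmw_test <- function(xs, ys, exact_limit = 12L) {
  m <- length(xs); n <- length(ys)
  if (!m || !n) stop("both groups must be non-empty")
  N <- m + n
  r <- rank(c(xs, ys))
  W <- sum(r[seq_len(m)])
  mu <- m * (N + 1) / 2
  direction <- if (W / m > (sum(r) - W) / n) "A" else
    if (W / m < (sum(r) - W) / n) "B" else "tie"
  if (N <= exact_limit) {
    combs <- utils::combn(N, m)
    tstat <- colSums(matrix(r[combs], nrow = m))
    p <- mean(abs(tstat - mu) >= abs(W - mu) - 1e-9)
  } else {
    ties <- table(r)
    sig2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (abs(W - mu) - 0.5) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
  }
  list(p = min(1, max(p, .Machine$double.xmin)), direction = direction)
}

#' Per-row two-group profiling of a profile matrix
#'
#' Runs [wmw_test()] on every matrix row, comparing the intensities of the
#' two sample groups (zeros, i.e. absent peptides, enter as intensity 0 by
#' default, matching the idea that predominant presence itself is signal),
#' and bins the p-values into a directional histogram.
#'
#' @param matrix A `profile_matrix`.
#' @param labels_a,labels_b Sample ids (or column indices) of groups A and B.
#' @param p_bin_width Width of the p-value histogram bins.
#' @param drop_zeros If `TRUE`, zero cells are removed before testing (rows
#'   where either group empties out are skipped).
#' @return List with `results` (data frame `mh`, `rt_ref`, `p`, `direction`)
#'   and `histogram` (data frame `bin_lo`, `bin_hi`, `n_total`, `n_a`,
#'   `n_b`).
#' @export
group_profile <- function(matrix, labels_a, labels_b, p_bin_width = 0.05,
                          drop_zeros = FALSE) {
  ia <- if (is.numeric(labels_a)) labels_a else
    match(labels_a, matrix$sample_ids)
  ib <- if (is.numeric(labels_b)) labels_b else
    match(labels_b, matrix$sample_ids)
  if (anyNA(ia) || anyNA(ib)) stop("unknown sample labels")
  res <- lapply(seq_along(matrix$mh), function(i) {
    xs <- matrix$intensities[i, ia]
    ys <- matrix$intensities[i, ib]
    if (drop_zeros) {
      xs <- xs[xs > 0]; ys <- ys[ys > 0]
      if (!length(xs) || !length(ys)) return(NULL)
    }
    t <- wmw_test(xs, ys)
    data.frame(mh = matrix$mh[i], rt_ref = matrix$rt_ref[i], p = t$p,
               direction = t$direction)
  })
  res <- do.call(rbind, res)
  list(results = res, histogram = .p_histogram(res, p_bin_width))
}

.p_histogram <- function(res, p_bin_width = 0.05) {
  br <- seq(0, 1, by = p_bin_width)
  if (br[length(br)] < 1) br <- c(br, 1)
  bin <- function(p) cut(p, br, include.lowest = FALSE)
  h <- data.frame(bin_lo = br[-length(br)], bin_hi = br[-1L])
  if (is.null(res) || !nrow(res)) {
    h$n_total <- 0L; h$n_a <- 0L; h$n_b <- 0L
    return(h)
  }
  all_b <- bin(res$p)
  h$n_total <- as.integer(table(all_b))
  h$n_a <- as.integer(table(bin(res$p[res$direction == "A"])))
  h$n_b <- as.integer(table(bin(res$p[res$direction == "B"])))
  h
}

#' Label-randomization baseline for the p-value histogram
#'
#' Repeats the group comparison under `n_rounds` random reassignments of the
#' sample labels (distinct assignments, sampled without replacement where
#' the label space allows it) and averages the resulting p-value histograms.
#' Any low-p excess of the observed histogram over this baseline indicates
#' real differential signal.
#'
#' @param matrix A `profile_matrix`.
#' @param n_a,n_b Group sizes (must sum to the number of samples).
#' @param n_rounds Number of randomization rounds.
#' @param seed Integer seed (mandatory, for reproducibility).
#' @param p_bin_width Histogram bin width.
#' @return List with `bin_lo`, `bin_hi`, `mean_counts` (per-bin average over
#'   rounds), `n_rounds`, `seed`.
#' @export
randomization_baseline <- function(matrix, n_a, n_b, n_rounds = 10L, seed,
                                   p_bin_width = 0.05) {
  ns <- length(matrix$sample_ids)
  if (n_a + n_b != ns) {
    stop("group sizes (", n_a, " + ", n_b, ") inconsistent with ", ns,
         " samples")
  }
  if (missing(seed)) stop("seed is required")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  seen <- character(0)
  counts <- NULL
  max_distinct <- choose(ns, n_a)
  for (r in seq_len(n_rounds)) {
    tries <- 0L
    repeat {
      ia <- sort(sample.int(ns, n_a))
      key <- paste(ia, collapse = ",")
      tries <- tries + 1L
      if (!(key %in% seen) || length(seen) >= max_distinct ||
          tries > 100L) break
    }
    seen <- c(seen, key)
    gp <- group_profile(matrix, ia, setdiff(seq_len(ns), ia),
                        p_bin_width = p_bin_width)
    counts <- rbind(counts, gp$histogram$n_total)
  }
  h <- .p_histogram(NULL, p_bin_width)
  list(bin_lo = h$bin_lo, bin_hi = h$bin_hi,
       mean_counts = colMeans(counts), n_rounds = n_rounds, seed = seed)
}
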