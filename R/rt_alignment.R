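#' Construct a retention-time drift model
#'
#' The inter-run drift is modeled as an amplitude decaying exponentially with
#' retention time past the mobile-phase dead time:
#' `dt(tr) = A * exp(-c * (tr - tm))`. The decay rate is a single composite
#' constant: its physical constituents (capacity-factor difference, gradient
#' slope) never appear separately in any computation and would not be
#' identifiable from anchor pairs.
#'
#' @param A Drift amplitude at `tr = tm`, seconds.
#' @param c Decay rate, 1/seconds (>= 0).
#' @param tm Mobile-phase dead time, seconds (default 120 s, approximately
#'   2 min).
#' @return An `rt_model` object.
#' @export
rt_model <- function(A, c, tm = 120) {
  stopifnot(is.finite(A), c >= 0, tm > 0)
  structure(list(A = A, c = c, tm = tm), class = "rt_model")
}

#' @export
print.rt_model <- function(x, ...) {
  cat(sprintf("<rt_model: dt(tr) = %.4g * exp(-%.4g * (tr - %.4g))>\n",
              x$A, x$c, x$tm))
  invisible(x)
}

#' Predicted retention-time drift at a given retention time
#'
#' @param model An `rt_model`.
#' @param tr Retention time(s) in seconds (> `tm`).
#' @return Drift in seconds (other run minus reference).
#' @export
#' @examples
#' m <- rt_model(A = 60, c = 5e-4)
#' predict_dt(m, 120)                    # = A at the dead time
#' predict_dt(m, 120 + log(2) / 5e-4)    # halved
predict_dt <- function(model, tr) UseMethod("predict_dt")

#' @export
predict_dt.rt_model <- function(model, tr) {
  model$A * exp(-model$c * (tr - model$tm))
}

#' Collect anchor mass pairs between two feature lists
#'
#' Unique mutual nearest-mass matches within `ppm_tol`: a pair is kept only
#' when each feature is the single within-tolerance candidate of the other;
#' masses with several within-tolerance candidates are dropped as ambiguous.
#' Pairs whose retention-time difference exceeds `max_dt_s` are discarded.
#'
#' @param features_ref,features_other Feature data frames (columns `mh`,
#'   `rt_apex`) of the reference and the run to be aligned.
#' @param ppm_tol Mass tolerance in ppm.
#' @param max_dt_s Maximum credible drift in seconds.
#' @return Data frame with columns `mh`, `tr_ref`, `dt` (other minus
#'   reference).
#' @export
collect_anchor_pairs <- function(features_ref, features_other, ppm_tol = 10,
                                 max_dt_s = 300) {
  a <- features_ref$mh
  b <- features_other$mh
  pairs <- list()
  for (i in seq_along(a)) {
    tol <- ppm_tol * 1e-6 * a[i]
    cand <- which(abs(b - a[i]) <= tol)
    if (length(cand) != 1L) next
    j <- cand
    back <- which(abs(a - b[j]) <= ppm_tol * 1e-6 * b[j])
    if (length(back) != 1L || back != i) next
    dt <- features_other$rt_apex[j] - features_ref$rt_apex[i]
    if (abs(dt) > max_dt_s) next
    pairs[[length(pairs) + 1L]] <- data.frame(
      mh = a[i], tr_ref = features_ref$rt_apex[i], dt = dt)
  }
  if (length(pairs) < 10L) {
    stop("insufficient anchors: only ", length(pairs),
         " unique mutual matches (need >= 10)")
  }
  out <- do.call(rbind, pairs)
  rownames(out) <- NULL
  out
}

#' Fit the exponential retention-time drift model to anchor pairs
#'
#' Robust two-stage fit: pairs are binned by reference retention time, the
#' median drift per bin damps mismatched-pair outliers, and the exponential
#' is least-squares fitted to the bin medians -- log-linearly when all
#' medians share one sign, refined by direct nonlinear least squares
#' (Levenberg-Marquardt) otherwise or afterwards. If every bin median is
#' zero the degenerate model A = 0, c = 0 is returned.
#'
#' @param pairs Anchor pairs from [collect_anchor_pairs()] (needs >= 10).
#' @param tm Dead time in seconds, fixed (weakly identified from pairs).
#' @param n_bins Number of retention-time bins.
#' @param form `"exponential"` (the theoretical drift law, default) or
#'   `"poly3"`, a cubic-polynomial fallback fitted to the bin medians and
#'   wrapped in the same prediction interface.
#' @return An `rt_model` (for `"poly3"`, an `rt_poly_model` with its own
#'   [predict_dt()] semantics via the `predict_fun` element).
#' @export
fit_rt_model <- function(pairs, tm = 120, n_bins = 20L,
                         form = c("exponential", "poly3")) {
  form <- match.arg(form)
  stopifnot(nrow(pairs) >= 10L)
  br <- seq(min(pairs$tr_ref), max(pairs$tr_ref), length.out = n_bins + 1L)
  bin <- cut(pairs$tr_ref, br, include.lowest = TRUE)
  med <- tapply(pairs$dt, bin, stats::median)
  mid <- tapply(pairs$tr_ref, bin, stats::median)
  keep <- !is.na(med)
  med <- as.numeric(med[keep]); mid <- as.numeric(mid[keep])
  if (form == "poly3") {
    deg <- min(3L, length(mid) - 1L)
    fit <- stats::lm(med ~ stats::poly(mid, degree = deg, raw = TRUE))
    return(structure(list(fit = fit, tm = tm), class = "rt_poly_model"))
  }
  if (all(med == 0)) return(rt_model(0, 0, tm))
  if (all(med > 0) || all(med < 0)) {
    sgn <- sign(med[1L])
    lf <- stats::lm(log(abs(med)) ~ I(mid - tm))
    A0 <- sgn * exp(stats::coef(lf)[[1L]])
    c0 <- max(0, -stats::coef(lf)[[2L]])
  } else {
    A0 <- med[which.min(mid)]
    c0 <- 1e-3
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(med ~ A * exp(-cc * (mid - tm)),
                      start = list(A = A0, cc = c0),
                      lower = c(A = -Inf, cc = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(rt_model(A0, c0, tm))
  cf <- stats::coef(fit)
  rt_model(cf[["A"]], max(0, cf[["cc"]]), tm)
}

#' @export
predict_dt.rt_poly_model <- function(model, tr) {
  unname(stats::predict(model$fit, data.frame(mid = tr)))
}

#' Apply a drift model to align a run onto the reference
#'
#' Every apex retention time is corrected by subtracting the predicted
#' drift: `rt' = rt - dt(rt)`.
#'
#' @param features Feature data frame with an `rt_apex` column (or `rt`, as
#'   in a noise list).
#' @param model An `rt_model`.
#' @return The feature data frame with corrected retention times.
#' @export
apply_alignment <- function(features, model) {
  col <- if ("rt_apex" %in% names(features)) "rt_apex" else "rt"
  features[[col]] <- features[[col]] - predict_dt(model, features[[col]])
  features
}
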