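#' Fisher-z functional connectivity matrix
#'
#' Symmetric matrix of Fisher-z transformed Pearson correlations between ROI
#' time series; the diagonal is fixed at 0 by convention (not atanh(1)).
#'
#' @param z symmetric numeric matrix.
#' @param roi_labels ROI labels (defaults to rownames of `z`).
#' @return object of class `functional_matrix` with fields `z`, `roi_labels`.
#' @export
functional_matrix <- function(z, roi_labels = rownames(z)) {
  z <- as.matrix(z)
  check_square_symmetric(z, "functional matrix", tol = 1e-8)
  if (is.null(roi_labels) || length(roi_labels) != nrow(z))
    stop2("functional matrix needs one label per row")
  if (any(!is.finite(z))) stop2("functional matrix has non-finite entries")
  z <- (z + t(z)) / 2          # exact symmetry
  diag(z) <- 0
  dimnames(z) <- list(roi_labels, roi_labels)
  structure(list(z = z, roi_labels = as.character(roi_labels)),
            class = "functional_matrix")
}

#' @export
print.functional_matrix <- function(x, ...) {
  cat(sprintf("<functional_matrix> %d x %d Fisher-z, mean |z| = %.3f\n",
              nrow(x$z), ncol(x$z), mean(abs(x$z[upper.tri(x$z)]))))
  invisible(x)
}

#' Discard initial volumes
#'
#' Drops the first `k` volumes of the data and nuisance channels, e.g. the
#' first five acquisitions recorded before scanner signal stabilization.
#'
#' @param ts a [subject_ts()].
#' @param k number of initial volumes to remove (default 5).
#' @return the trimmed [subject_ts()].
#' @export
discard_initial <- function(ts, k = 5) {
  if (k < 0) stop2("k must be >= 0")
  if (k >= n_volumes(ts))
    stop2("cannot discard %d of %d volumes", k, n_volumes(ts))
  if (k == 0) return(ts)
  keep <- seq.int(k + 1L, n_volumes(ts))
  subject_ts(ts$data[, keep, drop = FALSE], ts$roi_labels, ts$tr_seconds,
             nuisance = if (!is.null(ts$nuisance))
               ts$nuisance[, keep, drop = FALSE])
}

#' Nuisance regression
#'
#' Replaces every ROI series by its residual from an ordinary least-squares
#' fit on an intercept plus the nuisance channels (white-matter and CSF
#' averages in the imaging pipeline). Residuals are orthogonal to the
#' regressors up to numerical precision.
#'
#' @param ts a [subject_ts()] with nuisance channels.
#' @return [subject_ts()] of residuals (nuisance channels retained).
#' @export
regress_nuisance <- function(ts) {
  if (is.null(ts$nuisance) || nrow(ts$nuisance) == 0)
    stop2("no nuisance channels present; cannot run nuisance regression")
  x <- cbind(1, t(ts$nuisance))
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    warning("collinear nuisance channels; using pseudo-inverse fit",
            call. = FALSE)
  }
  res <- t(qr.resid(qx, t(ts$data)))  # rank-deficient qr = pseudo-inverse fit
  subject_ts(res, ts$roi_labels, ts$tr_seconds, nuisance = ts$nuisance)
}

#' Polynomial detrending
#'
#' Removes, per ROI, the least-squares polynomial of degree `order` in the
#' volume index (order 0 removes the mean); addresses slow thermal drift.
#'
#' @param ts a [subject_ts()].
#' @param order polynomial degree (>= 0; must be < volumes - 1).
#' @return detrended [subject_ts()].
#' @export
detrend_poly <- function(ts, order = 2) {
  nt <- n_volumes(ts)
  if (order < 0 || order >= nt - 1)
    stop2("detrending order %d invalid for %d volumes", order, nt)
  x <- if (order == 0) matrix(1, nt, 1)
       else cbind(1, poly(seq_len(nt), degree = order))
  res <- t(qr.resid(qr(x), t(ts$data)))
  subject_ts(res, ts$roi_labels, ts$tr_seconds, nuisance = ts$nuisance)
}

#' Zero-phase band-pass filtering
#'
#' Retains fluctuations between `f_lo` and `f_hi` (Hz) with a zero-phase
#' discrete-Fourier-transform filter: each ROI series is transformed, DFT
#' coefficients whose frequency falls outside `[f_lo, f_hi]` are zeroed
#' (including DC), and the series is inverse-transformed. Exact pass-band
#' gain 1 and stop-band gain 0 at the DFT frequencies.
#'
#' @param ts a [subject_ts()].
#' @param f_lo high-pass cutoff in Hz (default 0.01).
#' @param f_hi low-pass cutoff in Hz (default 0.1).
#' @return filtered [subject_ts()].
#' @export
bandpass <- function(ts, f_lo = 0.01, f_hi = 0.1) {
  nyq <- 1 / (2 * ts$tr_seconds)
  if (!(f_lo > 0 && f_lo < f_hi && f_hi < nyq))
    stop2("band [%g, %g] Hz outside (0, Nyquist = %g Hz)", f_lo, f_hi, nyq)
  nt <- n_volumes(ts)
  freq <- seq.int(0L, nt - 1L) / (nt * ts$tr_seconds)
  freq <- pmin(freq, 1 / ts$tr_seconds - freq)   # two-sided spectrum
  keep <- freq >= f_lo & freq <= f_hi
  xf <- mvfft(t(ts$data))
  xf[!keep, ] <- 0
  res <- t(Re(mvfft(xf, inverse = TRUE)) / nt)
  subject_ts(res, ts$roi_labels, ts$tr_seconds, nuisance = ts$nuisance)
}

#' Pearson correlation + Fisher z transform
#'
#' Computes the ROI x ROI Pearson correlation matrix and applies
#' z = atanh(r), clipping r at +/- (1 - 1e-7) so z stays finite; the
#' diagonal is set to 0 by convention.
#'
#' @param ts a [subject_ts()] with at least 3 volumes.
#' @return a [functional_matrix()].
#' @export
pearson_fisher <- function(ts) {
  if (n_volumes(ts) < 3) stop2("need at least 3 volumes for correlation")
  sds <- apply(ts$data, 1, sd)
  if (any(sds == 0))
    stop2("zero-variance ROI: %s", ts$roi_labels[which(sds == 0)[1]])
  r <- cor(t(ts$data))
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  functional_matrix(atanh(r), ts$roi_labels)
}

#' Preprocessing configuration
#'
#' @param discard number of initial volumes to drop (default 5).
#' @param detrend_order polynomial detrending degree (default 2).
#' @param band high/low-pass cutoffs in Hz (default c(0.01, 0.1)).
#' @param steps cleaning-step order; any subset of
#'   `c("discard", "nuisance", "detrend", "bandpass")`.
#' @return list of class `preproc_config`.
#' @export
preproc_config <- function(discard = 5, detrend_order = 2,
                           band = c(0.01, 0.1),
                           steps = c("discard", "nuisance", "detrend",
                                     "bandpass")) {
  bad <- setdiff(steps, c("discard", "nuisance", "detrend", "bandpass"))
  if (length(bad)) stop2("unknown preprocessing step: %s", bad[1])
  structure(list(discard = discard, detrend_order = detrend_order,
                 band = band, steps = steps),
            class = "preproc_config")
}

#' Full cleaning cascade to a Fisher-z connectivity matrix
#'
#' Applies, in the configured order (default: initial-volume discard,
#' nuisance regression, polynomial detrending, band-pass filtering), then
#' correlates and Fisher-transforms.
#'
#' @param ts a [subject_ts()].
#' @param config a [preproc_config()].
#' @param verbose log each step via `message()`.
#' @return a [functional_matrix()].
#' @export
run_preproc <- function(ts, config = preproc_config(), verbose = FALSE) {
  for (step in config$steps) {
    ts <- switch(step,
      discard  = discard_initial(ts, config$discard),
      nuisance = regress_nuisance(ts),
      detrend  = detrend_poly(ts, config$detrend_order),
      bandpass = bandpass(ts, config$band[1], config$band[2]))
    if (verbose) message("preproc: applied ", step,
                         " (", n_volumes(ts), " volumes)")
  }
  pearson_fisher(ts)
}
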