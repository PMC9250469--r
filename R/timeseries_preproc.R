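#' ROI-level BOLD time series with motion parameters
#'
#' Container for one subject's frames x ROI signal matrix, repetition time,
#' six rigid-body motion parameters per frame (translations in mm, rotations
#' in radians), optional extra nuisance signals (white matter, CSF), the
#' framewise displacement once computed, and the censoring mask used by
#' scrubbing.
#'
#' @param data numeric matrix, frames x ROIs, with ROI column names.
#' @param tr repetition time (seconds).
#' @param motion numeric matrix, frames x 6.
#' @param nuisance optional frames x k matrix of extra nuisance signals.
#' @return an object of class `roi_time_series`.
#' @export
roi_time_series <- function(data, tr, motion = NULL, nuisance = NULL) {
  data <- as.matrix(data)
  if (is.null(colnames(data))) colnames(data) <- sprintf("ROI%02d", seq_len(ncol(data)))
  stopifnot(is.numeric(data), tr > 0)
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (ncol(motion) != 6) stop("motion must have 6 columns (3 translations mm, 3 rotations rad)")
    if (nrow(motion) != nrow(data)) stop("motion and data must have equal frame counts")
  }
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != nrow(data)) stop("nuisance and data must have equal frame counts")
  }
  structure(list(data = data, tr = tr, motion = motion, nuisance = nuisance,
                 fd = NULL, censor = rep(TRUE, nrow(data)), log = character(0)),
            class = "roi_time_series")
}

#' @export
print.roi_time_series <- function(x, ...) {
  cat(sprintf("roi_time_series: %d frames x %d ROIs, TR = %gs\n",
              nrow(x$data), ncol(x$data), x$tr))
  if (!is.null(x$fd))
    cat(sprintf("  FD computed; %d/%d frames retained\n", sum(x$censor), length(x$censor)))
  if (length(x$log)) cat("  steps:", paste(x$log, collapse = " -> "), "\n")
  invisible(x)
}

n_frames <- function(ts) nrow(ts$data)

log_step <- function(ts, msg) { ts$log <- c(ts$log, msg); ts }

subset_frames <- function(ts, keep) {
  ts$data <- ts$data[keep, , drop = FALSE]
  if (!is.null(ts$motion)) ts$motion <- ts$motion[keep, , drop = FALSE]
  if (!is.null(ts$nuisance)) ts$nuisance <- ts$nuisance[keep, , drop = FALSE]
  if (!is.null(ts$fd)) ts$fd <- ts$fd[keep]
  ts$censor <- ts$censor[keep]
  ts
}

#' Drop initial frames (magnetisation equilibration)
#'
#' @param ts a `roi_time_series`.
#' @param k number of leading frames to remove (default 10).
#' @return the trimmed series; data, motion, nuisance and masks stay in lockstep.
#' @export
drop_initial_frames <- function(ts, k = 10) {
  stopifnot(inherits(ts, "roi_time_series"), k >= 0)
  if (n_frames(ts) <= k) stop(sprintf("cannot drop %d frames from a %d-frame series", k, n_frames(ts)))
  if (k == 0) return(ts)
  log_step(subset_frames(ts, -(seq_len(k))), sprintf("drop%d", k))
}

#' Remove a per-ROI least-squares linear trend
#'
#' @param ts a `roi_time_series` with at least 3 frames.
#' @return series with each column's fitted line (intercept + slope) removed.
#' @export
detrend_linear <- function(ts) {
  stopifnot(inherits(ts, "roi_time_series"), n_frames(ts) >= 3)
  t0 <- seq_len(n_frames(ts))
  res <- stats::lm.fit(cbind(1, t0), ts$data)$residuals
  ts$data <- matrix(res, n_frames(ts), ncol(ts$data),
                    dimnames = dimnames(ts$data))
  log_step(ts, "detrend")
}

# raised-cosine ramp: 0 below a, 1 above b
cos_ramp <- function(f, a, b) {
  g <- (f - a) / (b - a)
  g <- pmin(pmax(g, 0), 1)
  0.5 * (1 - cos(pi * g))
}

#' Band-pass filter ROI signals (frequency domain)
#'
#' Ideal pass band with a raised-cosine taper of half-width `taper_hz` at each
#' edge, applied via FFT. The DC component is always removed. Default band is
#' the standard resting-state 0.01-0.08 Hz window.
#'
#' @param ts a `roi_time_series`.
#' @param low,high band edges in Hz; `high` must be below Nyquist `1/(2 tr)`.
#' @param taper_hz transition half-width in Hz.
#' @return filtered series.
#' @export
bandpass <- function(ts, low = 0.01, high = 0.08, taper_hz = 0.004) {
  stopifnot(inherits(ts, "roi_time_series"), low >= 0, high > low)
  nyq <- 1 / (2 * ts$tr)
  if (high >= nyq) stop(sprintf("high edge %g Hz is at or above Nyquist %g Hz", high, nyq))
  n <- n_frames(ts)
  f <- seq(0, n - 1) / (n * ts$tr)
  f <- pmin(f, 1 / ts$tr - f)  # fold to [0, Nyquist]
  gain <- cos_ramp(f, low - taper_hz, low + taper_hz) *
    (1 - cos_ramp(f, high - taper_hz, high + taper_hz))
  gain[1] <- 0
  ts$data <- Re(stats::mvfft(stats::mvfft(ts$data) * gain, inverse = TRUE)) / n
  log_step(ts, sprintf("bandpass[%g,%g]", low, high))
}

#' Framewise displacement (Power definition)
#'
#' Sum of absolute frame-to-frame differences of the six motion parameters,
#' with rotations converted to arc length on a 50 mm sphere. The first frame
#' has FD 0 by convention.
#'
#' @param motion frames x 6 matrix (3 translations mm, 3 rotations rad).
#' @param radius_mm head-sphere radius for the rotation arc length.
#' @return numeric vector of per-frame FD in mm.
#' @export
compute_fd <- function(motion, radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion must have 6 columns")
  d <- abs(diff(motion))
  c(0, rowSums(d[, 1:3, drop = FALSE]) + radius_mm * rowSums(d[, 4:6, drop = FALSE]))
}

#' Friston-24 motion regressor expansion
#'
#' Columns in deterministic order: the 6 parameters, their one-frame lags
#' (first row zero), the 6 squares, and the lagged squares.
#'
#' @param motion frames x 6 matrix.
#' @return frames x 24 matrix.
#' @export
friston24 <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion must have 6 columns")
  lag1 <- rbind(0, motion[-nrow(motion), , drop = FALSE])
  out <- cbind(motion, lag1, motion^2, lag1^2)
  colnames(out) <- c(paste0("m", 1:6), paste0("m", 1:6, "_lag"),
                     paste0("m", 1:6, "_sq"), paste0("m", 1:6, "_lag_sq"))
  out
}

#' Regress nuisance signals out of the ROI time series
#'
#' Residualises each ROI signal on the confound matrix plus an intercept.
#' By default the confounds are the Friston-24 expansion of the stored motion
#' parameters together with any stored extra nuisance signals (WM, CSF).
#' Collinear confound columns are dropped via QR rank detection.
#'
#' @param ts a `roi_time_series`.
#' @param confounds optional frames x k confound matrix; if `NULL`, built from
#'   `ts$motion` and `ts$nuisance`.
#' @return series of residuals; each residual column is orthogonal to every
#'   retained confound.
#' @export
nuisance_regress <- function(ts, confounds = NULL) {
  stopifnot(inherits(ts, "roi_time_series"))
  if (is.null(confounds)) {
    confounds <- cbind(if (!is.null(ts$motion)) friston24(ts$motion),
                       ts$nuisance)
    if (is.null(confounds)) stop("no confounds available")
  }
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != n_frames(ts)) stop("confound rows must match frames")
  X <- cbind(`(Intercept)` = 1, confounds)
  qrX <- qr(X)
  if (qrX$rank >= n_frames(ts)) stop("more confounds than frames")
  X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  res <- stats::lm.fit(X, ts$data)$residuals
  ts$data <- matrix(res, n_frames(ts), ncol(ts$data),
                    dimnames = dimnames(ts$data))
  log_step(ts, sprintf("nuisance[%d]", ncol(X) - 1))
}

#' Scrub high-motion frames
#'
#' Computes FD (if not yet stored) and deletes frames with FD above the
#' threshold. Mirrors the practice of excluding subjects whose scan retains
#' too little data after motion censoring.
#'
#' @param ts a `roi_time_series` with motion parameters.
#' @param fd_threshold censoring threshold in mm (default 0.2).
#' @param min_frames minimum retained frames before the subject is rejected.
#' @return censored series; `$fd` and `$censor` record the decision.
#' @export
scrub <- function(ts, fd_threshold = 0.2, min_frames = 2) {
  stopifnot(inherits(ts, "roi_time_series"))
  if (is.null(ts$motion)) stop("motion parameters required to scrub")
  ts$fd <- compute_fd(ts$motion)
  keep <- ts$fd <= fd_threshold
  if (sum(keep) < min_frames)
    stop(sprintf("subject rejected: only %d frames with FD <= %g mm", sum(keep), fd_threshold))
  n_removed <- sum(!keep)
  ts <- subset_frames(ts, keep)
  ts$censor <- rep(TRUE, n_frames(ts))
  log_step(ts, sprintf("scrub[%g mm, -%d frames]", fd_threshold, n_removed))
}

#' Full ROI-level cleaning pipeline
#'
#' Fixed order: drop initial frames, linear detrend, band-pass, nuisance
#' regression, FD scrubbing. The order is recorded in `$log`.
#'
#' @param ts a `roi_time_series`.
#' @param drop_k initial frames to drop.
#' @param low,high band-pass edges (Hz).
#' @param fd_threshold scrubbing threshold (mm).
#' @return cleaned series.
#' @export
clean_timeseries <- function(ts, drop_k = 10, low = 0.01, high = 0.08,
                             fd_threshold = 0.2) {
  ts <- drop_initial_frames(ts, drop_k)
  ts <- detrend_linear(ts)
  ts <- bandpass(ts, low, high)
  ts <- nuisance_regress(ts)
  scrub(ts, fd_threshold)
}
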