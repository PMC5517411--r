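# Time-series conditioning: initial-volume discard, confound regression,
# polynomial detrending, discrete-cosine frequency filtering, and
# principal-eigenvariate summarization of voxel blocks.

#' Discard initial volumes
#'
#' Drops the first `n_discard` volumes of a session (magnetic-equilibration
#' scans); the default of 5 turns a 165-volume acquisition into the 160
#' volumes used for fitting.
#'
#' @param series A [session_series()].
#' @param n_discard Number of leading volumes to drop (default 5).
#' @return The shortened [session_series()].
#' @export
discard_initial <- function(series, n_discard = 5) {
  if (n_discard < 0 || n_discard >= nrow(series)) {
    ldcm_stop("`n_discard` must be smaller than the number of volumes")
  }
  if (n_discard == 0) return(series)
  session_series(unclass(series)[-seq_len(n_discard), , drop = FALSE],
                 tr = attr(series, "tr"), region_names = colnames(series))
}

#' Regress confounds out of a session series
#'
#' Returns the least-squares residuals of every region on the confound
#' columns plus an intercept; residuals are orthogonal to every confound.
#' Rank-deficient confound matrices are handled by dropping linearly
#' dependent columns with a warning.
#'
#' @param series A [session_series()].
#' @param confounds T x k numeric matrix (same T).
#' @return Residual [session_series()].
#' @export
regress_confounds <- function(series, confounds) {
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != nrow(series)) {
    ldcm_stop("confound matrix and series must have the same number of rows")
  }
  X <- cbind(intercept = 1, confounds)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    warning(sprintf("dropping %d linearly dependent confound column(s)",
                    ncol(X) - qrX$rank))
    qrX <- qr(X[, keep, drop = FALSE])
  }
  res <- qr.resid(qrX, unclass(series))
  session_series(res, tr = attr(series, "tr"), region_names = colnames(series))
}

#' Detrend and frequency-filter a session series
#'
#' Removes linear and quadratic trends by regression, then removes Fourier
#' components strictly below `highpass_hz` by discrete-cosine-basis
#' regression (and, optionally, components above `lowpass_hz`). Cosine-basis
#' regression avoids the edge transients IIR filters produce on short
#' (~160-sample) series. The defaults retain everything above 0.009 Hz and
#' do not remove high frequencies.
#'
#' @param series A [session_series()].
#' @param highpass_hz Cutoff below which slow components are removed.
#' @param lowpass_hz Optional cutoff above which components are removed
#'   (default `NULL`: keep high frequencies).
#' @return Filtered [session_series()].
#' @export
detrend_and_filter <- function(series, highpass_hz = 0.009,
                               lowpass_hz = NULL) {
  tr <- attr(series, "tr")
  T_ <- nrow(series)
  nyq <- 1 / (2 * tr)
  check_scalar(highpass_hz, "highpass_hz", lower = 1e-12)
  if (highpass_hz >= nyq) ldcm_stop("`highpass_hz` must be below Nyquist")
  tt <- seq_len(T_) / T_
  # DCT-II basis: component k has frequency k / (2 T tr)
  dct_freq <- function(k) k / (2 * T_ * tr)
  k_hp <- seq_len(T_ - 1)[dct_freq(seq_len(T_ - 1)) < highpass_hz]
  k_lp <- if (!is.null(lowpass_hz)) {
    check_scalar(lowpass_hz, "lowpass_hz", lower = highpass_hz)
    seq_len(T_ - 1)[dct_freq(seq_len(T_ - 1)) > lowpass_hz]
  } else integer(0)
  ks <- union(k_hp, k_lp)
  B <- if (length(ks)) {
    sapply(ks, function(k) cos(pi * k * (seq_len(T_) - 0.5) / T_))
  } else NULL
  # single joint projection (trends + cosine set): idempotent by construction
  X <- cbind(1, tt, tt^2, B)
  y <- qr.resid(qr(X), unclass(series))
  session_series(y, tr = tr, region_names = colnames(series))
}

#' Principal eigenvariate of a voxel block
#'
#' Summarizes a time x voxel block as its first left singular vector, scaled
#' so its variance equals the first eigenvalue of the voxel covariance
#' divided by the voxel count, and signed to correlate positively with the
#' voxel-mean series.
#'
#' @param voxels T x V numeric matrix, V >= 2, T >= 3.
#' @return Numeric length-T series.
#' @export
principal_eigenvariate <- function(voxels) {
  voxels <- as.matrix(voxels)
  if (ncol(voxels) < 2 || nrow(voxels) < 3) {
    ldcm_stop("need at least 2 voxels and 3 time points")
  }
  centred <- sweep(voxels, 2, colMeans(voxels))
  if (max(abs(centred)) == 0) {
    ldcm_stop("all-constant voxel block", class = "longdcm_degenerate_error")
  }
  sv <- svd(centred, nu = 1, nv = 0)
  e <- sv$u[, 1] * sv$d[1] / sqrt(ncol(voxels))
  if (stats::cor(e, rowMeans(centred)) < 0) e <- -e
  e
}

#' Standard conditioning pipeline for one session
#'
#' discard -> confound regression -> detrend/filter, in that order.
#'
#' @param series A [session_series()] (with the initial volumes still present).
#' @param confounds Confound matrix aligned with `series`.
#' @param n_discard,highpass_hz,lowpass_hz Passed to the stages.
#' @return Conditioned [session_series()].
#' @export
preprocess_session <- function(series, confounds, n_discard = 5,
                               highpass_hz = 0.009, lowpass_hz = NULL) {
  out <- discard_initial(series, n_discard)
  conf <- as.matrix(confounds)
  if (n_discard > 0) conf <- conf[-seq_len(n_discard), , drop = FALSE]
  out <- regress_confounds(out, conf)
  detrend_and_filter(out, highpass_hz, lowpass_hz)
}
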