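# Cross-spectral density estimation: the second-order data features that
# replace the time series as the fitting target.

#' Construct a spectral-data object
#'
#' @param freqs Strictly increasing positive frequencies (Hz).
#' @param csd n x n x length(freqs) complex array; each slice must be
#'   Hermitian with non-negative real diagonal.
#' @param source Free-form provenance string.
#' @return Object of class `"spectral_data"`.
#' @export
spectral_data <- function(freqs, csd, source = "unknown") {
  if (any(diff(freqs) <= 0) || any(freqs <= 0)) {
    ldcm_stop("`freqs` must be strictly increasing and positive")
  }
  csd <- as.array(csd)
  if (length(dim(csd)) != 3 || dim(csd)[3] != length(freqs) ||
      dim(csd)[1] != dim(csd)[2]) {
    ldcm_stop("`csd` must be n x n x n_freq")
  }
  for (k in seq_along(freqs)) {
    herm_err <- max(abs(csd[, , k] - Conj(t(csd[, , k]))))
    if (herm_err > 1e-10) ldcm_stop("cross-spectral matrices must be Hermitian")
    if (any(Re(diag(csd[, , k, drop = FALSE][, , 1])) < -1e-12)) {
      ldcm_stop("cross-spectral diagonals must be non-negative")
    }
  }
  structure(list(freqs = freqs, csd = csd, n_regions = dim(csd)[1],
                 source = source),
            class = "spectral_data")
}

#' @export
print.spectral_data <- function(x, ...) {
  cat(sprintf("<spectral_data> %d regions, %d frequencies [%.4g, %.4g] Hz (%s)\n",
              x$n_regions, length(x$freqs), min(x$freqs), max(x$freqs),
              x$source))
  invisible(x)
}

#' Default log-spaced frequency grid
#'
#' From the fundamental frequency `1/(T * tr)` up to `fmax` (default 0.25 Hz,
#' the Nyquist frequency of a 2-s TR), 32 logarithmically spaced points.
#'
#' @param n_volumes Number of volumes in the fitted series.
#' @param tr Repetition time (s).
#' @param n_freq Number of grid points.
#' @param fmin,fmax Optional explicit band edges (Hz).
#' @export
default_freq_grid <- function(n_volumes, tr, n_freq = 32, fmin = NULL,
                              fmax = 0.25) {
  fmin <- fmin %||% (1 / (n_volumes * tr))
  logspace(fmin, fmax, n_freq)
}

#' Fit a multivariate autoregressive (MAR) model
#'
#' Least-squares MAR of the stated order on the demeaned series; used as a
#' smooth parametric route to cross-spectral estimates on short series. An
#' ill-conditioned regression falls back to a ridge-regularized fit with a
#' warning.
#'
#' @param series A [session_series()] or plain T x n matrix.
#' @param order Positive model order (default 8).
#' @param tr Repetition time (s); taken from the series attribute if present.
#' @return List of class `"mar_fit"`: `coef` (list of n x n lag matrices),
#'   `sigma` (innovation covariance), `order`, `tr`.
#' @export
fit_mar <- function(series, order = 8, tr = attr(series, "tr")) {
  y <- as.matrix(unclass(series))
  if (is.null(tr)) ldcm_stop("`tr` missing and not an attribute of `series`")
  n <- ncol(y)
  T_ <- nrow(y)
  if (order < 1) ldcm_stop("MAR order must be at least 1")
  if (T_ <= n * order + n) ldcm_stop("series too short for requested MAR order")
  y <- sweep(y, 2, colMeans(y))
  Y <- y[(order + 1):T_, , drop = FALSE]
  X <- do.call(cbind, lapply(seq_len(order), function(k) {
    y[(order + 1 - k):(T_ - k), , drop = FALSE]
  }))
  XtX <- crossprod(X)
  if (rcond(XtX) < 1e-12) {
    warning("ill-conditioned MAR regression; using ridge regularization")
    XtX <- XtX + diag(1e-6 * mean(diag(XtX)), ncol(XtX))
  }
  B <- solve(XtX, crossprod(X, Y))
  resid <- Y - X %*% B
  sigma <- crossprod(resid) / nrow(Y)
  coef <- lapply(seq_len(order), function(k) {
    t(B[(k - 1) * n + seq_len(n), , drop = FALSE])
  })
  structure(list(coef = coef, sigma = (sigma + t(sigma)) / 2,
                 order = order, tr = tr, n_regions = n),
            class = "mar_fit")
}

#' Parametric cross-spectral density from a MAR fit
#'
#' Evaluates `S(f) = tr * T(f)^-1 Sigma T(f)^-H` with
#' `T(f) = I - sum_k A_k exp(-i 2 pi f tr k)`, the two-sided spectral density
#' (units^2/Hz) of the fitted process; Hermitian by construction.
#'
#' @param series A [session_series()].
#' @param order MAR order (default 8).
#' @param freqs Frequency grid in (0, Nyquist]; defaults to
#'   [default_freq_grid()].
#' @return A [spectral_data()].
#' @export
estimate_csd <- function(series, order = 8, freqs = NULL) {
  tr <- attr(series, "tr")
  freqs <- freqs %||% default_freq_grid(nrow(series), tr)
  if (any(freqs > 1 / (2 * tr) + 1e-12)) {
    ldcm_stop("`freqs` must lie within (0, Nyquist]")
  }
  fit <- fit_mar(series, order = order)
  mar_csd(fit, freqs)
}

#' @rdname estimate_csd
#' @param fit A `"mar_fit"` object.
#' @export
mar_csd <- function(fit, freqs) {
  n <- fit$n_regions
  csd <- array(complex(real = 0), c(n, n, length(freqs)))
  for (j in seq_along(freqs)) {
    z <- exp(-1i * 2 * pi * freqs[j] * fit$tr * seq_len(fit$order))
    Tf <- diag(n) + 0i
    for (k in seq_len(fit$order)) Tf <- Tf - fit$coef[[k]] * z[k]
    Ti <- solve(Tf)
    S <- fit$tr * Ti %*% fit$sigma %*% Conj(t(Ti))
    csd[, , j] <- (S + Conj(t(S))) / 2
  }
  spectral_data(freqs, csd, source = sprintf("mar(%d)", fit$order))
}

#' Welch cross-spectral estimate
#'
#' Nonparametric segment-averaged cross-periodogram (Hann window, 50%
#' overlap, per-segment mean and linear-trend removal), on the FFT grid of
#' the segment length. Serves as an independent validation route for the
#' MAR-based estimator and as the sample CSD of long simulations.
#'
#' @param x T x n matrix (or [session_series()]).
#' @param dt Sampling step (s).
#' @param seg_len_s Segment length in seconds (default 256).
#' @param fmax Keep frequencies up to this value (Hz).
#' @return A [spectral_data()] with two-sided density normalization.
#' @export
welch_csd <- function(x, dt, seg_len_s = 256, fmax = 0.25) {
  x <- as.matrix(unclass(x))
  n <- ncol(x)
  L <- min(nrow(x), 2 * floor(seg_len_s / dt / 2))
  step <- L %/% 2
  starts <- seq(1, nrow(x) - L + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))
  U <- mean(w^2)
  f_all <- seq_len(L %/% 2) / (L * dt)
  keep <- f_all <= fmax
  f <- f_all[keep]
  acc <- array(complex(real = 0), c(n, n, length(f)))
  tt <- seq_len(L)
  for (s0 in starts) {
    seg <- x[s0 + tt - 1, , drop = FALSE]
    seg <- qr.resid(qr(cbind(1, tt)), seg)
    Fx <- stats::mvfft(seg * w)[1 + seq_len(L %/% 2), , drop = FALSE][keep, ,
                                                                     drop = FALSE]
    for (j in seq_along(f)) {
      acc[, , j] <- acc[, , j] + outer(Fx[j, ], Conj(Fx[j, ]))
    }
  }
  acc <- acc * dt / (L * U * length(starts))
  for (j in seq_along(f)) acc[, , j] <- (acc[, , j] + Conj(t(acc[, , j]))) / 2
  spectral_data(f, acc, source = "welch")
}

#' Serialize / restore spectral data as JSON
#'
#' Stores the frequency grid and the real and imaginary parts of each
#' cross-spectral matrix.
#'
#' @param sd A [spectral_data()].
#' @param path File path (JSON).
#' @return `path` invisibly; `read_spectral_data()` returns the restored
#'   object.
#' @export
write_spectral_data <- function(sd, path) {
  jsonlite::write_json(
    list(freqs = sd$freqs, re = Re(sd$csd), im = Im(sd$csd),
         n_regions = sd$n_regions, source = sd$source),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_spectral_data
#' @export
read_spectral_data <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- raw$n_regions
  nf <- length(raw$freqs)
  re <- array(aperm(raw$re, c(1, 2, 3)), c(n, n, nf))
  im <- array(aperm(raw$im, c(1, 2, 3)), c(n, n, nf))
  spectral_data(raw$freqs, re + 1i * im, source = raw$source)
}
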