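# Forward simulation: stochastic linear neural dynamics with scale-free
# fluctuations, Balloon-Windkessel haemodynamic observation, TR sampling,
# observation noise, drifts and confound leakage.

#' Specification of stochastic fluctuations and measurement noise
#'
#' Neuronal state noise and channel noise both follow power-law (scale-free)
#' spectral densities `amp * f^(-exp)` (two-sided, units^2/Hz); `drift_amp`
#' scales slow polynomial scanner drifts added at acquisition.
#'
#' @param state_amp,state_exp Amplitude and exponent of neuronal fluctuations.
#' @param obs_amp,obs_exp Amplitude and exponent of observation noise.
#' @param drift_amp Scale of linear + quadratic drifts (signal units).
#' @return List of class `"noise_spec"`.
#' @export
noise_spec <- function(state_amp = 1e-4, state_exp = 1,
                       obs_amp = 1e-3, obs_exp = 1, drift_amp = 0.2) {
  check_scalar(state_amp, "state_amp", lower = 0)
  check_scalar(obs_amp, "obs_amp", lower = 0)
  check_scalar(drift_amp, "drift_amp", lower = 0)
  check_scalar(state_exp, "state_exp", lower = 0, upper = 2)
  check_scalar(obs_exp, "obs_exp", lower = 0, upper = 2)
  structure(list(state_amp = state_amp, state_exp = state_exp,
                 obs_amp = obs_amp, obs_exp = obs_exp,
                 drift_amp = drift_amp),
            class = "noise_spec")
}

#' Synthesize power-law noise by frequency-domain shaping
#'
#' White Gaussian noise is shaped in the frequency domain so the realized
#' two-sided spectral density is `amp * f^(-exponent)` on (0, Nyquist]; the
#' zero-frequency bin is set to 0 so every series is exactly zero-mean in
#' expectation. Returns a `n_steps` x `n_series` matrix.
#'
#' @param n_steps Number of samples.
#' @param dt Sampling step (s).
#' @param amp Spectral amplitude (units^2/Hz at 1 Hz).
#' @param exponent Spectral exponent in `[0, 2]`.
#' @param n_series Number of independent columns.
#' @export
powerlaw_noise <- function(n_steps, dt, amp, exponent, n_series = 1) {
  if (amp == 0) return(matrix(0, n_steps, n_series))
  n <- n_steps
  f <- seq_len(n %/% 2) / (n * dt)      # positive-frequency bins
  sd_bin <- sqrt(amp * f^(-exponent) * n / dt)
  out <- matrix(0, n, n_series)
  n_half <- length(f)
  has_nyq <- n %% 2 == 0
  n_int <- n_half - as.integer(has_nyq)  # interior complex bins
  for (j in seq_len(n_series)) {
    v <- complex(length.out = n)
    if (n_int > 0) {
      z <- complex(real = stats::rnorm(n_int), imaginary = stats::rnorm(n_int)) / sqrt(2)
      v[1 + seq_len(n_int)] <- sd_bin[seq_len(n_int)] * z
      v[n + 1 - seq_len(n_int)] <- Conj(v[1 + seq_len(n_int)])
    }
    if (has_nyq) v[n_half + 1] <- sd_bin[n_half] * stats::rnorm(1)
    out[, j] <- Re(stats::fft(v, inverse = TRUE)) / n
  }
  out
}

#' Simulate stochastic linear neural dynamics
#'
#' Integrates `dx/dt = A_eff x + v` where `A_eff` is [effective_matrix()] of
#' the coupling matrix and `v` is power-law noise synthesized in the frequency
#' domain (independent per region). The linear drift is propagated exactly via
#' the matrix exponential over each step (zero-order hold on the noise); a
#' burn-in is discarded so the returned trajectory is approximately
#' stationary.
#'
#' @param a n x n coupling matrix (must be stable).
#' @param noise A [noise_spec()].
#' @param duration Returned duration (s), `>= 64`.
#' @param dt Integration step (s), `<= 0.1`.
#' @param seed Integer seed.
#' @param burnin Discarded initial duration (s), `>= 32`.
#' @param x0 Optional initial state (mainly for deterministic tests).
#' @return `round(duration/dt)` x n matrix with attribute `dt`.
#' @export
simulate_neural <- function(a, noise, duration, dt = 0.05, seed = 1,
                            burnin = 64, x0 = NULL) {
  a <- validate_coupling(a)
  check_scalar(dt, "dt", lower = 1e-6, upper = 0.1)
  check_scalar(duration, "duration", lower = 64)
  if (burnin < 32) ldcm_stop("`burnin` must be at least 32 s")
  if (!is_stable(a)) {
    ldcm_stop("coupling matrix is unstable; cannot simulate a stationary resting state",
              class = "longdcm_stability_error")
  }
  n <- nrow(a)
  a_eff <- effective_matrix(a)
  prop <- as.matrix(Matrix::expm(a_eff * dt))
  inject <- solve(a_eff, prop - diag(n))   # zero-order-hold noise loading
  n_keep <- round(duration / dt)
  n_burn <- round(burnin / dt)
  n_tot <- n_keep + n_burn
  set.seed(seed)
  v <- powerlaw_noise(n_tot, dt, noise$state_amp, noise$state_exp, n)
  x <- matrix(0, n_tot, n)
  xt <- if (is.null(x0)) numeric(n) else as.numeric(x0)
  for (t in seq_len(n_tot)) {
    xt <- drop(prop %*% xt + inject %*% v[t, ])
    x[t, ] <- xt
  }
  out <- x[(n_burn + 1):n_tot, , drop = FALSE]
  attr(out, "dt") <- dt
  out
}

#' Balloon-Windkessel haemodynamic observation
#'
#' Per region, integrates the vasodilatory signal s, inflow f, venous volume v
#' and deoxyhemoglobin q driven by `epsilon * x`, from the resting fixed point
#' (s = 0, f = v = q = 1), with classical 4th-order Runge-Kutta on the
#' trajectory's grid, and emits percent signal change through the standard
#' static nonlinearity `100 V0 (k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v))`.
#' The constants used are those of [hemo_constants()] unless overridden.
#'
#' @param x Time x n neural trajectory (attribute `dt`, or pass `dt`).
#' @param h Haemodynamic parameter list as from [hemo_constants()];
#'   `tau` and `epsilon` may be per-region vectors.
#' @param dt Time step (s); defaults to `attr(x, "dt")`.
#' @return Time x n matrix of percent signal change, attribute `dt`.
#' @export
balloon_bold <- function(x, h = hemo_constants(), dt = attr(x, "dt")) {
  if (is.null(dt)) ldcm_stop("`dt` missing and not an attribute of `x`")
  x <- as.matrix(x)
  n <- ncol(x)
  with(h, {
    if (any(c(kappa, gamma, tau, alpha, epsilon, V0) <= 0) ||
        E0 <= 0 || E0 >= 1 || alpha >= 1) {
      ldcm_stop("non-physical haemodynamic parameters")
    }
  })
  tau <- rep(h$tau, length.out = n)
  eps <- rep(h$epsilon, length.out = n)
  ia <- 1 / h$alpha
  E0 <- h$E0
  deriv <- function(st, u) {
    s <- st[1, ]; f <- pmax(st[2, ], 1e-6)
    v <- pmax(st[3, ], 1e-6); q <- pmax(st[4, ], 1e-6)
    Ef <- 1 - (1 - E0)^(1 / f)
    rbind(eps * u - h$kappa * s - h$gamma * (f - 1),
          s,
          (f - v^ia) / tau,
          (f * Ef / E0 - v^(ia - 1) * q) / tau)
  }
  nt <- nrow(x)
  st <- rbind(0, 1, 1, 1)[, rep(1, n), drop = FALSE]
  y <- matrix(0, nt, n)
  emit <- function(st) {
    v <- st[3, ]; q <- st[4, ]
    100 * h$V0 * (h$k1 * (1 - q) + h$k2 * (1 - q / v) + h$k3 * (1 - v))
  }
  for (t in seq_len(nt)) {
    u0 <- x[t, ]
    u1 <- if (t < nt) x[t + 1, ] else x[t, ]
    um <- (u0 + u1) / 2
    k1 <- deriv(st, u0)
    k2 <- deriv(st + dt / 2 * k1, um)
    k3 <- deriv(st + dt / 2 * k2, um)
    k4 <- deriv(st + dt * k3, u1)
    st <- st + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    y[t, ] <- emit(st)
  }
  attr(y, "dt") <- dt
  y
}

#' Construct a BOLD session series
#'
#' @param data T x n numeric matrix (percent signal change).
#' @param tr Repetition time (s), positive.
#' @param region_names Optional column labels.
#' @return Object of class `"session_series"` (a matrix with `tr` attribute).
#' @export
session_series <- function(data, tr, region_names = NULL) {
  data <- as.matrix(data)
  check_scalar(tr, "tr", lower = 1e-9)
  if (nrow(data) < 32) ldcm_stop("a session needs at least 32 volumes")
  if (any(!is.finite(data))) ldcm_stop("session series contains missing values")
  colnames(data) <- region_names %||% colnames(data) %||%
    sprintf("R%d", seq_len(ncol(data)))
  structure(data, tr = tr, class = c("session_series", "matrix", "array"))
}

#' @export
print.session_series <- function(x, ...) {
  cat(sprintf("<session_series> %d volumes x %d regions, TR = %gs\n",
              nrow(x), ncol(x), attr(x, "tr")))
  invisible(x)
}

#' Sample a BOLD trajectory at the TR grid and corrupt it
#'
#' Decimates the fine-grid BOLD trajectory to the repetition-time grid, adds
#' power-law observation noise and linear + quadratic drifts, and emits a
#' confound matrix -- 6 smooth motion-like random walks, their first
#' differences, and 3 slow nuisance component signals -- each of which leaks
#' into the data with small random gains so that confound regression has real
#' work to do.
#'
#' @param bold Time x n matrix with attribute `dt` (from [balloon_bold()]).
#' @param tr Repetition time (s).
#' @param n_volumes Number of volumes to emit.
#' @param noise A [noise_spec()].
#' @param seed Integer seed.
#' @param leak_sd Standard deviation of the random confound-to-data gains
#'   (signal units per unit confound; 0 disables leakage).
#' @return List with `series` (a [session_series()]) and `confounds`
#'   (T x 15 labelled matrix).
#' @export
sample_and_corrupt <- function(bold, tr, n_volumes, noise, seed = 1,
                               leak_sd = 0.2) {
  dt <- attr(bold, "dt")
  if (is.null(dt)) ldcm_stop("`bold` must carry a `dt` attribute")
  if (nrow(bold) * dt < tr * n_volumes - dt / 2) {
    ldcm_stop("trajectory shorter than tr * n_volumes")
  }
  n <- ncol(bold)
  idx <- pmin(nrow(bold), round(seq(0, n_volumes - 1) * tr / dt) + 1)
  y <- bold[idx, , drop = FALSE]
  set.seed(seed)
  # observation noise and slow drifts
  y <- y + powerlaw_noise(n_volumes, tr, noise$obs_amp, noise$obs_exp, n)
  tt <- seq(0, 1, length.out = n_volumes)
  drift <- outer(tt, stats::rnorm(n)) + outer(tt^2, stats::rnorm(n))
  y <- y + noise$drift_amp * drift
  # motion-like confounds: smooth random walks + first differences
  walk <- apply(matrix(stats::rnorm(n_volumes * 6), n_volumes), 2,
                function(z) {
                  w <- cumsum(z) / sqrt(n_volumes)
                  as.numeric(stats::filter(w, rep(1 / 5, 5), sides = 2,
                                           circular = TRUE))
                })
  dwalk <- rbind(0, diff(walk))
  # slow nuisance components: low-order cosines with random weights
  dct <- sapply(1:4, function(k) cos(pi * k * (seq_len(n_volumes) - 0.5) / n_volumes))
  comp <- dct %*% matrix(stats::rnorm(12), 4)
  comp <- scale(comp)[, , drop = FALSE]
  confounds <- cbind(walk, dwalk, comp)
  colnames(confounds) <- c(sprintf("motion%d", 1:6), sprintf("dmotion%d", 1:6),
                           sprintf("comp%d", 1:3))
  if (leak_sd > 0) {
    gains <- matrix(stats::rnorm(ncol(confounds) * n, 0, leak_sd),
                    ncol(confounds), n)
    y <- y + confounds %*% gains
  }
  list(series = session_series(y, tr, colnames(bold)), confounds = confounds)
}

#' Expand a region series into noisy voxel blocks
#'
#' Fixture generator for eigenvariate extraction: each voxel is a random
#' positive gain times its region's series plus white noise.
#'
#' @param series A [session_series()].
#' @param n_voxels_per_region At least 2.
#' @param voxel_noise_sd White-noise standard deviation.
#' @param seed Integer seed.
#' @param gain_sd Log-normal spread of the positive voxel gains (0 gives unit
#'   gains).
#' @return Named list of T x V voxel matrices, one per region.
#' @export
make_voxels <- function(series, n_voxels_per_region, voxel_noise_sd,
                        seed = 1, gain_sd = 0.3) {
  if (n_voxels_per_region < 2) ldcm_stop("need at least 2 voxels per region")
  set.seed(seed)
  out <- lapply(seq_len(ncol(series)), function(r) {
    gains <- exp(stats::rnorm(n_voxels_per_region, 0, gain_sd))
    vox <- outer(as.numeric(series[, r]), gains)
    vox + matrix(stats::rnorm(length(vox), 0, voxel_noise_sd), nrow(vox))
  })
  names(out) <- colnames(series)
  out
}

#' Write/read a session series as TSV with a JSON sidecar
#'
#' The TSV holds one column per region; the sidecar `<path>.json` records the
#' repetition time and provenance.
#'
#' @param series A [session_series()].
#' @param path TSV file path.
#' @param provenance Optional list stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_session_series <- function(series, path, provenance = list()) {
  utils::write.table(as.data.frame(unclass(series)), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    c(list(tr = attr(series, "tr"), region_names = colnames(series)),
      provenance),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_session_series
#' @export
read_session_series <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dat <- utils::read.delim(path, check.names = FALSE)
  session_series(as.matrix(dat), tr = meta$tr, region_names = meta$region_names)
}
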