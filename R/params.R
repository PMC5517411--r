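# Packed parameter vector for the spectral generative model.
#
# Fixed ordering (documented here and relied on throughout the package):
#   1..n^2        : vec(A), column-major. A[i, k] couples source k -> target i;
#                   diagonal entries are log-scale self-connection parameters.
#   n^2+1..n^2+n  : h_tau, per-region log-deviation of haemodynamic transit time
#                   (tau_r = tau0 * exp(h_tau_r)).
#   ..+n          : h_eps, per-region log-deviation of neurovascular gain
#                   (epsilon_r = eps0 * exp(h_eps_r)).
#   last 4        : ln_alpha_v, beta_v, ln_alpha_e, beta_e -- log-amplitude and
#                   exponent of the power-law state and observation noise
#                   spectral densities alpha * f^(-beta) (two-sided, units^2/Hz).

#' Names of the packed parameter vector
#'
#' @param n_regions Number of regions.
#' @return Character vector of length `n_regions^2 + 2 * n_regions + 4`.
#' @export
param_names <- function(n_regions) {
  n <- n_regions
  a_names <- as.vector(outer(seq_len(n), seq_len(n),
                             function(i, k) sprintf("a[%d,%d]", i, k)))
  c(a_names,
    sprintf("h_tau[%d]", seq_len(n)),
    sprintf("h_eps[%d]", seq_len(n)),
    "ln_alpha_v", "beta_v", "ln_alpha_e", "beta_e")
}

#' Pack model parameters into a named vector
#'
#' @param a n x n coupling matrix.
#' @param h_tau,h_eps Per-region log-deviations of transit time and gain
#'   (default 0).
#' @param noise Length-4 numeric `c(ln_alpha_v, beta_v, ln_alpha_e, beta_e)`.
#' @return Named numeric vector in the package's canonical ordering.
#' @export
pack_params <- function(a, h_tau = NULL, h_eps = NULL,
                        noise = c(ln_alpha_v = log(0.01), beta_v = 1,
                                  ln_alpha_e = log(1e-4), beta_e = 1)) {
  a <- validate_coupling(a)
  n <- nrow(a)
  h_tau <- h_tau %||% rep(0, n)
  h_eps <- h_eps %||% rep(0, n)
  stopifnot(length(h_tau) == n, length(h_eps) == n, length(noise) == 4)
  theta <- c(as.vector(a), h_tau, h_eps, as.numeric(noise))
  names(theta) <- param_names(n)
  theta
}

#' Unpack a parameter vector
#'
#' Inverse of [pack_params()]; round-trips exactly.
#'
#' @param theta Packed parameter vector.
#' @param n_regions Number of regions.
#' @return List with elements `a`, `h_tau`, `h_eps`, `noise`.
#' @export
unpack_params <- function(theta, n_regions) {
  n <- n_regions
  p <- n^2 + 2 * n + 4
  if (length(theta) != p) {
    ldcm_stop(sprintf("parameter vector has length %d, expected %d",
                      length(theta), p))
  }
  noise <- theta[(p - 3):p]
  names(noise) <- c("ln_alpha_v", "beta_v", "ln_alpha_e", "beta_e")
  list(a = matrix(theta[seq_len(n^2)], n, n),
       h_tau = unname(theta[n^2 + seq_len(n)]),
       h_eps = unname(theta[n^2 + n + seq_len(n)]),
       noise = noise)
}

#' Indices of the coupling (A-matrix) block in the packed vector
#' @param n_regions Number of regions.
#' @export
a_indices <- function(n_regions) seq_len(n_regions^2)

#' Canonical haemodynamic (Balloon-Windkessel) constants
#'
#' Population means of the Balloon model: signal decay `kappa` (1/s),
#' autoregulatory feedback `gamma` (1/s), mean transit time `tau` (s), vessel
#' stiffness exponent `alpha`, resting oxygen extraction `E0`, neurovascular
#' gain `epsilon`, resting venous volume fraction `V0`, and the BOLD output
#' constants `k1 = 7 E0`, `k2 = 2`, `k3 = 2 E0 - 0.2` of the classical static
#' nonlinearity. These defaults follow the canonical Balloon-Windkessel
#' literature and are recorded in every run manifest.
#'
#' @return Named list of constants.
#' @export
hemo_constants <- function() {
  E0 <- 0.4
  list(kappa = 0.64, gamma = 0.32, tau = 2, alpha = 0.32, E0 = E0,
       epsilon = 1, V0 = 0.04,
       k1 = 7 * E0, k2 = 2, k3 = 2 * E0 - 0.2)
}

#' Default shrinkage priors for spectral-DCM inversion
#'
#' Conservative Gaussian priors over the packed parameter vector:
#' off-diagonal couplings N(0, 1/64), diagonal log-scale parameters
#' N(0, 1/256), haemodynamic log-deviations N(0, 1/256), noise log-amplitudes
#' N(ln_amp0, 1) and exponents N(1, 1/64). The log-amplitude means are
#' re-centered on the data scale during inversion (see [invert_spdcm()]);
#' their unit prior variance leaves overall noise power only weakly
#' constrained a priori. Zero prior variance marks a parameter as fixed.
#'
#' @param n_regions Number of regions.
#' @param ln_amp0 Prior mean for both log-amplitudes (default `log(0.01)`;
#'   data are rescaled internally during inversion so this is a relative
#'   scale).
#' @return List with `mean` and `variance`, both named numeric vectors, class
#'   `"dcm_prior"`.
#' @export
default_priors <- function(n_regions, ln_amp0 = log(0.01)) {
  n <- n_regions
  nm <- param_names(n)
  mu <- stats::setNames(numeric(length(nm)), nm)
  v <- stats::setNames(numeric(length(nm)), nm)
  ai <- a_indices(n)
  diag_idx <- ai[as.vector(diag(matrix(TRUE, n, n)))]
  v[ai] <- 1 / 64
  v[diag_idx] <- 1 / 256
  v[n^2 + seq_len(2 * n)] <- 1 / 256
  noise_idx <- length(nm) - 3:0
  mu[noise_idx] <- c(ln_amp0, 1, ln_amp0, 1)
  v[noise_idx] <- c(1, 1 / 64, 1, 1 / 64)
  structure(list(mean = mu, variance = v, n_regions = n),
            class = "dcm_prior")
}

#' @export
print.dcm_prior <- function(x, ...) {
  cat(sprintf("<dcm_prior> %d regions, %d parameters (%d free)\n",
              x$n_regions, length(x$mean), sum(x$variance > 0)))
  invisible(x)
}
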