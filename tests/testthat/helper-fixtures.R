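# Shared fixtures, all generated in code.

# 3-node coupling matrix with a single planted coupling source 1 -> target 2
planted_coupling <- function(size = 0.4, n = 3) {
  a <- matrix(0, n, n)
  a[2, 1] <- size
  a
}

# quiet noise spec: neural fluctuations only
neural_only_noise <- function(state_amp = 1e-4, state_exp = 1) {
  noise_spec(state_amp = state_amp, state_exp = state_exp,
             obs_amp = 0, obs_exp = 0, drift_amp = 0)
}

# one synthetic session through the standard acquisition + conditioning path
simulated_session_csd <- function(a, seed, n_freq = 24, order = 8) {
  ns <- noise_spec()
  x <- simulate_neural(a, ns, duration = 330, dt = 0.05, seed = seed)
  y <- balloon_bold(x)
  sc <- sample_and_corrupt(y, tr = 2, n_volumes = 165, noise = ns,
                           seed = seed + 1000)
  cleaned <- preprocess_session(sc$series, sc$confounds)
  estimate_csd(cleaned, order = order,
               freqs = default_freq_grid(nrow(cleaned), 2, n_freq = n_freq,
                                         fmin = 0.01))
}

# Gaussian pseudo-posterior for PEB unit tests
gauss_post <- function(mean_vec, cov, names = NULL) {
  names <- names %||% sprintf("a[%d,1]", seq_along(mean_vec))
  m <- stats::setNames(mean_vec, names)
  dimnames(cov) <- list(names, names)
  structure(list(mean = m, covariance = cov, prior = NULL),
            class = "dcm_posterior")
}
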