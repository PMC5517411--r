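test_that("self-connection log-scale parameters map to rates as documented", {
  expect_equal(self_rate(0), -0.5)
  expect_equal(self_rate(log(2)), -1)
  expect_equal(self_rate(1), -0.5 * exp(1), tolerance = 1e-6)
  expect_error(self_rate(NaN))
})

test_that("parameter vectors pack and unpack exactly", {
  a <- matrix(rnorm(9), 3, 3)
  th <- pack_params(a, h_tau = c(0.1, 0, -0.1), h_eps = c(0, 0.2, 0),
                    noise = c(-2, 1, -4, 0.5))
  up <- unpack_params(th, 3)
  expect_equal(up$a, a)
  expect_equal(up$h_tau, c(0.1, 0, -0.1))
  expect_equal(unname(up$noise), c(-2, 1, -4, 0.5))
  expect_identical(pack_params(up$a, up$h_tau, up$h_eps, up$noise), th)
  expect_error(unpack_params(th[-1], 3))
})

test_that("the bare neural transfer matches the scalar Ornstein-Uhlenbeck form", {
  th <- pack_params(matrix(0, 1, 1))
  fr <- c(0.01, 0.05, 0.2)
  H <- transfer_function(th, fr, 1, bypass_hemo = TRUE)
  expect_equal(abs(H[1, 1, ])^2, 1 / ((2 * pi * fr)^2 + 0.25),
               tolerance = 1e-12)
})

test_that("the full transfer function is low-pass", {
  th <- pack_params(planted_coupling(0.3))
  H <- transfer_function(th, c(0.01, 0.1, 1, 10), 3)
  norms <- apply(H, 3, function(M) sqrt(sum(abs(M)^2)))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[4] / norms[1], 1e-3)
})

test_that("the analytic system Jacobian agrees with central differences", {
  set.seed(1)
  a <- matrix(rnorm(9, 0, 0.2), 3, 3); diag(a) <- rnorm(3, 0, 0.1)
  th <- pack_params(a, h_tau = rnorm(3, 0, 0.1), h_eps = rnorm(3, 0, 0.1))
  up <- unpack_params(th, 3)
  J <- longdcm:::full_jacobian(up)
  st0 <- c(rep(0, 6), rep(1, 9))              # x = s = 0, f = v = q = 1
  Jfd <- matrix(0, 15, 15)
  h <- 1e-6
  for (k in 1:15) {
    sp <- st0; sm <- st0
    sp[k] <- sp[k] + h; sm[k] <- sm[k] - h
    Jfd[, k] <- (longdcm:::full_rhs(sp, up) - longdcm:::full_rhs(sm, up)) / (2 * h)
  }
  expect_lt(max(abs(J - Jfd)) / max(abs(J)), 1e-4)
})

test_that("predicted spectra have the stated noise structure", {
  fr <- default_freq_grid(160, 2, n_freq = 12)
  # state noise off: prediction equals the observation-noise spectrum
  th0 <- pack_params(planted_coupling(0.2),
                     noise = c(-Inf, 1, log(2e-3), 0.7))
  G <- predict_csd(th0, fr, 3)
  for (k in seq_along(fr)) {
    expect_equal(G$csd[, , k], diag(2e-3 * fr[k]^(-0.7), 3) + 0i,
                 tolerance = 1e-12)
  }
  # general case: Hermitian PSD everywhere
  th <- pack_params(planted_coupling(0.3), noise = c(-9, 1, -7, 1))
  G2 <- predict_csd(th, fr, 3)
  for (k in seq_along(fr)) {
    S <- G2$csd[, , k]
    expect_lt(max(abs(S - Conj(t(S)))), 1e-12)
    expect_gt(min(Re(eigen(S, only.values = TRUE)$values)), -1e-12)
  }
  expect_error(transfer_function(pack_params(matrix(c(0, 0.6, 0.6, 0), 2, 2)),
                                 fr, 2),
               class = "longdcm_stability_error")
})

test_that("inversion is self-consistent on data from the prior mean", {
  fr <- default_freq_grid(160, 2, n_freq = 16, fmin = 0.01)
  prior <- default_priors(3)
  mu <- prior$mean
  mu["ln_alpha_v"] <- log(1e-4); mu["ln_alpha_e"] <- log(1e-3)
  dat <- predict_csd(mu, fr, 3)
  post <- invert_spdcm(dat)
  free <- prior$variance > 0
  sds <- sqrt(pmax(diag(post$covariance)[free], 1e-12))
  z <- abs(post$mean[free] - mu[free]) / sds
  expect_gte(mean(z <= 2), 0.9)
  expect_true(post$converged)
})

test_that("a planted coupling is recovered from exact model spectra", {
  a <- planted_coupling(0.4)
  th <- pack_params(a, noise = c(log(1e-4), 1, log(1e-3), 1))
  fr <- default_freq_grid(160, 2, n_freq = 24)
  dat <- predict_csd(th, fr, 3)
  post <- invert_spdcm(dat)
  ap <- posterior_a(post)
  expect_equal(ap[2, 1], 0.4, tolerance = 0.05)
  off <- ap[row(ap) != col(ap)]
  expect_equal(max(abs(off)), ap[2, 1])
})

test_that("free energy is non-decreasing and inversion is deterministic", {
  dat <- simulated_session_csd(planted_coupling(0.4), seed = 31, n_freq = 16)
  p1 <- invert_spdcm(dat)
  p2 <- invert_spdcm(dat)
  expect_identical(p1$mean, p2$mean)
  expect_identical(p1$free_energy, p2$free_energy)
  expect_true(all(diff(p1$f_trace) > -1e-6))
  expect_true(all(eigen(p1$covariance[p1$prior$variance > 0,
                                      p1$prior$variance > 0],
                        symmetric = TRUE,
                        only.values = TRUE)$values >= -1e-10))
})

test_that("posterior noise amplitudes are reported on the data scale", {
  th <- pack_params(planted_coupling(0.2),
                    noise = c(log(1e-4), 1, log(1e-3), 1))
  fr <- default_freq_grid(160, 2, n_freq = 16, fmin = 0.01)
  dat <- predict_csd(th, fr, 3)
  post <- invert_spdcm(dat)
  # recovered state-noise amplitude within an order of magnitude on the
  # original (unscaled) axis
  expect_lt(abs(post$mean["ln_alpha_v"] - log(1e-4)), 2.5)
})

test_that("different initializations reach the same free-energy basin", {
  th <- pack_params(planted_coupling(0.4),
                    noise = c(log(1e-4), 1, log(1e-3), 1))
  fr <- default_freq_grid(160, 2, n_freq = 16, fmin = 0.01)
  dat <- predict_csd(th, fr, 3)
  p1 <- invert_spdcm(dat)
  init <- p1$prior$mean
  init[a_indices(3)] <- init[a_indices(3)] + 0.05
  p2 <- invert_spdcm(dat, opts = list(init = init))
  expect_lt(abs(p1$free_energy - p2$free_energy), 0.5)
})
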