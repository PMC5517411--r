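test_that("stability flag matches an eigenvalue oracle", {
  # trivial cases
  expect_true(is_stable(matrix(0, 3, 3)))
  a <- matrix(0, 2, 2); a[1, 2] <- a[2, 1] <- 0.6
  expect_false(is_stable(a))            # eigenvalues -0.5 +/- 0.6
  # random matrices against brute-force eigenvalues of the effective system
  set.seed(1)
  for (k in 1:25) {
    a <- matrix(rnorm(36, 0, 0.4), 6, 6)
    eff <- a; diag(eff) <- -0.5 * exp(diag(a))
    oracle <- all(Re(eigen(eff, only.values = TRUE)$values) < 0)
    expect_identical(is_stable(a), oracle)
  }
  expect_error(is_stable(matrix(c(0, NA, 0, 0), 2, 2)))
})

test_that("noise-free dynamics decay monotonically to rest", {
  x <- simulate_neural(matrix(0, 2, 2), neural_only_noise(0), duration = 64,
                       dt = 0.05, seed = 1, burnin = 32, x0 = c(1, -1))
  norms <- sqrt(rowSums(x^2))
  expect_true(all(diff(norms) <= 1e-12))
  expect_lt(norms[length(norms)], 1e-12)
})

test_that("white-noise single node matches the Ornstein-Uhlenbeck variance", {
  amp <- 0.05
  x <- simulate_neural(matrix(0, 1, 1), neural_only_noise(amp, 0),
                       duration = 4000, dt = 0.05, seed = 2)
  # stationary variance of dx = -0.5 x dt + noise with flat two-sided
  # spectral density amp: amp / (2 * 0.5)
  expect_equal(var(x[, 1]), amp / (2 * 0.5), tolerance = 0.1)
})

test_that("the simulated spectrum follows the analytic shaped power law", {
  amp <- 1e-4
  x <- simulate_neural(matrix(0, 1, 1), neural_only_noise(amp, 1),
                       duration = 4000, dt = 0.05, seed = 3)
  wc <- welch_csd(x, dt = 0.05, seg_len_s = 128, fmax = 0.25)
  keep <- wc$freqs >= 0.01
  analytic <- amp * wc$freqs[keep]^(-1) /
    ((2 * pi * wc$freqs[keep])^2 + 0.25)
  ratio <- Re(wc$csd[1, 1, keep]) / analytic
  expect_lt(abs(mean(ratio) - 1), 0.1)
})

test_that("power-law synthesis hits its target spectral density", {
  set.seed(4)
  v <- powerlaw_noise(8192, 0.1, amp = 0.3, exponent = 1, n_series = 1)
  wc <- welch_csd(v, dt = 0.1, seg_len_s = 100, fmax = 4)
  keep <- wc$freqs > 0.1 & wc$freqs < 4
  target <- 0.3 * wc$freqs[keep]^(-1)
  expect_lt(abs(mean(Re(wc$csd[1, 1, keep]) / target) - 1), 0.1)
  expect_equal(powerlaw_noise(64, 0.1, 0, 1, 2), matrix(0, 64, 2))
})

test_that("the Balloon observer rests at its fixed point and reaches steady state", {
  y <- balloon_bold(matrix(0, 100, 2), dt = 0.05)
  expect_equal(max(abs(y)), 0)
  # constant drive: derivatives vanish, output plateaus
  xc <- matrix(0.1, 4000, 1)
  attr(xc, "dt") <- 0.05
  yc <- balloon_bold(xc)
  tail_vals <- yc[3800:4000, 1]
  expect_lt(diff(range(tail_vals)), 1e-6)
})

test_that("the impulse response peaks at 3-8 s and matches a fine-grid integration", {
  dt <- 0.05
  x <- matrix(0, 600, 1); x[40, 1] <- 1 / dt   # unit-area impulse
  attr(x, "dt") <- dt
  y <- balloon_bold(x)
  pk <- which.max(y[, 1])
  t_pk <- (pk - 40) * dt
  expect_gt(t_pk, 3); expect_lt(t_pk, 8)
  expect_lt(min(y[, 1]), 0)                    # post-stimulus undershoot
  # oracle: same input on a 10x finer grid
  dtf <- dt / 10
  xf <- matrix(0, 6000, 1); xf[390 + 1:10, 1] <- 1 / dt
  attr(xf, "dt") <- dtf
  yf <- balloon_bold(xf)
  expect_equal(max(y[, 1]), max(yf[, 1]), tolerance = 0.01)
})

test_that("acquisition produces the study's session dimensions and is exact when clean", {
  a <- planted_coupling()
  ns <- neural_only_noise()
  x <- simulate_neural(a, ns, duration = 330, dt = 0.05, seed = 5)
  y <- balloon_bold(x)
  sc <- sample_and_corrupt(y, tr = 2, n_volumes = 165, noise = ns, seed = 6,
                           leak_sd = 0)
  expect_s3_class(sc$series, "session_series")
  expect_equal(nrow(sc$series), 165)
  expect_equal(attr(sc$series, "tr"), 2)
  expect_equal(ncol(sc$confounds), 15)
  # with obs/drift noise off and no leakage the decimation is exact
  idx <- round(seq(0, 164) * 2 / 0.05) + 1
  expect_equal(unclass(sc$series), y[idx, ], ignore_attr = TRUE)
})

test_that("confound regression removes leaked nuisance signal", {
  a <- planted_coupling()
  ns <- noise_spec(state_amp = 1e-4, obs_amp = 0, drift_amp = 0)
  x <- simulate_neural(a, ns, duration = 330, dt = 0.05, seed = 7)
  y <- balloon_bold(x)
  clean <- sample_and_corrupt(y, tr = 2, n_volumes = 165, noise = ns,
                              seed = 8, leak_sd = 0)$series
  # leakage strong enough to dominate the incidental correlation between the
  # (slow) BOLD signal and the smooth confounds
  leaky <- sample_and_corrupt(y, tr = 2, n_volumes = 165, noise = ns,
                              seed = 8, leak_sd = 2)
  res <- regress_confounds(leaky$series, leaky$confounds)
  centred_clean <- scale(unclass(clean), scale = FALSE)
  mse_with <- mean((unclass(res) - centred_clean)^2)
  mse_without <- mean((scale(unclass(leaky$series), scale = FALSE) -
                         centred_clean)^2)
  expect_lt(mse_with, mse_without)
})

test_that("voxel blocks reduce to their generating series", {
  a <- planted_coupling()
  s <- session_series(matrix(rnorm(300), 100, 3), tr = 2)
  vox0 <- make_voxels(s, 2, voxel_noise_sd = 0, seed = 1, gain_sd = 0)
  expect_equal(vox0[[1]][, 1], as.numeric(s[, 1]))
  expect_equal(vox0[[1]][, 2], as.numeric(s[, 1]))
  # noisy 50-voxel block: eigenvariate tracks the true series
  vox <- make_voxels(s, 50, voxel_noise_sd = 0.5, seed = 2)
  ev <- principal_eigenvariate(vox[[2]])
  expect_gt(abs(cor(ev, s[, 2])), 0.95)
})

test_that("simulation and acquisition are seed-deterministic", {
  a <- planted_coupling()
  ns <- noise_spec()
  x1 <- simulate_neural(a, ns, duration = 64, dt = 0.05, seed = 9)
  x2 <- simulate_neural(a, ns, duration = 64, dt = 0.05, seed = 9)
  expect_identical(x1, x2)
  y <- balloon_bold(x1)
  s1 <- sample_and_corrupt(y, 2, 32, ns, seed = 3)
  s2 <- sample_and_corrupt(y, 2, 32, ns, seed = 3)
  expect_identical(s1, s2)
})

test_that("session series round-trip through TSV + JSON sidecar", {
  s <- session_series(matrix(rnorm(96), 32, 3), tr = 2,
                      region_names = c("PrcG", "SMA", "rDT"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_session_series(s, path)
  back <- read_session_series(path)
  expect_equal(unclass(back), unclass(s), tolerance = 1e-12)
  expect_equal(attr(back, "tr"), 2)
  expect_equal(colnames(back), c("PrcG", "SMA", "rDT"))
})

test_that("unstable systems are rejected before simulation", {
  a <- matrix(0, 2, 2); a[1, 2] <- a[2, 1] <- 0.6
  expect_error(simulate_neural(a, neural_only_noise(), duration = 64),
               class = "longdcm_stability_error")
})
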