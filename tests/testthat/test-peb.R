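test_that("equal-precision all-ones PEB returns the arithmetic mean exactly", {
  ms <- c(0.1, 0.3, 0.5, 0.3)
  posts <- lapply(ms, function(m) {
    gauss_post(m, matrix(0.04, 1, 1), names = "a[1,1]")
  })
  X <- design_matrix(matrix(1, 4, 1, dimnames = list(NULL, "baseline")))
  # gamma pinned high and a flat beta prior: precision-weighted average with
  # equal weights
  fit <- peb_fit(posts, X, carried = 1, passes = 0, beta_var = 1e8,
                 gamma_range = c(12, 12 + 1e-9))
  expect_equal(unname(fit$beta_mean[1, 1]), mean(ms), tolerance = 1e-7)
})

test_that("with known between-level precision the fit equals the GLS closed form", {
  set.seed(2)
  p <- 3
  nm <- c("a[1,1]", "a[2,1]", "a[1,2]")
  posts <- lapply(1:4, function(i) {
    M <- matrix(rnorm(9), 3)
    gauss_post(rnorm(p), crossprod(M) / 5 + diag(0.01, 3), names = nm)
  })
  Xv <- cbind(baseline = 1, eff = c(1, -1, -1, 1))
  X <- design_matrix(Xv)
  g0 <- 2.5
  fit <- peb_fit(posts, X, carried = 1:3, passes = 0,
                 gamma_range = c(g0, g0 + 1e-9))
  # direct matrix oracle
  V <- lapply(posts, function(po) unname(po$covariance) + diag(exp(-g0), p))
  bigX <- do.call(rbind, lapply(1:4, function(i) kronecker(t(Xv[i, ]), diag(p))))
  W <- solve(as.matrix(Matrix::bdiag(V)))
  Pb <- t(bigX) %*% W %*% bigX + diag(1, 2 * p)
  oracle <- solve(Pb, t(bigX) %*% W %*% unlist(lapply(posts, `[[`, "mean")))
  expect_lt(max(abs(as.vector(t(fit$beta_mean)) - oracle)), 1e-8)
})

test_that("a saturated design with tiny between-level variance returns the unit means", {
  set.seed(3)
  posts <- lapply(1:3, function(i) gauss_post(rnorm(2), diag(1e-6, 2),
                                              names = c("a[1,1]", "a[2,1]")))
  X <- design_matrix(cbind(baseline = c(1, 1, 1),
                           d2 = c(0, 1, 0), d3 = c(0, 0, 1)))
  fit <- peb_fit(posts, X, carried = 1:2, passes = 0, beta_var = 1e6,
                 gamma_range = c(12, 12 + 1e-9))
  recon <- X$values %*% fit$beta_mean
  for (i in 1:3) {
    expect_equal(unname(recon[i, ]), unname(posts[[i]]$mean),
                 tolerance = 1e-4)
  }
})

test_that("PEB free energy is non-decreasing over EM sweeps", {
  set.seed(4)
  posts <- lapply(1:4, function(i) gauss_post(rnorm(2, 0, 0.3),
                                              diag(0.02, 2),
                                              names = c("a[1,1]", "a[2,1]")))
  fit <- peb_fit(posts, make_session_design(4), carried = 1:2, passes = 0,
                 em_iter = 4)
  expect_true(all(diff(fit$f_trace) > -1e-6))
})

test_that("group PEB is exchangeable and collapses correctly for identical subjects", {
  set.seed(5)
  X1 <- make_session_design(4)
  mk_subject <- function(seed) {
    set.seed(seed)
    posts <- lapply(1:4, function(i) gauss_post(rnorm(2, 0, 0.2),
                                                diag(0.02, 2),
                                                names = c("a[1,1]", "a[2,1]")))
    peb_fit(posts, X1, carried = 1:2, passes = 0)
  }
  subs <- lapply(c(11, 12, 13), mk_subject)
  g1 <- peb_of_peb(subs)
  g2 <- peb_of_peb(subs[c(3, 1, 2)])
  expect_equal(g1$beta_mean, g2$beta_mean, tolerance = 1e-6)
  expect_equal(g1$free_energy, g2$free_energy, tolerance = 1e-6)
  # identical subjects with (near) zero covariance: group mean equals the
  # shared second-level estimate
  s0 <- mk_subject(20)
  s0$beta_cov <- diag(1e-8, length(s0$beta_mean))
  gid <- peb_of_peb(list(s0, s0, s0))
  expect_equal(as.vector(t(gid$beta_mean)),
               unname(as.vector(t(s0$beta_mean))), tolerance = 1e-3)
})

test_that("inflating one subject's uncertainty shifts the group toward the others", {
  nm <- "a[1,1]"
  mk <- function(m, v) gauss_post(m, matrix(v, 1, 1), names = nm)
  X <- design_matrix(matrix(1, 3, 1, dimnames = list(NULL, "baseline")))
  g0 <- 6
  base <- peb_fit(list(mk(0.1, 0.01), mk(0.2, 0.01), mk(0.9, 0.01)),
                  X, carried = 1, passes = 0, gamma_range = c(g0, g0 + 1e-9))
  infl <- peb_fit(list(mk(0.1, 0.01), mk(0.2, 0.01), mk(0.9, 1)),
                  X, carried = 1, passes = 0, gamma_range = c(g0, g0 + 1e-9))
  # the outlying third subject loses weight, so the mean moves toward 0.15
  expect_lt(infl$beta_mean[1, 1], base$beta_mean[1, 1])
})

test_that("the credible-interval non-zero criterion thresholds correctly", {
  fake <- structure(list(
    beta_mean = matrix(c(0.3, 0.1, 0), 3, 1,
                       dimnames = list(c("baseline", "transient", "sustained"),
                                       "a[2,1]")),
    beta_cov = diag(0.01, 3),
    param_names = "a[2,1]",
    effect_grid = NULL), class = "peb_posterior")
  tab <- threshold_nonzero(fake)
  expect_s3_class(tab, "effect_table")
  expect_equal(tab$survives, c(TRUE, FALSE, FALSE))   # |z| = 3, 1, 0
  expect_equal(tab$lo95, tab$mean - 1.959964 * 0.1, tolerance = 1e-6)
  expect_equal(tab$source[1], 1)
  expect_equal(tab$target[1], 2)
})

test_that("constant scores give a null association posterior", {
  set.seed(6)
  posts <- lapply(1:2, function(j) {
    out <- lapply(1:4, function(i) gauss_post(rnorm(2, 0, 0.2), diag(0.02, 2),
                                              names = c("a[1,1]", "a[2,1]")))
    names(out) <- c("op-1d", "op+1d", "op+7d", "op+3m")
    out
  })
  scores <- data.frame(subject = rep(1:2, each = 3),
                       timepoint = rep(c("op-1d", "op+7d", "op+3m"), 2),
                       score = 15)
  g <- covariate_peb(posts, scores, score_name = "posture")
  idx <- which(g$effect_grid$session_effect == "posture")
  expect_lt(max(abs(as.vector(t(g$beta_mean))[idx])), 1e-6)
  tab <- threshold_nonzero(g)
  expect_false(any(tab$survives[tab$effect == "posture"]))
})

test_that("the association scales inversely with an affine score rescaling", {
  set.seed(7)
  nm <- c("a[1,1]", "a[2,1]")
  posts <- lapply(1:4, function(j) {
    sc <- c(10, 14, 18)
    out <- lapply(seq_len(4), function(i) {
      s <- c(10, 12, 14, 18)[i]
      gauss_post(c(0.05, 0.02) * s + rnorm(2, 0, 0.01), diag(0.005, 2),
                 names = nm)
    })
    names(out) <- c("op-1d", "op+1d", "op+7d", "op+3m")
    out
  })
  scores1 <- data.frame(subject = rep(1:4, each = 3),
                        timepoint = rep(c("op-1d", "op+7d", "op+3m"), 4),
                        score = rep(c(10, 14, 18), 4))
  scores2 <- scores1; scores2$score <- scores2$score * 2
  g1 <- covariate_peb(posts, scores1, score_name = "s")
  g2 <- covariate_peb(posts, scores2, score_name = "s")
  idx <- which(g1$effect_grid$session_effect == "s")
  b1 <- as.vector(t(g1$beta_mean))[idx]
  b2 <- as.vector(t(g2$beta_mean))[idx]
  expect_equal(b2, b1 / 2, tolerance = 0.05)
})

test_that("mismatched inputs are rejected", {
  posts <- list(gauss_post(0.1, matrix(0.01), names = "a[1,1]"),
                gauss_post(0.2, matrix(0.01), names = "a[2,1]"))
  X <- design_matrix(matrix(1, 2, 1, dimnames = list(NULL, "baseline")))
  expect_error(peb_fit(posts, X), "ordering")
  one <- gauss_post(0.1, matrix(0.01), names = "a[1,1]")
  expect_error(peb_fit(list(one), design_matrix(matrix(1, 3, 1,
                         dimnames = list(NULL, "baseline")))), "rows")
  scores_bad <- data.frame(subject = 1, timepoint = c("op-1d", "op+7d"),
                           score = c(1, 2))
  named <- list(`op-1d` = one, `op+1d` = one, `op+7d` = one, `op+3m` = one)
  expect_error(covariate_peb(list(named), scores_bad), "score")
})

test_that("PEB posteriors round-trip through JSON with identical thresholding", {
  set.seed(8)
  posts <- lapply(1:4, function(i) gauss_post(rnorm(2, 0, 0.3), diag(0.02, 2),
                                              names = c("a[1,1]", "a[2,1]")))
  fit <- peb_fit(posts, make_session_design(4), carried = 1:2, passes = 0)
  path <- withr::local_tempfile(fileext = ".json")
  write_peb_posterior(fit, path)
  back <- read_peb_posterior(path)
  expect_lt(max(abs(back$beta_mean - fit$beta_mean)), 1e-12)
  expect_lt(max(abs(back$beta_cov - fit$beta_cov)), 1e-12)
  expect_identical(threshold_nonzero(back)$survives,
                   threshold_nonzero(fit)$survives)
})
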