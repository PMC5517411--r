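# Spectral DCM: a generative model of BOLD cross-spectral densities
# parameterized by effective connectivity, haemodynamics and power-law noise,
# inverted by variational Laplace to a Gaussian posterior with free energy.

# ---- linearized forward model -------------------------------------------

#' Jacobian of the combined neural + haemodynamic system at its fixed point
#'
#' State ordering per region r: neural x_r, then s, f, v, q blocks. The
#' neural block is the effective rate matrix; the Balloon blocks are the
#' analytic partial derivatives at the resting fixed point
#' (x = 0, s = 0, f = v = q = 1).
#' @noRd
full_jacobian <- function(up, hc = hemo_constants()) {
  n <- nrow(up$a)
  tau <- hc$tau * exp(up$h_tau)
  eps <- hc$epsilon * exp(up$h_eps)
  J <- matrix(0, 5 * n, 5 * n)
  ix <- seq_len(n); is_ <- n + ix; if_ <- 2 * n + ix
  iv <- 3 * n + ix; iq <- 4 * n + ix
  J[ix, ix] <- effective_matrix(up$a)
  J[cbind(is_, ix)] <- eps
  J[cbind(is_, is_)] <- -hc$kappa
  J[cbind(is_, if_)] <- -hc$gamma
  J[cbind(if_, is_)] <- 1
  J[cbind(iv, if_)] <- 1 / tau
  J[cbind(iv, iv)] <- -1 / (hc$alpha * tau)
  dEdf <- 1 + (1 - hc$E0) * log(1 - hc$E0) / hc$E0   # d(f E(f)/E0)/df at f=1
  J[cbind(iq, if_)] <- dEdf / tau
  J[cbind(iq, iv)] <- -(1 / hc$alpha - 1) / tau
  J[cbind(iq, iq)] <- -1 / tau
  J
}

#' BOLD output gradient at the fixed point
#' @noRd
output_gradient <- function(n, hc = hemo_constants()) {
  L <- matrix(0, n, 5 * n)
  ix <- seq_len(n)
  L[cbind(ix, 3 * n + ix)] <- 100 * hc$V0 * (hc$k2 - hc$k3)
  L[cbind(ix, 4 * n + ix)] <- -100 * hc$V0 * (hc$k1 + hc$k2)
  L
}

#' Right-hand side of the combined deterministic system (for validation)
#'
#' Used to check the analytic Jacobian against finite differences.
#' @noRd
full_rhs <- function(state, up, hc = hemo_constants()) {
  n <- nrow(up$a)
  tau <- hc$tau * exp(up$h_tau)
  eps <- hc$epsilon * exp(up$h_eps)
  x <- state[seq_len(n)]; s <- state[n + seq_len(n)]
  f <- state[2 * n + seq_len(n)]; v <- state[3 * n + seq_len(n)]
  q <- state[4 * n + seq_len(n)]
  Ef <- 1 - (1 - hc$E0)^(1 / f)
  c(effective_matrix(up$a) %*% x,
    eps * x - hc$kappa * s - hc$gamma * (f - 1),
    s,
    (f - v^(1 / hc$alpha)) / tau,
    (f * Ef / hc$E0 - v^(1 / hc$alpha - 1) * q) / tau)
}

#' Neural-to-BOLD transfer function
#'
#' `H(f) = L (i 2 pi f I - J)^{-1} B`, with `J` the Jacobian of the combined
#' neural + haemodynamic system at its fixed point, `B` injecting state noise
#' into the neural states and `L` the gradient of the BOLD output equation.
#' Computed via one eigendecomposition of `J` shared across frequencies.
#'
#' @param params Packed parameter vector (see [pack_params()]).
#' @param freqs Frequency grid (Hz).
#' @param n_regions Number of regions.
#' @param bypass_hemo If `TRUE`, return the bare neural transfer
#'   `(i 2 pi f I - A_eff)^{-1}` (test mode).
#' @return n x n x n_freq complex array.
#' @export
transfer_function <- function(params, freqs, n_regions,
                              bypass_hemo = FALSE) {
  up <- unpack_params(params, n_regions)
  if (!is_stable(up$a)) {
    ldcm_stop("unstable coupling matrix", class = "longdcm_stability_error")
  }
  n <- n_regions
  H <- array(complex(real = 0), c(n, n, length(freqs)))
  if (bypass_hemo) {
    a_eff <- effective_matrix(up$a)
    for (j in seq_along(freqs)) {
      H[, , j] <- solve(diag(n) * (2i * pi * freqs[j]) - a_eff)
    }
    return(H)
  }
  J <- full_jacobian(up)
  L <- output_gradient(n)
  B <- rbind(diag(n), matrix(0, 4 * n, n))
  eg <- tryCatch(eigen(J), error = function(e) NULL)
  if (!is.null(eg) && min(abs(eg$values)) > 0 &&
      rcond(abs(eg$vectors)) > 1e-10) {
    W <- solve(eg$vectors, B + 0i)
    LU <- (L + 0i) %*% eg$vectors
    for (j in seq_along(freqs)) {
      H[, , j] <- LU %*% (W / (2i * pi * freqs[j] - eg$values))
    }
  } else {
    for (j in seq_along(freqs)) {
      H[, , j] <- (L + 0i) %*% solve(diag(5 * n) * (2i * pi * freqs[j]) - J, B + 0i)
    }
  }
  H
}

#' Predicted cross-spectral density of the generative model
#'
#' `G_y(f) = H(f) G_v(f) H(f)^H + G_e(f)` with diagonal power-law state and
#' observation noise spectra `exp(ln_alpha) * f^(-beta)`.
#'
#' @inheritParams transfer_function
#' @return A [spectral_data()].
#' @export
predict_csd <- function(params, freqs, n_regions, bypass_hemo = FALSE) {
  up <- unpack_params(params, n_regions)
  H <- transfer_function(params, freqs, n_regions, bypass_hemo = bypass_hemo)
  n <- n_regions
  gv <- exp(up$noise["ln_alpha_v"]) * freqs^(-up$noise["beta_v"])
  ge <- exp(up$noise["ln_alpha_e"]) * freqs^(-up$noise["beta_e"])
  G <- array(complex(real = 0), c(n, n, length(freqs)))
  for (j in seq_along(freqs)) {
    Hf <- H[, , j]
    S <- gv[j] * (Hf %*% Conj(t(Hf))) + diag(ge[j], n)
    G[, , j] <- (S + Conj(t(S))) / 2
  }
  spectral_data(freqs, G, source = "model")
}

# ---- data vectorization -------------------------------------------------

#' Vectorize a Hermitian CSD array into real channels
#'
#' Per frequency: the n real diagonal entries, then Re and Im of the upper
#' off-diagonal entries. Returns the vector plus a channel-class factor
#' ("diag"/"offdiag") used for precision hyperparameters.
#' @noRd
vec_csd <- function(csd) {
  n <- dim(csd)[1]
  ut <- which(upper.tri(matrix(0, n, n)))
  per_freq <- function(S) c(Re(diag(S)), Re(S[ut]), Im(S[ut]))
  y <- as.vector(apply(csd, 3, per_freq))
  cls <- rep(c(rep("diag", n), rep("offdiag", n * (n - 1))), dim(csd)[3])
  list(y = y, class = factor(cls, levels = c("diag", "offdiag")))
}

# ---- variational Laplace ------------------------------------------------

#' Whitened channel vector of the model prediction (helper for centering)
#' @noRd
gfun_raw <- function(theta, wvec, scale, freqs, n) {
  g <- predict_csd(theta, freqs, n)
  (vec_csd(g$csd)$y / scale) * wvec
}

#' Invert a spectral DCM by variational Laplace
#'
#' Iterated Gauss-Newton ascent on the variational free energy of a Gaussian
#' posterior approximation, treating real and imaginary parts of the CSD at
#' each frequency as independent Gaussian channels with log-precision
#' hyperparameters shared within channel class (diagonal vs off-diagonal),
#' updated by safeguarded Newton (EM) steps. Levenberg-style damping is used
#' on parameter steps; only steps that increase the free energy are accepted.
#' Convergence is declared when the free-energy change stays below `tol`
#' (0.01 nat) for 3 consecutive iterations, or at `maxit` iterations (the
#' `converged` flag is then `FALSE`).
#'
#' @param data A [spectral_data()] (e.g. from [estimate_csd()]).
#' @param prior A `"dcm_prior"` (default [default_priors()]).
#' @param opts List: `maxit` (128), `tol` (0.01), `fd_step` (1e-4),
#'   `lambda0`/`lambda_prec` (hyperprior on channel log-precisions),
#'   `scale_data` (TRUE), `verbose` (FALSE).
#' @return Object of class `"dcm_posterior"`: posterior `mean` and
#'   `covariance` over the packed parameters, `free_energy` (nats), the
#'   `prior`, iteration metadata and the free-energy trace.
#' @export
invert_spdcm <- function(data, prior = NULL, opts = list()) {
  stopifnot(inherits(data, "spectral_data"))
  n <- data$n_regions
  prior <- prior %||% default_priors(n)
  o <- utils::modifyList(list(maxit = 128, tol = 0.01, fd_step = 1e-4,
                              lambda0 = 4, lambda_prec = 1 / 16,
                              scale_data = TRUE, verbose = FALSE), opts)
  vec <- vec_csd(data$csd)
  scale <- if (o$scale_data) {
    mean(apply(data$csd, 3, function(S) mean(Re(diag(S)))))
  } else 1
  # per-frequency whitening: each frequency's channels are normalized by the
  # data's mean diagonal power there, so a steep spectrum does not let a few
  # low-frequency bins dominate the likelihood
  fweight <- apply(data$csd, 3, function(S) mean(Re(diag(S)))) / scale
  fweight <- pmax(fweight, 1e-6 * max(fweight))
  wvec <- rep(1 / fweight, each = data$n_regions^2)
  y <- (vec$y / scale) * wvec
  n_chan <- length(y)
  cls <- vec$class
  cls_idx <- split(seq_len(n_chan), cls)
  cls_idx <- cls_idx[vapply(cls_idx, length, 1L) > 0]
  n_cls <- length(cls_idx)
  freqs <- data$freqs

  mu0 <- prior$mean
  if (isTRUE(o$center_amplitudes %||% TRUE)) {
    # center the noise log-amplitude priors so the prior-mean model matches
    # the overall power of the (rescaled) data; without this the inversion
    # starts orders of magnitude off and the amplitude priors cannot bridge
    # the gap
    probe <- mu0
    probe["ln_alpha_v"] <- 0; probe["ln_alpha_e"] <- log(1e-12)
    gv_diag <- mean(tapply(gfun_raw(probe, wvec, scale, freqs, n),
                           cls == "diag", mean)["TRUE"])
    probe["ln_alpha_v"] <- log(1e-12); probe["ln_alpha_e"] <- 0
    ge_diag <- mean(tapply(gfun_raw(probe, wvec, scale, freqs, n),
                           cls == "diag", mean)["TRUE"])
    mu0["ln_alpha_v"] <- log(0.5 / max(gv_diag, 1e-12))
    mu0["ln_alpha_e"] <- log(0.5 / max(ge_diag, 1e-12))
  }
  free <- prior$variance > 0
  p_free <- sum(free)
  P0 <- diag(1 / prior$variance[free], p_free)
  ldP0 <- sum(log(1 / prior$variance[free]))

  gfun <- function(theta_free) {
    th <- mu0
    th[free] <- theta_free
    g <- tryCatch(predict_csd(th, freqs, n), error = function(e) NULL)
    if (is.null(g)) return(NULL)
    (vec_csd(g$csd)$y / scale) * wvec
  }

  jac <- function(theta_free, g0) {
    J <- matrix(0, n_chan, p_free)
    for (k in seq_len(p_free)) {
      h <- o$fd_step * max(1, abs(theta_free[k]))
      tp <- theta_free; tp[k] <- tp[k] + h
      gp <- gfun(tp)
      if (is.null(gp)) {             # perturbed model unstable: step backwards
        tp[k] <- theta_free[k] - h
        gm <- gfun(tp)
        if (is.null(gm)) ldcm_stop("model unstable under tiny perturbation")
        J[, k] <- (g0 - gm) / h
      } else {
        J[, k] <- (gp - g0) / h
      }
    }
    J
  }

  pi_vec <- function(lambda) {
    w <- numeric(n_chan)
    for (c_ in seq_len(n_cls)) w[cls_idx[[c_]]] <- exp(lambda[c_])
    w
  }

  fe <- function(e, lambda, d_free, Sigma) {
    w <- pi_vec(lambda)
    ll <- -0.5 * sum(w * e^2) + 0.5 * sum(log(w)) - 0.5 * n_chan * log(2 * pi)
    lp <- -0.5 * drop(t(d_free) %*% P0 %*% d_free)
    lh <- -0.5 * o$lambda_prec * sum((lambda - o$lambda0)^2)
    ent <- 0.5 * (determinant(Sigma, logarithm = TRUE)$modulus + ldP0)
    as.numeric(ll + lp + lh + ent)
  }

  theta <- mu0[free]
  if (!is.null(o$init)) {
    # alternative starting point (same priors); used to probe local optima
    init <- o$init
    if (length(init) == length(mu0)) init <- init[free]
    if (length(init) != p_free) ldcm_stop("`init` has the wrong length")
    theta <- as.numeric(init)
  }
  lambda <- rep(o$lambda0, n_cls)
  g0 <- gfun(theta)
  if (is.null(g0)) ldcm_stop("prior mean implies an unstable model",
                             class = "longdcm_stability_error")
  e <- y - g0
  J <- jac(theta, g0)
  damp <- 1
  F_trace <- numeric(0)
  F_cur <- -Inf
  n_small <- 0L
  converged <- FALSE
  iter <- 0L

  post_cov <- function(J, lambda) {
    w <- pi_vec(lambda)
    Hm <- crossprod(J * sqrt(w)) + P0
    Hm <- (Hm + t(Hm)) / 2
    tryCatch(solve(Hm),
             error = function(e2) solve(Hm + diag(1e-8 * mean(diag(Hm)), p_free)))
  }

  for (iter in seq_len(o$maxit)) {
    # --- M-step: safeguarded Newton updates of channel log-precisions
    Sigma <- post_cov(J, lambda)
    for (c_ in seq_len(n_cls)) {
      idx <- cls_idx[[c_]]
      Jc <- J[idx, , drop = FALSE]
      tr_c <- sum((Jc %*% Sigma) * Jc)
      sse <- sum(e[idx]^2)
      for (it2 in 1:4) {
        w_c <- exp(lambda[c_])
        gr <- 0.5 * (length(idx) - w_c * (sse + tr_c)) -
          o$lambda_prec * (lambda[c_] - o$lambda0)
        hs <- -0.5 * w_c * (sse + tr_c) - o$lambda_prec
        step <- -gr / hs
        step <- max(min(step, 2), -2)
        lambda[c_] <- max(min(lambda[c_] + step, 16), -8)
        if (abs(step) < 1e-4) break
      }
    }
    Sigma <- post_cov(J, lambda)
    F_cur <- fe(e, lambda, theta - mu0[free], Sigma)

    # --- E-step: damped Gauss-Newton step on the parameters
    w <- pi_vec(lambda)
    gvec <- drop(crossprod(J, w * e)) - P0 %*% (theta - mu0[free])
    Hm <- crossprod(J * sqrt(w)) + P0
    accepted <- FALSE
    for (try_ in 1:12) {
      Hd <- Hm + damp * diag(diag(Hm), p_free)
      delta <- tryCatch(solve(Hd, gvec), error = function(e2) NULL)
      if (!is.null(delta)) {
        theta_new <- theta + drop(delta)
        g_new <- gfun(theta_new)
        if (!is.null(g_new)) {
          e_new <- y - g_new
          J_new <- jac(theta_new, g_new)
          Sigma_new <- post_cov(J_new, lambda)
          F_new <- fe(e_new, lambda, theta_new - mu0[free], Sigma_new)
          if (is.finite(F_new) && F_new > F_cur - 1e-8) {
            theta <- theta_new; e <- e_new; J <- J_new
            dF <- F_new - F_cur
            F_cur <- F_new
            damp <- max(damp / 2, 1e-6)
            accepted <- TRUE
            break
          }
        }
      }
      damp <- damp * 8
    }
    F_trace <- c(F_trace, F_cur)
    if (o$verbose) message(sprintf("iter %3d  F = %.4f", iter, F_cur))
    if (accepted) {
      n_small <- if (dF < o$tol) n_small + 1L else 0L
    } else {
      n_small <- n_small + 1L
    }
    if (n_small >= 3L) { converged <- TRUE; break }
  }

  Sigma <- post_cov(J, lambda)
  if (!is.finite(F_cur)) {
    ldcm_stop("non-finite free energy during inversion",
              class = "longdcm_inversion_error")
  }
  mean_full <- mu0
  mean_full[free] <- theta
  cov_full <- matrix(0, length(mu0), length(mu0),
                     dimnames = list(names(mu0), names(mu0)))
  cov_full[free, free] <- nearest_psd(Sigma)
  structure(list(mean = mean_full, covariance = cov_full,
                 free_energy = F_cur, prior = prior, lambda = lambda,
                 iterations = iter, converged = converged,
                 f_trace = F_trace, data_scale = scale,
                 n_regions = n, freqs = freqs),
            class = "dcm_posterior")
}

#' @export
print.dcm_posterior <- function(x, ...) {
  cat(sprintf(paste0("<dcm_posterior> %d regions, F = %.2f nats, ",
                     "%d iterations%s\n"),
              x$n_regions, x$free_energy, x$iterations,
              if (x$converged) " (converged)" else " (NOT converged)"))
  invisible(x)
}

#' Posterior coupling matrix of an inversion
#'
#' @param posterior A `"dcm_posterior"`.
#' @return n x n posterior-mean coupling matrix.
#' @export
posterior_a <- function(posterior) {
  unpack_params(posterior$mean, posterior$n_regions)$a
}
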