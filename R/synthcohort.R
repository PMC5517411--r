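# Ground-truth cohort generation with the hierarchical structure of the
# three-level model: group effects -> per-subject effects -> per-session
# coupling matrices, plus symptom scores coupled to designated connections.

SESSION_LABELS <- c("op-1d", "op+1d", "op+7d", "op+3m")
SCORE_LABELS <- c("op-1d", "op+7d", "op+3m")
SCORE_SESSION <- c("op-1d" = 1L, "op+7d" = 3L, "op+3m" = 4L)

#' Session-level design matrix
#'
#' The 4-session longitudinal design: a baseline column `[1 1 1 1]`, a
#' transient-effect column `[1 -1 -1 1]` (pre and 3-month sessions vs the
#' early post-treatment sessions) and a sustained treatment-effect column
#' `[1 1 -1 -1]` (pre-treatment pair vs post-treatment pair). Only the
#' 4-session design is defined.
#'
#' @param n_sessions Must be 4.
#' @return Object of class `"design_matrix"`: list with `values` (4 x 3),
#'   `effect_names`, `unit_names`.
#' @export
make_session_design <- function(n_sessions = 4) {
  if (!identical(as.integer(n_sessions), 4L)) {
    ldcm_stop("only the 4-session longitudinal design is defined",
              class = "longdcm_design_error")
  }
  design_matrix(cbind(baseline = c(1, 1, 1, 1),
                      transient = c(1, -1, -1, 1),
                      sustained = c(1, 1, -1, -1)),
                unit_names = SESSION_LABELS)
}

#' Construct a design matrix
#'
#' @param values units x effects numeric matrix; the first column must be an
#'   all-ones baseline and the matrix must have full column rank.
#' @param effect_names,unit_names Optional labels (defaults from dimnames).
#' @return Object of class `"design_matrix"`.
#' @export
#' @param allow_rank_deficient Skip the full-rank check (used for degenerate
#'   covariate designs, e.g. a constant score whose centred column is zero;
#'   the Bayesian GLM remains proper through the prior).
design_matrix <- function(values, effect_names = NULL, unit_names = NULL,
                          allow_rank_deficient = FALSE) {
  values <- as.matrix(values)
  effect_names <- effect_names %||% colnames(values) %||%
    sprintf("effect%d", seq_len(ncol(values)))
  unit_names <- unit_names %||% rownames(values) %||%
    sprintf("unit%d", seq_len(nrow(values)))
  if (any(values[, 1] != 1)) {
    ldcm_stop("first design column must be an all-ones baseline")
  }
  if (!allow_rank_deficient &&
      (ncol(values) > nrow(values) || qr(values)$rank < ncol(values))) {
    ldcm_stop("design matrix must be full column rank with no more effects than units")
  }
  dimnames(values) <- list(unit_names, effect_names)
  structure(list(values = values, effect_names = effect_names,
                 unit_names = unit_names),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d units x %d effects\n",
              nrow(x$values), ncol(x$values)))
  print(x$values)
  invisible(x)
}

#' Specify planted connection effects
#'
#' @param source,target Region indices of the connection (source k -> target
#'   i, i.e. entry `A[target, source]`).
#' @param transient,sustained Effect sizes (coupling units) on the transient
#'   and sustained regressors.
#' @param score_coupling Gain linking this connection's session-wise coupling
#'   to the symptom score (score units per coupling unit).
#' @return A one-row data frame; rows can be `rbind`-ed to plant several
#'   connections.
#' @export
connection_effect <- function(source, target, transient = 0, sustained = 0,
                              score_coupling = 0) {
  data.frame(source = as.integer(source), target = as.integer(target),
             transient = transient, sustained = sustained,
             score_coupling = score_coupling)
}

#' @noRd
conn_index <- function(target, source, n) (source - 1L) * n + target

#' Sample a ground-truth cohort
#'
#' Draws a three-level hierarchy: a group-level effect matrix `beta3`
#' (baseline / transient / sustained x connections), per-subject effect
#' matrices `beta2[[j]] = beta3 + N(0, sigma3^2)` (all-ones group design),
#' and per-session coupling matrices
#' `theta[[j]][[i]] = X1[i, ] beta2[[j]] + N(0, sigma2^2)`. The baseline row
#' is a weakly coupled stable random network (off-diagonals N(0, 0.05^2),
#' diagonals 0, i.e. self-rate -0.5/s); random components are re-jittered
#' until every session matrix is stable (fixed planted effects untouched),
#' with a bounded retry count.
#'
#' @param n_subjects Number of subjects (default 8).
#' @param n_regions Number of regions (>= 2; default 6).
#' @param effect_spec Data frame of [connection_effect()] rows (may be NULL).
#' @param sigma2,sigma3 Between-session and between-subject random-effect
#'   standard deviations (coupling units).
#' @param seed Integer seed; the result is fully reproducible from it.
#' @param max_retries Stability retries per draw (default 100).
#' @return Object of class `"group_truth"` with fields `beta3`, `beta2`,
#'   `theta`, `sigma2`, `sigma3`, `score_coupling`, `design`, `n_regions`.
#' @export
sample_group_truth <- function(n_subjects = 8, n_regions = 6,
                               effect_spec = NULL, sigma2 = 0.05,
                               sigma3 = 0.05, seed = 1, max_retries = 100) {
  if (n_regions < 2) ldcm_stop("need at least 2 regions")
  check_scalar(sigma2, "sigma2", lower = 0)
  check_scalar(sigma3, "sigma3", lower = 0)
  if (!is.null(effect_spec)) {
    stopifnot(all(c("source", "target", "transient", "sustained") %in%
                    names(effect_spec)))
    if (any(!is.finite(as.matrix(effect_spec[c("transient", "sustained")])))) {
      ldcm_stop("effect sizes must be finite")
    }
    if (any(effect_spec$source > n_regions | effect_spec$target > n_regions)) {
      ldcm_stop("effect_spec indices exceed n_regions")
    }
  }
  n <- n_regions
  p <- n^2
  X1 <- make_session_design(4)
  set.seed(seed)

  # group-level effects: stable random baseline network
  baseline <- NULL
  for (try_ in seq_len(max_retries)) {
    a0 <- matrix(stats::rnorm(p, 0, 0.05), n, n)
    diag(a0) <- 0
    if (is_stable(a0)) { baseline <- a0; break }
  }
  if (is.null(baseline)) {
    ldcm_stop("could not draw a stable baseline network",
              class = "longdcm_generation_error")
  }
  beta3 <- matrix(0, 3, p,
                  dimnames = list(X1$effect_names, param_names(n)[seq_len(p)]))
  beta3[1, ] <- as.vector(baseline)
  score_coupling <- stats::setNames(numeric(p), colnames(beta3))
  if (!is.null(effect_spec)) {
    for (r in seq_len(nrow(effect_spec))) {
      j <- conn_index(effect_spec$target[r], effect_spec$source[r], n)
      beta3["transient", j] <- beta3["transient", j] + effect_spec$transient[r]
      beta3["sustained", j] <- beta3["sustained", j] + effect_spec$sustained[r]
      if ("score_coupling" %in% names(effect_spec)) {
        score_coupling[j] <- score_coupling[j] + effect_spec$score_coupling[r]
      }
    }
  }

  beta2 <- vector("list", n_subjects)
  theta <- vector("list", n_subjects)
  for (jsub in seq_len(n_subjects)) {
    beta2[[jsub]] <- beta3 + matrix(stats::rnorm(3 * p, 0, sigma3), 3, p,
                                    dimnames = dimnames(beta3))
    theta[[jsub]] <- vector("list", 4)
    names(theta[[jsub]]) <- SESSION_LABELS
    for (ises in 1:4) {
      fixed <- drop(X1$values[ises, ] %*% beta2[[jsub]])
      ok <- FALSE
      for (try_ in seq_len(max_retries)) {
        th <- fixed + stats::rnorm(p, 0, sigma2)
        if (is_stable(matrix(th, n, n))) {
          theta[[jsub]][[ises]] <- matrix(th, n, n)
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        ldcm_stop(sprintf(
          "could not draw a stable session matrix for subject %d, session %s",
          jsub, SESSION_LABELS[ises]), class = "longdcm_generation_error")
      }
    }
  }
  structure(list(beta3 = beta3, beta2 = beta2, theta = theta,
                 sigma2 = sigma2, sigma3 = sigma3,
                 score_coupling = score_coupling, design = X1,
                 n_regions = n, n_subjects = n_subjects, seed = seed),
            class = "group_truth")
}

#' @export
print.group_truth <- function(x, ...) {
  cat(sprintf("<group_truth> %d subjects x 4 sessions, %d regions (seed %d)\n",
              x$n_subjects, x$n_regions, x$seed))
  invisible(x)
}

#' Generate symptom scores from a cohort's coupling trajectories
#'
#' Scores at the three measured time points (1 day before, 7 days after and
#' 3 months after treatment; the day-after session carries no score) are a
#' baseline plus a linear combination of the subject's session-wise coupling
#' values through `score_coupling`, plus Gaussian noise, clipped at 0.
#'
#' @param truth A [sample_group_truth()] result.
#' @param baseline_score Score at zero coupling deviation (clinical scale
#'   units, default 20).
#' @param noise_sd Score noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return Data frame of class `"score_table"` with columns
#'   `subject,timepoint,score`; exactly 3 rows per subject.
#' @export
generate_scores <- function(truth, baseline_score = 20, noise_sd = 1,
                            seed = 1) {
  check_scalar(noise_sd, "noise_sd", lower = 0)
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(truth$n_subjects), function(jsub) {
    do.call(rbind, lapply(SCORE_LABELS, function(tp) {
      ises <- SCORE_SESSION[[tp]]
      th <- as.vector(truth$theta[[jsub]][[ises]])
      raw <- baseline_score + sum(truth$score_coupling * th) +
        stats::rnorm(1, 0, noise_sd)
      data.frame(subject = jsub, timepoint = tp, score = max(raw, 0))
    }))
  }))
  rows$timepoint <- factor(rows$timepoint, levels = SCORE_LABELS)
  class(rows) <- c("score_table", "data.frame")
  rows
}

#' Serialize / restore a ground-truth cohort as JSON
#'
#' @param truth A `"group_truth"`.
#' @param path File path (JSON).
#' @return `path` invisibly; `read_group_truth()` returns the restored
#'   object.
#' @export
write_group_truth <- function(truth, path) {
  out <- list(beta3 = truth$beta3, beta2 = truth$beta2,
              theta = lapply(truth$theta, function(tl) lapply(tl, identity)),
              sigma2 = truth$sigma2, sigma3 = truth$sigma3,
              score_coupling = as.list(truth$score_coupling),
              n_regions = truth$n_regions, n_subjects = truth$n_subjects,
              seed = truth$seed)
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_group_truth
#' @export
read_group_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  n <- raw$n_regions
  X1 <- make_session_design(4)
  as_mat <- function(rows, nr, nc) {
    matrix(unlist(rows), nr, nc, byrow = TRUE)   # JSON stores row-major
  }
  beta3 <- as_mat(raw$beta3, 3, n^2)
  dimnames(beta3) <- list(X1$effect_names, param_names(n)[seq_len(n^2)])
  beta2 <- lapply(raw$beta2, function(b) {
    out <- as_mat(b, 3, n^2)
    dimnames(out) <- dimnames(beta3)
    out
  })
  theta <- lapply(raw$theta, function(tl) {
    out <- lapply(tl, as_mat, nr = n, nc = n)
    names(out) <- SESSION_LABELS
    out
  })
  structure(list(beta3 = beta3, beta2 = beta2, theta = theta,
                 sigma2 = raw$sigma2, sigma3 = raw$sigma3,
                 score_coupling = stats::setNames(unlist(raw$score_coupling),
                                                  colnames(beta3)),
                 design = X1, n_regions = n, n_subjects = raw$n_subjects,
                 seed = raw$seed),
            class = "group_truth")
}
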