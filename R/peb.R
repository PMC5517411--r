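# Parametric empirical Bayes: Bayesian general linear models over lower-level
# Gaussian posteriors -- per-subject PEB across sessions, group PEB-of-PEB
# across subjects, symptom-covariate PEB, and credible-interval thresholding.
#
# Model for m units with carried parameter vectors theta_i (dimension p):
#   theta_i = (x_i' (x) I_p) beta + eps_i,   eps_i ~ N(0, exp(-gamma) I_p)
#   beta ~ N(0, I)
# The lower level enters through its posterior means AND covariances: the
# observation model is m_i ~ N(theta_i, C_i), so the marginal covariance of
# unit i is V_i(gamma) = C_i + exp(-gamma) I_p. Given gamma the posterior
# over beta is the generalized-least-squares (GLS) solution; gamma is
# optimized by EM on the Laplace free energy (exact 1-D maximization of the
# marginal likelihood plus a mild N(0, 4^2) hyperprior).

#' Fit a parametric-empirical-Bayes model over Gaussian posteriors
#'
#' @param posteriors List of `"dcm_posterior"` (or `"peb_posterior"`) objects
#'   sharing a parameter ordering; one per design row.
#' @param X A [design_matrix()] with one row per posterior.
#' @param carried Integer indices of the packed parameters carried to this
#'   level (default: all coupling-matrix entries).
#' @param gamma_range Search interval for the between-level log precision.
#' @param beta_var Prior variance of each beta entry (default 1).
#' @param passes Number of empirical-prior passes: after the first fit, the
#'   lower-level posteriors are re-evaluated under the level's empirical
#'   priors by Gaussian conditioning and the level is refit (default 1 extra
#'   pass; 0 disables).
#' @param em_iter Number of EM sweeps recorded in the free-energy trace.
#' @return Object of class `"peb_posterior"`: `beta_mean` (effects x
#'   connections), `beta_cov`, `gamma`, `free_energy`, `f_trace`, `design`,
#'   `carried`, `param_names`, and `empirical_priors` (per unit).
#' @export
peb_fit <- function(posteriors, X, carried = NULL, gamma_range = c(-8, 12),
                    beta_var = 1, passes = 1, em_iter = 3) {
  stopifnot(inherits(X, "design_matrix"))
  m <- length(posteriors)
  if (nrow(X$values) != m) {
    ldcm_stop("design matrix rows must match the number of posteriors")
  }
  nm_list <- lapply(posteriors, function(p_) names(p_$mean))
  if (length(unique(vapply(nm_list, paste, "", collapse = "|"))) != 1) {
    ldcm_stop("posteriors do not share a parameter ordering")
  }
  n_par <- length(posteriors[[1]]$mean)
  carried <- carried %||% {
    if (!is.null(posteriors[[1]]$n_regions)) {
      a_indices(posteriors[[1]]$n_regions)
    } else {
      seq_len(n_par)
    }
  }
  if (any(carried < 1 | carried > n_par)) {
    ldcm_stop("`carried` indices out of range")
  }
  p <- length(carried)
  pnames <- names(posteriors[[1]]$mean)[carried]
  ms <- lapply(posteriors, function(po) unname(po$mean[carried]))
  Cs <- lapply(posteriors, function(po) {
    C <- po$covariance[carried, carried, drop = FALSE]
    nearest_psd(unname(C))
  })
  fit <- peb_core(ms, Cs, X$values, gamma_range, beta_var, em_iter)

  if (passes > 0) {
    for (pass in seq_len(passes)) {
      ms2 <- ms; Cs2 <- Cs
      for (i in seq_len(m)) {
        # prior marginal over carried parameters at the lower level
        po <- posteriors[[i]]
        pr_mean <- if (!is.null(po$prior)) unname(po$prior$mean[carried]) else rep(0, p)
        pr_var <- if (!is.null(po$prior)) unname(po$prior$variance[carried]) else rep(beta_var, p)
        upd <- reduce_posterior(ms[[i]], Cs[[i]], pr_mean, pr_var,
                                fit$emp_mean[[i]], fit$emp_cov[[i]])
        if (!is.null(upd)) { ms2[[i]] <- upd$mean; Cs2[[i]] <- upd$cov }
      }
      fit <- peb_core(ms2, Cs2, X$values, gamma_range, beta_var, em_iter)
      ms <- ms2; Cs <- Cs2
    }
  }

  beta_mean <- matrix(fit$b, ncol(X$values), p, byrow = TRUE,
                      dimnames = list(X$effect_names, pnames))
  structure(list(beta_mean = beta_mean, beta_cov = fit$Sb,
                 gamma = fit$gamma, free_energy = fit$F,
                 f_trace = fit$f_trace, design = X, carried = carried,
                 param_names = pnames,
                 unit_means = ms, unit_covs = Cs,
                 empirical_priors = Map(function(m_, C_) list(mean = m_, cov = C_),
                                        fit$emp_mean, fit$emp_cov)),
            class = "peb_posterior")
}

#' GLS + evidence core of the PEB model
#' @noRd
peb_core <- function(ms, Cs, Xv, gamma_range, beta_var, em_iter) {
  m <- length(ms)
  p <- length(ms[[1]])
  e <- ncol(Xv)
  prior_prec <- diag(1 / beta_var, e * p)

  fit_given_gamma <- function(gamma) {
    Vinv <- lapply(Cs, function(C) solve(C + diag(exp(-gamma), p)))
    P <- prior_prec
    rhs <- numeric(e * p)
    for (i in seq_len(m)) {
      # X_i = x_i' (x) I_p maps beta (stacked effect blocks) to unit i
      xi <- Xv[i, ]
      P <- P + kronecker(tcrossprod(xi), Vinv[[i]])
      rhs <- rhs + kronecker(xi, drop(Vinv[[i]] %*% ms[[i]]))
    }
    Sb <- solve((P + t(P)) / 2)
    b <- drop(Sb %*% rhs)
    list(Vinv = Vinv, Sb = Sb, b = b, P = P)
  }

  evidence <- function(gamma) {
    f <- fit_given_gamma(gamma)
    ld_v <- 0; quad <- 0
    for (i in seq_len(m)) {
      V <- Cs[[i]] + diag(exp(-gamma), p)
      ld_v <- ld_v + determinant(V, logarithm = TRUE)$modulus
      quad <- quad + drop(t(ms[[i]]) %*% f$Vinv[[i]] %*% ms[[i]])
    }
    ld_post <- determinant(f$P, logarithm = TRUE)$modulus +
      p * ncol(Xv) * log(beta_var)
    as.numeric(-0.5 * (m * p * log(2 * pi) + ld_v + ld_post +
                         quad - drop(t(f$b) %*% f$P %*% f$b))) +
      stats::dnorm(gamma, 0, 4, log = TRUE)
  }

  gamma <- 0
  f_trace <- numeric(0)
  width <- diff(gamma_range)
  lo <- gamma_range[1]; hi <- gamma_range[2]
  for (sweep in seq_len(em_iter)) {
    opt <- stats::optimize(evidence, c(lo, hi), maximum = TRUE, tol = 1e-4)
    gamma <- opt$maximum
    f_trace <- c(f_trace, opt$objective)
    # narrow the bracket around the current optimum (keeps F non-decreasing)
    width <- width / 4
    lo <- max(gamma_range[1], gamma - width)
    hi <- min(gamma_range[2], gamma + width)
  }
  f <- fit_given_gamma(gamma)
  # kron ordering used above stacks connection-within-effect; reorder to
  # effect blocks (beta = stack over effects of length-p blocks)
  # -- P was built with kronecker(x x', Vinv): index = (effect-1)*p + conn
  emp_mean <- lapply(seq_len(m), function(i) {
    drop(kronecker(t(Xv[i, ]), diag(p)) %*% f$b)
  })
  emp_cov <- lapply(seq_len(m), function(i) {
    Xi <- kronecker(t(Xv[i, ]), diag(p))
    diag(exp(-gamma), p) + Xi %*% f$Sb %*% t(Xi)
  })
  list(b = f$b, Sb = f$Sb, gamma = gamma, F = f_trace[length(f_trace)],
       f_trace = f_trace, emp_mean = emp_mean, emp_cov = emp_cov)
}

#' Re-evaluate a Gaussian posterior under a new (empirical) prior
#'
#' Gaussian conditioning / Bayesian model reduction on the carried subset:
#' swaps the original prior (mean `pr_mean`, variance `pr_var`) for the
#' empirical prior `(emp_mean, emp_cov)`.
#' @noRd
reduce_posterior <- function(m_i, C_i, pr_mean, pr_var, emp_mean, emp_cov) {
  pr_var <- pmax(pr_var, 1e-12)
  Pi_post <- tryCatch(solve(C_i), error = function(e) NULL)
  if (is.null(Pi_post)) return(NULL)
  Pi_new <- Pi_post - diag(1 / pr_var, length(pr_var)) + solve(emp_cov)
  ev <- eigen((Pi_new + t(Pi_new)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(NULL)  # reduction not well posed; keep original
  rhs <- Pi_post %*% m_i - (1 / pr_var) * pr_mean + solve(emp_cov, emp_mean)
  C_new <- solve((Pi_new + t(Pi_new)) / 2)
  list(mean = drop(C_new %*% rhs), cov = nearest_psd(C_new))
}

#' @export
print.peb_posterior <- function(x, ...) {
  cat(sprintf("<peb_posterior> %d effects x %d parameters, gamma = %.2f, F = %.2f\n",
              nrow(x$beta_mean), ncol(x$beta_mean), x$gamma, x$free_energy))
  invisible(x)
}

#' Group-level PEB over per-subject session PEBs (PEB of PEB)
#'
#' Applies [peb_fit()] to the subjects' session-effect posteriors (means and
#' covariances) with a group design `X2`; the default is a single all-ones
#' column modelling the group average of each session effect.
#'
#' @param session_pebs List of per-subject `"peb_posterior"` objects sharing
#'   the same session design and carried set.
#' @param X2 Group [design_matrix()] (default all-ones column).
#' @return Group `"peb_posterior"` whose parameters are the session effects
#'   stacked over connections; `effect_grid` maps rows to (group effect,
#'   session effect) pairs.
#' @export
peb_of_peb <- function(session_pebs, X2 = NULL) {
  m <- length(session_pebs)
  designs <- vapply(session_pebs, function(s) {
    paste(s$design$effect_names, collapse = "|")
  }, "")
  carried_sets <- vapply(session_pebs, function(s) {
    paste(s$carried, collapse = ",")
  }, "")
  if (length(unique(designs)) != 1 || length(unique(carried_sets)) != 1) {
    ldcm_stop("subjects must share the session design and carried set")
  }
  X2 <- X2 %||% design_matrix(matrix(1, m, 1,
                                     dimnames = list(sprintf("S%d", seq_len(m)),
                                                     "group")))
  e1 <- nrow(session_pebs[[1]]$beta_mean)
  eff1 <- session_pebs[[1]]$design$effect_names
  pn <- session_pebs[[1]]$param_names
  pseudo <- lapply(session_pebs, function(s) {
    list(mean = stats::setNames(as.vector(t(s$beta_mean)),
                                paste(rep(eff1, each = length(pn)), pn,
                                      sep = ":")),
         covariance = s$beta_cov,
         prior = NULL)
  })
  out <- peb_fit(pseudo, X2, carried = seq_len(e1 * length(pn)), passes = 0)
  out$effect_grid <- expand.grid(connection = pn, session_effect = eff1,
                                 stringsAsFactors = FALSE)
  out$session_effects <- eff1
  out
}

#' Symptom-covariate PEB across the measured sessions
#'
#' Restricts each subject to the sessions with symptom scores (pre-treatment,
#' 7 days and 3 months after), builds a per-subject design
#' `[1, centred score]`, runs a session-level PEB per subject, then a group
#' PEB-of-PEB with an all-ones design. Scores are mean-centred within
#' subject, so the association regressor is orthogonal to the baseline
#' column.
#'
#' @param posteriors_by_subject List (one element per subject) of lists of
#'   `"dcm_posterior"` objects named by session label (`op-1d`, `op+1d`,
#'   `op+7d`, `op+3m`; only the scored sessions are used).
#' @param scores A [generate_scores()]-style data frame
#'   (`subject,timepoint,score`).
#' @param score_name Label used for the association effect (default
#'   `"score"`).
#' @param carried Carried parameter indices (default: coupling entries).
#' @return Group `"peb_posterior"` for the (baseline, score-association)
#'   effects per connection.
#' @export
covariate_peb <- function(posteriors_by_subject, scores,
                          score_name = "score", carried = NULL) {
  n_sub <- length(posteriors_by_subject)
  session_pebs <- vector("list", n_sub)
  for (jsub in seq_len(n_sub)) {
    sc <- scores[scores$subject == jsub, ]
    if (nrow(sc) != length(SCORE_LABELS) ||
        !setequal(as.character(sc$timepoint), SCORE_LABELS)) {
      ldcm_stop(sprintf("subject %d must have exactly one score per measured session",
                        jsub))
    }
    sc <- sc[match(SCORE_LABELS, as.character(sc$timepoint)), ]
    posts <- posteriors_by_subject[[jsub]][SCORE_LABELS]
    if (any(vapply(posts, is.null, TRUE))) {
      ldcm_stop(sprintf("subject %d is missing a session posterior for a scored session",
                        jsub))
    }
    centred <- sc$score - mean(sc$score)
    Xj <- design_matrix(cbind(baseline = rep(1, 3), centred),
                        effect_names = c("baseline", score_name),
                        unit_names = SCORE_LABELS,
                        allow_rank_deficient = TRUE)
    session_pebs[[jsub]] <- peb_fit(posts, Xj, carried = carried, passes = 0)
  }
  peb_of_peb(session_pebs)
}

#' Threshold a PEB posterior with a credible-interval non-zero criterion
#'
#' Per (effect, connection): a Gaussian credible interval
#' `mean +/- z(level) sd`; an effect survives iff the interval excludes 0.
#' A single multivariate Bayesian model underlies all intervals, so no
#' multiplicity correction is applied.
#'
#' @param peb A `"peb_posterior"`.
#' @param level Credible level in (0, 1); default 0.95
#'   (`z = 1.959964`).
#' @param region_names Optional region labels for source/target columns.
#' @return Data frame of class `"effect_table"` with columns
#'   `source,target,effect,mean,sd,lo95,hi95,survives`.
#' @export
threshold_nonzero <- function(peb, level = 0.95, region_names = NULL) {
  check_scalar(level, "level", lower = 1e-6, upper = 1 - 1e-6)
  z <- stats::qnorm(1 - (1 - level) / 2)
  b <- as.vector(t(peb$beta_mean))
  sds <- sqrt(pmax(diag(peb$beta_cov), 0))
  if (!is.null(peb$effect_grid)) {
    conn <- peb$effect_grid$connection
    eff <- peb$effect_grid$session_effect
  } else {
    conn <- rep(peb$param_names, nrow(peb$beta_mean))
    eff <- rep(rownames(peb$beta_mean), each = ncol(peb$beta_mean))
  }
  ij <- parse_conn_names(conn)
  src <- ij$source; tgt <- ij$target
  if (!is.null(region_names)) {
    src <- ifelse(is.na(src), NA, region_names[src])
    tgt <- ifelse(is.na(tgt), NA, region_names[tgt])
  }
  lo <- b - z * sds
  hi <- b + z * sds
  out <- data.frame(source = src, target = tgt, effect = eff,
                    mean = b, sd = sds, lo95 = lo, hi95 = hi,
                    survives = (lo > 0 | hi < 0))
  class(out) <- c("effect_table", "data.frame")
  out
}

#' @noRd
parse_conn_names <- function(conn) {
  mm <- regmatches(conn, regexec("a\\[(\\d+),(\\d+)\\]", conn))
  tgt <- vapply(mm, function(g) if (length(g) == 3) as.integer(g[2]) else NA_integer_, 1L)
  src <- vapply(mm, function(g) if (length(g) == 3) as.integer(g[3]) else NA_integer_, 1L)
  list(source = src, target = tgt)
}

#' Write an effect table as CSV and directed-graph files
#'
#' Writes the table as CSV and, for the surviving off-diagonal effects, a
#' directed graph in GraphML and DOT formats with edge attributes for effect
#' size and sign.
#'
#' @param tab An `"effect_table"`.
#' @param path CSV path; the graph files replace the extension with
#'   `.graphml` / `.dot`.
#' @param effects Which effect names to include as graph edges (default all
#'   non-baseline).
#' @return `path`, invisibly.
#' @export
write_effect_table <- function(tab, path, effects = NULL) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  eff_sel <- effects %||% setdiff(unique(tab$effect), "baseline")
  edges <- tab[tab$survives & tab$effect %in% eff_sel &
                 !is.na(tab$source) & tab$source != tab$target, , drop = FALSE]
  nodes <- sort(unique(c(tab$source, tab$target)))
  nodes <- nodes[!is.na(nodes)]
  g <- igraph::make_empty_graph(n = length(nodes), directed = TRUE)
  igraph::V(g)$name <- as.character(nodes)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, rbind(match(edges$source, nodes),
                                    match(edges$target, nodes)))
    igraph::E(g)$effect <- edges$effect
    igraph::E(g)$size <- edges$mean
    igraph::E(g)$sign <- ifelse(edges$mean > 0, "positive", "negative")
  }
  base <- sub("\\.csv$", "", path)
  igraph::write_graph(g, paste0(base, ".graphml"), format = "graphml")
  igraph::write_graph(g, paste0(base, ".dot"), format = "dot")
  invisible(path)
}

#' Serialize / restore a PEB posterior as JSON
#'
#' @param peb A `"peb_posterior"`.
#' @param path File path (JSON).
#' @return `path` invisibly; `read_peb_posterior()` returns the restored
#'   object (design and effect grid included; unit-level empirical priors
#'   are not serialized).
#' @export
write_peb_posterior <- function(peb, path) {
  jsonlite::write_json(
    list(beta_mean = peb$beta_mean, beta_cov = peb$beta_cov,
         gamma = peb$gamma, free_energy = peb$free_energy,
         design_values = peb$design$values,
         effect_names = peb$design$effect_names,
         unit_names = peb$design$unit_names,
         carried = peb$carried, param_names = peb$param_names,
         effect_grid = peb$effect_grid,
         session_effects = peb$session_effects),
    path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_peb_posterior
#' @export
read_peb_posterior <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  e <- length(raw$effect_names)
  p <- length(raw$param_names)
  pn <- unlist(raw$param_names)
  bm <- matrix(unlist(raw$beta_mean), e, p, byrow = TRUE,
               dimnames = list(unlist(raw$effect_names), pn))
  bc <- matrix(unlist(raw$beta_cov), e * p, e * p, byrow = TRUE)
  X <- design_matrix(matrix(unlist(raw$design_values),
                            length(raw$unit_names), e, byrow = TRUE),
                     effect_names = unlist(raw$effect_names),
                     unit_names = unlist(raw$unit_names),
                     allow_rank_deficient = TRUE)
  grid <- if (!is.null(raw$effect_grid)) {
    data.frame(connection = vapply(raw$effect_grid, function(r) r$connection, ""),
               session_effect = vapply(raw$effect_grid,
                                       function(r) r$session_effect, ""),
               stringsAsFactors = FALSE)
  } else NULL
  structure(list(beta_mean = bm, beta_cov = bc, gamma = raw$gamma,
                 free_energy = raw$free_energy, design = X,
                 carried = unlist(raw$carried), param_names = pn,
                 effect_grid = grid,
                 session_effects = if (is.null(raw$session_effects)) NULL
                                   else unlist(raw$session_effects)),
            class = "peb_posterior")
}
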