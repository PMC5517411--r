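# End-to-end orchestration: cohort generation -> forward simulation ->
# preprocessing -> cross-spectra -> per-session inversion -> session PEB per
# subject -> group PEB-of-PEB -> covariate PEBs -> effect tables, graphs and
# a manifest sufficient to re-run bit-identically.

#' Default run configuration
#'
#' Returns the nested configuration list consumed by [run_pipeline()]. The
#' defaults encode the study conditions the package emulates: 8 subjects x 4
#' sessions, 6 regions, TR = 2 s, 165 volumes per session (5 discarded), a
#' planted sustained effect being optional (NULL `effects` gives a null
#' cohort).
#'
#' @param n_subjects,n_regions Cohort size.
#' @param effects Data frame of [connection_effect()] rows or NULL.
#' @param seed Global seed.
#' @return Nested configuration list.
#' @export
default_config <- function(n_subjects = 8, n_regions = 6, effects = NULL,
                           seed = 1) {
  list(
    seed = seed,
    cohort = list(n_subjects = n_subjects, n_regions = n_regions,
                  effects = effects, sigma2 = 0.05, sigma3 = 0.05,
                  baseline_score = 20, score_noise_sd = 1),
    simulation = list(tr = 2, n_volumes = 165, dt = 0.05,
                      state_amp = 1e-4, state_exp = 1,
                      obs_amp = 1e-3, obs_exp = 1, drift_amp = 0.2,
                      leak_sd = 0.2),
    preprocess = list(n_discard = 5, highpass_hz = 0.009, lowpass_hz = NULL),
    csd = list(order = 8, n_freq = 24, fmin = 0.01, fmax = 0.25),
    spdcm = list(maxit = 128, tol = 0.01),
    peb = list(passes = 1, level = 0.95),
    region_names = if (n_regions == 6) {
      c("PrcG", "SMA", "VL", "Thal", "Put", "rDT")
    } else {
      sprintf("R%d", seq_len(n_regions))
    }
  )
}

#' @noRd
config_schema <- function() {
  list(seed = NULL,
       cohort = c("n_subjects", "n_regions", "effects", "sigma2", "sigma3",
                  "baseline_score", "score_noise_sd"),
       simulation = c("tr", "n_volumes", "dt", "state_amp", "state_exp",
                      "obs_amp", "obs_exp", "drift_amp", "leak_sd"),
       preprocess = c("n_discard", "highpass_hz", "lowpass_hz"),
       csd = c("order", "n_freq", "fmin", "fmax"),
       spdcm = c("maxit", "tol"),
       peb = c("passes", "level"),
       region_names = NULL)
}

#' Validate a run configuration
#'
#' Checks the nested structure against the schema; unknown keys are
#' rejected (typos must not silently fall back to defaults).
#'
#' @param config Nested list (as from [default_config()], possibly modified).
#' @return `config`, invisibly, or a validation error.
#' @export
validate_config <- function(config) {
  schema <- config_schema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown)) {
    ldcm_stop(sprintf("unknown config key(s): %s",
                      paste(unknown, collapse = ", ")))
  }
  for (blk in names(config)) {
    allowed <- schema[[blk]]
    if (is.null(allowed)) next
    bad <- setdiff(names(config[[blk]]), allowed)
    if (length(bad)) {
      ldcm_stop(sprintf("unknown key(s) in config$%s: %s", blk,
                        paste(bad, collapse = ", ")))
    }
  }
  if (is.null(config$seed)) ldcm_stop("config$seed is required")
  invisible(config)
}

#' Simulate one session's acquisition from a coupling matrix
#'
#' forward simulation + acquisition for a single subject/session; exposed so
#' smaller experiments can reuse the exact pipeline conditions.
#'
#' @param a Coupling matrix.
#' @param sim Simulation block of the config.
#' @param seed Session seed.
#' @return List with `series` and `confounds`.
#' @export
simulate_session <- function(a, sim, seed) {
  ns <- noise_spec(state_amp = sim$state_amp, state_exp = sim$state_exp,
                   obs_amp = sim$obs_amp, obs_exp = sim$obs_exp,
                   drift_amp = sim$drift_amp)
  x <- simulate_neural(a, ns, duration = sim$tr * sim$n_volumes,
                       dt = sim$dt, seed = seed)
  y <- balloon_bold(x)
  sample_and_corrupt(y, tr = sim$tr, n_volumes = sim$n_volumes, noise = ns,
                     seed = derive_seed(seed, 1), leak_sd = sim$leak_sd)
}

#' Run the full longitudinal pipeline
#'
#' Executes cohort generation, per-session forward simulation, time-series
#' conditioning, cross-spectral estimation, spectral-DCM inversion (4
#' sessions x N subjects), per-subject session PEBs, the group PEB-of-PEB,
#' covariate PEBs for the posture- and action-like scores, 95% thresholding,
#' and (optionally) writes effect tables, graphs, the ground truth and a
#' manifest to `outdir`.
#'
#' @param config Configuration list (see [default_config()]).
#' @param outdir Output directory, or NULL to skip writing files.
#' @param progress Emit per-stage messages.
#' @return List of class `"longdcm_run"`: `truth`, `scores`, `posteriors`
#'   (subject x session), `session_pebs`, `group_peb`, `covariate_pebs`,
#'   `effect_tables`, `config`, `manifest`.
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL,
                         progress = FALSE) {
  validate_config(config)
  say <- function(...) if (progress) message(sprintf(...))
  seed <- config$seed
  ch <- config$cohort
  n <- ch$n_regions

  say("cohort: sampling ground truth")
  truth <- sample_group_truth(n_subjects = ch$n_subjects, n_regions = n,
                              effect_spec = ch$effects, sigma2 = ch$sigma2,
                              sigma3 = ch$sigma3,
                              seed = derive_seed(seed, 1))
  # two symptom scales (posture- and action-like), sharing the cohort's
  # score-coupling structure but with independent measurement noise
  scores <- list(
    posture = generate_scores(truth, baseline_score = ch$baseline_score,
                              noise_sd = ch$score_noise_sd,
                              seed = derive_seed(seed, 2)),
    action = generate_scores(truth, baseline_score = ch$baseline_score,
                             noise_sd = ch$score_noise_sd,
                             seed = derive_seed(seed, 3)))

  sim <- config$simulation
  pp <- config$preprocess
  csd_cfg <- config$csd
  n_fit <- sim$n_volumes - pp$n_discard
  freqs <- default_freq_grid(n_fit, sim$tr, n_freq = csd_cfg$n_freq,
                             fmin = csd_cfg$fmin, fmax = csd_cfg$fmax)

  posteriors <- vector("list", ch$n_subjects)
  n_nonconverged <- 0L
  for (jsub in seq_len(ch$n_subjects)) {
    posteriors[[jsub]] <- vector("list", 4)
    names(posteriors[[jsub]]) <- SESSION_LABELS
    for (ises in 1:4) {
      stage <- sprintf("subject %d session %s", jsub, SESSION_LABELS[ises])
      res <- tryCatch({
        sess <- simulate_session(truth$theta[[jsub]][[ises]], sim,
                                 seed = derive_seed(seed, 10, jsub, ises))
        cleaned <- preprocess_session(sess$series, sess$confounds,
                                      n_discard = pp$n_discard,
                                      highpass_hz = pp$highpass_hz,
                                      lowpass_hz = pp$lowpass_hz)
        cs <- estimate_csd(cleaned, order = csd_cfg$order, freqs = freqs)
        invert_spdcm(cs, opts = config$spdcm)
      }, longdcm_error = function(e) {
        ldcm_stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
                  class = "longdcm_pipeline_error")
      })
      if (!res$converged) {
        n_nonconverged <- n_nonconverged + 1L
        warning(sprintf("inversion did not converge for %s", stage))
      }
      posteriors[[jsub]][[ises]] <- res
      say("spdcm: %s done (F = %.1f, %d iter)", stage, res$free_energy,
          res$iterations)
    }
  }

  say("peb: session level per subject")
  X1 <- make_session_design(4)
  session_pebs <- lapply(posteriors, function(posts) {
    peb_fit(posts, X1, passes = config$peb$passes)
  })
  say("peb: group level")
  group_peb <- peb_of_peb(session_pebs)
  say("peb: covariates")
  covariate_pebs <- lapply(names(scores), function(nm) {
    covariate_peb(posteriors, scores[[nm]], score_name = nm)
  })
  names(covariate_pebs) <- names(scores)

  rn <- config$region_names
  effect_tables <- c(
    list(longitudinal = threshold_nonzero(group_peb, level = config$peb$level,
                                          region_names = rn)),
    lapply(covariate_pebs, threshold_nonzero, level = config$peb$level,
           region_names = rn))

  manifest <- list(
    package_version = tryCatch(as.character(utils::packageVersion("longdcm")), error = function(e) "dev"),
    seed = seed,
    config = config[setdiff(names(config), "cohort")],
    cohort = ch[setdiff(names(ch), "effects")],
    planted_effects = if (!is.null(ch$effects)) as.list(ch$effects) else NULL,
    frequencies_hz = freqs,
    bold_constants = hemo_constants(),
    pipeline_order = c("discard", "confound_regression", "detrend_filter",
                       "mar_csd", "spdcm", "session_peb", "group_peb",
                       "covariate_peb"),
    n_nonconverged = n_nonconverged,
    outputs = character(0))

  run <- structure(list(truth = truth, scores = scores,
                        posteriors = posteriors,
                        session_pebs = session_pebs, group_peb = group_peb,
                        covariate_pebs = covariate_pebs,
                        effect_tables = effect_tables, config = config,
                        manifest = manifest),
                   class = "longdcm_run")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- c()
    for (nm in names(effect_tables)) {
      fp <- file.path(outdir, sprintf("effects_%s.csv", nm))
      write_effect_table(effect_tables[[nm]], fp)
      files <- c(files, fp)
    }
    tp <- file.path(outdir, "ground_truth.json")
    write_group_truth(truth, tp)
    sps <- character(0)
    for (nm in names(scores)) {
      sp <- file.path(outdir, sprintf("scores_%s.csv", nm))
      utils::write.csv(as.data.frame(scores[[nm]]), sp, row.names = FALSE,
                       quote = FALSE)
      sps <- c(sps, sp)
    }
    run$manifest$outputs <- c(files, tp, sps)
    jsonlite::write_json(run$manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  run
}

#' @export
print.longdcm_run <- function(x, ...) {
  cat(sprintf("<longdcm_run> %d subjects x 4 sessions, %d regions\n",
              x$truth$n_subjects, x$truth$n_regions))
  surv <- x$effect_tables$longitudinal
  surv <- surv[surv$survives & surv$effect != "baseline", ]
  cat(sprintf("  surviving non-baseline longitudinal effects: %d\n",
              nrow(surv)))
  invisible(x)
}

#' Compare a pipeline run against its ground truth
#'
#' Emits per-effect-type sign agreement, 95% interval coverage and RMSE of
#' the recovered group effects against the generating `beta3`, as a
#' machine-readable list (optionally written as JSON).
#'
#' @param run A `"longdcm_run"`.
#' @param truth The generating `"group_truth"` (defaults to the run's own).
#' @param path Optional JSON output path.
#' @return List with elements per session effect: `rmse`, `coverage`,
#'   `sign_agreement` (NA where the truth is zero), `false_positive_rate`.
#' @export
compare_truth <- function(run, truth = run$truth, path = NULL) {
  grid <- run$group_peb$effect_grid
  if (is.null(grid)) ldcm_stop("run's group PEB lacks an effect grid")
  if (!setequal(unique(grid$session_effect), rownames(truth$beta3)) ||
      !setequal(unique(grid$connection), colnames(truth$beta3))) {
    ldcm_stop("truth and run do not describe the same parameters")
  }
  b <- as.vector(t(run$group_peb$beta_mean))
  sds <- sqrt(pmax(diag(run$group_peb$beta_cov), 0))
  out <- list()
  for (eff in rownames(truth$beta3)) {
    idx <- which(grid$session_effect == eff)
    tru <- truth$beta3[eff, match(grid$connection[idx], colnames(truth$beta3))]
    est <- b[idx]; sd_ <- sds[idx]
    lo <- est - 1.959964 * sd_; hi <- est + 1.959964 * sd_
    nonzero <- which(tru != 0)
    out[[eff]] <- list(
      rmse = sqrt(mean((est - tru)^2)),
      coverage = mean(lo <= tru & tru <= hi),
      sign_agreement = if (length(nonzero)) {
        mean(sign(est[nonzero]) == sign(tru[nonzero]))
      } else NA,
      false_positive_rate = if (length(nonzero) < length(tru)) {
        mean((lo > 0 | hi < 0)[tru == 0])
      } else NA)
  }
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  out
}

#' Load a run configuration from JSON
#'
#' Reads a JSON file whose blocks override [default_config()] values
#' (block-wise merge), converts a `cohort$effects` record list into a
#' [connection_effect()] data frame, and validates the result.
#'
#' @param path JSON file path.
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  for (blk in names(raw)) {
    if (is.list(raw[[blk]]) && is.list(cfg[[blk]])) {
      cfg[[blk]] <- utils::modifyList(cfg[[blk]], as.list(raw[[blk]]))
    } else {
      cfg[[blk]] <- raw[[blk]]
    }
  }
  if (!is.null(cfg$cohort$effects)) {
    cfg$cohort$effects <- as.data.frame(cfg$cohort$effects)
  }
  validate_config(cfg)
  cfg
}
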