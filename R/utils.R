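# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed error
#'
#' All user-facing validation failures raise conditions subclassed under
#' "longdcm_error" so callers (and tests) can distinguish validation errors,
#' stability errors and generation errors.
#' @noRd
ldcm_stop <- function(msg, class = "longdcm_validation_error") {
  stop(structure(
    class = c(class, "longdcm_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Derive a reproducible sub-seed from a master seed and integer labels
#'
#' A small LCG-style hash keeps every stage/subject/session on an independent,
#' reproducible stream while staying within 32-bit integer range.
#' @noRd
derive_seed <- function(seed, ...) {
  ints <- c(...)
  val <- as.double(seed) %% 2147483647
  for (k in ints) {
    val <- (val * 69069 + as.double(k) + 1) %% 2147483647
  }
  as.integer(val)
}

#' Logarithmically spaced sequence
#' @noRd
logspace <- function(from, to, n) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Check a numeric scalar
#' @noRd
check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    ldcm_stop(sprintf("`%s` must be a finite numeric scalar", name))
  }
  if (x < lower || x > upper) {
    ldcm_stop(sprintf("`%s` must be in [%g, %g]", name, lower, upper))
  }
  invisible(x)
}

#' Symmetrize and project a matrix to the PSD cone (eigenvalue clipping)
#' @noRd
nearest_psd <- function(S, floor = 0) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (all(e$values >= floor)) return(S)
  v <- pmax(e$values, floor)
  S2 <- e$vectors %*% (v * t(e$vectors))
  (S2 + t(S2)) / 2
}
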