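# Effective-connectivity matrix conventions.
#
# A coupling matrix A is an n x n real matrix with entry A[i, k] the influence
# of source region k on target region i (row = target), matching the
# dx/dt = A x reading of the neural state equation. Off-diagonal entries are
# rates (1/s). Diagonal entries are dimensionless log-scale parameters of
# self-inhibition: the effective self-decay rate is -0.5 * exp(A[i, i]), so
# a_ii = 0 corresponds to the canonical -0.5 1/s and the diagonal of the
# effective rate matrix is negative by construction.

#' Effective self-connection rate from a log-scale parameter
#'
#' Diagonal entries of the coupling matrix are log-scale parameters; the
#' self-inhibition rate they encode is `-0.5 * exp(a_ii)` (1/s), so positive
#' values mean stronger self-inhibition and 0 maps to -0.5 1/s.
#'
#' @param a_ii Numeric vector of diagonal (log-scale) parameters.
#' @return Self-connection rate(s) in 1/s, strictly negative.
#' @examples
#' self_rate(0)      # -0.5
#' self_rate(log(2)) # -1
#' @export
self_rate <- function(a_ii) {
  if (!is.numeric(a_ii) || any(!is.finite(a_ii))) {
    ldcm_stop("`a_ii` must be finite numeric")
  }
  -0.5 * exp(a_ii)
}

#' Effective rate matrix of a coupling matrix
#'
#' Off-diagonals are taken as-is (rates, 1/s); the diagonal is replaced by
#' the self-inhibition rate [self_rate()] encodes.
#'
#' @param a n x n coupling matrix (row = target).
#' @return n x n real rate matrix with strictly negative diagonal.
#' @export
effective_matrix <- function(a) {
  a <- validate_coupling(a)
  diag(a) <- self_rate(diag(a))
  a
}

#' Stability of a coupling matrix
#'
#' A resting-state network is stationary only if the effective rate matrix is
#' Hurwitz-stable. Returns `TRUE` iff every eigenvalue of
#' [effective_matrix()] has strictly negative real part.
#'
#' @param a n x n coupling matrix.
#' @return Logical flag.
#' @export
is_stable <- function(a) {
  a_eff <- effective_matrix(a)
  all(Re(eigen(a_eff, only.values = TRUE)$values) < 0)
}

#' @noRd
validate_coupling <- function(a) {
  a <- as.matrix(a)
  if (nrow(a) != ncol(a) || !is.numeric(a) || any(!is.finite(a))) {
    ldcm_stop("coupling matrix must be square with finite numeric entries")
  }
  a
}
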