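#' Build the transition intensity matrix for one covariate configuration
#'
#' @param params an [msm_parameters] object.
#' @param z named numeric vector of covariate values (one per covariate in
#'   the model's covariate spec; reference levels coded 0).
#' @param age_ge_65 logical: is the subject's current age at least 65?
#' @return `n_states x n_states` generator matrix Q (units 1/year): allowed
#'   off-diagonal entries are the transition intensities, disallowed entries
#'   are exactly 0, each row sums to 0, absorbing rows are all 0.
#' @examples
#' Q <- intensity_matrix(msm_parameters(hip_structure(), log_q0 = log(0.1)))
#' rowSums(Q)  # all zero
#' @export
intensity_matrix <- function(params, z = NULL, age_ge_65 = FALSE) {
  stopifnot(inherits(params, "msm_parameters"))
  st <- params$structure
  K <- params$covariates$K
  if (K > 0L) {
    if (is.null(z)) stop("covariate values 'z' required")
    z <- unlist(z)
    missing <- setdiff(params$covariates$names, names(z))
    if (length(missing)) {
      stop("missing covariate value(s): ", paste(missing, collapse = ", "))
    }
    z <- as.numeric(z[params$covariates$names])
    if (anyNA(z)) stop("missing covariate value")
  } else {
    z <- numeric(0)
  }
  eta <- params$log_q0 + as.numeric(isTRUE(age_ge_65)) * params$gamma
  if (K > 0L) eta <- eta + drop(params$beta %*% z)
  q <- exp(eta)
  Q <- matrix(0, st$n_states, st$n_states,
              dimnames = list(st$states, st$states))
  Q[cbind(st$from, st$to)] <- q
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

#' Transition probability matrix over an interval of constant intensities
#'
#' Computes P = exp(Q dt) by scaling-and-squaring Pade approximation
#' (via [Matrix::expm]), which is accurate for the non-symmetric, possibly
#' defective generators that arise here.
#'
#' @param Q generator matrix (rows summing to 0).
#' @param dt interval length in years, `>= 0`.
#' @return stochastic matrix P of the same dimension; rows sum to 1.
#' @examples
#' Q <- intensity_matrix(msm_parameters(hip_structure(), log_q0 = log(0.1)))
#' P <- transition_probability(Q, 6)
#' @export
transition_probability <- function(Q, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt < 0) {
    stop("'dt' must be a single non-negative number")
  }
  Q <- as.matrix(Q)
  if (nrow(Q) != ncol(Q)) stop("Q must be square")
  if (max(abs(rowSums(Q))) > 1e-8) stop("Q rows must sum to 0")
  if (dt == 0) {
    P <- diag(nrow(Q))
    dimnames(P) <- dimnames(Q)
    return(P)
  }
  P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * dt, sparse = FALSE)))
  # clip tiny negative round-off; renormalization is not needed at the
  # accuracy delivered by the Pade/scaling-squaring algorithm
  P[P < 0 & P > -1e-12] <- 0
  dimnames(P) <- dimnames(Q)
  P
}

#' Transition probabilities along piecewise-constant intensity segments
#'
#' Multiplies per-segment transition probability matrices in order; this is
#' how time-dependent covariates and the age-65 changepoint enter interval
#' probabilities.
#'
#' @param segments list of segments, each a list with elements `Q`
#'   (generator) and `dt` (duration, years); an empty list yields the
#'   identity.
#' @param n_states matrix dimension when `segments` is empty (default 5).
#' @return the ordered product of per-segment matrices.
#' @export
path_probability <- function(segments, n_states = 5L) {
  if (length(segments) == 0L) return(diag(n_states))
  P <- NULL
  for (seg in segments) {
    Pi <- transition_probability(seg$Q, seg$dt)
    P <- if (is.null(P)) Pi else P %*% Pi
  }
  P
}
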