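#' Model parameters for a multi-state intensity model
#'
#' The intensity of transition r->s for a subject with covariate vector z
#' and current age a is
#'   q_rs(z, a) = exp( log_q0[r->s] + sum_k beta[r->s, k] z_k
#'                     + gamma[r->s] I(a >= 65) ),
#' so `exp(beta)` is the hazard ratio of the covariate on that transition
#' and `exp(gamma)` the intensity multiplier applied from age 65 onward.
#'
#' @param structure an [msm_structure].
#' @param covariates an [msm_covariates] or `NULL` for a covariate-free
#'   model.
#' @param log_q0 numeric, length `n_trans` (recycled): log baseline
#'   intensities, events per person-year.
#' @param beta `n_trans x K` matrix of log hazard ratios (recycled if
#'   scalar); entries outside the covariate mask must be 0.
#' @param gamma numeric, length `n_trans` (recycled): log intensity
#'   multipliers applied when current age >= 65.
#' @return object of class `msm_parameters`.
#' @examples
#' p <- msm_parameters(hip_structure(), log_q0 = log(0.1))
#' @export
msm_parameters <- function(structure, covariates = NULL, log_q0 = log(0.01),
                           beta = NULL, gamma = 0) {
  nt <- structure$n_trans
  if (is.null(covariates)) covariates <- msm_covariates(character(), structure = structure)
  K <- covariates$K
  log_q0 <- rep_len(as.numeric(log_q0), nt)
  gamma <- rep_len(as.numeric(gamma), nt)
  if (is.null(beta)) beta <- matrix(0, nt, K)
  if (length(beta) == 1L) beta <- matrix(as.numeric(beta), nt, K)
  beta <- as.matrix(beta)
  if (!identical(dim(beta), c(nt, K)) && !(K == 0L && nrow(beta) == nt)) {
    stop("beta must be n_trans x K")
  }
  if (K > 0L && any(beta[!covariates$mask] != 0)) {
    stop("beta must be 0 where the covariate mask excludes a transition")
  }
  if (!all(is.finite(log_q0)) || !all(is.finite(gamma)) ||
      (K > 0L && !all(is.finite(beta)))) {
    stop("non-finite parameter value")
  }
  names(log_q0) <- names(gamma) <- structure$trans
  dimnames(beta) <- list(structure$trans, covariates$names)
  structure(list(structure = structure, covariates = covariates,
                 log_q0 = log_q0, beta = beta, gamma = gamma),
            class = "msm_parameters")
}

#' @export
print.msm_parameters <- function(x, ...) {
  cat("msm_parameters:", x$structure$n_trans, "transitions,",
      x$covariates$K, "covariate(s)\n")
  cat("baseline intensities (per person-year):\n")
  print(round(exp(x$log_q0), 5))
  if (x$covariates$K) {
    cat("hazard ratios exp(beta):\n")
    print(round(exp(x$beta), 4))
  }
  if (any(x$gamma != 0)) {
    cat("age>=65 multipliers exp(gamma):\n")
    print(round(exp(x$gamma), 4))
  }
  invisible(x)
}

# ---- packing: map msm_parameters <-> optimizer vector -----------------------
#
# A layout records, for every parameter slot (log_q0 per transition, beta per
# masked transition x covariate, gamma per transition if the age-65
# changepoint is active), either a 0-based index into the working vector
# theta or -1 with a fixed value.  `frozen_q` marks transitions whose
# baseline intensity is held at its initial value (sparse-data freezing).
param_layout <- function(structure, covariates, changepoint = TRUE,
                         frozen_q = logical(structure$n_trans)) {
  nt <- structure$n_trans
  K <- covariates$K
  idx <- 0L
  lq_idx <- integer(nt)
  for (t in seq_len(nt)) {
    if (frozen_q[t]) lq_idx[t] <- -1L else { lq_idx[t] <- idx; idx <- idx + 1L }
  }
  # frozen transitions carry no information: their covariate and
  # changepoint coefficients are fixed at 0 rather than estimated
  b_idx <- matrix(-1L, nt, K)
  if (K > 0L) {
    for (k in seq_len(K)) for (t in seq_len(nt)) {
      if (covariates$mask[t, k] && !frozen_q[t]) {
        b_idx[t, k] <- idx; idx <- idx + 1L
      }
    }
  }
  g_idx <- rep(-1L, nt)
  if (changepoint) for (t in seq_len(nt)) {
    if (!frozen_q[t]) { g_idx[t] <- idx; idx <- idx + 1L }
  }
  nms <- character(idx)
  if (any(lq_idx >= 0)) nms[lq_idx[lq_idx >= 0] + 1L] <-
    paste0("logq(", structure$trans[lq_idx >= 0], ")")
  if (K > 0L) for (k in seq_len(K)) {
    sel <- b_idx[, k] >= 0
    nms[b_idx[sel, k] + 1L] <- paste0("beta(", structure$trans[sel], ",",
                                      covariates$names[k], ")")
  }
  if (any(g_idx >= 0)) nms[g_idx[g_idx >= 0] + 1L] <-
    paste0("gamma(", structure$trans[g_idx >= 0], ")")
  list(structure = structure, covariates = covariates,
       n_theta = idx, theta_names = nms,
       lq_idx = lq_idx, b_idx = b_idx, g_idx = g_idx,
       lq_fix = numeric(nt), b_fix = matrix(0, nt, K), g_fix = numeric(nt),
       changepoint = changepoint, frozen_q = frozen_q)
}

pack_parameters <- function(params, layout) {
  theta <- numeric(layout$n_theta)
  sel <- layout$lq_idx >= 0
  theta[layout$lq_idx[sel] + 1L] <- params$log_q0[sel]
  layout$lq_fix[!sel] <- params$log_q0[!sel]
  K <- layout$covariates$K
  if (K > 0L) {
    sel <- layout$b_idx >= 0
    theta[layout$b_idx[sel] + 1L] <- params$beta[sel]
    layout$b_fix[!sel] <- params$beta[!sel]
  }
  sel <- layout$g_idx >= 0
  theta[layout$g_idx[sel] + 1L] <- params$gamma[sel]
  layout$g_fix[!sel] <- params$gamma[!sel]
  list(theta = theta, layout = layout)
}

unpack_parameters <- function(theta, layout) {
  nt <- layout$structure$n_trans
  K <- layout$covariates$K
  log_q0 <- ifelse(layout$lq_idx >= 0, theta[layout$lq_idx + 1L], layout$lq_fix)
  gamma <- ifelse(layout$g_idx >= 0, theta[layout$g_idx + 1L], layout$g_fix)
  beta <- matrix(0, nt, K)
  if (K > 0L) {
    sel <- layout$b_idx >= 0
    beta[sel] <- theta[layout$b_idx[sel] + 1L]
    beta[!sel] <- layout$b_fix[!sel]
  }
  msm_parameters(layout$structure, layout$covariates, log_q0 = log_q0,
                 beta = beta, gamma = gamma)
}

# layout list in the form the C++ core expects
layout_for_cpp <- function(layout) {
  st <- layout$structure
  list(ns = st$n_states, nt = st$n_trans, K = layout$covariates$K,
       from = st$from - 1L, to = st$to - 1L,
       absorb = match(st$absorbing[1], st$states) - 1L,
       lq_idx = layout$lq_idx, lq_fix = layout$lq_fix,
       b_idx = as.integer(layout$b_idx), b_fix = as.numeric(layout$b_fix),
       g_idx = layout$g_idx, g_fix = layout$g_fix)
}
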