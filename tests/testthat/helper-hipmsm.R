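# shared fixtures, all built in code

# random valid 5-state generator respecting the hip structure, intensities
# in [lo, hi]
rand_hip_Q <- function(lo = 0.01, hi = 0.5) {
  st <- hip_structure()
  q <- runif(st$n_trans, lo, hi)
  Q <- matrix(0, 5, 5, dimnames = list(st$states, st$states))
  Q[cbind(st$from, st$to)] <- q
  diag(Q) <- -rowSums(Q)
  Q
}

# Kolmogorov-forward ODE oracle: integrate dP/dt = P Q from P(0) = I
ode_P <- function(Q, dt) {
  n <- nrow(Q)
  rhs <- function(t, y, parms) {
    P <- matrix(y, n, n)
    list(as.numeric(P %*% parms))
  }
  out <- deSolve::lsoda(as.numeric(diag(n)), c(0, dt), rhs, Q,
                        rtol = 1e-12, atol = 1e-12)
  matrix(out[2, -1], n, n)
}

# random parameters for the hip model with one binary covariate
rand_params <- function(covariates = NULL, lo = 0.01, hi = 0.2,
                        beta_sd = 0.3, gamma_sd = 0.3) {
  st <- hip_structure()
  if (is.null(covariates)) covariates <- msm_covariates(character(), structure = st)
  K <- covariates$K
  beta <- matrix(rnorm(st$n_trans * K, 0, beta_sd), st$n_trans, K)
  if (K) beta[!covariates$mask] <- 0
  msm_parameters(st, covariates,
                 log_q0 = log(runif(st$n_trans, lo, hi)),
                 beta = beta,
                 gamma = rnorm(st$n_trans, 0, gamma_sd))
}

# small hand-built cohort with 2 covariates, mixed deaths/censoring
tiny_cohort <- function() {
  mk <- function(id, age0, tt, ss, ob, dm, death = NA) {
    list(panel = data.frame(subject_id = id, t_years = tt, age = age0 + tt,
                            state = ss, obesity = ob, dm = dm),
         death = data.frame(subject_id = id, death_time_years = death))
  }
  subs <- list(
    mk("s1", 60, c(0, 5.5, 12), c("A", "C", "D"), c(0, 1, 1), c(0, 0, 1)),
    mk("s2", 70, c(0, 6), c("B", "B"), c(1, 1), c(0, 0), death = 9.3),
    mk("s3", 63, c(0, 6.2, 11.8), c("C", "A", "A"), c(0, 0, 1), c(0, 1, 1)),
    mk("s4", 52, c(0, 7), c("A", "D"), c(1, 1), c(1, 1), death = 14.2),
    mk("s5", 66, c(0, 5.9, 12.5), c("D", "D", "B"), c(1, 0, 0), c(1, 1, 1)))
  panel <- do.call(rbind, lapply(subs, `[[`, "panel"))
  deaths <- do.call(rbind, lapply(subs, `[[`, "death"))
  msm_cohort(panel, deaths, covariates = c("obesity", "dm"))
}

tiny_covariates <- function() {
  msm_covariates(c("obesity", "dm"), structure = hip_structure())
}

# single-transition structure A -> E (two-state survival)
surv_structure <- function() {
  msm_structure(c("A", "E"), "A->E", absorbing = "E")
}

# one-subject history helper
history1 <- function(age0 = 60, tt = 0, states = "A",
                     covs = data.frame(obesity = 0, dm = 0)[rep(1, length(tt)), ,
                                                            drop = FALSE],
                     death_time = NA) {
  list(id = "h1", t = tt, age0 = age0, states = states,
       covariates = covs, death_time = death_time)
}

# cohort with the pairwise/triple combination indicator columns attached
coh_with_combos <- function(coh, com = c("obesity", "dm", "cvd")) {
  p <- coh$panel
  p <- hipmsm:::add_pair_columns(p, com[1], com[2])
  p <- hipmsm:::add_pair_columns(p, com[1], com[3])
  p <- hipmsm:::add_pair_columns(p, com[2], com[3])
  p <- hipmsm:::add_triple_columns(p, com)
  coh$panel <- p
  coh$covariates <- union(coh$covariates,
                          setdiff(names(p),
                                  c("subject_id", "t_years", "age", "state")))
  coh
}
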