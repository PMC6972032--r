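#' Crude initial intensities from observed pair counts and person-time
#'
#' For each allowed transition r->s, the initial intensity is the number of
#' consecutive observed panel pairs (r, s) divided by the total observation
#' time spent with last-observed state r (exact deaths count as observed
#' pairs into the absorbing state).  Transitions with no observed pairs are
#' initialized at a small floor.  Covariate and changepoint coefficients
#' start at 0.
#'
#' @param cohort an [msm_cohort].
#' @param structure an [msm_structure].
#' @param covariates optional [msm_covariates] to size the beta block.
#' @param floor minimum initial intensity (events/person-year).
#' @return an [msm_parameters] object.
#' @export
crude_initial_values <- function(cohort, structure, covariates = NULL,
                                 floor = 1e-3) {
  if (!nrow(cohort$panel)) stop("empty cohort")
  p <- cohort$panel
  counts <- setNames(numeric(structure$n_trans), structure$trans)
  ptime <- setNames(numeric(structure$n_states), structure$states)
  sp <- split(seq_len(nrow(p)), p$subject_id)
  dth <- cohort$deaths
  abs_state <- structure$absorbing[1]
  for (id in names(sp)) {
    rows <- sp[[id]]
    ss <- p$state[rows]; tt <- p$t_years[rows]
    n <- length(rows)
    if (n >= 2L) {
      for (i in seq_len(n - 1L)) {
        ptime[ss[i]] <- ptime[ss[i]] + (tt[i + 1L] - tt[i])
        lab <- paste0(ss[i], "->", ss[i + 1L])
        if (lab %in% names(counts)) counts[lab] <- counts[lab] + 1
      }
    }
    dt <- dth$death_time_years[match(id, dth$subject_id)]
    if (length(dt) && !is.na(dt)) {
      ptime[ss[n]] <- ptime[ss[n]] + (dt - tt[n])
      lab <- paste0(ss[n], "->", abs_state)
      if (lab %in% names(counts)) counts[lab] <- counts[lab] + 1
    } else {
      au <- cohort$alive_until$alive_until_years[
        match(id, cohort$alive_until$subject_id)]
      if (length(au) && !is.na(au) && au > tt[n]) {
        ptime[ss[n]] <- ptime[ss[n]] + (au - tt[n])
      }
    }
  }
  q0 <- numeric(structure$n_trans)
  for (t in seq_len(structure$n_trans)) {
    src <- structure$states[structure$from[t]]
    q0[t] <- if (ptime[src] > 0) counts[t] / ptime[src] else 0
  }
  low <- q0 < floor
  if (any(low)) {
    q0[low] <- floor
    if (any(counts == 0)) {
      message("transitions with no observed pairs floored at ", floor, ": ",
              paste(structure$trans[counts == 0], collapse = ", "))
    }
  }
  out <- msm_parameters(structure, covariates, log_q0 = log(q0))
  attr(out, "pair_counts") <- counts
  out
}

#' Fit the multi-state model by maximum likelihood
#'
#' Maximizes the interval-censored panel log-likelihood over the
#' unconstrained working scale (log intensities, raw covariate and
#' changepoint coefficients) with BFGS using the exact adjoint gradient,
#' followed by Newton polishing on the finite-difference Hessian until the
#' gradient max-norm is below `grad_tol`.  Transitions with no supporting
#' observed pairs are frozen at the initialization floor with a warning.
#' The fit is deterministic given the data and initial values.
#'
#' @param cohort an [msm_cohort].
#' @param structure an [msm_structure]; default [hip_structure()].
#' @param covariates an [msm_covariates] (or `NULL` for intensities only).
#' @param init optional [msm_parameters] starting values; default
#'   [crude_initial_values()].
#' @param changepoint estimate the age-threshold log-multipliers gamma
#'   (default `TRUE`).
#' @param age_threshold changepoint age in years (default 65).
#' @param death_exact treat death times as exact (default) or as
#'   interval-censored by the recorded date (see [total_loglik()]).
#' @param grad_tol gradient max-norm defining convergence.
#' @param hessian_step central-difference step (working scale) for the
#'   observed information.
#' @param control passed to [stats::optim].
#' @return object of class `msm_fit`: `params` (MLE), `theta`,
#'   `theta_names`, `loglik`, `vcov` (inverse observed information),
#'   `information`, `convergence` (list: converged, grad_norm, iterations,
#'   newton_steps, optim_status), `layout`, `counts`, `n_subjects`.
#' @export
fit_msm <- function(cohort, structure = hip_structure(), covariates = NULL,
                    init = NULL, changepoint = TRUE, age_threshold = 65,
                    death_exact = TRUE, grad_tol = 1e-5, hessian_step = 1e-4,
                    control = list()) {
  if (is.null(covariates)) covariates <- msm_covariates(character(), structure = structure)
  check_structural_support(cohort, structure)
  if (is.null(init)) init <- crude_initial_values(cohort, structure, covariates)
  counts <- attr(init, "pair_counts")
  if (is.null(counts)) {
    counts <- attr(crude_initial_values(cohort, structure), "pair_counts")
  }
  frozen <- counts == 0
  if (any(frozen)) {
    warning("freezing transition(s) with no observed pairs: ",
            paste(structure$trans[frozen], collapse = ", "))
  }
  layout <- param_layout(structure, covariates, changepoint = changepoint,
                         frozen_q = frozen)
  pk <- pack_parameters(init, layout)
  layout <- pk$layout
  dat <- build_likelihood_data(cohort, covariates, structure,
                               threshold = age_threshold,
                               death_exact = death_exact)
  cl <- layout_for_cpp(layout)
  n_subj <- length(unique(cohort$panel$subject_id))

  big <- 1e10
  negll <- function(th) {
    v <- cpp_panel_loglik(th, cl, dat$iv, dat$de, dat$sv, FALSE)$loglik
    if (!is.finite(v)) big else -v
  }
  neggr <- function(th) {
    r <- cpp_panel_loglik(th, cl, dat$iv, dat$de, dat$sv, TRUE)
    if (!is.finite(r$loglik)) numeric(length(th)) else -r$grad
  }
  ctl <- modifyList(list(maxit = 300, reltol = 1e-10), control)
  opt <- optim(pk$theta, negll, neggr, method = "BFGS", control = ctl)
  theta <- opt$par

  # Newton/chord polishing to drive the gradient max-norm below grad_tol;
  # the Hessian is reused across steps (chord iteration) and refreshed
  # only when progress stalls
  res <- cpp_panel_loglik(theta, cl, dat$iv, dat$de, dat$sv, TRUE)
  gr <- res$grad
  cur_ll <- res$loglik
  newton <- 0L
  H <- NULL
  H_at <- NULL
  fresh <- FALSE
  while (is.finite(cur_ll) && max(abs(gr)) > grad_tol && newton < 40L) {
    if (is.null(H) || newton %% 6L == 0L) {
      H <- fd_hessian(theta, cl, dat, hessian_step)
      H_at <- theta
      fresh <- TRUE
    }
    step <- tryCatch(-solve(H, gr), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    cand <- theta + step
    damp <- 0L
    cand_ll <- -negll(cand)
    while (cand_ll < cur_ll - 1e-9 && damp < 10L) {
      step <- step / 2
      cand <- theta + step
      cand_ll <- -negll(cand)
      damp <- damp + 1L
    }
    if (damp >= 10L) {
      if (fresh) break
      H <- NULL   # stale Hessian: refresh and retry
      next
    }
    theta <- cand
    cur_ll <- cand_ll
    gr <- cpp_panel_loglik(theta, cl, dat$iv, dat$de, dat$sv, TRUE)$grad
    newton <- newton + 1L
    fresh <- FALSE
  }
  if (is.null(H_at) || max(abs(theta - H_at)) > 0) {
    H <- fd_hessian(theta, cl, dat, hessian_step)
  }

  loglik <- cpp_panel_loglik(theta, cl, dat$iv, dat$de, dat$sv, FALSE)$loglik
  info <- -(H + t(H)) / 2   # observed information, symmetrized
  ev <- tryCatch(min(eigen(info, symmetric = TRUE, only.values = TRUE)$values),
                 error = function(e) NA_real_)
  pd <- is.finite(ev) && ev > 0
  vcov <- if (pd) tryCatch(solve(info), error = function(e) NULL) else NULL
  grad_norm <- max(abs(gr))
  converged <- grad_norm < grad_tol
  if (!converged) {
    warning("fit did not reach gradient tolerance (max |grad| = ",
            signif(grad_norm, 3), ")")
  }
  if (converged && !pd) {
    warning("observed information not positive definite at the optimum")
  }
  structure(
    list(params = unpack_parameters(theta, layout), theta = theta,
         theta_names = layout$theta_names, loglik = loglik,
         vcov = vcov, information = info,
         convergence = list(converged = converged, grad_norm = grad_norm,
                            iterations = opt$counts[["function"]],
                            newton_steps = newton,
                            optim_status = opt$convergence,
                            info_positive_definite = pd),
         layout = layout, counts = counts, frozen = frozen,
         n_subjects = n_subj),
    class = "msm_fit")
}

# central-difference Hessian of the log-likelihood via the exact gradient
fd_hessian <- function(theta, cl, dat, h = 1e-4) {
  p <- length(theta)
  H <- matrix(0, p, p)
  for (i in seq_len(p)) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    gp <- cpp_panel_loglik(tp, cl, dat$iv, dat$de, dat$sv, TRUE)$grad
    gm <- cpp_panel_loglik(tm, cl, dat$iv, dat$de, dat$sv, TRUE)$grad
    H[i, ] <- (gp - gm) / (2 * h)
  }
  (H + t(H)) / 2
}

#' @export
print.msm_fit <- function(x, ...) {
  cat("msm_fit:", x$n_subjects, "subjects, log-likelihood",
      format(x$loglik, digits = 8), "\n")
  cat("  converged:", x$convergence$converged,
      "(max |grad| =", signif(x$convergence$grad_norm, 3), ")\n")
  cat("baseline intensities (per person-year):\n")
  print(round(exp(x$params$log_q0), 5))
  invisible(x)
}

#' @export
logLik.msm_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$theta), class = "logLik")
}

#' @export
vcov.msm_fit <- function(object, ...) object$vcov

# standard error of a single working parameter; NA if unavailable
theta_se <- function(fit, idx) {
  if (is.null(fit$vcov)) return(NA_real_)
  v <- fit$vcov[idx + 1L, idx + 1L]
  if (!is.finite(v) || v < 0) NA_real_ else sqrt(v)
}

#' Hazard-ratio table in the reporting layout
#'
#' One row per (transition, covariate contrast): adjusted hazard ratio
#' `exp(beta)`, Wald confidence limits `exp(beta +/- z SE)` with SE from
#' the inverse observed information, transition counts split by exposure,
#' and a significance flag (CI excludes 1).  By default rows are emitted
#' for the six reported living-state transitions; transitions into death
#' are estimated but suppressed unless `include_death = TRUE`.
#'
#' @param fit an [fit_msm()] result.
#' @param covariates covariate names to report (default: all in the fit).
#' @param cohort optional [msm_cohort] for the exposed/unexposed pair
#'   counts (binary covariates only; `NA` otherwise).
#' @param transitions transitions to report; default [reported_transitions()]
#'   intersected with the fitted structure.
#' @param conf_level confidence level (default 0.95).
#' @param include_death also report transitions into the absorbing state.
#' @return data.frame with columns `transition`, `label`, `covariate`,
#'   `n_exposed`, `n_unexposed`, `aHR`, `lower`, `upper`, `se_log`,
#'   `significant`, `estimable`.
#' @export
hazard_ratio_table <- function(fit, covariates = NULL, cohort = NULL,
                               transitions = NULL, conf_level = 0.95,
                               include_death = FALSE) {
  st <- fit$params$structure
  cv <- fit$params$covariates
  if (is.null(covariates)) covariates <- cv$names
  if (is.null(transitions)) {
    transitions <- intersect(reported_transitions(), st$trans)
    if (include_death) {
      transitions <- c(transitions,
                       st$trans[st$states[st$to] %in% st$absorbing])
    }
  }
  zq <- qnorm(1 - (1 - conf_level) / 2)
  if (is.null(fit$vcov) && fit$convergence$converged) {
    warning("information matrix singular; confidence intervals unavailable")
  }
  rows <- list()
  for (cov in covariates) {
    k <- match(cov, cv$names)
    if (is.na(k)) stop("covariate not in fit: ", cov)
    cnt <- if (!is.null(cohort)) {
      transition_count_table(cohort, st, cov)
    } else NULL
    for (tr in transitions) {
      t <- match(tr, st$trans)
      bi <- fit$layout$b_idx[t, k]
      est <- fit$params$beta[t, k]
      if (bi < 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          transition = tr, label = transition_label(st, tr), covariate = cov,
          n_exposed = NA_real_, n_unexposed = NA_real_,
          aHR = NA_real_, lower = NA_real_, upper = NA_real_,
          se_log = NA_real_, significant = NA, estimable = FALSE)
        next
      }
      se <- theta_se(fit, bi)
      lo <- exp(est - zq * se); hi <- exp(est + zq * se)
      ne <- nu <- NA_real_
      if (!is.null(cnt)) {
        i <- match(tr, cnt$transition)
        ne <- cnt$n_exposed[i]; nu <- cnt$n_unexposed[i]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        transition = tr, label = transition_label(st, tr), covariate = cov,
        n_exposed = ne, n_unexposed = nu,
        aHR = exp(est), lower = lo, upper = hi, se_log = se,
        significant = if (is.na(se)) NA else (lo > 1 || hi < 1),
        estimable = TRUE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

transition_label <- function(st, tr) {
  ft <- strsplit(tr, "->", fixed = TRUE)[[1]]
  paste0(st$labels[ft[1]], " (", ft[1], ") to ", st$labels[ft[2]],
         " (", ft[2], ")")
}

#' Observed transition counts by exposure status
#'
#' Tallies consecutive observed panel pairs matching each allowed
#' living-state transition, classified by the (binary) exposure value in
#' effect at the interval start.
#'
#' @param cohort an [msm_cohort].
#' @param structure an [msm_structure].
#' @param exposure name of a binary (0/1) covariate column.
#' @return data.frame with columns `transition`, `n_exposed`,
#'   `n_unexposed`.
#' @export
transition_count_table <- function(cohort, structure, exposure) {
  p <- cohort$panel
  if (!exposure %in% names(p)) stop("unknown exposure column: ", exposure)
  ev <- p[[exposure]]
  if (!all(ev %in% c(0, 1))) stop("exposure must be binary 0/1")
  living <- structure$trans[!(structure$states[structure$to] %in% structure$absorbing)]
  ne <- nu <- setNames(numeric(length(living)), living)
  sp <- split(seq_len(nrow(p)), p$subject_id)
  for (rows in sp) {
    n <- length(rows)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) {
      lab <- paste0(p$state[rows[i]], "->", p$state[rows[i + 1L]])
      if (lab %in% living) {
        if (ev[rows[i]] == 1) ne[lab] <- ne[lab] + 1 else nu[lab] <- nu[lab] + 1
      }
    }
  }
  data.frame(transition = living, n_exposed = as.numeric(ne),
             n_unexposed = as.numeric(nu), row.names = NULL)
}
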