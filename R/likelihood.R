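#' Split an observation interval into constant-intensity segments
#'
#' Covariates recorded at the visit opening the interval are carried
#' forward across the whole interval (last observation carried forward).
#' The only within-interval change of intensities is the age-65
#' changepoint: if the subject turns 65 strictly inside `(t0, t1)` the
#' interval is split there.  The age indicator uses the half-open
#' convention `[65, Inf)`: a subject turning 65 exactly at `t1` spends the
#' whole interval below the threshold.
#'
#' @param history a subject history (see [subject_history()]).
#' @param t0,t1 interval endpoints, years since the subject's baseline;
#'   `t0` must be one of the subject's observation times.
#' @param threshold changepoint age in years (default 65).
#' @return data.frame with columns `duration` and `age_ge_65`, plus the
#'   covariate values in effect (attribute `"z"`); durations sum to
#'   `t1 - t0`.
#' @export
segment_interval <- function(history, t0, t1, threshold = 65) {
  if (t1 <= t0) stop("'t1' must exceed 't0'")
  i <- match(TRUE, abs(history$t - t0) < 1e-9)
  if (is.na(i)) stop("'t0' is not an observation time of the subject")
  z <- unlist(history$covariates[i, , drop = FALSE])
  t65 <- threshold - history$age0   # study time at the changepoint age
  if (t65 <= t0) {
    seg <- data.frame(duration = t1 - t0, age_ge_65 = TRUE)
  } else if (t65 >= t1) {
    seg <- data.frame(duration = t1 - t0, age_ge_65 = FALSE)
  } else {
    seg <- data.frame(duration = c(t65 - t0, t1 - t65),
                      age_ge_65 = c(FALSE, TRUE))
  }
  attr(seg, "z") <- z
  seg
}

# Segment plan -> list of (Q, dt) for path_probability
segments_to_Q <- function(params, seg) {
  z <- attr(seg, "z")
  lapply(seq_len(nrow(seg)), function(j) {
    list(Q = intensity_matrix(params, z, age_ge_65 = seg$age_ge_65[j]),
         dt = seg$duration[j])
  })
}

#' Log-likelihood contribution of one interval-censored panel pair
#'
#' The probability of observing state `s1` at `t1` given state `s0` at
#' `t0` is the `[s0, s1]` entry of the product of per-segment transition
#' probability matrices (matrix exponentials of the generator in effect on
#' each segment).
#'
#' @param params an [msm_parameters].
#' @param history a subject history (see [subject_history()]).
#' @param t0,s0 interval start time and observed state there.
#' @param t1,s1 interval end time and observed state there.
#' @return log-probability; `-Inf` (with attribute `"impossible"`) when the
#'   panel pair has probability 0 under the transition structure.
#' @export
interval_loglik <- function(params, history, t0, s0, t1, s1) {
  st <- params$structure
  seg <- segment_interval(history, t0, t1)
  P <- path_probability(segments_to_Q(params, seg), n_states = st$n_states)
  p <- P[match(s0, st$states), match(s1, st$states)]
  if (p <= 0) {
    out <- -Inf
    attr(out, "impossible") <- TRUE
    return(out)
  }
  log(p)
}

#' Log-likelihood contribution of an exactly observed death
#'
#' Death times are known exactly (registry linkage), so the contribution is
#' a density, not an interval probability: the subject survives from the
#' last visit in some living state k and then jumps to death, i.e.
#' `sum_k P[s_last, k](t_last, t_death) * q_{k,E}` with the death
#' intensities evaluated at the covariates carried forward from the last
#' visit and the age indicator at the death instant.
#'
#' @param params an [msm_parameters].
#' @param history a subject history.
#' @param t_last,s_last time and state of the last visit.
#' @param t_death exact death time (years since baseline), `> t_last`.
#' @param threshold changepoint age in years (default 65).
#' @return log-density; `-Inf` with attribute `"impossible"` if every death
#'   intensity is structurally zero.
#' @export
death_loglik <- function(params, history, t_last, s_last, t_death,
                         threshold = 65) {
  if (t_death <= t_last) stop("'t_death' must exceed 't_last'")
  st <- params$structure
  seg <- segment_interval(history, t_last, t_death, threshold)
  P <- path_probability(segments_to_Q(params, seg), n_states = st$n_states)
  z <- attr(seg, "z")
  age_at_death <- history$age0 + t_death >= threshold
  Qd <- intensity_matrix(params, z, age_ge_65 = age_at_death)
  abs_i <- match(st$absorbing[1], st$states)
  living <- setdiff(seq_len(st$n_states), abs_i)
  dens <- sum(P[match(s_last, st$states), living] * Qd[living, abs_i])
  if (dens <= 0) {
    out <- -Inf
    attr(out, "impossible") <- TRUE
    return(out)
  }
  log(dens)
}

# ---- flattened likelihood data for the C++ core -----------------------------
#
# iv: one row per consecutive panel pair: s0, s1 (1-based state index),
#     dt1, a1, dt2, a2 (up to two constant-intensity segments; dt2 = 0 when
#     the age-65 crossing does not fall inside the interval), then the K
#     covariate values in effect.
# de: one row per exact death: s0, dt1, a1, dt2, a2, adeath, covariates.
# sv: one row per subject known alive at vital-status ascertainment later
#     than the last visit: s0, dt1, a1, dt2, a2, covariates.
build_likelihood_data <- function(cohort, covariates, structure,
                                  threshold = 65, death_exact = TRUE) {
  p <- cohort$panel
  covn <- covariates$names
  miss <- setdiff(covn, names(p))
  if (length(miss)) stop("cohort lacks covariate column(s): ",
                         paste(miss, collapse = ", "))
  sidx <- match(p$state, structure$states)
  ids <- unique(p$subject_id)
  dth <- cohort$deaths$death_time_years[match(ids, cohort$deaths$subject_id)]
  aut <- cohort$alive_until$alive_until_years[
    match(ids, cohort$alive_until$subject_id)]
  if (is.null(aut)) aut <- rep(NA_real_, length(ids))
  sp <- split(seq_len(nrow(p)), factor(p$subject_id, levels = ids))

  iv <- list(); de <- list(); sv <- list()
  iv_subj <- list(); de_subj <- list()
  dropped <- character(0)
  for (j in seq_along(ids)) {
    rows <- sp[[j]]
    n <- length(rows)
    has_death <- !is.na(dth[j])
    has_surv <- !has_death && !is.na(aut[j]) &&
      aut[j] > p$t_years[rows[n]] + 1e-12
    if (n + has_death + has_surv < 2L) { dropped <- c(dropped, ids[j]); next }
    tt <- p$t_years[rows]
    age0 <- p$age[rows[1]] - tt[1]
    t65 <- threshold - age0
    zmat <- as.matrix(p[rows, covn, drop = FALSE])
    if (n >= 2L) {
      for (i in seq_len(n - 1L)) {
        t0 <- tt[i]; t1 <- tt[i + 1L]
        iv[[length(iv) + 1L]] <- c(sidx[rows[i]], sidx[rows[i + 1L]],
                                   split_at_65(t0, t1, t65), zmat[i, ])
        iv_subj[[length(iv_subj) + 1L]] <- ids[j]
      }
    }
    if (has_death) {
      t0 <- tt[n]; t1 <- dth[j]
      if (death_exact) {
        de[[length(de) + 1L]] <- c(sidx[rows[n]],
                                   split_at_65(t0, t1, t65),
                                   as.numeric(age0 + t1 >= threshold),
                                   zmat[n, ])
        de_subj[[length(de_subj) + 1L]] <- ids[j]
      } else {
        # interval-censored death: known only to have occurred by t1, an
        # ordinary panel pair into the absorbing state
        abs_i <- match(structure$absorbing[1], structure$states)
        iv[[length(iv) + 1L]] <- c(sidx[rows[n]], abs_i,
                                   split_at_65(t0, t1, t65), zmat[n, ])
        iv_subj[[length(iv_subj) + 1L]] <- ids[j]
      }
    }
    if (has_surv) {
      sv[[length(sv) + 1L]] <- c(sidx[rows[n]],
                                 split_at_65(tt[n], aut[j], t65), zmat[n, ])
    }
  }
  if (length(dropped)) {
    warning(length(dropped), " subject(s) with a single time point excluded: ",
            paste(head(dropped, 5), collapse = ", "))
  }
  K <- length(covn)
  iv <- if (length(iv)) do.call(rbind, iv) else matrix(0, 0, 6 + K)
  de <- if (length(de)) do.call(rbind, de) else matrix(0, 0, 6 + K)
  sv <- if (length(sv)) do.call(rbind, sv) else matrix(0, 0, 5 + K)
  list(iv = iv, de = de, sv = sv,
       iv_subj = unlist(iv_subj) %||% character(0),
       de_subj = unlist(de_subj) %||% character(0),
       dropped = dropped)
}

# (dt1, a1, dt2, a2) for the interval [t0, t1) given the age-65 crossing time
split_at_65 <- function(t0, t1, t65) {
  if (t65 <= t0) c(t1 - t0, 1, 0, 0)
  else if (t65 >= t1) c(t1 - t0, 0, 0, 0)
  else c(t65 - t0, 0, t1 - t65, 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total panel log-likelihood of a cohort
#'
#' Sums, over subjects, the interval contributions of consecutive panel
#' pairs, the exact-death density where a death time is recorded, and the
#' known-alive survival probability over `(last visit, alive_until]` for
#' subjects with registry vital-status follow-up.  Subjects with fewer
#' than two time points (counting death or vital-status follow-up) carry
#' no information and are excluded with a warning.
#'
#' @param params an [msm_parameters].
#' @param cohort an [msm_cohort] whose panel carries the model's covariate
#'   columns.
#' @param method `"cpp"` (default): fast uniformization core;
#'   `"reference"`: independent R implementation built on
#'   [path_probability()] matrix exponentials (used for cross-checking).
#' @param death_exact treat recorded death times as exact event times
#'   (default, registry-linkage model); `FALSE` treats each death as
#'   interval-censored — known only to have occurred by the recorded
#'   date — contributing the plain transition probability into the
#'   absorbing state.
#' @return scalar log-likelihood; `-Inf` with attribute `"impossible"`
#'   (listing offending subjects) when a structurally impossible record is
#'   present.
#' @export
total_loglik <- function(params, cohort, method = c("cpp", "reference"),
                         death_exact = TRUE) {
  method <- match.arg(method)
  if (method == "reference") {
    return(total_loglik_reference(params, cohort, death_exact = death_exact))
  }
  layout <- param_layout(params$structure, params$covariates, changepoint = TRUE)
  pk <- pack_parameters(params, layout)
  dat <- suppressWarnings(build_likelihood_data(cohort, params$covariates,
                                                params$structure,
                                                death_exact = death_exact))
  res <- cpp_panel_loglik(pk$theta, layout_for_cpp(pk$layout), dat$iv, dat$de,
                          dat$sv, FALSE)
  ll <- res$loglik
  if (!is.finite(ll)) {
    bad <- unique(c(dat$iv_subj[res$bad_iv], dat$de_subj[res$bad_de]))
    attr(ll, "impossible") <- bad
  }
  ll
}

# Straightforward per-subject implementation on the expm route; shares no
# matrix code with the C++ core.
total_loglik_reference <- function(params, cohort, death_exact = TRUE) {
  ids <- unique(cohort$panel$subject_id)
  ll <- 0
  for (id in ids) {
    h <- subject_history(cohort, id)
    n <- length(h$t)
    has_surv <- is.na(h$death_time) && !is.null(h$alive_until) &&
      !is.na(h$alive_until) && h$alive_until > h$t[n] + 1e-12
    if (n + (!is.na(h$death_time)) + has_surv < 2L) next
    if (n >= 2L) {
      for (i in seq_len(n - 1L)) {
        ll <- ll + interval_loglik(params, h, h$t[i], h$states[i],
                                   h$t[i + 1L], h$states[i + 1L])
      }
    }
    if (!is.na(h$death_time)) {
      ll <- ll + if (death_exact) {
        death_loglik(params, h, h$t[n], h$states[n], h$death_time)
      } else {
        interval_loglik(params, h, h$t[n], h$states[n], h$death_time,
                        params$structure$absorbing[1])
      }
    } else if (!is.null(h$alive_until) && !is.na(h$alive_until) &&
               h$alive_until > h$t[n] + 1e-12) {
      seg <- segment_interval(h, h$t[n], h$alive_until)
      P <- path_probability(segments_to_Q(params, seg),
                            n_states = params$structure$n_states)
      living <- !(params$structure$states %in% params$structure$absorbing)
      ll <- ll + log(sum(P[match(h$states[n], params$structure$states),
                           living]))
    }
  }
  as.numeric(ll)
}

# Pre-fit structural check: every observed panel pair must connect through
# the reflexive-transitive closure of the allowed transitions.
check_structural_support <- function(cohort, structure) {
  reach <- reachable_states(structure)
  p <- cohort$panel
  bad <- character(0)
  sp <- split(seq_len(nrow(p)), p$subject_id)
  for (rows in sp) {
    s <- p$state[rows]
    if (length(s) >= 2L) {
      ok <- reach[cbind(s[-length(s)], s[-1L])]
      if (!all(ok)) bad <- c(bad, p$subject_id[rows[1]])
    }
  }
  if (length(bad)) {
    stop("structurally impossible panel pair(s) for subject(s): ",
         paste(head(bad, 10), collapse = ", "),
         if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10))
  }
  invisible(TRUE)
}
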