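#' Observed state prevalence over follow-up
#'
#' At each grid time t, a subject's observed state is the one recorded at
#' their most recent visit at or before t; subjects with a death time at
#' or before t occupy the absorbing state; subjects past their last visit
#' and not known dead are removed from the denominator (censored).
#'
#' @param cohort an [msm_cohort].
#' @param grid numeric vector of times (years since baseline).
#' @param structure an [msm_structure] (for the state set).
#' @return data.frame, one row per (time, state): columns `time`, `state`,
#'   `observed` (proportion), `n_at_risk` (denominator at that time).
#' @export
observed_prevalence <- function(cohort, grid, structure = hip_structure()) {
  if (length(grid) == 0L) stop("empty grid")
  p <- cohort$panel
  ids <- unique(p$subject_id)
  last_t <- tapply(p$t_years, p$subject_id, max)[ids]
  dth <- cohort$deaths$death_time_years[match(ids, cohort$deaths$subject_id)]
  abs_state <- structure$absorbing[1]
  sp <- split(seq_len(nrow(p)), factor(p$subject_id, levels = ids))
  out <- list()
  for (tg in grid) {
    dead <- !is.na(dth) & dth <= tg
    infu <- last_t >= tg
    denom <- dead | infu
    states <- character(length(ids))
    states[dead] <- abs_state
    for (j in which(denom & !dead)) {
      rows <- sp[[j]]
      k <- max(which(p$t_years[rows] <= tg + 1e-9))
      states[j] <- p$state[rows[k]]
    }
    tb <- table(factor(states[denom], levels = structure$states))
    out[[length(out) + 1L]] <- data.frame(
      time = tg, state = structure$states,
      observed = if (sum(tb)) as.numeric(tb) / sum(tb) else NA_real_,
      n_at_risk = sum(denom))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Expected state prevalence under a fitted model
#'
#' Each subject's baseline state is propagated through the fitted
#' piecewise-constant transition probabilities along their own recorded
#' covariate path (carried forward, split at the age-65 crossing) to each
#' grid time; occupancy distributions are averaged over the same
#' denominator as [observed_prevalence()].
#'
#' @param fit an `msm_fit` or an [msm_parameters] object.
#' @param cohort an [msm_cohort].
#' @param grid numeric vector of times (years since baseline).
#' @return data.frame with columns `time`, `state`, `expected`,
#'   `n_at_risk`.
#' @export
expected_prevalence <- function(fit, cohort, grid) {
  params <- if (inherits(fit, "msm_fit")) fit$params
            else if (inherits(fit, "msm_parameters")) fit
            else stop("'fit' must be an msm_fit or msm_parameters object")
  if (length(grid) == 0L) stop("empty grid")
  st <- params$structure
  p <- cohort$panel
  ids <- unique(p$subject_id)
  last_t <- tapply(p$t_years, p$subject_id, max)[ids]
  dth <- cohort$deaths$death_time_years[match(ids, cohort$deaths$subject_id)]
  grid <- sort(grid)
  occ_sum <- matrix(0, length(grid), st$n_states,
                    dimnames = list(NULL, st$states))
  denom <- numeric(length(grid))
  for (j in seq_along(ids)) {
    h <- subject_history(cohort, ids[j])
    in_denom <- (!is.na(dth[j]) & dth[j] <= grid) | (last_t[j] >= grid)
    if (!any(in_denom)) next
    v <- as.numeric(st$states == h$states[1])
    t_cur <- 0
    seg_times <- sort(unique(c(h$t, pmax(65 - h$age0, 0))))
    for (gi in seq_along(grid)) {
      tg <- grid[gi]
      if (tg > t_cur) {
        # advance v across [t_cur, tg), breaking at visit/changepoint times
        brk <- seg_times[seg_times > t_cur + 1e-12 & seg_times < tg - 1e-12]
        ends <- c(brk, tg)
        for (e in ends) {
          vi <- max(c(1L, which(h$t <= t_cur + 1e-9)))
          z <- unlist(h$covariates[vi, , drop = FALSE])
          Q <- intensity_matrix(params, z, age_ge_65 = h$age0 + t_cur >= 65)
          v <- as.numeric(v %*% transition_probability(Q, e - t_cur))
          t_cur <- e
        }
      }
      if (in_denom[gi]) {
        occ_sum[gi, ] <- occ_sum[gi, ] + v
        denom[gi] <- denom[gi] + 1
      }
    }
  }
  out <- data.frame(
    time = rep(grid, each = st$n_states),
    state = rep(st$states, length(grid)),
    expected = as.numeric(t(occ_sum / pmax(denom, 1))),
    n_at_risk = rep(denom, each = st$n_states))
  out$expected[rep(denom == 0, each = st$n_states)] <- NA_real_
  out
}

#' Observed-versus-expected prevalence table and plot
#'
#' Qualitative model assessment: observed and model-expected prevalence
#' for each state over follow-up on a common grid (default yearly from 0
#' to 18).
#'
#' @param fit an `msm_fit` or [msm_parameters].
#' @param cohort an [msm_cohort].
#' @param grid time grid; default `0:18` years.
#' @return data.frame with columns `time`, `state`, `observed`,
#'   `expected`, `n_at_risk`.
#' @export
prevalence_curves <- function(fit, cohort, grid = 0:18) {
  params <- if (inherits(fit, "msm_fit")) fit$params else fit
  ob <- observed_prevalence(cohort, grid, params$structure)
  ex <- expected_prevalence(fit, cohort, grid)
  m <- merge(ob, ex[, c("time", "state", "expected")],
             by = c("time", "state"), sort = FALSE)
  m[order(m$time, match(m$state, params$structure$states)),
    c("time", "state", "observed", "expected", "n_at_risk")]
}

#' Plot observed-versus-expected prevalence
#'
#' One panel per state: observed prevalence as points, model-expected as
#' a line.
#'
#' @param curves output of [prevalence_curves()].
#' @param file optional path; if given the figure is saved (vector formats
#'   such as `.pdf` or `.svg` recommended).
#' @return the ggplot object, invisibly.
#' @export
plot_prevalence <- function(curves, file = NULL) {
  gg <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected, colour = "expected")) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed, colour = "observed"),
                        size = 1) +
    ggplot2::facet_wrap(~state, scales = "free_y") +
    ggplot2::scale_colour_manual(NULL, values = c(expected = "#D55E00",
                                                  observed = "#0072B2")) +
    ggplot2::labs(x = "Years since baseline", y = "Prevalence") +
    ggplot2::theme_bw()
  if (!is.null(file)) ggplot2::ggsave(file, gg, width = 8, height = 5)
  invisible(gg)
}
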