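#' Define the analysis plan of the comorbidity model suite
#'
#' The full suite comprises: an *individual* model containing all three
#' comorbidities jointly; three *pairwise* combination models, each coding
#' a four-level exposure (neither [reference], first only, second only,
#' both) as mutually exclusive time-dependent indicators while adjusting
#' for the third comorbidity; and a *triple* combination model comparing
#' subjects with all three comorbidities to those with none (subjects with
#' one or two form their own indicator group).  Stratified runs (by sex
#' and by race, individual model only) drop the stratifying variable from
#' the adjustment set.
#'
#' @param models subset of `"individual"`, `"pairwise"`, `"triple"`.
#' @param strata subset of `"overall"`, `"sex"`, `"race"`.
#' @param comorbidities the three time-dependent exposure columns.
#' @param adjusters shared adjustment covariates (baseline demographics,
#'   cohort, mean-centered birth year, time-dependent hip injury).
#' @param mask transition inclusion for covariates (`"all"` or
#'   `"living"`).
#' @param changepoint estimate age-threshold multipliers.
#' @param age_threshold changepoint age (years).
#' @param conf_level confidence level for reported intervals.
#' @param include_death report covariate effects on death transitions
#'   (suppressed by default).
#' @return object of class `analysis_plan`.
#' @export
analysis_plan <- function(models = c("individual", "pairwise", "triple"),
                          strata = c("overall", "sex", "race"),
                          comorbidities = c("obesity", "dm", "cvd"),
                          adjusters = c("age0_c", "male", "black",
                                        "educ_lt12", "enrich", "byear_c",
                                        "hip_injury"),
                          mask = "all", changepoint = TRUE,
                          age_threshold = 65, conf_level = 0.95,
                          include_death = FALSE) {
  models <- match.arg(models, several.ok = TRUE)
  strata <- match.arg(strata, several.ok = TRUE)
  stopifnot(length(comorbidities) == 3L)
  structure(list(models = models, strata = strata,
                 comorbidities = comorbidities, adjusters = adjusters,
                 mask = mask, changepoint = changepoint,
                 age_threshold = age_threshold, conf_level = conf_level,
                 include_death = include_death),
            class = "analysis_plan")
}

# mutually exclusive time-dependent combination indicators for a pair,
# recomputed at every visit from the component comorbidities
add_pair_columns <- function(panel, a, b) {
  panel[[paste0(a, "_only")]] <- as.numeric(panel[[a]] == 1 & panel[[b]] == 0)
  panel[[paste0(b, "_only")]] <- as.numeric(panel[[a]] == 0 & panel[[b]] == 1)
  panel[[paste0(a, "_", b)]] <- as.numeric(panel[[a]] == 1 & panel[[b]] == 1)
  panel
}

add_triple_columns <- function(panel, com) {
  s <- panel[[com[1]]] + panel[[com[2]]] + panel[[com[3]]]
  panel$one_or_two <- as.numeric(s >= 1 & s <= 2)
  panel$all_three <- as.numeric(s == 3)
  panel
}

# subset a cohort to given subject ids, keeping attributes needed downstream
subset_cohort <- function(cohort, ids) {
  au <- cohort$alive_until
  msm_cohort(cohort$panel[cohort$panel$subject_id %in% ids, , drop = FALSE],
             cohort$deaths[cohort$deaths$subject_id %in% ids, , drop = FALSE],
             covariates = cohort$covariates,
             alive_until = if (!is.null(au))
               au[au$subject_id %in% ids, , drop = FALSE],
             monotone = cohort$monotone, states = cohort$states)
}

# drop covariates that are constant in this (sub)cohort: they are
# collinear with the baseline intensities and unidentifiable
prune_constant <- function(cohort, covs, log) {
  keep <- vapply(covs, function(cv) {
    v <- cohort$panel[[cv]]
    !is.null(v) && length(unique(v)) > 1L
  }, logical(1))
  if (any(!keep)) {
    log(paste("dropping constant covariate(s):",
              paste(covs[!keep], collapse = ", ")))
  }
  covs[keep]
}

#' Run the full comorbidity analysis suite
#'
#' Fits every model of the plan on the panel data and assembles the
#' report bundle: per-model hazard-ratio tables for the six reported
#' transitions (with exposed/unexposed transition counts), prevalence
#' assessment curves, convergence diagnostics and a run log.  Sparse or
#' empty transitions are frozen and their rows marked not estimable.
#'
#' @param cohort an [msm_cohort], or the path of a panel file readable by
#'   [read_panel()].
#' @param plan an [analysis_plan].
#' @param out_dir optional directory: writes per-model hazard-ratio and
#'   prevalence tables (CSV), prevalence figures (PDF) and a YAML run
#'   manifest.
#' @param structure the transition structure (default [hip_structure()]).
#' @return object of class `analysis_bundle`: a list with `results` (one
#'   element per model x stratum: `fit`, `hr_table`, `curves`), `plan`,
#'   `log`.
#' @export
run_analysis <- function(cohort, plan = analysis_plan(), out_dir = NULL,
                         structure = hip_structure()) {
  if (is.character(cohort)) cohort <- read_panel(cohort)
  stopifnot(inherits(plan, "analysis_plan"))
  logline <- local({
    lines <- character(0)
    function(msg = NULL) {
      if (is.null(msg)) return(lines)
      lines <<- c(lines, msg)
      message(msg)
    }
  })
  com <- plan$comorbidities
  cohort$panel <- add_triple_columns(
    Reduce(function(p, ab) add_pair_columns(p, ab[1], ab[2]),
           list(com[c(1, 2)], com[c(1, 3)], com[c(2, 3)]),
           cohort$panel), com)
  derived <- setdiff(names(cohort$panel),
                     c("subject_id", "t_years", "age", "state",
                       cohort$covariates))
  cohort$covariates <- c(cohort$covariates, derived)

  model_defs <- list()
  if ("individual" %in% plan$models) {
    for (stw in plan$strata) {
      if (stw == "overall") {
        model_defs[["individual"]] <- list(
          exposures = com, adjusters = plan$adjusters, subset = NULL)
      } else {
        svar <- if (stw == "sex") "male" else "black"
        for (lev in 0:1) {
          nm <- sprintf("individual_%s%d", svar, lev)
          model_defs[[nm]] <- list(
            exposures = com,
            adjusters = setdiff(plan$adjusters, svar),
            subset = list(var = svar, level = lev))
        }
      }
    }
  }
  if ("pairwise" %in% plan$models) {
    pairs <- list(com[c(1, 2)], com[c(1, 3)], com[c(2, 3)])
    for (ab in pairs) {
      nm <- paste0("pairwise_", ab[1], "_", ab[2])
      third <- setdiff(com, ab)
      model_defs[[nm]] <- list(
        exposures = c(paste0(ab[1], "_only"), paste0(ab[2], "_only"),
                      paste0(ab[1], "_", ab[2])),
        adjusters = c(plan$adjusters, third), subset = NULL)
    }
  }
  if ("triple" %in% plan$models) {
    model_defs[["triple"]] <- list(
      exposures = c("one_or_two", "all_three"),
      adjusters = plan$adjusters, subset = NULL)
  }

  results <- list()
  for (nm in names(model_defs)) {
    def <- model_defs[[nm]]
    coh <- cohort
    if (!is.null(def$subset)) {
      base <- coh$panel[coh$panel$t_years == 0, ]
      ids <- base$subject_id[base[[def$subset$var]] == def$subset$level]
      if (!length(ids)) stop("empty stratum: ", nm)
      coh <- subset_cohort(coh, ids)
    }
    logline(sprintf("fitting model '%s' (%d subjects)", nm,
                    length(unique(coh$panel$subject_id))))
    covs <- prune_constant(coh, c(def$exposures, def$adjusters), logline)
    cv <- msm_covariates(covs,
                         kind = "time-dependent",
                         mask = plan$mask, structure = structure)
    fit <- withCallingHandlers(
      fit_msm(coh, structure, cv, changepoint = plan$changepoint,
              age_threshold = plan$age_threshold),
      warning = function(w) {
        logline(sprintf("  [%s] %s", nm, conditionMessage(w)))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        logline(sprintf("  [%s] %s", nm, trimws(conditionMessage(m))))
        invokeRestart("muffleMessage")
      })
    if (any(fit$frozen)) {
      logline(sprintf("  [%s] not estimable (no events): %s", nm,
                      paste(structure$trans[fit$frozen], collapse = ", ")))
    }
    hr <- do.call(rbind, lapply(intersect(def$exposures, covs), function(e) {
      hazard_ratio_table(fit, e, cohort = coh, conf_level = plan$conf_level,
                         include_death = plan$include_death)
    }))
    curves <- prevalence_curves(fit, coh)
    results[[nm]] <- list(name = nm, fit = fit, hr_table = hr,
                          curves = curves, n_subjects = fit$n_subjects)
  }

  bundle <- structure(list(results = results, plan = plan, log = logline()),
                      class = "analysis_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' @export
print.analysis_bundle <- function(x, ...) {
  cat("analysis_bundle:", length(x$results), "fitted model(s)\n")
  for (r in x$results) {
    cat(sprintf("  %-24s n=%-5d loglik=%.2f converged=%s\n", r$name,
                r$n_subjects, r$fit$loglik, r$fit$convergence$converged))
  }
  invisible(x)
}

#' Write an analysis bundle to disk
#'
#' Emits, per fitted model, `hr_<model>.csv` (hazard-ratio table),
#' `prevalence_<model>.csv` and `prevalence_<model>.pdf`, plus
#' `manifest.yaml` (per-model log-likelihood, convergence, parameter
#' counts) and `run.log`.
#'
#' @param bundle an `analysis_bundle`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  man <- list(models = list())
  for (r in bundle$results) {
    write.csv(r$hr_table, file.path(out_dir, paste0("hr_", r$name, ".csv")),
              row.names = FALSE)
    write.csv(r$curves, file.path(out_dir, paste0("prevalence_", r$name, ".csv")),
              row.names = FALSE)
    plot_prevalence(r$curves,
                    file.path(out_dir, paste0("prevalence_", r$name, ".pdf")))
    man$models[[r$name]] <- list(
      n_subjects = r$n_subjects,
      loglik = r$fit$loglik,
      converged = r$fit$convergence$converged,
      grad_norm = r$fit$convergence$grad_norm,
      n_parameters = length(r$fit$theta))
  }
  yaml::write_yaml(man, file.path(out_dir, "manifest.yaml"))
  writeLines(bundle$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Sensitivity analysis restricted to subjects with sufficient follow-up
#'
#' Refits the plan on the subset of subjects with at least `min_visits`
#' post-baseline observation times and tabulates the resulting hazard
#' ratios next to the full-data ones.
#'
#' @param cohort an [msm_cohort] or panel file path.
#' @param plan an [analysis_plan].
#' @param min_visits minimum number of post-baseline visits required.
#' @param full optional pre-computed full-data bundle (avoids refitting).
#' @param ... passed to [run_analysis()].
#' @return list with `bundle` (subset fit), `full` (full-data bundle) and
#'   `comparison` (data.frame of aHRs side by side with
#'   `log_hr_shift = log(aHR_subset) - log(aHR_full)`).
#' @export
sensitivity_min_followups <- function(cohort, plan = analysis_plan(),
                                      min_visits = 2, full = NULL, ...) {
  if (is.character(cohort)) cohort <- read_panel(cohort)
  nfol <- tapply(cohort$panel$t_years > 0, cohort$panel$subject_id, sum)
  keep <- names(nfol)[nfol >= min_visits]
  if (!length(keep)) stop("no subjects with at least ", min_visits,
                          " follow-up time points")
  sub <- if (min_visits > 0) subset_cohort(cohort, keep) else cohort
  if (is.null(full)) full <- run_analysis(cohort, plan, ...)
  bundle <- run_analysis(sub, plan, ...)
  comp <- list()
  for (nm in names(full$results)) {
    if (!nm %in% names(bundle$results)) next
    a <- full$results[[nm]]$hr_table
    b <- bundle$results[[nm]]$hr_table
    m <- merge(a[, c("transition", "covariate", "aHR", "se_log")],
               b[, c("transition", "covariate", "aHR", "se_log")],
               by = c("transition", "covariate"),
               suffixes = c("_full", "_subset"))
    m$model <- nm
    comp[[nm]] <- m
  }
  comp <- do.call(rbind, comp)
  rownames(comp) <- NULL
  comp$log_hr_shift <- log(comp$aHR_subset) - log(comp$aHR_full)
  list(bundle = bundle, full = full, comparison = comp)
}
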