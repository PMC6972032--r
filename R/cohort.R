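#' Construct a panel cohort
#'
#' A cohort holds long-format panel observations (one row per subject and
#' visit, living states only) together with exact death times.  Observation
#' times are years since the subject's own baseline; `age` is the subject's
#' age at the observation.  Time-dependent covariates take effect at the
#' visit where they are recorded and are carried forward to the next visit.
#'
#' @param panel data.frame with columns `subject_id`, `t_years`, `age`,
#'   `state`, plus one column per covariate.
#' @param deaths data.frame with columns `subject_id`, `death_time_years`
#'   (years since that subject's baseline); subjects absent from `deaths`
#'   (or with `NA`) are censored alive at their last visit.
#' @param alive_until optional data.frame with columns `subject_id`,
#'   `alive_until_years`: the registry vital-status ascertainment time for
#'   subjects known alive (years since baseline).  Subjects with a death
#'   record must not appear here.  When present, the likelihood adds the
#'   known-alive survival contribution over `(last visit, alive_until]`.
#' @param covariates character vector of covariate column names (default:
#'   all extra columns of `panel`).
#' @param monotone covariate names that may only develop, never resolve
#'   (validated); defaults to the intersection of
#'   `c("dm", "cvd", "hip_injury")` with `covariates`.
#' @param states state codes that may appear in `panel$state`.
#' @return object of class `msm_cohort`.
#' @export
msm_cohort <- function(panel, deaths = NULL, covariates = NULL,
                       alive_until = NULL, monotone = NULL,
                       states = c("A", "B", "C", "D")) {
  need <- c("subject_id", "t_years", "age", "state")
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop("panel missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(covariates)) covariates <- setdiff(names(panel), need)
  if (is.null(monotone)) monotone <- intersect(c("dm", "cvd", "hip_injury"), covariates)
  panel <- panel[order(panel$subject_id, panel$t_years), , drop = FALSE]
  rownames(panel) <- NULL
  panel$state <- as.character(panel$state)
  if (is.null(deaths)) {
    deaths <- data.frame(subject_id = character(0), death_time_years = numeric(0))
  }
  deaths <- deaths[!is.na(deaths$death_time_years), , drop = FALSE]
  if (is.null(alive_until)) {
    alive_until <- data.frame(subject_id = character(0),
                              alive_until_years = numeric(0))
  }
  alive_until <- alive_until[!is.na(alive_until$alive_until_years), ,
                             drop = FALSE]
  obj <- structure(list(panel = panel, deaths = deaths,
                        alive_until = alive_until,
                        covariates = covariates, monotone = monotone,
                        states = states),
                   class = "msm_cohort")
  validate_cohort(obj)
  obj
}

#' Validate a cohort against the panel-data contract
#'
#' Checks: observation times non-negative and strictly increasing within
#' subject; states among the living states; death strictly after the last
#' observation; no duplicated death record; monotone (develop-only)
#' covariates non-decreasing within subject.
#'
#' @param cohort an [msm_cohort].
#' @return the cohort, invisibly; errors describe the offending subjects.
#' @export
validate_cohort <- function(cohort) {
  p <- cohort$panel
  if (any(p$t_years < 0)) stop("negative observation time")
  bad <- !(p$state %in% cohort$states)
  if (any(bad)) {
    stop("invalid state value(s) '", paste(unique(p$state[bad]), collapse = "', '"),
         "' for subject(s) ", paste(unique(p$subject_id[bad]), collapse = ", "))
  }
  sp <- split(seq_len(nrow(p)), p$subject_id)
  for (rows in sp) {
    tt <- p$t_years[rows]
    if (any(diff(tt) <= 0)) {
      stop("observation times not strictly increasing for subject ",
           p$subject_id[rows[1]])
    }
    for (cv in cohort$monotone) {
      if (any(diff(p[[cv]][rows]) < 0)) {
        stop("monotone covariate '", cv, "' decreases for subject ",
             p$subject_id[rows[1]])
      }
    }
  }
  au <- cohort$alive_until
  if (!is.null(au) && nrow(au)) {
    if (any(au$subject_id %in% cohort$deaths$subject_id)) {
      stop("subject(s) recorded both dead and alive at ascertainment")
    }
    m <- match(as.character(au$subject_id), p$subject_id)
    if (anyNA(m)) stop("alive_until recorded for unknown subject")
  }
  d <- cohort$deaths
  if (anyDuplicated(d$subject_id)) stop("duplicated death record")
  if (nrow(d)) {
    last_t <- vapply(sp, function(r) max(p$t_years[r]), numeric(1))
    m <- match(as.character(d$subject_id), names(sp))
    if (anyNA(m)) stop("death recorded for unknown subject")
    late <- d$death_time_years <= last_t[m]
    if (any(late)) {
      stop("death time not after last observation for subject(s) ",
           paste(d$subject_id[late], collapse = ", "))
    }
  }
  invisible(cohort)
}

#' @export
print.msm_cohort <- function(x, ...) {
  cat("msm_cohort:", length(unique(x$panel$subject_id)), "subjects,",
      nrow(x$panel), "observations,", nrow(x$deaths), "deaths,",
      if (!is.null(x$alive_until)) nrow(x$alive_until) else 0L,
      "with vital-status follow-up\n")
  if (length(x$covariates)) {
    cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Extract one subject's history
#'
#' @param cohort an [msm_cohort].
#' @param id subject identifier.
#' @return list with elements `id`, `t` (observation times), `age0`
#'   (baseline age), `states`, `covariates` (data.frame, one row per
#'   observation), `death_time` (`NA` if alive/censored) and
#'   `alive_until` (vital-status ascertainment time, `NA` if none).
#' @export
subject_history <- function(cohort, id) {
  rows <- cohort$panel$subject_id == id
  if (!any(rows)) stop("unknown subject: ", id)
  p <- cohort$panel[rows, , drop = FALSE]
  dt <- cohort$deaths$death_time_years[match(id, cohort$deaths$subject_id)]
  au <- cohort$alive_until$alive_until_years[
    match(id, cohort$alive_until$subject_id)]
  list(id = id, t = p$t_years, age0 = p$age[1] - p$t_years[1],
       states = p$state,
       covariates = p[, cohort$covariates, drop = FALSE],
       death_time = if (length(dt) && !is.na(dt)) dt else NA_real_,
       alive_until = if (length(au) && !is.na(au)) au else NA_real_)
}

#' Write a cohort to a delimited panel file
#'
#' One CSV row per subject-visit with columns `subject_id`, `t_years`,
#' `age`, `state`, the covariate columns, and `death_time_years` (repeated
#' on each of the subject's rows; empty for subjects alive at last
#' contact).
#'
#' @param cohort an [msm_cohort].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(cohort, path) {
  p <- cohort$panel
  dt <- cohort$deaths$death_time_years[match(p$subject_id, cohort$deaths$subject_id)]
  au <- cohort$alive_until$alive_until_years[
    match(p$subject_id, cohort$alive_until$subject_id)]
  out <- cbind(p[, c("subject_id", "t_years", "age", "state")],
               p[, cohort$covariates, drop = FALSE],
               death_time_years = dt,
               alive_until_years = au)
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a delimited panel file
#'
#' Inverse of [write_panel()], with strict schema validation: missing
#' columns, non-numeric times, invalid states, inconsistent death times and
#' monotonicity violations are reported with the offending line numbers
#' where possible.
#'
#' @param path file path.
#' @param covariates covariate column names; default: every column other
#'   than the required schema columns.
#' @param ... passed to [msm_cohort()].
#' @return an [msm_cohort].
#' @export
read_panel <- function(path, covariates = NULL, ...) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "t_years", "age", "state", "death_time_years")
  optional <- "alive_until_years"
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("panel file ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  }
  for (col in c("t_years", "age")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & raw[[col]] != "")
    if (length(bad)) {
      stop("non-numeric '", col, "' at line(s) ",
           paste(head(bad + 1L, 5), collapse = ", "), " of ", path)
    }
    raw[[col]] <- v
  }
  if (is.null(covariates)) covariates <- setdiff(names(raw), c(need, optional))
  dt <- suppressWarnings(as.numeric(raw$death_time_years))
  per <- tapply(dt, raw$subject_id, function(x) {
    u <- unique(x[!is.na(x)])
    if (length(u) > 1L) return(NA_real_) else if (length(u)) u else NA_real_
  })
  incons <- tapply(dt, raw$subject_id, function(x) length(unique(x[!is.na(x)])) > 1L)
  if (any(incons)) {
    stop("inconsistent death_time_years within subject(s) ",
         paste(names(incons)[incons], collapse = ", "), " in ", path)
  }
  deaths <- data.frame(subject_id = names(per),
                       death_time_years = as.numeric(per))
  alive_until <- NULL
  if ("alive_until_years" %in% names(raw)) {
    covariates <- setdiff(covariates, "alive_until_years")
    auv <- suppressWarnings(as.numeric(raw$alive_until_years))
    pera <- tapply(auv, raw$subject_id, function(x) {
      u <- unique(x[!is.na(x)])
      if (length(u)) u[1] else NA_real_
    })
    alive_until <- data.frame(subject_id = names(pera),
                              alive_until_years = as.numeric(pera))
  }
  msm_cohort(raw[, c("subject_id", "t_years", "age", "state", covariates)],
             deaths = deaths, covariates = covariates,
             alive_until = alive_until, ...)
}
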