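#' Default covariate specification of the hip OA analysis
#'
#' Static adjusters: centered baseline age in decades (`age0_c`), `male`,
#' `black`, `educ_lt12` (< 12 years of education), `enrich` (enrichment
#' vs original cohort), mean-centered birth year in decades (`byear_c`).
#' Time-dependent: `obesity` (reversible), `dm` and `cvd` (develop-only),
#' `hip_injury` (absorbing once reported).  All reference levels are 0.
#'
#' @param structure an [msm_structure].
#' @param mask transition inclusion mask, as in [msm_covariates()].
#' @return an [msm_covariates].
#' @export
hip_covariates <- function(structure = hip_structure(), mask = "all") {
  msm_covariates(
    names = c("age0_c", "male", "black", "educ_lt12", "enrich", "byear_c",
              "obesity", "dm", "cvd", "hip_injury"),
    kind = c(rep("static", 6), rep("time-dependent", 4)),
    mask = mask, structure = structure)
}

#' Default generating truth for synthetic cohorts
#'
#' Baseline intensities (events/person-year, below age 65, reference
#' covariates) are calibrated so that roughly a quarter of subjects
#' starting free of disease and symptoms are observed to transition to a
#' living OA/symptom state over the full follow-up, under the default
#' visit schedule, dropout and mortality.  Planted comorbidity hazard
#' ratios use the individually-modeled point estimates of the motivating
#' cohort analysis for realism (e.g. obesity on A->C: 1.33).  The age-65
#' multipliers raise progression and mortality and slightly lower symptom
#' resolution after 65.
#'
#' @param structure an [msm_structure] (the five-state hip model).
#' @param covariates an [msm_covariates]; defaults to [hip_covariates()].
#' @return an [msm_parameters].
#' @export
hip_truth <- function(structure = hip_structure(),
                      covariates = hip_covariates(structure)) {
  q0 <- c("A->B" = 0.017, "A->C" = 0.034, "C->A" = 0.110, "C->D" = 0.028,
          "B->D" = 0.020, "D->B" = 0.100,
          "A->E" = 0.018, "B->E" = 0.022, "C->E" = 0.020, "D->E" = 0.034)
  q0 <- q0[structure$trans]
  hr <- matrix(1, structure$n_trans, covariates$K,
               dimnames = list(structure$trans, covariates$names))
  # tolerate reduced covariate sets / structures (recovery studies)
  set_hr <- function(hr, cov, vals) {
    if (!cov %in% colnames(hr)) return(hr)
    vals <- vals[names(vals) %in% rownames(hr)]
    hr[names(vals), cov] <- vals
    hr
  }
  hr <- set_hr(hr, "obesity", c("A->B" = 0.88, "C->D" = 1.46, "A->C" = 1.33,
                                "B->D" = 0.93, "C->A" = 0.88, "D->B" = 0.85))
  hr <- set_hr(hr, "dm", c("A->B" = 1.06, "C->D" = 1.49, "A->C" = 1.05,
                           "B->D" = 1.29, "C->A" = 0.74, "D->B" = 0.64))
  hr <- set_hr(hr, "cvd", c("A->B" = 1.34, "C->D" = 1.07, "A->C" = 1.25,
                            "B->D" = 1.08, "C->A" = 0.61, "D->B" = 0.74))
  hr <- set_hr(hr, "hip_injury", c("A->C" = 1.50, "B->D" = 1.50))
  hr <- set_hr(hr, "male", c("A->C" = 0.80, "B->D" = 0.80,
                             "A->E" = 1.40, "B->E" = 1.40, "C->E" = 1.40,
                             "D->E" = 1.40))
  # baseline age, per decade, on mortality
  hr <- set_hr(hr, "age0_c", c("A->E" = 1.80, "B->E" = 1.80, "C->E" = 1.80,
                               "D->E" = 1.80))
  beta <- log(hr)
  beta[!covariates$mask] <- 0
  prog <- structure$trans %in% c("A->B", "A->C", "C->D", "B->D")
  reso <- structure$trans %in% c("C->A", "D->B")
  dead <- structure$states[structure$to] %in% structure$absorbing
  gamma <- numeric(structure$n_trans)
  gamma[prog] <- log(1.3)
  gamma[reso] <- log(0.9)
  gamma[dead] <- log(1.8)
  msm_parameters(structure, covariates, log_q0 = log(q0), beta = beta,
                 gamma = gamma)
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the structure of a community-based hip OA cohort:
#' 3857 subjects, 33% African American, 39% men, baseline age
#' Normal(62.2, 9.8) truncated at 45, 37% with < 12 years education, 29%
#' enrichment-cohort members, baseline state mix A/B/C/D =
#' 0.45/0.19/0.25/0.11, baseline obesity 40% (per-visit onset 0.10,
#' remission 0.05), diabetes 14% (develop-only, per-visit onset 0.06,
#' reaching ~28% by the third follow-up), CVD 22% (develop-only, onset
#' 0.125, reaching ~48%), hip injury 6% (absorbing, onset 0.02), three
#' follow-up visits spaced Normal(6, 1.2) years (minimum 2), an
#' administrative horizon of 19 years, and per-visit dropout chosen to
#' approximate the observed attendance decline.
#'
#' @param n_subjects cohort size.
#' @param seed RNG seed used by [generate_cohort()].
#' @param truth generating [msm_parameters]; default [hip_truth()].
#' @param baseline_states named probabilities over living states.
#' @param p_black,p_male,p_educ_lt12,p_enrich demographic fractions.
#' @param age_mean,age_sd,age_min baseline age distribution (truncated
#'   normal).
#' @param p_obesity,p_dm,p_cvd,p_injury baseline comorbidity prevalences.
#' @param obesity_onset,obesity_remission,dm_onset,cvd_onset,injury_onset
#'   per-visit transition probabilities of the covariate processes.
#' @param n_followups,spacing_mean,spacing_sd,spacing_min visit schedule.
#' @param horizon administrative censoring horizon, years.
#' @param dropout per-follow-up-visit dropout probabilities (recycled).
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 3857, seed = 20200120,
                          truth = hip_truth(),
                          baseline_states = c(A = 0.45, B = 0.19,
                                              C = 0.25, D = 0.11),
                          p_black = 0.33, p_male = 0.39,
                          p_educ_lt12 = 0.37, p_enrich = 0.29,
                          age_mean = 62.2, age_sd = 9.8, age_min = 45,
                          p_obesity = 0.40, p_dm = 0.14, p_cvd = 0.22,
                          p_injury = 0.06,
                          obesity_onset = 0.10, obesity_remission = 0.05,
                          dm_onset = 0.06, cvd_onset = 0.125,
                          injury_onset = 0.02,
                          n_followups = 3, spacing_mean = 6.0,
                          spacing_sd = 1.2, spacing_min = 2,
                          horizon = 19,
                          dropout = c(0.22, 0.25, 0.45)) {
  stopifnot(abs(sum(baseline_states) - 1) < 1e-8,
            all(baseline_states >= 0),
            inherits(truth, "msm_parameters"))
  probs <- c(p_black, p_male, p_educ_lt12, p_enrich, p_obesity, p_dm, p_cvd,
             p_injury, obesity_onset, obesity_remission, dm_onset, cvd_onset,
             injury_onset, dropout)
  stopifnot(all(probs >= 0 & probs <= 1))
  structure(as.list(environment()), class = "cohort_config")
}

# truncated-normal draws by inverse CDF (deterministic under the R RNG)
rtnorm_min <- function(n, mean, sd, min) {
  p0 <- pnorm(min, mean, sd)
  qnorm(p0 + runif(n) * (1 - p0), mean, sd)
}

#' Simulate per-visit comorbidity paths
#'
#' Given baseline values, advances the covariate processes across visit
#' slots: diabetes, CVD and hip injury may only develop (non-decreasing
#' paths); obesity may both develop and resolve.
#'
#' @param baseline data.frame (or matrix) with columns `obesity`, `dm`,
#'   `cvd`, `hip_injury` of 0/1 baseline values.
#' @param n_visits number of follow-up slots to simulate.
#' @param config a [cohort_config] (per-visit onset/remission
#'   probabilities).
#' @return list of `n_visits + 1` data.frames, one per visit slot
#'   (baseline first).
#' @export
simulate_covariate_paths <- function(baseline, n_visits, config) {
  n <- nrow(baseline)
  out <- vector("list", n_visits + 1L)
  cur <- as.data.frame(baseline)
  out[[1L]] <- cur
  for (v in seq_len(n_visits)) {
    nxt <- cur
    nxt$obesity <- ifelse(cur$obesity == 1,
                          rbinom(n, 1, 1 - config$obesity_remission),
                          rbinom(n, 1, config$obesity_onset))
    nxt$dm <- pmax(cur$dm, rbinom(n, 1, config$dm_onset))
    nxt$cvd <- pmax(cur$cvd, rbinom(n, 1, config$cvd_onset))
    nxt$hip_injury <- pmax(cur$hip_injury, rbinom(n, 1, config$injury_onset))
    cur <- nxt
    out[[v + 1L]] <- cur
  }
  out
}

# vectorized generator rows: one ns*ns flattened Q per segment
build_seg_Q <- function(params, Z, aflag) {
  st <- params$structure
  ns <- st$n_states
  eta <- matrix(params$log_q0, nrow(Z), st$n_trans, byrow = TRUE)
  if (params$covariates$K > 0) eta <- eta + Z %*% t(params$beta)
  eta <- eta + outer(aflag, params$gamma)
  q <- exp(eta)
  Qf <- matrix(0, nrow(Z), ns * ns)
  for (t in seq_len(st$n_trans)) {
    i <- st$from[t]; j <- st$to[t]
    Qf[, (i - 1) * ns + j] <- Qf[, (i - 1) * ns + j] + q[, t]
    Qf[, (i - 1) * ns + i] <- Qf[, (i - 1) * ns + i] - q[, t]
  }
  Qf
}

#' Simulate one subject's panel history exactly
#'
#' Exact continuous-time simulation (competing exponential sojourns within
#' each constant-intensity segment); the state is recorded at each visit
#' time, death at its exact event time, and visits after death are
#' discarded.
#'
#' @param baseline_state state code at `t = 0`.
#' @param covariate_path data.frame, one row per visit slot (baseline
#'   first), holding the model covariates.
#' @param truth an [msm_parameters].
#' @param age0 baseline age in years.
#' @param visit_times follow-up visit times (years since baseline),
#'   strictly increasing.
#' @param horizon administrative censoring time for death ascertainment.
#' @return list with `t`, `states` (observed living states at attended
#'   times, `NA` once dead) and `death_time` (`NA` if alive at `horizon`).
#' @export
simulate_subject <- function(baseline_state, covariate_path, truth, age0,
                             visit_times, horizon = max(visit_times)) {
  st <- truth$structure
  tt <- c(0, visit_times)
  stopifnot(nrow(covariate_path) == length(tt), all(diff(tt) > 0))
  bounds <- sort(unique(c(tt, pmin(pmax(65 - age0, 0), horizon), horizon)))
  bounds <- bounds[bounds <= horizon + 1e-12]
  segs <- data.frame(t0 = bounds[-length(bounds)], t1 = bounds[-1])
  vis_idx <- findInterval(segs$t0 + 1e-9, tt)   # covariates in effect
  Z <- as.matrix(covariate_path[vis_idx, truth$covariates$names, drop = FALSE])
  aflag <- as.numeric(age0 + segs$t0 >= 65)
  Qf <- build_seg_Q(truth, Z, aflag)
  is_visit <- segs$t1 %in% tt[-1]
  sim <- cpp_sim_cohort(c(0L, nrow(segs)), segs$t1 - segs$t0, Qf,
                        as.integer(is_visit),
                        match(baseline_state, st$states) - 1L,
                        st$n_states, match(st$absorbing[1], st$states) - 1L)
  states <- st$states[sim$states[1, ] + 1L]
  list(t = segs$t1[is_visit], states = states,
       death_time = sim$death_time[1])
}

#' Generate a synthetic cohort with its truth manifest
#'
#' Draws demographics, baseline states, visit schedules, dropout and
#' comorbidity paths from `config`, simulates every subject's state
#' process exactly under `config$truth`, and assembles the long-format
#' panel consumed by the likelihood.  Covariates advance at the visits a
#' subject attends (so the carried-forward covariate model is exactly the
#' generating model); vital status is ascertained up to the administrative
#' horizon regardless of dropout: deaths carry their exact time and
#' surviving subjects a known-alive record at the horizon.  Output is deterministic given
#' `(config, config$seed)`.
#'
#' @param config a [cohort_config].
#' @param dir optional output directory; if given, writes `panel.csv`
#'   (via [write_panel()]), `truth.yaml` (the manifest) and a
#'   human-readable `summary.txt`.
#' @return an [msm_cohort] with attribute `"truth"` (the generating
#'   [msm_parameters]) and `"config"`.
#' @export
generate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  truth <- config$truth
  st <- truth$structure
  covn <- truth$covariates$names

  if (n == 0) {
    panel <- data.frame(subject_id = character(0), t_years = numeric(0),
                        age = numeric(0), state = character(0))
    for (cv in covn) panel[[cv]] <- numeric(0)
    coh <- structure(list(panel = panel,
                          deaths = data.frame(subject_id = character(0),
                                              death_time_years = numeric(0)),
                          alive_until = data.frame(
                            subject_id = character(0),
                            alive_until_years = numeric(0)),
                          covariates = covn,
                          monotone = intersect(c("dm", "cvd", "hip_injury"), covn),
                          states = setdiff(st$states, st$absorbing)),
                     class = "msm_cohort")
    attr(coh, "truth") <- truth; attr(coh, "config") <- config
    if (!is.null(dir)) write_cohort_dir(coh, dir)
    return(coh)
  }

  id <- sprintf("S%05d", seq_len(n))
  male <- rbinom(n, 1, config$p_male)
  black <- rbinom(n, 1, config$p_black)
  educ <- rbinom(n, 1, config$p_educ_lt12)
  enrich <- rbinom(n, 1, config$p_enrich)
  age0 <- rtnorm_min(n, config$age_mean, config$age_sd, config$age_min)
  enroll_year <- ifelse(enrich == 1, 2003 + runif(n),
                        1991 + 6 * runif(n))
  byear <- enroll_year - age0
  demo <- data.frame(age0_c = (age0 - config$age_mean) / 10, male = male,
                     black = black, educ_lt12 = educ, enrich = enrich,
                     byear_c = 0)
  demo$byear_c <- (byear - mean(byear)) / 10

  s0 <- sample(names(config$baseline_states), n, replace = TRUE,
               prob = config$baseline_states)

  nf <- config$n_followups
  spac <- matrix(pmax(rnorm(n * nf, config$spacing_mean, config$spacing_sd),
                      config$spacing_min), n, nf)
  vt <- t(apply(spac, 1, cumsum))
  if (nf == 1) vt <- matrix(vt, n, 1)
  vt[vt > config$horizon] <- NA   # beyond administrative horizon

  drop_p <- rep_len(config$dropout, nf)
  dropu <- matrix(runif(n * nf), n, nf)
  attends <- matrix(FALSE, n, nf)
  alive_sched <- rep(TRUE, n)
  for (v in seq_len(nf)) {
    stay <- dropu[, v] >= drop_p[v]
    alive_sched <- alive_sched & stay
    attends[, v] <- alive_sched & !is.na(vt[, v])
  }

  base_cov <- data.frame(
    obesity = rbinom(n, 1, config$p_obesity),
    dm = rbinom(n, 1, config$p_dm),
    cvd = rbinom(n, 1, config$p_cvd),
    hip_injury = rbinom(n, 1, config$p_injury))
  paths <- simulate_covariate_paths(base_cov, nf, config)

  # per-subject piecewise-constant segments: breaks at attended visits,
  # the age-65 crossing, and the horizon; covariates advance at attended
  # visits only (the carried-forward model is the generating model)
  seg_dur <- list(); seg_visit <- list(); seg_slot <- list()
  seg_aflag <- list(); seg_off <- integer(n + 1L)
  td_names <- c("obesity", "dm", "cvd", "hip_injury")
  for (i in seq_len(n)) {
    avis <- which(attends[i, ])
    tvis <- vt[i, avis]
    t65 <- 65 - age0[i]
    bounds <- sort(unique(c(0, tvis,
                            if (t65 > 0 && t65 < config$horizon) t65,
                            config$horizon)))
    t0s <- bounds[-length(bounds)]; t1s <- bounds[-1]
    # covariate path slot in effect on each segment: the last attended
    # visit at or before the segment start (baseline slot = 0)
    k <- vapply(t0s, function(x) sum(tvis <= x + 1e-9), integer(1))
    seg_slot[[i]] <- ifelse(k == 0L, 0L, avis[pmax(k, 1L)])
    seg_dur[[i]] <- t1s - t0s
    seg_visit[[i]] <- as.integer(!is.na(match(round(t1s, 9), round(tvis, 9))))
    seg_aflag[[i]] <- as.numeric(age0[i] + t0s >= 65)
    seg_off[i + 1L] <- seg_off[i] + length(t0s)
  }
  seg_subj <- rep.int(seq_len(n), diff(seg_off))
  slot_vec <- unlist(seg_slot)
  # covariate matrix per segment: demographics + time-dependent slot values
  td_arr <- array(unlist(lapply(paths, function(p) as.matrix(p[, td_names]))),
                  dim = c(n, length(td_names), nf + 1L))
  Ztd <- matrix(0, length(seg_subj), length(td_names),
                dimnames = list(NULL, td_names))
  for (j in seq_along(td_names)) {
    Ztd[, j] <- td_arr[cbind(seg_subj, j, slot_vec + 1L)]
  }
  Zst <- as.matrix(demo[seg_subj, , drop = FALSE])
  Z <- cbind(Zst, Ztd)[, covn, drop = FALSE]

  sim <- cpp_sim_cohort(seg_off, unlist(seg_dur),
                        build_seg_Q(truth, Z, unlist(seg_aflag)),
                        unlist(seg_visit),
                        match(s0, st$states) - 1L, st$n_states,
                        match(st$absorbing[1], st$states) - 1L)

  # assemble long-format panel (flat vectors; one row per attended visit
  # while alive)
  nvis <- rowSums(attends)
  ot <- os <- ost <- vector("list", n)
  death_id <- character(0); death_t <- numeric(0)
  for (i in seq_len(n)) {
    nv <- nvis[i]
    obs_t <- c(0, if (nv) vt[i, seq_len(nv)] else numeric(0))
    obs_slot <- 0:nv
    stv <- c(match(s0[i], st$states) - 1L,
             if (nv) sim$states[i, seq_len(nv)] else integer(0))
    keep <- !is.na(stv)
    ot[[i]] <- obs_t[keep]; os[[i]] <- obs_slot[keep]; ost[[i]] <- stv[keep]
    if (!is.na(sim$death_time[i])) {
      death_id <- c(death_id, id[i]); death_t <- c(death_t, sim$death_time[i])
    }
  }
  nrows <- lengths(ot)
  ridx <- rep.int(seq_len(n), nrows)
  t_years <- unlist(ot); slot_r <- unlist(os); st_r <- unlist(ost)
  tdm <- matrix(0, length(ridx), length(td_names),
                dimnames = list(NULL, td_names))
  for (j in seq_along(td_names)) {
    tdm[, j] <- td_arr[cbind(ridx, j, slot_r + 1L)]
  }
  panel <- data.frame(subject_id = id[ridx], t_years = t_years,
                      age = age0[ridx] + t_years,
                      state = st$states[st_r + 1L],
                      demo[ridx, , drop = FALSE], tdm, row.names = NULL)
  deaths <- data.frame(subject_id = death_id, death_time_years = death_t)
  # vital status is ascertained to the administrative horizon for everyone
  alive_ids <- setdiff(id, death_id)
  alive_until <- data.frame(subject_id = alive_ids,
                            alive_until_years = rep(config$horizon,
                                                    length(alive_ids)))
  coh <- msm_cohort(panel[, c("subject_id", "t_years", "age", "state", covn)],
                    deaths, covariates = covn, alive_until = alive_until)
  attr(coh, "truth") <- truth
  attr(coh, "config") <- config
  if (!is.null(dir)) write_cohort_dir(coh, dir)
  coh
}

# write panel + truth manifest + summary into a directory
write_cohort_dir <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_panel(cohort, file.path(dir, "panel.csv"))
  write_truth_manifest(attr(cohort, "config"), file.path(dir, "truth.yaml"))
  p <- cohort$panel
  con <- file(file.path(dir, "summary.txt"), "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("subjects: %d", length(unique(p$subject_id))),
    sprintf("observations: %d", nrow(p)),
    sprintf("deaths: %d", nrow(cohort$deaths)),
    sprintf("baseline states: %s",
            paste(capture_counts(p$state[p$t_years == 0]), collapse = ", ")),
    sprintf("mean baseline age: %.1f", mean(p$age[p$t_years == 0]))),
    con)
  invisible(dir)
}

capture_counts <- function(x) {
  tb <- table(x)
  paste0(names(tb), "=", as.integer(tb))
}

#' Write / read the truth manifest of a synthetic cohort
#'
#' The manifest serializes the full generator configuration, including the
#' exact generating parameters, so that the cohort can be regenerated
#' bit-identically from `(config, seed)`.
#'
#' @param config a [cohort_config].
#' @param path YAML file path.
#' @return `path` (write) or a [cohort_config] (read).
#' @export
write_truth_manifest <- function(config, path) {
  tr <- config$truth
  obj <- config[setdiff(names(config), c("truth", "probs"))]
  obj <- lapply(obj, function(x) if (is.numeric(x)) unname(x) else x)
  obj$baseline_states <- as.list(config$baseline_states)
  obj$truth <- list(
    states = tr$structure$states,
    absorbing = tr$structure$absorbing,
    transitions = tr$structure$trans,
    covariates = tr$covariates$names,
    covariate_kind = unname(tr$covariates$kind),
    mask = apply(tr$covariates$mask, 1, as.logical, simplify = FALSE),
    log_q0 = unname(tr$log_q0),
    beta = apply(tr$beta, 1, as.numeric, simplify = FALSE),
    gamma = unname(tr$gamma))
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_truth_manifest
#' @export
read_truth_manifest <- function(path) {
  obj <- yaml::read_yaml(path)
  tr <- obj$truth
  st <- msm_structure(tr$states, unlist(tr$transitions), tr$absorbing)
  K <- length(tr$covariates)
  mask <- if (K) t(vapply(tr$mask, as.logical, logical(K)))
          else matrix(logical(), st$n_trans, 0)
  cv <- msm_covariates(unlist(tr$covariates), kind = unlist(tr$covariate_kind),
                       mask = mask, structure = st)
  beta <- if (K) t(vapply(tr$beta, as.numeric, numeric(K)))
          else matrix(0, st$n_trans, 0)
  truth <- msm_parameters(st, cv, log_q0 = unlist(tr$log_q0), beta = beta,
                          gamma = unlist(tr$gamma))
  args <- obj[setdiff(names(obj), "truth")]
  args$baseline_states <- unlist(args$baseline_states)
  args$dropout <- unlist(args$dropout)
  do.call(cohort_config, c(args, list(truth = truth)))
}
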