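test_that("comorbidity paths respect their monotonicity contracts", {
  set.seed(70)
  cfg <- cohort_config(n_subjects = 500, seed = 1)
  base <- data.frame(obesity = rbinom(500, 1, 0.4), dm = rbinom(500, 1, 0.14),
                     cvd = rbinom(500, 1, 0.22),
                     hip_injury = rbinom(500, 1, 0.06))
  paths <- simulate_covariate_paths(base, 3, cfg)
  dm <- sapply(paths, `[[`, "dm")
  cvd <- sapply(paths, `[[`, "cvd")
  inj <- sapply(paths, `[[`, "hip_injury")
  expect_true(all(t(apply(dm, 1, diff)) >= 0))
  expect_true(all(t(apply(cvd, 1, diff)) >= 0))
  expect_true(all(t(apply(inj, 1, diff)) >= 0))
  ob <- sapply(paths, `[[`, "obesity")
  expect_true(any(apply(ob, 1, diff) < 0))  # remission occurs

  # zero onset freezes diabetes; zero remission makes obesity monotone
  cfg0 <- cohort_config(n_subjects = 500, dm_onset = 0, obesity_remission = 0)
  paths0 <- simulate_covariate_paths(base, 3, cfg0)
  expect_identical(sapply(paths0, `[[`, "dm")[, 4], base$dm)
  expect_true(all(t(apply(sapply(paths0, `[[`, "obesity"), 1, diff)) >= 0))
})

test_that("comorbidity prevalence drifts as configured", {
  set.seed(71)
  n <- 10000
  cfg <- cohort_config(n_subjects = n)
  base <- data.frame(obesity = rbinom(n, 1, cfg$p_obesity),
                     dm = rbinom(n, 1, cfg$p_dm),
                     cvd = rbinom(n, 1, cfg$p_cvd),
                     hip_injury = rbinom(n, 1, cfg$p_injury))
  paths <- simulate_covariate_paths(base, 3, cfg)
  # analytic expectation from the configured per-visit incidences:
  # monotone processes converge to 1 - (1-p0)(1-i)^3; the targets mirror
  # the motivating cohort's doubling (DM 14 -> 28%, CVD 22 -> 48%)
  p_dm <- 1 - (1 - cfg$p_dm) * (1 - cfg$dm_onset)^3
  p_cvd <- 1 - (1 - cfg$p_cvd) * (1 - cfg$cvd_onset)^3
  se <- function(p) sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(paths[[4]]$dm) - p_dm), 3 * se(p_dm))
  expect_lt(abs(mean(paths[[4]]$cvd) - p_cvd), 3 * se(p_cvd))
  expect_gt(p_dm, 1.9 * cfg$p_dm)   # doubling by the third follow-up
  expect_lt(p_dm, 2.2 * cfg$p_dm)
})

test_that("zero intensities freeze subjects in their baseline state", {
  st <- hip_structure()
  cv <- msm_covariates(character(), structure = st)
  frozen <- msm_parameters(st, cv, log_q0 = -800)
  sim <- simulate_subject("C", data.frame()[rep(1, 4), , drop = FALSE],
                          frozen, age0 = 60, visit_times = c(5, 11, 17),
                          horizon = 19)
  expect_identical(sim$states, c("C", "C", "C"))
  expect_true(is.na(sim$death_time))
})

test_that("exponential survival fractions match the closed form", {
  set.seed(72)
  st2 <- surv_structure()
  p2 <- msm_parameters(st2, msm_covariates(character(), structure = st2),
                       log_q0 = log(0.1))
  n <- 2e4
  sim <- hipmsm:::cpp_sim_chain_mc(10, matrix(as.numeric(t(matrix(c(-0.1, 0.1, 0, 0),
                                                                  2, 2, byrow = TRUE))),
                                              1), 0L, n, 2L, 1L)
  frac_dead <- mean(sim$final_state == 1L)
  p_true <- 1 - exp(-1)
  expect_lt(abs(frac_dead - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
})

test_that("simulated panel pair frequencies converge to matrix exponentials", {
  # the central simulator-engine consistency check, at reduced scale
  set.seed(73)
  truth <- hip_truth()
  cv <- truth$covariates
  z <- setNames(rep(0, cv$K), cv$names)
  Qy <- intensity_matrix(truth, z, FALSE)
  n <- 1e5
  sim <- hipmsm:::cpp_sim_chain_mc(6, matrix(as.numeric(t(Qy)), 1), 0L, n,
                                   5L, 4L)
  P <- transition_probability(Qy, 6)
  freq <- tabulate(sim$final_state + 1L, 5) / n
  for (s in 1:5) {
    se <- sqrt(max(P[1, s] * (1 - P[1, s]), 1e-12) / n)
    expect_lt(abs(freq[s] - P[1, s]), 3 * se + 1e-4)
  }
})

test_that("cohort generation is deterministic and byte-identical per seed", {
  cfg <- cohort_config(n_subjects = 60, seed = 99)
  d1 <- tempfile(); d2 <- tempfile()
  c1 <- suppressWarnings(generate_cohort(cfg, dir = d1))
  c2 <- suppressWarnings(generate_cohort(cfg, dir = d2))
  expect_identical(readBin(file.path(d1, "panel.csv"), "raw", 1e6),
                   readBin(file.path(d2, "panel.csv"), "raw", 1e6))
  expect_identical(c1$panel, c2$panel)
  # different seed differs
  c3 <- suppressWarnings(generate_cohort(cohort_config(n_subjects = 60,
                                                       seed = 100)))
  expect_false(identical(c1$panel, c3$panel))
  # truth manifest round-trips into an equivalent configuration
  cfg2 <- read_truth_manifest(file.path(d1, "truth.yaml"))
  c4 <- suppressWarnings(generate_cohort(cfg2))
  expect_identical(c1$panel, c4$panel)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("an empty cohort still writes a valid panel file", {
  cfg <- cohort_config(n_subjects = 0)
  d <- tempfile()
  coh <- suppressWarnings(generate_cohort(cfg, dir = d))
  expect_identical(nrow(coh$panel), 0L)
  back <- read_panel(file.path(d, "panel.csv"))
  expect_identical(nrow(back$panel), 0L)
  unlink(d, recursive = TRUE)
})

test_that("baseline draws match the configured demographic mix", {
  coh <- suppressWarnings(generate_cohort(cohort_config(n_subjects = 3857,
                                                        seed = 2020)))
  base <- coh$panel[coh$panel$t_years == 0, ]
  n <- nrow(base)
  expect_identical(n, 3857L)
  probs <- c(A = 0.45, B = 0.19, C = 0.25, D = 0.11)
  cnt <- table(factor(base$state, levels = names(probs)))
  for (s in names(probs)) {
    se <- sqrt(probs[[s]] * (1 - probs[[s]]) * n)
    expect_lt(abs(cnt[[s]] - n * probs[[s]]), 3 * se)
  }
  expect_lt(abs(mean(base$male) - 0.39), 3 * sqrt(0.39 * 0.61 / n))
  expect_lt(abs(mean(base$black) - 0.33), 3 * sqrt(0.33 * 0.67 / n))
  expect_gt(min(base$age), 45)   # truncation bound

  # no observations after death; monotone covariates never reverse
  expect_silent(validate_cohort(coh))
  last_t <- tapply(coh$panel$t_years, coh$panel$subject_id, max)
  dd <- coh$deaths
  expect_true(all(dd$death_time_years >
                    last_t[as.character(dd$subject_id)]))
})
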