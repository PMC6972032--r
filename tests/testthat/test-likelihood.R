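test_that("interval segmentation carries covariates forward and splits at 65", {
  h <- history1(age0 = 63, tt = c(0, 6), states = c("A", "A"),
                covs = data.frame(obesity = c(0, 1), dm = c(0, 0)))
  seg <- segment_interval(h, 0, 6)
  expect_equal(seg$duration, c(2, 4))
  expect_equal(seg$age_ge_65, c(FALSE, TRUE))
  expect_equal(sum(seg$duration), 6, tolerance = 1e-12)
  # covariates are those recorded at the interval start
  expect_equal(unname(attr(seg, "z")["obesity"]), 0)

  # already past the threshold: a single old-age segment
  seg70 <- segment_interval(history1(age0 = 70, tt = c(0, 6),
                                     states = c("A", "A"),
                                     covs = data.frame(obesity = c(0, 0),
                                                       dm = c(0, 0))), 0, 6)
  expect_equal(nrow(seg70), 1L)
  expect_true(seg70$age_ge_65)

  # turning 65 exactly at the interval end: half-open convention
  seg_edge <- segment_interval(history1(age0 = 59, tt = c(0, 6),
                                        states = c("A", "A"),
                                        covs = data.frame(obesity = c(0, 0),
                                                          dm = c(0, 0))), 0, 6)
  expect_equal(nrow(seg_edge), 1L)
  expect_false(seg_edge$age_ge_65)
  expect_error(segment_interval(h, 6, 6), "exceed")
})

test_that("interval log-likelihood equals the matrix-exponential entry", {
  set.seed(50)
  par <- rand_params(tiny_covariates())
  h <- history1(age0 = 61, tt = c(0, 6), states = c("A", "C"),
                covs = data.frame(obesity = c(1, 1), dm = c(0, 1)))
  ll <- interval_loglik(par, h, 0, "A", 6, "C")
  seg <- segment_interval(h, 0, 6)
  P <- path_probability(hipmsm:::segments_to_Q(par, seg))
  expect_equal(ll, log(P["A", "C"]))

  # staying probability in the two-state survival model: log P = -q t
  st2 <- surv_structure()
  p2 <- msm_parameters(st2, log_q0 = log(0.5))
  h2 <- history1(age0 = 50, tt = c(0, 2), states = c("A", "A"),
                 covs = data.frame(x = c(0, 0))[, 0, drop = FALSE])
  expect_equal(interval_loglik(p2, h2, 0, "A", 2, "A"), -1)

  # structurally impossible pair: B cannot reach A among living states
  llB <- interval_loglik(par, history1(age0 = 50, tt = c(0, 4),
                                       states = c("B", "A"),
                                       covs = h$covariates), 0, "B", 4, "A")
  expect_identical(as.numeric(llB), -Inf)
  expect_true(attr(llB, "impossible"))
})

test_that("exact-death contribution is survival times death intensity", {
  # only A->E allowed, q = 0.3: density at t = 2 is exp(-0.6) * 0.3
  st2 <- surv_structure()
  p2 <- msm_parameters(st2, log_q0 = log(0.3))
  h2 <- history1(age0 = 50, tt = 0, states = "A",
                 covs = data.frame(x = 0)[, 0, drop = FALSE], death_time = 2)
  expect_equal(death_loglik(p2, h2, 0, "A", 2), log(exp(-0.6) * 0.3))
  expect_error(death_loglik(p2, h2, 0, "A", 0), "exceed")

  # all death intensities effectively zero -> impossible flag
  p0 <- msm_parameters(hip_structure(), log_q0 = c(rep(log(0.1), 6), rep(-800, 4)))
  h5 <- history1(age0 = 55, tt = 0, states = "A",
                 covs = data.frame(x = 0)[, 0, drop = FALSE], death_time = 3)
  dl <- death_loglik(p0, h5, 0, "A", 3)
  expect_identical(as.numeric(dl), -Inf)
})

test_that("total log-likelihood is additive and order-invariant", {
  set.seed(51)
  par <- rand_params(tiny_covariates())
  coh <- tiny_cohort()
  ll <- total_loglik(par, coh)
  # doubling the cohort doubles the log-likelihood
  p2 <- coh$panel
  p2$subject_id <- paste0(p2$subject_id, "bis")
  d2 <- coh$deaths
  d2$subject_id <- paste0(d2$subject_id, "bis")
  dup <- msm_cohort(rbind(coh$panel, p2), rbind(coh$deaths, d2),
                    covariates = coh$covariates)
  expect_equal(total_loglik(par, dup), 2 * ll, tolerance = 1e-9)
  # order of subjects is irrelevant
  shuf <- msm_cohort(coh$panel[rev(seq_len(nrow(coh$panel))), ],
                     coh$deaths, covariates = coh$covariates)
  expect_equal(total_loglik(par, shuf), ll, tolerance = 1e-10)
  # empty cohort contributes nothing
  empty <- suppressWarnings(generate_cohort(cohort_config(n_subjects = 0)))
  expect_identical(total_loglik(hip_truth(), empty), 0)
})

test_that("fast likelihood equals an independent matrix-exponential route", {
  # 50-subject cohort; the reference path shares no matrix code with the
  # uniformization core
  cv <- msm_covariates(c("obesity", "dm"), structure = hip_structure())
  truth <- hip_truth(hip_structure(), cv)
  coh <- suppressWarnings(generate_cohort(
    cohort_config(n_subjects = 50, seed = 77, truth = truth)))
  set.seed(52)
  for (i in 1:3) {
    par <- rand_params(cv)
    expect_equal(total_loglik(par, coh),
                 total_loglik(par, coh, method = "reference"),
                 tolerance = 1e-9)
  }
})

test_that("interval probabilities and death add up to total probability one", {
  set.seed(53)
  par <- rand_params(tiny_covariates())
  h <- history1(age0 = 62, tt = c(0, 6), states = c("C", "C"),
                covs = data.frame(obesity = c(1, 1), dm = c(0, 0)))
  seg <- segment_interval(h, 0, 6)
  P <- path_probability(hipmsm:::segments_to_Q(par, seg))
  probs <- vapply(c("A", "B", "C", "D"), function(s1)
    exp(interval_loglik(par, h, 0, "C", 6, s1)), numeric(1))
  expect_equal(sum(probs) + P["C", "E"], 1, tolerance = 1e-8)
})

test_that("the Markov property factorizes multi-visit likelihoods", {
  set.seed(54)
  par <- rand_params(tiny_covariates())
  covs <- data.frame(obesity = c(1, 0, 1), dm = c(0, 0, 1))
  h <- history1(age0 = 58, tt = c(0, 5, 11), states = c("A", "C", "D"),
                covs = covs)
  panel <- data.frame(subject_id = "m1", t_years = h$t, age = 58 + h$t,
                      state = h$states, covs)
  coh <- msm_cohort(panel, covariates = c("obesity", "dm"))
  expect_equal(total_loglik(par, coh),
               interval_loglik(par, h, 0, "A", 5, "C") +
                 interval_loglik(par, h, 5, "C", 11, "D"),
               tolerance = 1e-10)
})

test_that("covariates recorded at the interval end do not affect it", {
  set.seed(55)
  par <- rand_params(tiny_covariates())
  covs1 <- data.frame(obesity = c(1, 0), dm = c(0, 0))
  covs2 <- data.frame(obesity = c(1, 1), dm = c(0, 1))  # perturbed at t1
  h1 <- history1(age0 = 60, tt = c(0, 6), states = c("A", "C"), covs = covs1)
  h2 <- history1(age0 = 60, tt = c(0, 6), states = c("A", "C"), covs = covs2)
  expect_identical(interval_loglik(par, h1, 0, "A", 6, "C"),
                   interval_loglik(par, h2, 0, "A", 6, "C"))
})

test_that("monotone covariate violations and schema errors are rejected", {
  panel <- data.frame(subject_id = "v1", t_years = c(0, 6), age = c(60, 66),
                      state = c("A", "A"), obesity = c(0, 1), dm = c(1, 0))
  expect_error(msm_cohort(panel, covariates = c("obesity", "dm")),
               "monotone covariate 'dm'")
  panel$dm <- c(0, 1)
  expect_silent(msm_cohort(panel, covariates = c("obesity", "dm")))
  # death before last observation
  expect_error(msm_cohort(panel, data.frame(subject_id = "v1",
                                            death_time_years = 3),
                          covariates = c("obesity", "dm")),
               "death time")
  # invalid state
  panel2 <- panel
  panel2$state[2] <- "E"
  expect_error(msm_cohort(panel2, covariates = c("obesity", "dm")),
               "invalid state")
})

test_that("panel files round-trip with validation", {
  coh <- tiny_cohort()
  tf <- tempfile(fileext = ".csv")
  write_panel(coh, tf)
  back <- read_panel(tf)
  expect_equal(back$panel$state, coh$panel$state)
  expect_equal(back$panel$t_years, coh$panel$t_years, tolerance = 1e-12)
  expect_equal(sort(back$deaths$subject_id), sort(coh$deaths$subject_id))
  # schema violations carry line numbers / column names
  raw <- read.csv(tf)
  raw$t_years[3] <- "not-a-number"
  tf2 <- tempfile(fileext = ".csv")
  write.csv(raw, tf2, row.names = FALSE)
  expect_error(read_panel(tf2), "line")
  raw2 <- read.csv(tf)[, -3]
  write.csv(raw2, tf2, row.names = FALSE)
  expect_error(read_panel(tf2), "missing column")
  unlink(c(tf, tf2))
})

test_that("panel pair probabilities match large-scale chain simulation", {
  # Monte-Carlo oracle at reduced scale (the acceptance suite runs the
  # full 10^6-chain version): pair (A, D) over 6 years crosses the age-65
  # changepoint and requires two jumps
  set.seed(56)
  par <- rand_params(tiny_covariates(), lo = 0.03, hi = 0.25)
  h <- history1(age0 = 62, tt = c(0, 6), states = c("A", "D"),
                covs = data.frame(obesity = c(1, 1), dm = c(0, 0)))
  z <- c(obesity = 1, dm = 0)
  Qy <- intensity_matrix(par, z, FALSE)
  Qo <- intensity_matrix(par, z, TRUE)
  nrep <- 2e5
  sim <- hipmsm:::cpp_sim_chain_mc(c(3, 3), rbind(as.numeric(t(Qy)),
                                                  as.numeric(t(Qo))),
                                   0L, nrep, 5L, 4L)
  p_hat <- mean(sim$final_state == 3L)
  p_mod <- exp(interval_loglik(par, h, 0, "A", 6, "D"))
  se <- sqrt(p_mod * (1 - p_mod) / nrep)
  expect_lt(abs(p_hat - p_mod), 3 * se + 1e-12)
})

test_that("interval-censored death reduces to a panel pair into death", {
  set.seed(57)
  par <- rand_params(tiny_covariates())
  coh <- tiny_cohort()
  ll_int <- total_loglik(par, coh, death_exact = FALSE)
  ll_ref <- total_loglik(par, coh, method = "reference", death_exact = FALSE)
  expect_equal(ll_int, ll_ref, tolerance = 1e-9)
  # discarding the exact timing changes (and here lowers the magnitude
  # of information in) the contribution: the two likelihoods differ
  expect_false(isTRUE(all.equal(ll_int, total_loglik(par, coh))))
  # and the interval form is the log of the P[s, E] entry
  h <- subject_history(coh, "s2")
  seg <- segment_interval(h, h$t[2], h$death_time)
  P <- path_probability(hipmsm:::segments_to_Q(par, seg))
  manual <- interval_loglik(par, h, 0, "B", h$t[2], "B") + log(P["B", "E"])
  h_only <- msm_cohort(coh$panel[coh$panel$subject_id == "s2", ],
                       coh$deaths[coh$deaths$subject_id == "s2", ],
                       covariates = coh$covariates)
  expect_equal(total_loglik(par, h_only, death_exact = FALSE), manual,
               tolerance = 1e-9)
})
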