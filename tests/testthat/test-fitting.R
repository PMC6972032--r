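test_that("crude initial rates are pair counts over person-time", {
  st <- hip_structure()
  # one subject observed A at 0 and B at 4: q_AB = 1/4, others floored
  p1 <- data.frame(subject_id = "c1", t_years = c(0, 4), age = c(50, 54),
                   state = c("A", "B"))
  init <- crude_initial_values(suppressMessages(msm_cohort(p1)), st)
  expect_equal(unname(exp(init$log_q0["A->B"])), 0.25)
  expect_equal(unname(exp(init$log_q0[st$trans != "A->B"])), rep(1e-3, 9))

  # three-subject fixture with hand-computed person-time, incl. a death
  p3 <- data.frame(
    subject_id = rep(c("c1", "c2", "c3"), times = c(3, 2, 2)),
    t_years = c(0, 4, 10, 0, 5, 0, 6),
    age = 50 + c(0, 4, 10, 0, 5, 0, 6),
    state = c("A", "B", "B", "A", "C", "C", "C"))
  d3 <- data.frame(subject_id = "c3", death_time_years = 8)
  init3 <- crude_initial_values(suppressMessages(msm_cohort(p3, d3)), st)
  # A time: 4 (c1) + 5 (c2) = 9; pairs A->B: 1, A->C: 1
  expect_equal(unname(exp(init3$log_q0["A->B"])), 1 / 9)
  expect_equal(unname(exp(init3$log_q0["A->C"])), 1 / 9)
  # C time: 6 (c3 interval) + 2 (to death) = 8; C->E: 1
  expect_equal(unname(exp(init3$log_q0["C->E"])), 1 / 8)
  # B time: 6 (c1 second interval), no B-> pairs: floored
  expect_equal(unname(exp(init3$log_q0["B->D"])), 1e-3)
  expect_error(crude_initial_values(
    suppressWarnings(generate_cohort(cohort_config(n_subjects = 0))), st),
    "empty")
})

test_that("the analytic gradient matches central finite differences", {
  set.seed(60)
  cv <- tiny_covariates()
  coh <- suppressWarnings(generate_cohort(
    cohort_config(n_subjects = 80, seed = 3,
                  truth = hip_truth(hip_structure(), cv))))
  par <- rand_params(cv)
  layout <- hipmsm:::param_layout(hip_structure(), cv, changepoint = TRUE)
  pk <- hipmsm:::pack_parameters(par, layout)
  dat <- suppressWarnings(hipmsm:::build_likelihood_data(coh, cv, hip_structure()))
  cl <- hipmsm:::layout_for_cpp(pk$layout)
  got <- hipmsm:::cpp_panel_loglik(pk$theta, cl, dat$iv, dat$de, dat$sv, TRUE)
  h <- 1e-6
  fd <- vapply(seq_along(pk$theta), function(i) {
    tp <- pk$theta; tp[i] <- tp[i] + h
    tm <- pk$theta; tm[i] <- tm[i] - h
    (hipmsm:::cpp_panel_loglik(tp, cl, dat$iv, dat$de, dat$sv, FALSE)$loglik -
       hipmsm:::cpp_panel_loglik(tm, cl, dat$iv, dat$de, dat$sv, FALSE)$loglik) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(got$grad - fd) / pmax(abs(fd), 1)), 1e-3)
})

test_that("refitting data at the fitted parameters cannot beat the MLE", {
  set.seed(61)
  cv <- msm_covariates("obesity", mask = "living", structure = hip_structure())
  truth <- hip_truth(hip_structure(), cv)
  coh <- suppressWarnings(generate_cohort(
    cohort_config(n_subjects = 300, seed = 8, truth = truth)))
  fit <- suppressWarnings(fit_msm(coh, covariates = cv))
  expect_true(fit$convergence$converged)
  expect_lt(fit$convergence$grad_norm, 1e-5)
  # likelihood at the MLE beats the generating truth on this sample
  expect_gte(fit$loglik, total_loglik(truth, coh) - 1e-9)
  # observed information is symmetric positive definite at the optimum
  expect_equal(fit$information, t(fit$information))
  ev <- eigen(fit$information, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  # deterministic refit: identical estimates
  fit2 <- suppressWarnings(fit_msm(coh, covariates = cv))
  expect_identical(fit$theta, fit2$theta)
})

test_that("rescaling a covariate halves its coefficient, not the fit", {
  set.seed(62)
  cv <- msm_covariates("obesity", mask = "living", structure = hip_structure())
  truth <- hip_truth(hip_structure(), cv)
  coh <- suppressWarnings(generate_cohort(
    cohort_config(n_subjects = 250, seed = 12, truth = truth)))
  fit1 <- suppressWarnings(fit_msm(coh, covariates = cv, changepoint = FALSE))
  coh2 <- coh
  coh2$panel$obesity <- 2 * coh2$panel$obesity
  fit2 <- suppressWarnings(fit_msm(coh2, covariates = cv, changepoint = FALSE))
  expect_equal(fit2$loglik, fit1$loglik, tolerance = 1e-6)
  sel <- cv$mask[, 1]
  expect_equal(fit2$params$beta[sel, 1], fit1$params$beta[sel, 1] / 2,
               tolerance = 1e-4)
})

test_that("adding a covariate never decreases the maximized likelihood", {
  set.seed(63)
  cv1 <- msm_covariates("obesity", mask = "living", structure = hip_structure())
  cv2 <- msm_covariates(c("obesity", "dm"), mask = "living",
                        structure = hip_structure())
  truth <- hip_truth(hip_structure(), cv2)
  coh <- suppressWarnings(generate_cohort(
    cohort_config(n_subjects = 250, seed = 13, truth = truth)))
  f1 <- suppressWarnings(fit_msm(coh, covariates = cv1, changepoint = FALSE))
  f2 <- suppressWarnings(fit_msm(coh, covariates = cv2, changepoint = FALSE))
  expect_gte(f2$loglik, f1$loglik - 1e-6)
})

test_that("hazard-ratio rows reproduce the Wald arithmetic", {
  set.seed(64)
  cv <- msm_covariates("obesity", mask = "living", structure = hip_structure())
  coh <- suppressWarnings(generate_cohort(
    cohort_config(n_subjects = 300, seed = 14,
                  truth = hip_truth(hip_structure(), cv))))
  fit <- suppressWarnings(fit_msm(coh, covariates = cv))
  tb <- hazard_ratio_table(fit, "obesity", cohort = coh)
  expect_identical(tb$transition, reported_transitions())
  expect_true(all(tb$lower <= tb$aHR & tb$aHR <= tb$upper, na.rm = TRUE))
  expect_true(all(tb$aHR > 0, na.rm = TRUE))
  # Wald arithmetic: the published-style row exp(0.2852 +/- 1.96 * 0.1385)
  # prints as 1.33 (1.01, 1.74)
  i <- match("A->C", tb$transition)
  expect_equal(tb$aHR[i], exp(fit$params$beta["A->C", "obesity"]))
  expect_equal(round(exp(0.2852 + c(0, -1, 1) * 1.959964 * 0.1385), 2),
               c(1.33, 1.01, 1.74))
  # significance is "CI excludes 1"
  expect_equal(tb$significant, tb$lower > 1 | tb$upper < 1)
  # death transitions appear only on request
  tb_d <- hazard_ratio_table(fit, "obesity", include_death = TRUE)
  expect_true(all(grepl("->E", setdiff(tb_d$transition, tb$transition))))
  expect_false(any(tb_d$estimable[grepl("->E", tb_d$transition)]))
})

test_that("degenerate hazard-ratio limits behave", {
  # beta = 0 gives aHR 1 with a log-symmetric CI; SE -> 0 collapses the CI
  se <- 0.25
  lo <- exp(0 - 1.959964 * se); hi <- exp(0 + 1.959964 * se)
  expect_equal(lo * hi, 1, tolerance = 1e-12)
  expect_equal(exp(log(2) + c(-1, 1) * 1.959964 * 1e-12), c(2, 2),
               tolerance = 1e-9)
})

test_that("transition counts split by exposure match a brute-force tally", {
  st <- hip_structure()
  # hand case: A(exposed) -> C -> A with constant exposure
  p <- data.frame(subject_id = "t1", t_years = c(0, 5, 10),
                  age = c(60, 65, 70), state = c("A", "C", "A"),
                  x = c(1, 1, 1))
  tc <- transition_count_table(msm_cohort(p, covariates = "x"), st, "x")
  expect_equal(tc$n_exposed[tc$transition == "A->C"], 1)
  expect_equal(tc$n_exposed[tc$transition == "C->A"], 1)
  expect_equal(sum(tc$n_unexposed), 0)

  # generated cohort vs an independent tally over consecutive row pairs
  coh <- suppressWarnings(generate_cohort(cohort_config(n_subjects = 120,
                                                        seed = 21)))
  tc2 <- transition_count_table(coh, st, "obesity")
  pp <- coh$panel
  brute <- setNames(numeric(nrow(tc2) * 2),
                    c(paste0(tc2$transition, "_1"), paste0(tc2$transition, "_0")))
  for (id in unique(pp$subject_id)) {
    rows <- which(pp$subject_id == id)
    if (length(rows) < 2) next
    for (i in seq_len(length(rows) - 1)) {
      lab <- paste0(pp$state[rows[i]], "->", pp$state[rows[i + 1]], "_",
                    pp$obesity[rows[i]])
      if (lab %in% names(brute)) brute[lab] <- brute[lab] + 1
    }
  }
  expect_equal(tc2$n_exposed, unname(brute[paste0(tc2$transition, "_1")]))
  expect_equal(tc2$n_unexposed, unname(brute[paste0(tc2$transition, "_0")]))
  # empty cohort: all zeros
  tc0 <- transition_count_table(
    suppressWarnings(generate_cohort(cohort_config(n_subjects = 0))), st,
    "obesity")
  expect_true(all(tc0$n_exposed == 0 & tc0$n_unexposed == 0))
  expect_error(transition_count_table(coh, st, "age0_c"), "binary")
})

test_that("structurally impossible records abort fitting with diagnostics", {
  p <- data.frame(subject_id = c("x1", "x1", "x2", "x2"),
                  t_years = c(0, 5, 0, 6), age = c(60, 65, 55, 61),
                  state = c("B", "A", "A", "B"))
  coh <- msm_cohort(p)
  expect_error(suppressWarnings(fit_msm(coh)), "x1")
})
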