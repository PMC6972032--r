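test_that("observed prevalence follows the last-visit-carried state", {
  # all subjects observed only in A at baseline
  p <- data.frame(subject_id = c("a1", "a2"), t_years = 0, age = c(60, 70),
                  state = "A")
  ob0 <- observed_prevalence(msm_cohort(p), 0)
  expect_equal(ob0$observed[ob0$state == "A"], 1)
  expect_equal(sum(ob0$observed), 1, tolerance = 1e-12)

  # a subject dead at year 3 occupies E at year 4; censored subjects leave
  # the denominator
  p2 <- data.frame(subject_id = c("b1", "b1", "b2", "b3", "b3"),
                   t_years = c(0, 2, 0, 0, 5), age = c(60, 62, 65, 58, 63),
                   state = c("A", "C", "B", "A", "A"))
  d2 <- data.frame(subject_id = "b1", death_time_years = 3)
  coh2 <- msm_cohort(p2, d2)
  ob4 <- observed_prevalence(coh2, 4)
  # at t=4: b1 dead (E), b2 censored (last visit 0 < 4), b3 in follow-up (A)
  expect_equal(ob4$n_at_risk[1], 2)
  expect_equal(ob4$observed[ob4$state == "E"], 0.5)
  expect_equal(ob4$observed[ob4$state == "A"], 0.5)
  expect_error(observed_prevalence(coh2, numeric(0)), "empty grid")
})

test_that("observed prevalence matches an independent per-timepoint tally", {
  coh <- suppressWarnings(generate_cohort(cohort_config(n_subjects = 100,
                                                        seed = 31)))
  grid <- c(0, 4, 9, 15)
  ob <- observed_prevalence(coh, grid)
  p <- coh$panel
  ids <- unique(p$subject_id)
  dth <- coh$deaths$death_time_years[match(ids, coh$deaths$subject_id)]
  for (tg in grid) {
    states <- vapply(seq_along(ids), function(j) {
      rows <- p[p$subject_id == ids[j], ]
      if (!is.na(dth[j]) && dth[j] <= tg) return("E")
      if (max(rows$t_years) < tg) return(NA_character_)
      rows$state[max(which(rows$t_years <= tg))]
    }, character(1))
    tab <- table(factor(states, levels = c("A", "B", "C", "D", "E")))
    got <- ob[ob$time == tg, ]
    expect_equal(got$observed, as.numeric(tab) / sum(tab))
    expect_equal(got$n_at_risk[1], sum(!is.na(states)))
  }
})

test_that("expected prevalence reproduces the baseline mix at time zero", {
  coh <- suppressWarnings(generate_cohort(cohort_config(n_subjects = 150,
                                                        seed = 32)))
  ex0 <- expected_prevalence(hip_truth(), coh, 0)
  base <- coh$panel[coh$panel$t_years == 0, ]
  mix <- table(factor(base$state, levels = c("A", "B", "C", "D", "E")))
  expect_equal(ex0$expected, as.numeric(mix) / sum(mix), tolerance = 1e-12)
})

test_that("expected occupancies are probability vectors with monotone death", {
  coh <- suppressWarnings(generate_cohort(cohort_config(n_subjects = 80,
                                                        seed = 33)))
  grid <- 0:12
  ex <- expected_prevalence(hip_truth(), coh, grid)
  for (tg in grid) {
    v <- ex$expected[ex$time == tg]
    expect_true(all(v >= 0 & v <= 1))
    expect_equal(sum(v), 1, tolerance = 1e-10)
  }
  # absorbing-state occupancy cannot decrease for a fixed denominator:
  # use a subject followed over the whole grid
  p1 <- data.frame(subject_id = "m1", t_years = c(0, 18), age = c(60, 78),
                   state = c("A", "A"))
  one <- msm_cohort(cbind(p1, hip_truth()$covariates$names |>
                            sapply(function(x) c(0, 0)) |> as.data.frame()),
                    covariates = hip_truth()$covariates$names)
  exE <- expected_prevalence(hip_truth(), one, 0:18)
  eE <- exE$expected[exE$state == "E"]
  expect_true(all(diff(eE) >= -1e-12))
  expect_gt(eE[19], 0)
})

test_that("zero intensities give constant expected prevalence", {
  # two subjects followed across the whole grid, so the denominator is
  # constant and only the dynamics matter
  p <- data.frame(subject_id = c("z1", "z1", "z2", "z2"),
                  t_years = c(0, 12, 0, 12), age = c(60, 72, 55, 67),
                  state = c("C", "C", "D", "D"))
  coh <- msm_cohort(p)
  cv0 <- msm_covariates(character(), structure = hip_structure())
  frozen <- msm_parameters(hip_structure(), cv0, log_q0 = -800)
  ex <- expected_prevalence(frozen, coh, c(0, 3, 12))
  for (tg in c(3, 12)) {
    expect_equal(ex$expected[ex$time == tg], ex$expected[ex$time == 0],
                 tolerance = 1e-9)
  }
  expect_equal(ex$expected[ex$time == 12 & ex$state == "C"], 0.5)
})

test_that("prevalence curves align observed and expected on one grid", {
  # dropout-free: the denominator convention is exactly self-consistent
  coh <- suppressWarnings(generate_cohort(cohort_config(n_subjects = 120,
                                                        seed = 35,
                                                        dropout = 0)))
  cur <- prevalence_curves(hip_truth(), coh, grid = 0:10)
  expect_setequal(names(cur),
                  c("time", "state", "observed", "expected", "n_at_risk"))
  expect_identical(nrow(cur), 11L * 5L)
  # simulation at the truth: observed within Monte-Carlo error of expected
  z <- abs(cur$observed - cur$expected) /
    sqrt(pmax(cur$expected * (1 - cur$expected), 1e-10) / cur$n_at_risk)
  expect_lt(max(z[cur$time > 0]), 4)
  gg <- plot_prevalence(cur)
  expect_s3_class(gg, "ggplot")
})
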