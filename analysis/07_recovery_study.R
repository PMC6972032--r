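#!/usr/bin/env Rscript
# Parameter-recovery simulation: can the fitting engine recover a planted
# obesity effect (hazard ratio 1.33 on symptom development, A->C) and the
# baseline intensities from cohorts of the study's shape?
#
# Writes: results/recovery_study.csv

library(hipmsm)

st <- hip_structure()
cv <- msm_covariates("obesity", mask = "living", structure = st)
truth <- hip_truth(st, cv)
truth$beta["A->C", "obesity"] <- log(1.33)
k <- match("A->C", st$trans)

nrep <- 40
n_sub <- 1500
rows <- vector("list", nrep)
for (r in seq_len(nrep)) {
  coh <- suppressWarnings(generate_cohort(
    cohort_config(n_subjects = n_sub, seed = 52000 + r, truth = truth)))
  fit <- suppressWarnings(fit_msm(coh, st, cv))
  if (!fit$convergence$converged || is.null(fit$vcov)) next
  bi <- fit$layout$b_idx[k, 1]
  se <- sqrt(fit$vcov[bi + 1, bi + 1])
  est <- fit$params$beta[k, 1]
  rows[[r]] <- data.frame(replicate = r, log_hr = est, se = se,
                          covered = abs(est - log(1.33)) <= qnorm(0.975) * se)
  cat(sprintf("replicate %2d: aHR %.3f (SE %.3f)\n", r, exp(est), se))
}
res <- do.call(rbind, rows)
write.csv(res, "results/recovery_study.csv", row.names = FALSE)
cat(sprintf("\nplanted aHR 1.33 on A->C: recovered exp(mean logHR) = %.3f, bias(log) = %+.4f, 95%% CI coverage = %.2f (%d replicates, n = %d)\n",
            exp(mean(res$log_hr)), mean(res$log_hr) - log(1.33),
            mean(res$covered), nrow(res), n_sub))
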