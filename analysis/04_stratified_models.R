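#!/usr/bin/env Rscript
# Exploratory sex- and race-stratified individual comorbidity models.
# The stratifying variable is dropped from the adjustment set in each
# stratum; combinations are not stratified (sample-size limits).
#
# Reads:  scratch/cohort/panel.csv
# Writes: results/table3_by_sex.csv, results/table4_by_race.csv

library(hipmsm)

coh <- read_panel("scratch/cohort/panel.csv")

for (sw in c("sex", "race")) {
  plan <- analysis_plan(models = "individual", strata = sw)
  bundle <- run_analysis(coh, plan)
  tabs <- lapply(bundle$results, function(r) cbind(stratum = r$name,
                                                   n = r$n_subjects,
                                                   r$hr_table))
  tab <- do.call(rbind, tabs)
  tab$aHR_ci <- sprintf("%.2f (%.2f, %.2f)", tab$aHR, tab$lower, tab$upper)
  out <- sprintf("results/table%d_by_%s.csv", if (sw == "sex") 3 else 4, sw)
  write.csv(tab, out, row.names = FALSE)
  cat("\n==", sw, "strata (written to", out, ") ==\n")
  print(tab[, c("stratum", "transition", "covariate", "aHR_ci",
                "significant")], row.names = FALSE)
}
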