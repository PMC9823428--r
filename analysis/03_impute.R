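#!/usr/bin/env Rscript
# Stage 3 — multiple imputation for the intention-to-treat analysis.
#
# Chained-equations imputation (predictive mean matching, donor pool 5) of
# the monotone missing follow-up cells, conditioning each variable on group,
# its own other timepoints and the concurrent diet-quality context. The
# study analysis used 50 imputations; the driver default is 50 (set
# HEINVS_M to scale down for a quick pass).

suppressPackageStartupMessages(library(heinvs))

m <- as.integer(Sys.getenv("HEINVS_M", "50"))
panel <- read_trial_table("results/analysis_panel.csv")
imp <- impute_trial(panel, m = m, maxit = 5, seed = 20260926)

dir.create("results/imputations", showWarnings = FALSE)
for (i in seq_len(min(m, 3))) {
  write_trial_table(complete_panel(imp, i),
                    sprintf("results/imputations/imputation_%02d.csv", i))
}
saveRDS(imp, "results/imputed.rds")

n_missing <- sum(is.na(panel$value))
cat(sprintf("Imputed %d missing cells in %d datasets (PMM, maxit 5).\n",
            n_missing, m))
cat(sprintf("Descriptives (Table-3 shape) written; first %d completed",
            min(m, 3)), "datasets exported as CSV.\n")
readr::write_csv(descriptive_table(imp), "results/table3_descriptives.csv")
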