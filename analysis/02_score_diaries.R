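#!/usr/bin/env Rscript
# Stage 2 — score the seven-day diaries.
#
# Runs the HEI-NVS scoring engine over every diary record: ten component
# scores against the DGE-based reference table, the 0-110 total, dietary
# energy density (beverages excluded) and mean daily energy intake. The
# scored values replace the diet variables in the analysis panel, so
# everything downstream rests on the engine, not on the generator's targets.

suppressPackageStartupMessages(library(heinvs))

diaries <- read_food_records("results/diaries.csv")
panel <- read_trial_table("results/trial_panel.csv")

scores <- score_diaries(diaries)
readr::write_csv(scores, "results/scores.csv")

diet_long <- scores_to_panel(scores) |>
  dplyr::rename(scored_value = value) |>
  dplyr::select(-group)
panel <- panel |>
  dplyr::left_join(diet_long, by = c("subject_id", "timepoint", "variable")) |>
  dplyr::mutate(value = dplyr::if_else(!is.na(scored_value) & !is.na(value),
                                       scored_value, value)) |>
  dplyr::select(-scored_value)
write_trial_table(panel, "results/analysis_panel.csv")

t0 <- scores[scores$timepoint == "t0", ]
cat(sprintf("Scored %d diary records; baseline HEI-NVS %.1f (SD %.1f),\n",
            nrow(scores), mean(t0$hei_nvs_total), sd(t0$hei_nvs_total)))
cat(sprintf("baseline energy density %.2f kcal/g, energy intake %.0f kcal/d.\n",
            mean(t0$energy_density), mean(t0$energy_intake)))
cat("Wrote results/scores.csv and results/analysis_panel.csv\n")
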