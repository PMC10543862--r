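#!/usr/bin/env Rscript
# Stage 3 — method comparison as measured (no collocation).
#
# Agreement battery between the automatic method and manual rater 1 on the
# raw measurements: Bland-Altman bias and limits, percentage error relative
# to the manual grand mean, Pearson r with Fisher-z CI, ICC, and the
# Lilliefors normality check of the differences. The per-electrode
# difference pattern at this stage still contains the partial periodic
# component induced by the hidden axis offsets.

library(cochloc)

meas <- read_measurements("results/cohort_measurements.csv")
auto <- meas[meas$method == "auto", ]
manual <- meas[meas$method == "manual_rater1", ]
criteria <- read_criteria_json("results/apriori_criteria.json")

report <- run_comparison(auto, manual, criteria = criteria,
                         with_collocation = FALSE)
print(report)
render_outputs(report, "results/compare_pre", moving_df = auto,
               reference_df = manual)
message("figures and report under results/compare_pre/")
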