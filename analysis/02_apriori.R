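#!/usr/bin/env Rscript
# Stage 2 — a-priori interrater criteria.
#
# The two manual rater series define how well the manual method agrees with
# itself: the +/- 1.96 SD half-width of their Bland-Altman limits per
# parameter is the precision criterion against which the automatic method's
# bias is later judged, and the ICC(A,k) documents interrater reliability.

library(cochloc)

meas <- read_measurements("results/cohort_measurements.csv")
r1 <- meas[meas$method == "manual_rater1", ]
r2 <- meas[meas$method == "manual_rater2", ]

criteria <- run_apriori(r1, r2)
print(criteria)
write_criteria_json(criteria, "results/apriori_criteria.json")
message("wrote results/apriori_criteria.json")
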