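#!/usr/bin/env Rscript
# Stage 4 — post-hoc mid-modiolar axis collocation and re-comparison.
#
# For each array, the automatic method's electrode cloud is translated by
# the 2-D shift minimizing the correlation cost against the manual
# measurements (one shift per array), and the agreement battery is rerun on
# the collocated measurements. With the axis mismatch removed, the limits
# of agreement should shrink toward the interrater calibration. The
# recovered shifts are compared against the generator's hidden truth.

library(cochloc)

meas <- read_measurements("results/cohort_measurements.csv")
auto <- meas[meas$method == "auto", ]
manual <- meas[meas$method == "manual_rater1", ]
criteria <- read_criteria_json("results/apriori_criteria.json")
truth <- jsonlite::read_json("results/cohort_truth.json",
                             simplifyVector = TRUE)

report <- run_comparison(auto, manual, criteria = criteria,
                         with_collocation = TRUE)
print(report)
render_outputs(report, "results/compare_post", moving_df = auto,
               reference_df = manual)
write_shifts_json(report$shifts, "results/shifts.json")

merged <- merge(report$shifts, truth, by = "array_id")
err <- sqrt((merged$shift_x_mm - merged$true_offset_x_mm)^2 +
              (merged$shift_y_mm - merged$true_offset_y_mm)^2)
message(sprintf("offset recovery: median %.3f mm, max %.3f mm over %d arrays",
                median(err), max(err), nrow(merged)))
message(sprintf("EMD LoA halfwidth: %.3f mm pre -> %.3f mm post (%.0f%% reduction)",
                1.96 * report$pre$emd$sd, 1.96 * report$post$emd$sd,
                100 * (1 - report$post$emd$sd / report$pre$emd$sd)))
message(sprintf("aDOI LoA halfwidth: %.1f deg pre -> %.1f deg post (%.0f%% reduction)",
                1.96 * report$pre$adoi$sd, 1.96 * report$post$adoi$sd,
                100 * (1 - report$post$adoi$sd / report$pre$adoi$sd)))
message("figures and report under results/compare_post/")
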