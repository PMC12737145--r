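#!/usr/bin/env Rscript
# Stage 2: calibrate the empirical dose scale k so the cohort mean
# breast dose equals the 9.76 mGy reference, label every patient with
# the internal-radiation model, and verify the 80/20 split (seed 42) is
# comparable across sides.

library(breastdose)

cohort <- read_cohort("results/cohort.csv")

stats <- normalization_stats(cohort)
k <- calibrate_k(cohort, stats, target_mean = 9.76)
params <- dose_model_params(k = k, stats = stats)
labelled <- label_cohort(cohort, params)

write_cohort(labelled, "results/cohort_labelled.csv")
write_dose_params(params, "results/dose_params.json")

cat(sprintf("Calibrated k = %.6g (cohort mean dose pinned to 9.76 mGy)\n", k))
cat(sprintf("IR: mean %.3f mGy | sd %.3f | range %.2f-%.2f mGy\n",
            mean(labelled$ir_mgy), sd(labelled$ir_mgy),
            min(labelled$ir_mgy), max(labelled$ir_mgy)))

sp <- split_cohort(labelled, train_fraction = 0.8, seed = 42)
cat("\nTrain/test comparability report (unstratified split, seed 42):\n")
print(sp$report, digits = 4, row.names = FALSE)
write.csv(sp$report, "results/split_report.csv", row.names = FALSE)
cat("\nWrote results/cohort_labelled.csv, results/dose_params.json,",
    "results/split_report.csv\n")
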