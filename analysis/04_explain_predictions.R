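#!/usr/bin/env Rscript
# Stage 4: local surrogate explanations for three contrasting test
# patients (lowest, median, and highest DLP), using the best family
# from stage 3. Conditions are quartile intervals on the standardized
# feature scale; contributions are in mGy.

library(breastdose)

labelled <- read_cohort("results/cohort_labelled.csv")
bench <- readRDS("scratch/bench.rds")

res_ok <- bench$results[bench$results$status == "ok", ]
best_name <- res_ok$model[which.min(res_ok$mse)]
cat("Explaining predictions of the best family:", best_name, "\n\n")

spec <- model_spec(best_name)
ctl <- pso_control(n_particles = 10, n_iterations = 20, seed = 20260103,
                   cv_folds = 5)
tuned <- tune_and_fit(spec, bench$split$train, control = ctl)

Xtr <- feature_matrix(bench$split$train)
stats <- feature_stats(Xtr)
predict_fun <- function(df) spec$predict(tuned$model,
                                         as.matrix(df[, colnames(Xtr)]))

test <- bench$split$test
Xte <- feature_matrix(test)
ord <- order(test$total_dlp_mgycm)
picks <- ord[c(1, round(length(ord) / 2), length(ord))]

dir.create("scratch/figures", showWarnings = FALSE, recursive = TRUE)
all_expl <- list()
for (i in seq_along(picks)) {
  idx <- picks[i]
  e <- explain_instance(predict_fun, Xte[idx, ], stats,
                        n_samples = 5000, seed = 20260104 + i)
  cat(sprintf("Patient %s (DLP %.1f mGy.cm, true dose %.2f mGy):\n",
              test$patient_id[idx], test$total_dlp_mgycm[idx],
              test$ir_mgy[idx]))
  print(e)
  cat("\n")
  all_expl[[i]] <- list(patient_id = test$patient_id[idx],
                        intercept = e$intercept,
                        local_prediction = e$local_prediction,
                        model_prediction = e$model_prediction,
                        features = e$features)
  ggplot2::ggsave(
    file.path("scratch/figures",
              paste0("explanation_", test$patient_id[idx], ".png")),
    plot_explanation(e, paste("Patient", test$patient_id[idx])),
    width = 6, height = 3
  )
}
jsonlite::write_json(all_expl, "results/explanations.json",
                     auto_unbox = TRUE, digits = NA)
cat("Wrote results/explanations.json and scratch/figures/explanation_*.png\n")
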