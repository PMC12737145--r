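# Shared fixtures: small synthetic cohorts and scaled-down model specs
# used across the unit tests.

small_cohort <- function(n = 160, seed = 11) {
  generate_cohort(cohort_config(n = n), seed = seed)
}

labelled_small_cohort <- function(n = 160, seed = 11, target_mean = 9.76) {
  patients <- small_cohort(n = n, seed = seed)
  stats <- normalization_stats(patients)
  k <- calibrate_k(patients, stats, target_mean = target_mean)
  label_cohort(patients, dose_model_params(k = k, stats = stats))
}

# Hand-built 3-patient table with easy numbers.
tiny_patients <- function() {
  data.frame(
    patient_id = c("A", "B", "C"),
    weight_kg = c(50, 70, 90),
    height_m = c(1.50, 1.60, 1.70),
    age_years = c(40, 55, 70),
    breast_thickness_mm = c(35, 45, 55),
    total_dlp_mgycm = c(100, 200, 300),
    stringsAsFactors = FALSE
  )
}

# Reduced search spaces so tuning tests stay fast.
tiny_spec <- function(name) {
  spaces <- list(
    xgboost = search_space(
      pso_dim("iterations", 20, 80, kind = "integer"),
      pso_dim("depth", 2, 6, kind = "integer"),
      pso_dim("learning_rate", 0.05, 0.5, log = TRUE)
    ),
    gboost = search_space(
      pso_dim("n_estimators", 10, 60, kind = "integer"),
      pso_dim("max_depth", 2, 5, kind = "integer"),
      pso_dim("learning_rate", 0.05, 0.5, log = TRUE),
      pso_dim("min_samples_split", 2, 10, kind = "integer")
    ),
    extratrees = search_space(
      pso_dim("n_estimators", 20, 80, kind = "integer"),
      pso_dim("max_depth", 2, 12, kind = "integer"),
      pso_dim("min_node_size", 1, 10, kind = "integer")
    ),
    adaboost = search_space(
      pso_dim("n_estimators", 5, 30, kind = "integer"),
      pso_dim("learning_rate", 0.1, 1, log = TRUE),
      pso_dim("max_depth", 2, 6, kind = "integer")
    ),
    randomforest = search_space(
      pso_dim("n_estimators", 20, 80, kind = "integer"),
      pso_dim("max_depth", 2, 12, kind = "integer"),
      pso_dim("min_node_size", 1, 10, kind = "integer")
    )
  )
  model_spec(name, space = spaces[[name]])
}

tiny_control <- function(seed = 5) {
  pso_control(n_particles = 4, n_iterations = 3, seed = seed, cv_folds = 3)
}

# Fresh path under the session temp dir.
withr_local_file <- function(name) {
  tempfile(pattern = paste0(sub("\\.", "-", name), "-"))
}
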