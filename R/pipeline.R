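# End-to-end pipeline: generate -> label (calibrated) -> split -> tune
# and fit -> metrics -> explanations, with a manifest of seeds, sizes
# and file hashes.

#' Derive per-stage seeds from one master seed
#'
#' Fixed offsets (generate +101, label-noise +202, PSO +303, explain
#' +404), reduced modulo 2^31 - 2 so derived seeds stay valid R
#' integers. Any stage can therefore be re-run independently of the
#' others from the master seed alone.
#'
#' @param master_seed integer master seed.
#' @return named list of integer seeds.
#' @export
derive_seeds <- function(master_seed) {
  base <- as.integer(master_seed %% (.Machine$integer.max - 1L))
  mk <- function(off) as.integer((base + off) %% (.Machine$integer.max - 1L))
  list(generate = mk(101L), noise = mk(202L), pso = mk(303L),
       explain = mk(404L))
}

#' Full-pipeline configuration
#'
#' @param master_seed single master seed; all stage seeds derive from it
#'   via [derive_seeds()].
#' @param cohort a [cohort_config()].
#' @param w_bmi,w_bt,w_age dose-model factor weights.
#' @param target_mean_dose calibration target for the cohort mean dose
#'   (mGy).
#' @param dose_form BODY term form, see [dose_model_params()].
#' @param train_fraction,split_seed data split (defaults 0.8 and 42).
#' @param families character vector of family names to benchmark.
#' @param n_particles,n_iterations,cv_folds PSO budget and objective
#'   folds.
#' @param include_bmi include BMI among the regression features.
#' @param explain_instances number of test instances to explain (the
#'   lowest-, median- and highest-DLP test patients when 3).
#' @param explain_samples perturbation count per explanation.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(master_seed = 42,
                            cohort = cohort_config(),
                            w_bmi = 0.40, w_bt = 0.30, w_age = 0.30,
                            target_mean_dose = 9.76,
                            dose_form = "weighted",
                            train_fraction = 0.8, split_seed = 42,
                            families = c("xgboost", "gboost", "extratrees",
                                         "adaboost", "randomforest"),
                            n_particles = 10, n_iterations = 20,
                            cv_folds = 5, include_bmi = TRUE,
                            explain_instances = 3, explain_samples = 5000) {
  structure(list(master_seed = master_seed, cohort = cohort, w_bmi = w_bmi,
                 w_bt = w_bt, w_age = w_age,
                 target_mean_dose = target_mean_dose, dose_form = dose_form,
                 train_fraction = train_fraction, split_seed = split_seed,
                 families = families, n_particles = n_particles,
                 n_iterations = n_iterations, cv_folds = cv_folds,
                 include_bmi = include_bmi,
                 explain_instances = explain_instances,
                 explain_samples = explain_samples),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Generates the cohort, calibrates the dose scale, labels, splits,
#' PSO-tunes every configured family, evaluates held-out metrics and
#' explains selected test predictions with the best family's model. All
#' artifacts are written under `out_dir` along with a manifest recording
#' seeds, split sizes, stage status and file MD5 hashes. A stage failure
#' preserves earlier outputs and marks the stage as failed in the
#' manifest.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); `NULL` keeps
#'   everything in memory.
#' @return list with `cohort`, `params`, `bench`, `explanations`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- derive_seeds(config$master_seed)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  manifest <- list(master_seed = config$master_seed, seeds = seeds,
                   stages = list(), files = list())
  out <- list()
  emit <- function(name, writer) {
    if (!is.null(out_dir)) {
      path <- file.path(out_dir, name)
      writer(path)
      manifest$files[[name]] <<- unname(tools::md5sum(path))
    }
  }
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- paste("failed:", conditionMessage(res))
      NULL
    } else {
      manifest$stages[[name]] <<- "ok"
      res
    }
  }

  labelled <- run_stage("generate_label", {
    patients <- generate_cohort(config$cohort, seed = seeds$generate)
    stats <- normalization_stats(patients)
    k <- calibrate_k(patients, stats, config$w_bmi, config$w_bt, config$w_age,
                     target_mean = config$target_mean_dose,
                     form = config$dose_form)
    params <- dose_model_params(k = k, w_bmi = config$w_bmi,
                                w_bt = config$w_bt, w_age = config$w_age,
                                stats = stats, form = config$dose_form)
    lab <- label_cohort(patients, params)
    if (config$cohort$label_noise_sd > 0) {
      lab$ir_mgy <- lab$ir_mgy + with_seed(seeds$noise, {
        rnorm(nrow(lab), sd = config$cohort$label_noise_sd)
      })
      lab$ir_mgy <- pmax(lab$ir_mgy, 1e-6)
    }
    emit("cohort.csv", function(p) write_cohort(lab, p))
    emit("dose_params.json", function(p) write_dose_params(params, p))
    lab
  })
  out$cohort <- labelled
  out$params <- attr(labelled, "dose_params")
  if (is.null(labelled)) {
    out$manifest <- manifest
    if (!is.null(out_dir)) {
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    return(out)
  }

  bench <- if (length(config$families) == 0) NULL else
  run_stage("benchmark", {
    specs <- lapply(config$families, model_spec)
    ctl <- pso_control(n_particles = config$n_particles,
                       n_iterations = config$n_iterations,
                       seed = seeds$pso, cv_folds = config$cv_folds)
    run_benchmark(labelled, specs, train_fraction = config$train_fraction,
                  split_seed = config$split_seed, control = ctl,
                  include_bmi = config$include_bmi)
  })
  out$bench <- bench
  if (!is.null(bench)) {
    manifest$split <- list(train = nrow(bench$split$train),
                           test = nrow(bench$split$test))
    emit("benchmark.csv", function(p) {
      utils::write.csv(bench$results, p, row.names = FALSE)
    })
    emit("benchmark_detail.json", function(p) {
      detail <- lapply(bench$fits, function(f) {
        if (is.null(f)) return(NULL)
        list(params = f$params, cv_mse = f$cv_score,
             predictions = f$predictions, y_true = f$y_true,
             g_best = f$trace$g_best, p_best = f$trace$p_best)
      })
      jsonlite::write_json(detail, p, auto_unbox = TRUE, digits = NA)
    })
  }

  explanations <- NULL
  if (!is.null(bench) && config$explain_instances > 0 &&
      any(bench$results$status == "ok")) {
    explanations <- run_stage("explain", {
      ok_rows <- bench$results[bench$results$status == "ok", ]
      best_name <- ok_rows$model[which.min(ok_rows$mse)]
      best_spec <- model_spec(best_name)
      best_fit <- tune_and_fit(best_spec, bench$split$train,
                               control = pso_control(
                                 n_particles = config$n_particles,
                                 n_iterations = config$n_iterations,
                                 seed = seeds$pso,
                                 cv_folds = config$cv_folds),
                               include_bmi = config$include_bmi)
      Xtr <- feature_matrix(bench$split$train, config$include_bmi)
      stats <- feature_stats(Xtr)
      predict_fun <- function(df) {
        best_spec$predict(best_fit$model, as.matrix(df[, colnames(Xtr)]))
      }
      test <- bench$split$test
      ord <- order(test$total_dlp_mgycm)
      n_exp <- min(config$explain_instances, nrow(test))
      pick <- ord[unique(round(seq(1, length(ord), length.out = n_exp)))]
      Xte <- feature_matrix(test, config$include_bmi)
      expl <- lapply(seq_along(pick), function(i) {
        inst <- Xte[pick[i], ]
        e <- explain_instance(predict_fun, inst, stats,
                              n_samples = config$explain_samples,
                              seed = seeds$explain + i)
        list(patient_id = test$patient_id[pick[i]], explanation = e)
      })
      emit("explanations.json", function(p) {
        jsonlite::write_json(lapply(expl, function(e) {
          list(patient_id = e$patient_id,
               intercept = e$explanation$intercept,
               local_prediction = e$explanation$local_prediction,
               model_prediction = e$explanation$model_prediction,
               features = e$explanation$features)
        }), p, auto_unbox = TRUE, digits = NA)
      })
      expl
    })
  }
  out$explanations <- explanations

  out$manifest <- manifest
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
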