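# Metrics, tuning, and the multi-family benchmark.

test_that("metrics match the hand-computed example and edge predictors", {
  m <- evaluate_metrics(c(10, 20, 30), c(12, 18, 33))
  expect_equal(m$mse, 17 / 3)
  expect_equal(m$mae, 7 / 3)
  expect_equal(m$mape, 0.4 / 3)
  expect_equal(m$r2, 1 - 17 / 200)
  # perfect predictor
  y <- c(2.5, 7.1, 9.9, 14)
  perfect <- evaluate_metrics(y, y)
  expect_equal(unlist(perfect), c(mse = 0, mae = 0, mape = 0, r2 = 1))
  # constant-mean predictor has R2 = 0
  expect_equal(evaluate_metrics(y, rep(mean(y), 4))$r2, 0)
  # near-zero actuals make MAPE undefined but keep other metrics
  expect_warning(mz <- evaluate_metrics(c(0, 1, 2), c(0.1, 1, 2)), "MAPE")
  expect_true(is.na(mz$mape))
  expect_false(is.na(mz$mse))
  expect_error(evaluate_metrics(1:3, 1:4), "length")
})

test_that("Jensen inequality mae^2 <= mse holds on random prediction sets", {
  set.seed(7)
  for (i in 1:20) {
    y <- runif(40, 1, 30)
    p <- y + rnorm(40, sd = runif(1, 0.1, 3))
    m <- evaluate_metrics(y, p)
    expect_lte(m$mae^2, m$mse + 1e-12)
  }
})

test_that("tuning counts objective calls and beats the library defaults", {
  lab <- labelled_small_cohort(n = 150, seed = 23)
  sp <- split_cohort(lab, 0.8, seed = 1)
  ctl <- tiny_control(seed = 6)
  spec <- tiny_spec("xgboost")
  tuned <- tune_and_fit(spec, sp$train, control = ctl)
  # one call per particle at init plus one per particle per iteration
  expect_equal(tuned$n_objective_calls,
               ctl$n_particles * (ctl$n_iterations + 1))
  # warm start guarantees: tuned CV MSE <= default-config CV MSE
  folds <- breastdose:::cv_fold_assignment(nrow(sp$train), ctl$cv_folds,
                                           ctl$seed)
  X <- feature_matrix(sp$train); y <- sp$train$ir_mgy
  sse <- 0
  for (f in seq_len(ctl$cv_folds)) {
    hold <- folds == f
    fit <- spec$fit(X[!hold, , drop = FALSE], y[!hold], spec$default_params)
    sse <- sse + sum((y[hold] - spec$predict(fit, X[hold, , drop = FALSE]))^2)
  }
  expect_lte(tuned$best_score, sse / length(y) + 1e-12)
})

test_that("a single-point search space forces the returned parameters", {
  lab <- labelled_small_cohort(n = 120, seed = 29)
  sp <- split_cohort(lab, 0.8, seed = 1)
  space <- search_space(
    pso_dim("iterations", 30, 31, kind = "integer"),
    pso_dim("depth", 3, 4, kind = "integer"),
    pso_dim("learning_rate", 0.2, 0.2000001, log = TRUE)
  )
  spec <- model_spec("xgboost", space = space)
  ctl <- pso_control(n_particles = 3, n_iterations = 2, seed = 2, cv_folds = 3)
  tuned <- tune_and_fit(spec, sp$train, control = ctl)
  expect_true(tuned$best_params$iterations %in% c(30L, 31L))
  expect_true(tuned$best_params$depth %in% c(3L, 4L))
  expect_equal(tuned$best_params$learning_rate, 0.2, tolerance = 1e-6)
})

test_that("the benchmark table is deterministic and internally consistent", {
  lab <- labelled_small_cohort(n = 150, seed = 23)
  specs <- list(tiny_spec("xgboost"), tiny_spec("randomforest"))
  ctl <- tiny_control(seed = 6)
  b1 <- run_benchmark(lab, specs, split_seed = 1, control = ctl)
  b2 <- run_benchmark(lab, specs, split_seed = 1, control = ctl)
  expect_identical(b1$results, b2$results)
  expect_true(all(b1$results$status == "ok"))
  expect_false(b1$failed)
  # metric recomputability from stored predictions
  for (name in names(b1$fits)) {
    f <- b1$fits[[name]]
    m <- evaluate_metrics(f$y_true, f$predictions)
    row <- b1$results[b1$results$model == name, ]
    expect_identical(unname(unlist(m)),
                     unname(unlist(row[c("mse", "mae", "mape", "r2")])))
    expect_lte(row$mae^2, row$mse + 1e-12)
    # trace invariant holds on stored PSO traces
    expect_true(all(diff(f$trace$g_best) <= 0))
  }
})

test_that("every family fits, predicts, and improves on heavy label noise", {
  lab <- labelled_small_cohort(n = 150, seed = 37)
  sp <- split_cohort(lab, 0.8, seed = 2)
  X <- feature_matrix(sp$train); y <- sp$train$ir_mgy
  Xte <- feature_matrix(sp$test); yte <- sp$test$ir_mgy
  set.seed(99)
  y_noisy <- y + rnorm(length(y), sd = 10)
  for (name in c("xgboost", "gboost", "extratrees", "adaboost",
                 "randomforest")) {
    spec <- model_spec(name)
    fit <- spec$fit(X, y, spec$default_params)
    pred <- spec$predict(fit, Xte)
    expect_length(pred, nrow(Xte))
    r2_clean <- evaluate_metrics(yte, pred)$r2
    fit_noisy <- spec$fit(X, y_noisy, spec$default_params)
    r2_noisy <- evaluate_metrics(yte, spec$predict(fit_noisy, Xte))$r2
    expect_gt(r2_clean, r2_noisy)
    expect_gt(r2_clean, 0.5)
  }
})

test_that("a failing family yields a failed row without stopping the run", {
  lab <- labelled_small_cohort(n = 120, seed = 41)
  bad <- tiny_spec("xgboost")
  bad$fit <- function(X, y, params) stop("synthetic failure")
  specs <- list(bad, tiny_spec("randomforest"))
  expect_warning(b <- run_benchmark(lab, specs, split_seed = 1,
                                    control = tiny_control()),
                 "synthetic failure")
  expect_true(b$failed)
  expect_equal(b$results$status, c("failed", "ok"))
  expect_true(is.na(b$results$mse[1]))
})
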