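# The five tree-ensemble regression families of the benchmark.
#
# - "xgboost":      gradient-boosted trees (xgboost, exact greedy splits:
#                   the cohort is small and all-numeric), standing in for
#                   categorical boosting (ordered/categorical handling is
#                   moot without categorical features).
# - "gboost":       classical least-squares gradient boosting over CART
#                   trees (Friedman), implemented in-package over the
#                   compiled exact-CART base learner (src/cart.cpp).
# - "extratrees":   extremely randomized trees (ranger, splitrule
#                   "extratrees").
# - "adaboost":     AdaBoost.R2 over depth-limited CART trees (Drucker);
#                   case weights enter the tree fit directly rather than
#                   via weighted bootstrap resampling, which makes each
#                   boost round deterministic.
# - "randomforest": random forest (ranger, splitrule "variance").
#
# Every family fixes its internal random state to 42 so a benchmark run
# is reproducible given the data and tuned hyperparameters.

FAMILY_RANDOM_STATE <- 42L

# Depth-limited exact CART regression tree (compiled; see src/cart.cpp).
# Weighted-SSE greedy splits, midpoint thresholds; the base learner of
# the two in-package boosting families.
cart_tree <- function(X, y, w = NULL, max_depth = 3, min_split = 2,
                      min_bucket = 1) {
  X <- as.matrix(X)
  if (is.null(w)) w <- rep(1, length(y))
  .cart_fit(X, as.numeric(y), as.numeric(w), as.integer(max_depth),
            as.integer(min_split), as.integer(min_bucket))
}

cart_tree_predict <- function(tree, X) {
  .cart_predict(tree, as.matrix(X))
}

# ---- classical least-squares gradient boosting ------------------------

fit_gboost <- function(X, y, n_estimators, max_depth, learning_rate,
                       min_samples_split = 2) {
  X <- as.matrix(X)
  f0 <- mean(y)
  current <- rep(f0, length(y))
  trees <- vector("list", n_estimators)
  for (m in seq_len(n_estimators)) {
    tree <- cart_tree(X, y - current, max_depth = max_depth,
                      min_split = min_samples_split)
    current <- current + learning_rate * cart_tree_predict(tree, X)
    trees[[m]] <- tree
  }
  structure(list(f0 = f0, trees = trees, learning_rate = learning_rate),
            class = "gboost_model")
}

predict_gboost <- function(model, X) {
  X <- as.matrix(X)
  pred <- rep(model$f0, nrow(X))
  for (tree in model$trees) {
    pred <- pred + model$learning_rate * cart_tree_predict(tree, X)
  }
  pred
}

# ---- AdaBoost.R2 (linear loss) ----------------------------------------

fit_adaboost <- function(X, y, n_estimators, learning_rate, max_depth) {
  X <- as.matrix(X)
  n <- length(y)
  w <- rep(1 / n, n)
  trees <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    tree <- cart_tree(X, y, w = w * n, max_depth = max_depth)
    pred <- cart_tree_predict(tree, X)
    abs_err <- abs(y - pred)
    emax <- max(abs_err)
    if (emax <= 0) { # perfect fit: keep with full confidence and stop
      trees[[m]] <- tree
      alphas[m] <- 1
      break
    }
    e <- abs_err / emax
    loss <- sum(w * e)
    if (loss >= 0.5) {
      if (m == 1) { # even the first learner is too weak; keep it anyway
        trees[[m]] <- tree
        alphas[m] <- 1
      }
      break
    }
    beta <- loss / (1 - loss)
    alphas[m] <- learning_rate * log(1 / beta)
    trees[[m]] <- tree
    w <- w * beta^(learning_rate * (1 - e))
    w <- w / sum(w)
  }
  structure(list(trees = trees, alphas = alphas), class = "adaboost_model")
}

# Weighted-median combination of the boost rounds' predictions.
predict_adaboost <- function(model, X) {
  X <- as.matrix(X)
  P <- vapply(model$trees, function(t) cart_tree_predict(t, X),
              numeric(nrow(X)))
  if (is.null(dim(P))) P <- matrix(P, nrow = nrow(X))
  a <- model$alphas
  apply(P, 1, function(p) {
    o <- order(p)
    cw <- cumsum(a[o])
    p[o][which(cw >= 0.5 * sum(a))[1]]
  })
}

# ---- family registry ---------------------------------------------------

#' Specification of one benchmark model family
#'
#' Bundles a family's PSO search space, its library-default
#' hyperparameters (used to warm-start the swarm), and fit/predict
#' closures. `space` may be overridden, e.g. to shrink the search for a
#' quick run; it must keep the same dimension names.
#'
#' @param name one of `"xgboost"`, `"gboost"`, `"extratrees"`,
#'   `"adaboost"`, `"randomforest"`.
#' @param space optional [search_space()] replacing the family default.
#' @return an object of class `model_spec` with elements `name`, `label`,
#'   `space`, `default_params`, `fit(X, y, params)`, `predict(model, X)`.
#' @export
model_spec <- function(name = c("xgboost", "gboost", "extratrees",
                                "adaboost", "randomforest"),
                       space = NULL) {
  name <- match.arg(name)
  spec <- switch(name,
    xgboost = list(
      label = "Gradient-boosted trees (xgboost)",
      space = search_space(
        pso_dim("iterations", 50, 500, kind = "integer"),
        pso_dim("depth", 2, 10, kind = "integer"),
        pso_dim("learning_rate", 0.01, 0.5, log = TRUE)
      ),
      default_params = list(iterations = 100L, depth = 6L, learning_rate = 0.3),
      fit = function(X, y, params) {
        xgboost::xgb.train(
          params = list(max_depth = params$depth, eta = params$learning_rate,
                        tree_method = "exact", nthread = 1,
                        seed = FAMILY_RANDOM_STATE),
          data = xgboost::xgb.DMatrix(as.matrix(X), label = y, nthread = 1),
          nrounds = params$iterations, verbose = 0
        )
      },
      predict = function(model, X) {
        predict(model, xgboost::xgb.DMatrix(as.matrix(X), nthread = 1))
      }
    ),
    gboost = list(
      label = "Gradient boosting (least-squares CART boosting)",
      space = search_space(
        pso_dim("n_estimators", 50, 250, kind = "integer"),
        pso_dim("max_depth", 2, 8, kind = "integer"),
        pso_dim("learning_rate", 0.01, 0.5, log = TRUE),
        pso_dim("min_samples_split", 2, 10, kind = "integer")
      ),
      default_params = list(n_estimators = 100L, max_depth = 3L,
                            learning_rate = 0.1, min_samples_split = 2L),
      fit = function(X, y, params) {
        fit_gboost(X, y, params$n_estimators, params$max_depth,
                   params$learning_rate, params$min_samples_split)
      },
      predict = function(model, X) predict_gboost(model, X)
    ),
    extratrees = list(
      label = "Extremely randomized trees (ranger)",
      space = search_space(
        pso_dim("n_estimators", 50, 300, kind = "integer"),
        pso_dim("max_depth", 2, 14, kind = "integer"),
        pso_dim("min_node_size", 1, 10, kind = "integer")
      ),
      default_params = list(n_estimators = 100L, max_depth = 14L,
                            min_node_size = 5L),
      fit = function(X, y, params) {
        ranger::ranger(x = as.data.frame(X), y = y,
                       num.trees = params$n_estimators,
                       max.depth = params$max_depth,
                       min.node.size = params$min_node_size,
                       splitrule = "extratrees", num.random.splits = 1,
                       num.threads = 1, seed = FAMILY_RANDOM_STATE)
      },
      predict = function(model, X) {
        predict(model, data = as.data.frame(X), num.threads = 1)$predictions
      }
    ),
    adaboost = list(
      label = "AdaBoost.R2 over depth-limited CART",
      space = search_space(
        pso_dim("n_estimators", 30, 150, kind = "integer"),
        pso_dim("learning_rate", 0.05, 1, log = TRUE),
        pso_dim("max_depth", 2, 8, kind = "integer")
      ),
      default_params = list(n_estimators = 50L, learning_rate = 1,
                            max_depth = 3L),
      fit = function(X, y, params) {
        fit_adaboost(X, y, params$n_estimators, params$learning_rate,
                     params$max_depth)
      },
      predict = function(model, X) predict_adaboost(model, X)
    ),
    randomforest = list(
      label = "Random forest (ranger)",
      space = search_space(
        pso_dim("n_estimators", 50, 300, kind = "integer"),
        pso_dim("max_depth", 2, 14, kind = "integer"),
        pso_dim("min_node_size", 1, 10, kind = "integer")
      ),
      default_params = list(n_estimators = 100L, max_depth = 14L,
                            min_node_size = 5L),
      fit = function(X, y, params) {
        ranger::ranger(x = as.data.frame(X), y = y,
                       num.trees = params$n_estimators,
                       max.depth = params$max_depth,
                       min.node.size = params$min_node_size,
                       splitrule = "variance",
                       num.threads = 1, seed = FAMILY_RANDOM_STATE)
      },
      predict = function(model, X) {
        predict(model, data = as.data.frame(X), num.threads = 1)$predictions
      }
    )
  )
  if (!is.null(space)) {
    stopifnot(inherits(space, "search_space"))
    if (!setequal(names(space), names(spec$space))) {
      stop("replacement space must keep dimension names ",
           paste(names(spec$space), collapse = ", "), call. = FALSE)
    }
    spec$space <- space
  }
  structure(c(list(name = name), spec), class = "model_spec")
}

#' Default specifications for all five benchmark families
#'
#' @return named list of [model_spec()] objects.
#' @export
default_model_specs <- function() {
  names <- c("xgboost", "gboost", "extratrees", "adaboost", "randomforest")
  stats::setNames(lapply(names, model_spec), names)
}
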