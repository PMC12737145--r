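# Local surrogate explanations: standard-normal perturbations in
# z-score space, exponential kernel weights, and a weighted ridge fit on
# quartile-bin membership indicators -- the LIME recipe for tabular
# regressors, written from scratch.

#' Per-feature training statistics for the explainer
#'
#' Mean, standard deviation, and quartiles of the standardized feature
#' (z-score against the same mean/sd) for each column of the training
#' feature matrix.
#'
#' @param X training feature matrix (as from the benchmark).
#' @return an object of class `feature_stats`: named list per feature of
#'   `mean`, `sd`, `breaks` (z-scale quartiles q1 <= q2 <= q3).
#' @export
feature_stats <- function(X) {
  X <- as.matrix(X)
  out <- lapply(colnames(X), function(col) {
    x <- X[, col]
    m <- mean(x); s <- sd(x)
    if (!is.finite(s) || s <= 0) {
      stop("degenerate feature '", col, "': zero training sd", call. = FALSE)
    }
    z <- (x - m) / s
    list(mean = m, sd = s,
         breaks = unname(quantile(z, probs = c(0.25, 0.5, 0.75))))
  })
  names(out) <- colnames(X)
  structure(out, class = "feature_stats")
}

#' Discretize one feature value into a quartile bin
#'
#' The value is z-scored against the training statistics and assigned to
#' one of four quartile bins with left-open boundaries, so a value equal
#' to the training median lands in the second bin. Extreme bins render
#' as one-sided conditions (`x <= q1`, `x > q3`), inner bins as bounded
#' intervals, all on the standardized scale.
#'
#' @param value raw feature value.
#' @param stats a [feature_stats()] object.
#' @param feature feature name.
#' @return list with `bin` (1-4), `z` (standardized value), and
#'   `condition` (display string).
#' @export
discretize_feature <- function(value, stats, feature) {
  stopifnot(inherits(stats, "feature_stats"))
  st <- stats[[feature]]
  if (is.null(st)) stop("unknown feature '", feature, "'", call. = FALSE)
  z <- (value - st$mean) / st$sd
  b <- st$breaks
  # small tolerance so a value numerically equal to a quartile boundary
  # (e.g. the training median) lands in the lower bin
  bin <- 1L + sum(z > b + 1e-9)
  condition <- switch(bin,
    sprintf("%s <= %.2f", feature, b[1]),
    sprintf("%.2f < %s <= %.2f", b[1], feature, b[2]),
    sprintf("%.2f < %s <= %.2f", b[2], feature, b[3]),
    sprintf("%s > %.2f", feature, b[3])
  )
  list(bin = bin, z = z, condition = condition)
}

#' Explain a single prediction with a local ridge surrogate
#'
#' Draws `n_samples` standard-normal perturbations per feature in
#' z-score space (the instance itself is the first sample), weights them
#' by `exp(-d^2 / kernel_width^2)` with `d` the Euclidean distance to
#' the instance in z-space (normalized to mean 1 so the ridge penalty
#' keeps the same scale for central and outlying instances), and fits
#' a weighted ridge regression of the
#' model's predictions on bin-membership indicators (1 if a sample falls
#' in the same quartile bin as the instance). The top `top_k` features
#' by absolute contribution are refit as the reported surrogate, so the
#' additivity identity `intercept + sum(contributions) = local
#' prediction` holds exactly for the reported set.
#'
#' @param predict_fun function(data.frame) -> numeric predictions; the
#'   data frame has the feature columns of `stats` on the raw scale.
#' @param instance named numeric vector (or one-row data frame) of raw
#'   feature values.
#' @param stats a [feature_stats()] object from the training split.
#' @param n_samples number of perturbations (>= 100; default 5000).
#' @param kernel_width kernel width in z-space (default
#'   `0.75 * sqrt(d)` with `d` the number of features).
#' @param ridge ridge penalty (default 1e-3); increased automatically
#'   (with a message) if the weighted design is singular.
#' @param top_k number of features to report (default 5).
#' @param seed integer seed; identical seeds give identical explanations.
#' @return an object of class `explanation`: list with `features` (data
#'   frame: feature, condition, value, contribution in mGy), `intercept`,
#'   `local_prediction`, `model_prediction`.
#' @export
explain_instance <- function(predict_fun, instance, stats,
                             n_samples = 5000, kernel_width = NULL,
                             ridge = 1e-3, top_k = 5, seed = 1) {
  stopifnot(inherits(stats, "feature_stats"))
  if (n_samples < 100) stop("n_samples must be >= 100", call. = FALSE)
  if (is.data.frame(instance)) instance <- unlist(instance[1, , drop = TRUE])
  feats <- names(stats)
  if (!all(feats %in% names(instance))) {
    stop("instance is missing feature(s): ",
         paste(setdiff(feats, names(instance)), collapse = ", "), call. = FALSE)
  }
  d <- length(feats)
  if (is.null(kernel_width)) kernel_width <- 0.75 * sqrt(d)

  mu <- vapply(stats, `[[`, 0, "mean")
  sg <- vapply(stats, `[[`, 0, "sd")
  z_inst <- (instance[feats] - mu) / sg
  inst_disc <- lapply(feats, function(f) discretize_feature(instance[[f]], stats, f))
  names(inst_disc) <- feats
  inst_bins <- vapply(inst_disc, `[[`, 0L, "bin")

  Z <- with_seed(seed, matrix(rnorm(n_samples * d), nrow = n_samples))
  colnames(Z) <- feats
  Z[1, ] <- z_inst

  # bin membership indicators relative to the instance's bins
  B <- matrix(0, n_samples, d, dimnames = list(NULL, feats))
  for (j in seq_len(d)) {
    br <- stats[[feats[j]]]$breaks
    bins <- 1L + (Z[, j] > br[1] + 1e-9) + (Z[, j] > br[2] + 1e-9) +
      (Z[, j] > br[3] + 1e-9)
    B[, j] <- as.numeric(bins == inst_bins[j])
  }

  raw <- sweep(sweep(Z, 2, sg, "*"), 2, mu, "+")
  preds <- predict_fun(as.data.frame(raw))
  if (length(preds) != n_samples || any(!is.finite(preds))) {
    stop("predict_fun must return one finite prediction per sample",
         call. = FALSE)
  }

  dist <- sqrt(rowSums(sweep(Z, 2, z_inst)^2))
  w <- exp(-dist^2 / kernel_width^2)
  # normalize to mean 1: for instances far from the training bulk the
  # raw kernel weights underflow uniformly, and an absolute ridge
  # penalty would otherwise dominate the weighted design
  sw <- sum(w)
  if (!is.finite(sw) || sw <= 0) {
    message("kernel weights degenerate at this instance; using uniform weights")
    w <- rep(1, n_samples)
    sw <- n_samples
  }
  w <- w * (n_samples / sw)

  fit_ridge <- function(cols) {
    Xd <- cbind(intercept = 1, B[, cols, drop = FALSE])
    XtW <- t(Xd * w)
    A <- XtW %*% Xd
    pen <- diag(c(0, rep(1, length(cols))), nrow = ncol(Xd))
    lambda <- ridge
    repeat {
      beta <- tryCatch(solve(A + lambda * pen, XtW %*% preds),
                       error = function(e) NULL)
      if (!is.null(beta)) return(drop(beta))
      message("singular weighted design; increasing ridge penalty to ",
              lambda * 10)
      lambda <- lambda * 10
    }
  }

  beta_all <- fit_ridge(feats)
  contrib_all <- beta_all[-1]
  keep <- feats[order(abs(contrib_all), decreasing = TRUE)][seq_len(min(top_k, d))]
  beta <- fit_ridge(keep)
  intercept <- beta[1]
  contributions <- beta[-1]

  features <- data.frame(
    feature = keep,
    condition = vapply(inst_disc[keep], `[[`, "", "condition"),
    value = unname(instance[keep]),
    contribution = unname(contributions),
    stringsAsFactors = FALSE
  )
  features <- features[order(abs(features$contribution), decreasing = TRUE), ]
  rownames(features) <- NULL

  structure(list(
    features = features,
    intercept = unname(intercept),
    local_prediction = unname(intercept + sum(contributions)),
    model_prediction = preds[1]
  ), class = "explanation")
}

#' @export
print.explanation <- function(x, ...) {
  cat("Local surrogate explanation\n")
  cat(sprintf("  model prediction: %.3f mGy | surrogate: %.3f mGy | intercept: %.3f\n",
              x$model_prediction, x$local_prediction, x$intercept))
  for (i in seq_len(nrow(x$features))) {
    f <- x$features[i, ]
    cat(sprintf("  %-28s value %8.2f  contribution %+.3f\n",
                f$condition, f$value, f$contribution))
  }
  invisible(x)
}
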