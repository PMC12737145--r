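# Synthetic patient-cohort generator: truncated marginals coupled by a
# Gaussian copula, emulating a single-scanner mammography + chest-CT
# cohort of 653 women.

#' Synthetic cohort generator configuration
#'
#' Defaults emulate the reference cohort: weight mean 73.1 kg (46-133),
#' height mean 1.59 m (1.47-1.77), age mean 58.6 y (33-88), mammographic
#' breast thickness around 39-57 mm, and total DLP between 68.81 and
#' 914.5 mGy.cm. The DLP marginal is a two-component mixture: a
#' truncated-lognormal routine-protocol bulk plus a small
#' truncated-exponential tail of extended-coverage / repeat acquisitions
#' (real single-protocol DLP histograms have a tight bulk and a sparse
#' decaying high tail).
#'
#' Dependence is a Gaussian copula with rank-correlation targets placed
#' on weight as the body-size driver (automatic exposure control raises
#' DLP with body size): weight-height 0.3, weight-breast-thickness 0.4,
#' weight-DLP 0.5.
#'
#' @param n number of patients (>= 1).
#' @param weight,height,age,breast_thickness truncated-normal marginal
#'   specs: `list(mean, sd, lower, upper)`.
#' @param dlp DLP mixture spec: `list(median, sdlog, lower, bulk_upper,
#'   upper, p_tail, tail_scale)`.
#' @param rank_cor named vector of rank-correlation targets for pairs
#'   `weight_height`, `weight_bt`, `weight_dlp`.
#' @param label_noise_sd additive Gaussian noise (mGy, sd) applied to the
#'   dose labels by [run_pipeline()]; 0 keeps labels exactly recomputable
#'   from the dose model.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n = 653,
                          weight = list(mean = 73.1, sd = 15, lower = 46, upper = 133),
                          height = list(mean = 1.59, sd = 0.06, lower = 1.47, upper = 1.77),
                          age = list(mean = 58.6, sd = 12, lower = 33, upper = 88),
                          breast_thickness = list(mean = 50, sd = 12, lower = 25, upper = 80),
                          dlp = list(median = 205, sdlog = 0.25, lower = 68.81,
                                     bulk_upper = 550, upper = 914.5,
                                     p_tail = 0.02, tail_scale = 130),
                          rank_cor = c(weight_height = 0.3, weight_bt = 0.4,
                                       weight_dlp = 0.5),
                          label_noise_sd = 0) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  for (f in list(weight, height, age, breast_thickness)) {
    if (f$lower >= f$upper) stop("marginal bounds need lower < upper", call. = FALSE)
    if (f$sd <= 0) stop("marginal sd must be positive", call. = FALSE)
    if (f$mean <= f$lower || f$mean >= f$upper) {
      stop("marginal mean must lie strictly inside its bounds", call. = FALSE)
    }
  }
  if (!(dlp$lower < dlp$bulk_upper && dlp$bulk_upper <= dlp$upper)) {
    stop("dlp bounds need lower < bulk_upper <= upper", call. = FALSE)
  }
  if (dlp$p_tail < 0 || dlp$p_tail >= 1) stop("dlp$p_tail must be in [0, 1)", call. = FALSE)
  if (label_noise_sd < 0) stop("label_noise_sd must be >= 0", call. = FALSE)
  cfg <- list(n = as.integer(n), weight = weight, height = height, age = age,
              breast_thickness = breast_thickness, dlp = dlp,
              rank_cor = rank_cor, label_noise_sd = label_noise_sd)
  # fail early on an infeasible dependence structure
  copula_correlation(cfg)
  structure(cfg, class = "cohort_config")
}

# Latent Gaussian correlation matrix for the copula. Spearman targets are
# converted to Pearson correlations of the latent normals via
# r = 2 sin(pi * rho_s / 6).
copula_correlation <- function(config) {
  vars <- c("weight", "height", "age", "breast_thickness", "dlp")
  R <- diag(5)
  dimnames(R) <- list(vars, vars)
  s2p <- function(rho) 2 * sin(pi * rho / 6)
  rc <- config$rank_cor
  R["weight", "height"] <- R["height", "weight"] <- s2p(rc[["weight_height"]])
  R["weight", "breast_thickness"] <- R["breast_thickness", "weight"] <-
    s2p(rc[["weight_bt"]])
  R["weight", "dlp"] <- R["dlp", "weight"] <- s2p(rc[["weight_dlp"]])
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) {
    stop("infeasible rank-correlation targets: copula correlation matrix ",
         "is not positive definite", call. = FALSE)
  }
  R
}

# Inverse CDF of a normal truncated to [lower, upper].
qtruncnorm <- function(u, mean, sd, lower, upper) {
  a <- pnorm((lower - mean) / sd)
  b <- pnorm((upper - mean) / sd)
  mean + sd * qnorm(a + u * (b - a))
}

# Location parameter mu such that the [lower, upper]-truncated normal
# with scale sd has mean mean_target. Asymmetric truncation would
# otherwise bias the realized cohort mean away from the configured one.
truncnorm_location <- function(mean_target, sd, lower, upper) {
  f <- function(mu) {
    a <- (lower - mu) / sd
    b <- (upper - mu) / sd
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) /
      (pnorm(b) - pnorm(a)) - mean_target
  }
  stats::uniroot(f, interval = c(lower, upper), extendInt = "yes",
                 tol = 1e-10)$root
}

# Inverse CDF of the two-component DLP mixture: with probability
# 1 - p_tail a lognormal truncated to [lower, bulk_upper]; with
# probability p_tail an exponential (scale tail_scale) truncated to
# [bulk_upper, upper]. The copula uniform's upper tail maps onto the
# high-DLP band, so DLP outliers inherit the body-size dependence.
qdlp <- function(u, spec) {
  meanlog <- log(spec$median)
  a <- plnorm(spec$lower, meanlog, spec$sdlog)
  b <- plnorm(spec$bulk_upper, meanlog, spec$sdlog)
  p_bulk <- 1 - spec$p_tail
  bulk <- qlnorm(a + pmin(u / p_bulk, 1) * (b - a), meanlog, spec$sdlog)
  if (spec$p_tail == 0) return(bulk)
  fmax <- 1 - exp(-(spec$upper - spec$bulk_upper) / spec$tail_scale)
  v <- pmax(0, pmin((u - p_bulk) / spec$p_tail, 1))
  tail <- spec$bulk_upper - spec$tail_scale * log(1 - v * fmax)
  ifelse(u < p_bulk, bulk, tail)
}

#' Generate a synthetic patient cohort
#'
#' Draws `config$n` patients from the configured marginals under the
#' Gaussian copula. Deterministic for a given seed.
#'
#' @param config a [cohort_config()] object.
#' @param seed integer seed.
#' @return an unlabelled cohort table (see [validate_patients()]).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  R <- copula_correlation(config)
  n <- config$n
  U <- with_seed(seed, {
    Z <- matrix(rnorm(n * 5), nrow = n) %*% chol(R)
    pnorm(Z)
  })
  qtn <- function(u, spec) {
    mu <- truncnorm_location(spec$mean, spec$sd, spec$lower, spec$upper)
    qtruncnorm(u, mu, spec$sd, spec$lower, spec$upper)
  }
  patients <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    weight_kg = qtn(U[, 1], config$weight),
    height_m = qtn(U[, 2], config$height),
    age_years = qtn(U[, 3], config$age),
    breast_thickness_mm = qtn(U[, 4], config$breast_thickness),
    total_dlp_mgycm = qdlp(U[, 5], config$dlp),
    stringsAsFactors = FALSE
  )
  validate_patients(patients)
  patients
}

#' Split a cohort into training and test sets
#'
#' Random, disjoint, exhaustive partition with `floor(n * train_fraction)`
#' training patients. A comparability report (mean and range of the dose
#' per side) is attached so the unstratified split can be sanity-checked.
#'
#' @param cohort a (typically labelled) cohort table.
#' @param train_fraction fraction of patients assigned to training,
#'   strictly between 0 and 1.
#' @param seed integer seed controlling the index assignment.
#' @return a list with `train`, `test`, and `report` (a data frame of
#'   per-split n, mean, min, max of `ir_mgy` when present).
#' @export
split_cohort <- function(cohort, train_fraction = 0.8, seed = 42) {
  stopifnot(is.data.frame(cohort))
  n <- nrow(cohort)
  if (n < 2) stop("cohort must contain at least 2 patients", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be strictly between 0 and 1", call. = FALSE)
  }
  n_train <- floor(n * train_fraction)
  if (n_train < 1 || n_train >= n) {
    stop("split would leave an empty train or test set", call. = FALSE)
  }
  idx <- with_seed(seed, sample.int(n, n_train))
  train <- cohort[sort(idx), , drop = FALSE]
  test <- cohort[setdiff(seq_len(n), idx), , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  report <- NULL
  if ("ir_mgy" %in% names(cohort)) {
    summarise <- function(df, split) data.frame(
      split = split, n = nrow(df), mean_ir = mean(df$ir_mgy),
      min_ir = min(df$ir_mgy), max_ir = max(df$ir_mgy)
    )
    report <- rbind(summarise(train, "train"), summarise(test, "test"))
  }
  list(train = train, test = test, report = report)
}
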