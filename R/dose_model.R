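# Internal-radiation (IR) dose model: IR = k * DLP * BODY, with BODY a
# weighted combination of min-max normalized BMI, breast thickness and age.

#' Cohort table column names
#'
#' Canonical column order for a patient cohort table. `ir_mgy` is present
#' only on labelled cohorts.
#' @keywords internal
cohort_columns <- function(labelled = FALSE) {
  cols <- c("patient_id", "weight_kg", "height_m", "age_years",
            "breast_thickness_mm", "total_dlp_mgycm")
  if (labelled) c(cols, "ir_mgy") else cols
}

#' Validate a patient cohort table
#'
#' Checks that the required columns are present, numeric, and strictly
#' positive. Errors name the offending row (by `patient_id` where
#' available) and column.
#'
#' @param patients data frame of patient records.
#' @param require_ir if `TRUE`, also require a positive `ir_mgy` column.
#' @return the validated data frame, invisibly.
#' @export
validate_patients <- function(patients, require_ir = FALSE) {
  stopifnot(is.data.frame(patients))
  needed <- cohort_columns(labelled = require_ir)
  missing <- setdiff(needed, names(patients))
  if (length(missing) > 0) {
    stop("cohort table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(patients) == 0) return(invisible(patients))
  num_cols <- setdiff(needed, "patient_id")
  for (col in num_cols) {
    x <- patients[[col]]
    if (!is.numeric(x)) {
      stop("column '", col, "' is not numeric", call. = FALSE)
    }
    bad <- which(!is.finite(x) | x <= 0)
    if (length(bad) > 0) {
      id <- as.character(patients$patient_id[bad[1]])
      stop("invalid value in column '", col, "' at row ", bad[1],
           " (patient_id '", id, "'): must be a positive finite number",
           call. = FALSE)
    }
  }
  if (anyDuplicated(patients$patient_id)) {
    stop("duplicated patient_id values in cohort", call. = FALSE)
  }
  invisible(patients)
}

#' Body mass index
#'
#' @param weight body weight in kg (positive).
#' @param height standing height in m (positive).
#' @return BMI in kg/m^2.
#' @examples
#' compute_bmi(73.1, 1.59)
#' @export
compute_bmi <- function(weight, height) {
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    stop("weight must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(height)) || any(height <= 0)) {
    stop("height must be positive and finite", call. = FALSE)
  }
  weight / height^2
}

#' Min-max normalization with clamping
#'
#' Maps `x` to `(x - lo) / (hi - lo)` and clamps the result into \[0, 1\]
#' for values outside the reference range.
#'
#' @param x numeric vector.
#' @param lo,hi reference minimum and maximum; `hi > lo` is required (a
#'   zero-width range indicates a broken reference cohort and is an error).
#' @return values in \[0, 1\].
#' @export
minmax_normalize <- function(x, lo, hi) {
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo) {
    stop("degenerate normalization range: hi must be > lo", call. = FALSE)
  }
  pmin(pmax((x - lo) / (hi - lo), 0), 1)
}

#' Normalization statistics for the dose model
#'
#' Per-feature min and max of BMI, breast thickness and age over a
#' reference cohort. These fix the 0 and 1 points of the normalized dose
#' factors F1 (BMI), F2 (breast thickness) and F3 (age).
#'
#' @param patients cohort table (see [validate_patients()]).
#' @return an object of class `dose_norm_stats`: a named list with
#'   `bmi`, `breast_thickness` and `age`, each `c(min, max)`.
#' @export
normalization_stats <- function(patients) {
  validate_patients(patients)
  if (nrow(patients) < 2) {
    stop("need at least 2 patients to derive normalization statistics",
         call. = FALSE)
  }
  bmi <- compute_bmi(patients$weight_kg, patients$height_m)
  stats <- list(
    bmi = c(min = min(bmi), max = max(bmi)),
    breast_thickness = c(min = min(patients$breast_thickness_mm),
                         max = max(patients$breast_thickness_mm)),
    age = c(min = min(patients$age_years), max = max(patients$age_years))
  )
  for (f in names(stats)) {
    if (stats[[f]]["max"] <= stats[[f]]["min"]) {
      stop("degenerate range for feature '", f, "': min equals max",
           call. = FALSE)
    }
  }
  structure(stats, class = "dose_norm_stats")
}

#' Dose model parameters
#'
#' Bundles the empirical scale `k`, the factor weights and the
#' normalization statistics that fully determine the IR model. Weights
#' must sum to 1 (defaults 0.40 BMI / 0.30 breast thickness / 0.30 age).
#' `form = "weighted"` uses the convex-combination BODY term (default);
#' `form = "product"` uses the pure product `F1 * F2 * F3`, which zeroes
#' the dose whenever any factor sits at its cohort minimum and is kept
#' only for comparison.
#'
#' @param k positive empirical scale (mGy per mGy.cm, folded with the
#'   dimensionless BODY term).
#' @param w_bmi,w_bt,w_age factor weights; must sum to 1 within 1e-9.
#' @param stats a `dose_norm_stats` object.
#' @param form `"weighted"` or `"product"`.
#' @return an object of class `dose_model_params`.
#' @export
dose_model_params <- function(k = 1, w_bmi = 0.40, w_bt = 0.30, w_age = 0.30,
                              stats, form = c("weighted", "product")) {
  form <- match.arg(form)
  if (!is.finite(k) || k <= 0) stop("k must be a positive real", call. = FALSE)
  w <- c(w_bmi, w_bt, w_age)
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("weights must be non-negative finite numbers", call. = FALSE)
  }
  if (abs(sum(w) - 1) > 1e-9) {
    stop("factor weights must sum to 1 (within 1e-9); got ", sum(w),
         call. = FALSE)
  }
  if (!inherits(stats, "dose_norm_stats")) {
    stop("stats must be a dose_norm_stats object (see normalization_stats())",
         call. = FALSE)
  }
  structure(list(k = k, w_bmi = w_bmi, w_bt = w_bt, w_age = w_age,
                 stats = stats, form = form),
            class = "dose_model_params")
}

# Normalized factors for a cohort under given stats: matrix with columns
# f1 (BMI), f2 (breast thickness), f3 (age), each clamped into [0, 1].
dose_factors <- function(patients, stats) {
  bmi <- compute_bmi(patients$weight_kg, patients$height_m)
  cbind(
    f1 = minmax_normalize(bmi, stats$bmi["min"], stats$bmi["max"]),
    f2 = minmax_normalize(patients$breast_thickness_mm,
                          stats$breast_thickness["min"],
                          stats$breast_thickness["max"]),
    f3 = minmax_normalize(patients$age_years,
                          stats$age["min"], stats$age["max"])
  )
}

#' Body-size correction term
#'
#' Combines the three normalized factors into the BODY multiplier. Under
#' the default weighted form this is a convex combination and therefore
#' bounded by the smallest and largest input factor.
#'
#' @param f1,f2,f3 normalized BMI, breast-thickness and age factors, each
#'   in \[0, 1\].
#' @param params a [dose_model_params()] object.
#' @return the BODY factor in \[0, 1\].
#' @export
body_factor <- function(f1, f2, f3, params) {
  stopifnot(inherits(params, "dose_model_params"))
  fs <- cbind(f1, f2, f3)
  if (any(fs < -1e-12) || any(fs > 1 + 1e-12)) {
    stop("factors must lie in [0, 1]", call. = FALSE)
  }
  if (params$form == "product") {
    f1 * f2 * f3
  } else {
    params$w_bmi * f1 + params$w_bt * f2 + params$w_age * f3
  }
}

#' Patient-specific internal radiation dose
#'
#' `IR = k * DLP * BODY(F1, F2, F3)` in mGy. Non-negative, and linear in
#' DLP at fixed anthropometrics.
#'
#' @param patients cohort table.
#' @param params a [dose_model_params()] object.
#' @return numeric vector of doses (mGy), one per patient.
#' @export
internal_radiation <- function(patients, params) {
  stopifnot(inherits(params, "dose_model_params"))
  validate_patients(patients)
  if (nrow(patients) == 0) return(numeric(0))
  fs <- dose_factors(patients, params$stats)
  body <- body_factor(fs[, "f1"], fs[, "f2"], fs[, "f3"], params)
  unname(params$k * patients$total_dlp_mgycm * body)
}

#' Calibrate the empirical dose scale k
#'
#' The reference calibration pins the cohort mean dose: `k` is chosen so
#' that the mean of `k * DLP_i * BODY_i` equals `target_mean`
#' (closed form: `k = target_mean / mean(DLP_i * BODY_i)`).
#'
#' @param patients cohort table used for calibration.
#' @param stats a `dose_norm_stats` object.
#' @param w_bmi,w_bt,w_age factor weights (sum to 1).
#' @param target_mean target cohort mean dose in mGy (default 9.76, a
#'   reference mean breast dose for chest CT).
#' @param form BODY form, see [dose_model_params()].
#' @return the calibrated scale `k` (positive scalar).
#' @export
calibrate_k <- function(patients, stats, w_bmi = 0.40, w_bt = 0.30,
                        w_age = 0.30, target_mean = 9.76,
                        form = c("weighted", "product")) {
  form <- match.arg(form)
  if (!is.finite(target_mean) || target_mean <= 0) {
    stop("target_mean must be positive", call. = FALSE)
  }
  probe <- dose_model_params(k = 1, w_bmi = w_bmi, w_bt = w_bt, w_age = w_age,
                             stats = stats, form = form)
  base <- internal_radiation(patients, probe)
  m <- mean(base)
  if (!is.finite(m) || m <= 0) {
    stop("calibration impossible: all DLP x BODY products are zero",
         call. = FALSE)
  }
  target_mean / m
}

#' Label a cohort with model-derived doses
#'
#' Computes the per-patient IR under `params` and appends it as `ir_mgy`.
#' The parameters used are attached as the `"dose_params"` attribute so
#' the labels remain recomputable.
#'
#' @param patients cohort table.
#' @param params a [dose_model_params()] object.
#' @return the cohort with an `ir_mgy` column (a labelled cohort).
#' @export
label_cohort <- function(patients, params) {
  ir <- internal_radiation(patients, params)
  out <- patients
  out$ir_mgy <- ir
  attr(out, "dose_params") <- params
  out
}
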