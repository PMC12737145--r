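# Cohort / parameter / result I/O. CSV dialect: comma-separated, UTF-8,
# '.' decimal separator, header required.

#' Write a cohort table to CSV
#'
#' @param cohort cohort table (labelled or not).
#' @param path output file.
#' @export
write_cohort <- function(cohort, path) {
  labelled <- "ir_mgy" %in% names(cohort)
  validate_patients(cohort, require_ir = labelled)
  utils::write.csv(cohort[, cohort_columns(labelled)], path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a cohort CSV
#'
#' Requires the documented header (`patient_id`, `weight_kg`, `height_m`,
#' `age_years`, `breast_thickness_mm`, `total_dlp_mgycm`, optionally
#' `ir_mgy`). Schema problems raise errors naming the row and column.
#'
#' @param path CSV file path.
#' @return validated cohort data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- cohort_columns()
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("cohort CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  labelled <- "ir_mgy" %in% names(df)
  for (col in setdiff(cohort_columns(labelled), "patient_id")) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      stop("non-numeric value in column '", col, "' at row ",
           ifelse(is.na(bad), 1, bad), call. = FALSE)
    }
  }
  df$patient_id <- as.character(df$patient_id)
  validate_patients(df, require_ir = labelled)
  df
}

#' Serialize dose-model parameters to JSON
#'
#' Numbers are written at full precision so that a write/read round trip
#' is bit-exact.
#'
#' @param params a [dose_model_params()] object.
#' @param path output JSON file.
#' @export
write_dose_params <- function(params, path) {
  stopifnot(inherits(params, "dose_model_params"))
  st <- unclass(params$stats)
  as_minmax <- function(mm) list(min = unname(mm["min"]), max = unname(mm["max"]))
  obj <- list(
    k = params$k, w_bmi = params$w_bmi, w_bt = params$w_bt,
    w_age = params$w_age, form = params$form,
    stats = list(bmi = as_minmax(st$bmi),
                 bt = as_minmax(st$breast_thickness),
                 age = as_minmax(st$age))
  )
  # digits = I(17): 17 significant digits round-trip an IEEE double exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read dose-model parameters from JSON
#'
#' @param path JSON file written by [write_dose_params()].
#' @return a [dose_model_params()] object.
#' @export
read_dose_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mm <- function(x) c(min = x$min, max = x$max)
  stats <- structure(
    list(bmi = mm(obj$stats$bmi), breast_thickness = mm(obj$stats$bt),
         age = mm(obj$stats$age)),
    class = "dose_norm_stats"
  )
  dose_model_params(k = obj$k, w_bmi = obj$w_bmi, w_bt = obj$w_bt,
                    w_age = obj$w_age, stats = stats, form = obj$form)
}
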