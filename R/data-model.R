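#' Covariate specification table
#'
#' Describes how each modelling covariate is obtained from raw cohort or
#' longitudinal columns: its role (fixed at baseline vs. measured
#' longitudinally), the divisor applied before modelling, and an optional
#' category coding for factors.
#'
#' The default specification follows the renal-transplant convention:
#' age per 10 years, weight per 10 kg, hematocrit per 10 percentage points
#' (so a hematocrit of 29.5\% scales to 2.95), GFR per 10 ml/min,
#' proteinuria per 1 g/24 h, and sex coded male = 0, female = 1.
#'
#' @param name character vector of covariate names.
#' @param role one of `"baseline"` or `"longitudinal"` per covariate.
#' @param divisor positive numeric divisor per covariate.
#' @param coding named list; for coded covariates a named numeric vector
#'   mapping category labels to numeric codes, otherwise `NULL`.
#' @return An object of class `"covariate_spec"`: a data frame with one row
#'   per covariate and a `coding` attribute.
#' @examples
#' covariate_specs()
#' @export
covariate_specs <- function(name = c("age", "sex", "weight",
                                     "hematocrit", "proteinuria", "gfr"),
                            role = c("baseline", "baseline", "baseline",
                                     "longitudinal", "longitudinal",
                                     "longitudinal"),
                            divisor = c(10, 1, 10, 10, 1, 10),
                            coding = list(sex = c(male = 0, female = 1))) {
  stopifnot(length(name) == length(role), length(name) == length(divisor))
  if (any(divisor <= 0)) stop("covariate divisors must be positive")
  role <- match.arg(role, c("baseline", "longitudinal"), several.ok = TRUE)
  spec <- data.frame(name = as.character(name), role = role,
                     divisor = as.numeric(divisor),
                     stringsAsFactors = FALSE)
  attr(spec, "coding") <- coding
  class(spec) <- c("covariate_spec", "data.frame")
  spec
}

spec_roles <- function(spec, role) spec$name[spec$role == role]

#' Scale raw covariate values for modelling
#'
#' Divides each covariate column named in the specification by its divisor
#' and replaces coded categories (e.g. sex labels) by their numeric codes.
#' The transform is invertible via [invert_scaling()].
#'
#' @param data data frame holding raw covariate columns.
#' @param spec a [covariate_specs()] object.
#' @return `data` with the named columns scaled/coded. Columns absent from
#'   `data` are ignored silently only if `strict = FALSE`.
#' @param strict error if a spec name is missing from `data` (default TRUE
#'   only for names present in neither role; internal callers subset first).
#' @export
apply_scaling <- function(data, spec, strict = FALSE) {
  coding <- attr(spec, "coding")
  for (i in seq_len(nrow(spec))) {
    nm <- spec$name[i]
    if (!nm %in% names(data)) {
      if (strict) stop("covariate '", nm, "' not found in data")
      next
    }
    cd <- coding[[nm]]
    if (!is.null(cd)) {
      x <- as.character(data[[nm]])
      bad <- !is.na(x) & !x %in% names(cd)
      if (any(bad)) {
        stop("unknown category label(s) for '", nm, "': ",
             paste(unique(x[bad]), collapse = ", "))
      }
      data[[nm]] <- unname(cd[x])
    } else {
      data[[nm]] <- data[[nm]] / spec$divisor[i]
    }
  }
  data
}

#' Invert [apply_scaling()]
#'
#' @inheritParams apply_scaling
#' @return `data` with scaled columns mapped back to raw values/labels.
#' @export
invert_scaling <- function(data, spec) {
  coding <- attr(spec, "coding")
  for (i in seq_len(nrow(spec))) {
    nm <- spec$name[i]
    if (!nm %in% names(data)) next
    cd <- coding[[nm]]
    if (!is.null(cd)) {
      data[[nm]] <- names(cd)[match(data[[nm]], cd)]
    } else {
      data[[nm]] <- data[[nm]] * spec$divisor[i]
    }
  }
  data
}

cohort_columns <- c("id", "time_years", "event", "age", "sex", "weight")
longitudinal_columns <- c("id", "obstime", "hematocrit", "proteinuria", "gfr")

rename_columns <- function(df, rename) {
  if (is.null(rename)) return(df)
  # rename: named character vector, names = native column, value = canonical
  hit <- names(df) %in% names(rename)
  names(df)[hit] <- unname(rename[names(df)[hit]])
  df
}

#' Read a cohort table
#'
#' Reads a comma-separated patient table with one row per subject and the
#' columns `id,time_years,event,age,sex,weight` (raw, unscaled values).
#' A `rename` map supports datasets distributed with different column names.
#'
#' @param path path to a CSV file with a header row.
#' @param rename optional named character vector mapping native column names
#'   to the canonical ones, e.g. `c(years = "time_years")`.
#' @return A validated data frame of raw patient records.
#' @export
read_cohort <- function(path, rename = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- rename_columns(df, rename)
  validate_cohort(df)
}

#' @rdname read_cohort
#' @param cohort a cohort data frame to validate directly.
#' @export
validate_cohort <- function(cohort) {
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- which(!is.finite(cohort$time_years) | cohort$time_years <= 0)
  if (length(bad)) {
    stop("non-positive survival time for id(s): ",
         paste(utils::head(cohort$id[bad], 5), collapse = ", "))
  }
  if (!all(cohort$event %in% c(0, 1))) {
    stop("event indicator must be 0 or 1")
  }
  if (anyDuplicated(cohort$id)) stop("subject ids must be unique in a cohort")
  cohort
}

#' Read a longitudinal measurement table
#'
#' Reads a comma-separated long-format table of biomarker visits with
#' columns `id,obstime,hematocrit,proteinuria,gfr`. Empty biomarker cells
#' become `NA` (never zero). Records are returned sorted by `(id, obstime)`.
#'
#' @inheritParams read_cohort
#' @param cohort optional cohort data frame; if supplied, measurement ids
#'   must occur in the cohort and `obstime` may not exceed the subject's
#'   follow-up time.
#' @return A validated, sorted data frame of measurement records.
#' @export
read_longitudinal <- function(path, rename = NULL, cohort = NULL) {
  if (!file.exists(path)) stop("longitudinal file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- rename_columns(df, rename)
  validate_longitudinal(df, cohort)
}

#' @rdname read_longitudinal
#' @param measurements a measurement data frame to validate directly.
#' @export
validate_longitudinal <- function(measurements, cohort = NULL) {
  missing_cols <- setdiff(longitudinal_columns, names(measurements))
  if (length(missing_cols)) {
    stop("longitudinal table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(!is.finite(measurements$obstime) | measurements$obstime < 0)) {
    stop("observation times must be non-negative")
  }
  if (!is.null(cohort)) {
    orphan <- setdiff(measurements$id, cohort$id)
    if (length(orphan)) {
      stop("measurement id(s) absent from cohort: ",
           paste(utils::head(orphan, 5), collapse = ", "))
    }
    tmax <- cohort$time_years[match(measurements$id, cohort$id)]
    if (any(measurements$obstime > tmax + 1e-9)) {
      stop("observation time after the subject's follow-up time")
    }
  }
  measurements[order(measurements$id, measurements$obstime), , drop = FALSE]
}

# Format numeric columns at full precision so write/read round-trips exactly.
format_full <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) {
      df[[j]] <- vapply(df[[j]], function(v) {
        if (is.na(v)) NA_character_ else formatC(v, digits = 17, format = "g")
      }, character(1))
    }
  }
  df
}

#' Write cohort / longitudinal tables
#'
#' Writers matching [read_cohort()] and [read_longitudinal()]; numeric
#' values are written at full precision so a write/read round trip
#' reproduces them exactly.
#'
#' @param x data frame to write.
#' @param path output CSV path.
#' @export
write_cohort <- function(x, path) {
  utils::write.csv(format_full(x), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
write_longitudinal <- write_cohort
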