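#' Landmark grid
#'
#' An inclusive equidistant grid of prediction (landmark) times together
#' with the prediction window `w`. The default grid places 41 landmarks
#' every 3 months on the interval \[0, 10\] years with a 5-year window.
#'
#' @param s0 first landmark time (years).
#' @param sL last landmark time (years); `sL - s0` must be an integer
#'   multiple of `spacing` (tolerance 1e-9).
#' @param spacing distance between landmarks (years, > 0).
#' @param w prediction window (years, > 0).
#' @return An object of class `"landmark_grid"` with elements `s0`, `sL`,
#'   `spacing`, `w`, `points`.
#' @examples
#' length(landmark_grid(0, 10, 0.25, 5)$points) # 41
#' @export
landmark_grid <- function(s0 = 0, sL = 10, spacing = 0.25, w = 5) {
  if (sL <= s0) stop("sL must exceed s0")
  if (spacing <= 0) stop("spacing must be positive")
  if (w <= 0) stop("prediction window w must be positive")
  steps <- (sL - s0) / spacing
  if (abs(steps - round(steps)) > 1e-9) {
    near <- (sL - s0) / round(steps)
    stop(sprintf(paste0("(sL - s0) is not a multiple of spacing; ",
                        "nearest valid spacing is %.6g"), near))
  }
  points <- s0 + spacing * (0:round(steps))
  structure(list(s0 = s0, sL = sL, spacing = spacing, w = w,
                 points = points),
            class = "landmark_grid")
}

#' @export
print.landmark_grid <- function(x, ...) {
  cat(sprintf("Landmark grid: %d points on [%g, %g], spacing %g y, window %g y\n",
              length(x$points), x$s0, x$sL, x$spacing, x$w))
  invisible(x)
}

#' Last-observation-carried-forward biomarker value at a landmark
#'
#' Returns the value of `biomarker` from the latest visit at or before
#' `s`, for one subject's measurement records. If the subject has no visit
#' by `s`, or the biomarker is missing at that latest visit, the result is
#' `NA` (missingness is a value, not an error).
#'
#' @param measurements one subject's measurement rows, sorted by `obstime`.
#' @param s landmark time (years).
#' @param biomarker column name to extract.
#' @return The raw carried-forward value, or `NA`.
#' @export
covariate_at <- function(measurements, s, biomarker) {
  idx <- which(measurements$obstime <= s)
  if (!length(idx)) return(NA_real_)
  measurements[[biomarker]][max(idx)]
}

# LOCF for all subjects at once: latest visit row at or before s, per id.
# measurements must be sorted by (id, obstime).
locf_rows <- function(measurements, s) {
  sub <- measurements[measurements$obstime <= s, , drop = FALSE]
  if (!nrow(sub)) return(sub)
  sub[!duplicated(sub$id, fromLast = TRUE), , drop = FALSE]
}

#' Build one landmark dataset
#'
#' Selects subjects still at risk at the landmark time `s` (strictly
#' `time_years > s`), evaluates their covariates at `s` (baseline values
#' plus carried-forward biomarkers, scaled per `spec`), administratively
#' censors at the window end, and returns one row per subject with
#' counting-process fields `entry = s`, `exit = min(T, s + w)` and
#' `status = 1` iff the event occurred by `s + w` (events exactly at
#' `s + w` count). Subjects with an unresolvable biomarker at `s` are
#' dropped (their count is recorded in the `"n_dropped"` attribute).
#'
#' @param cohort raw patient table (see [read_cohort()]).
#' @param measurements raw sorted measurement table.
#' @param s landmark time (years).
#' @param w prediction window (years).
#' @param spec a [covariate_specs()] object.
#' @return A data frame with columns `id, landmark, entry, exit, status`
#'   plus one scaled column per covariate.
#' @export
build_landmark_dataset <- function(cohort, measurements, s, w,
                                   spec = covariate_specs()) {
  at_risk <- cohort[cohort$time_years > s, , drop = FALSE]
  long_names <- spec_roles(spec, "longitudinal")
  base_names <- spec_roles(spec, "baseline")
  if (!nrow(at_risk)) {
    warning(sprintf("empty risk set at landmark s = %g", s))
    out <- data.frame(id = at_risk$id, landmark = numeric(0),
                      entry = numeric(0), exit = numeric(0),
                      status = integer(0))
    for (nm in c(base_names, long_names)) out[[nm]] <- numeric(0)
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  loc <- locf_rows(measurements, s)
  m <- match(at_risk$id, loc$id)
  out <- data.frame(id = at_risk$id, landmark = s, entry = s,
                    exit = pmin(at_risk$time_years, s + w),
                    status = as.integer(at_risk$event == 1 &
                                          at_risk$time_years <= s + w))
  out <- cbind(out, at_risk[, base_names, drop = FALSE])
  for (nm in long_names) out[[nm]] <- loc[[nm]][m]
  keep <- stats::complete.cases(out[, long_names, drop = FALSE])
  n_dropped <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  out <- apply_scaling(out, spec)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Stack landmark datasets into a super-dataset
#'
#' Concatenates the landmark datasets for every point of the grid into the
#' stacked dataset on which the dynamic Cox super-model is fitted. Rows are
#' ordered by landmark, then subject id; the subject id doubles as the
#' cluster identifier for robust variance estimation.
#'
#' @inheritParams build_landmark_dataset
#' @param grid a [landmark_grid()].
#' @return An object of class `"landmark_stack"`: a data frame as in
#'   [build_landmark_dataset()] covering all landmarks, with attributes
#'   `grid`, `spec` and `n_dropped`.
#' @export
stack_landmarks <- function(cohort, measurements, grid = landmark_grid(),
                            spec = covariate_specs()) {
  validate_cohort(cohort)
  measurements <- measurements[order(measurements$id, measurements$obstime), ,
                               drop = FALSE]
  parts <- lapply(grid$points, function(s) {
    suppressWarnings(build_landmark_dataset(cohort, measurements, s,
                                            grid$w, spec))
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$landmark, out$id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "grid") <- grid
  attr(out, "spec") <- spec
  attr(out, "n_dropped") <- sum(vapply(parts, attr, 0L, which = "n_dropped"))
  class(out) <- c("landmark_stack", "data.frame")
  out
}

#' Write a stacked landmark dataset for external inspection
#'
#' @param x a `"landmark_stack"`.
#' @param path output CSV path.
#' @export
write_stack <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
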