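#' Basis specification for time-varying effects
#'
#' Controls the polynomial degree (in standardized landmark time
#' `u = (s - s0) / (sL - s0)`) of each covariate's effect function and of
#' the landmark time function theta. Degree 0 is a constant effect, degree
#' 1 adds a `u` term, degree 2 a `u^2` term. The default reproduces the
#' renal-transplant dynamic model structure: constant effects for age and
#' weight, linear-in-u effects for hematocrit and GFR, a quadratic effect
#' for proteinuria, sex excluded, and a quadratic theta.
#'
#' @param degrees named integer vector of per-covariate degrees (0-2);
#'   covariates not named are excluded from the model.
#' @param theta_degree degree of the landmark time function theta
#'   (0 omits theta entirely; theta has no constant term).
#' @return An object of class `"basis_spec"`.
#' @export
basis_spec <- function(degrees = c(age = 0, weight = 0, hematocrit = 1,
                                   gfr = 1, proteinuria = 2),
                       theta_degree = 2) {
  if (!all(degrees %in% 0:2) || !theta_degree %in% 0:2) {
    stop("polynomial degrees must be 0, 1 or 2")
  }
  if (is.null(names(degrees)) || any(names(degrees) == "")) {
    stop("degrees must be a named vector")
  }
  structure(list(degrees = degrees, theta_degree = theta_degree),
            class = "basis_spec")
}

# column names for one covariate block: k, k:u, k:u^2
block_names <- function(k, d) {
  c(k, if (d >= 1) paste0(k, ":u"), if (d >= 2) paste0(k, ":u^2"))
}

#' Expand covariates at a landmark into the super-model design row(s)
#'
#' For covariate `k` with degree `d`, emits columns
#' `z_k, z_k*u, ..., z_k*u^d`; theta contributes columns `u, ..., u^td`.
#' `u = (s - s0) / (sL - s0)` is the standardized landmark time.
#'
#' @param z named list/data frame of scaled covariate values (vectorized:
#'   each element may be a vector).
#' @param s landmark time(s), recycled against the covariate vectors.
#' @param grid a [landmark_grid()] supplying the standardization.
#' @param spec a [basis_spec()].
#' @return A numeric matrix with one row per input record.
#' @examples
#' g <- landmark_grid()
#' expand_basis(list(x = 2), 5, g, basis_spec(c(x = 2), theta_degree = 0))
#' @export
expand_basis <- function(z, s, grid, spec = basis_spec()) {
  u <- (s - grid$s0) / (grid$sL - grid$s0)
  nrec <- max(length(u), vapply(z, length, 1L))
  u <- rep_len(u, nrec)
  cols <- list()
  for (k in names(spec$degrees)) {
    if (is.null(z[[k]])) stop("covariate '", k, "' named in the basis ",
                              "specification is absent from the data")
    zk <- rep_len(z[[k]], nrec)
    d <- spec$degrees[[k]]
    for (j in 0:d) cols[[length(cols) + 1L]] <- zk * u^j
  }
  td <- spec$theta_degree
  if (td >= 1) for (j in 1:td) cols[[length(cols) + 1L]] <- u^j
  x <- do.call(cbind, cols)
  colnames(x) <- c(unlist(lapply(names(spec$degrees), function(k)
    block_names(k, spec$degrees[[k]]))),
    if (td >= 1) paste0("theta:", c("u", "u^2")[1:td]))
  x
}

#' Fit the dynamic Cox landmark super-model
#'
#' Builds (or accepts) the stacked landmark dataset, expands covariates
#' into polynomial time-varying effect terms plus the landmark time
#' function theta, and fits one Cox model on the stacked
#' counting-process rows with a single common baseline hazard,
#' `h(t | Z, s) = h0(t) exp(Z'(s) beta(s) + theta(s))`, using
#' subject-level clusters for the robust sandwich variance. The Breslow
#' baseline hazard is attached for conditional survival prediction.
#'
#' @param cohort raw patient table (ignored if `stacked` is supplied).
#' @param measurements raw measurement table (ignored if `stacked` given).
#' @param grid a [landmark_grid()].
#' @param basis a [basis_spec()].
#' @param spec a [covariate_specs()].
#' @param stacked optionally a prebuilt [stack_landmarks()] result.
#' @return An object of class `"dyncox"` with components `coefficients`,
#'   `var`, `rvar`, `baseline` (Breslow hazard), `basis`, `grid`, `spec`,
#'   `cox` (the engine fit), `n`, `nevent`, `n_subjects`.
#' @seealso [predict.dyncox()], [dynamic_hr()], [static_cox()]
#' @export
dyncox <- function(cohort = NULL, measurements = NULL,
                   grid = landmark_grid(), basis = basis_spec(),
                   spec = covariate_specs(), stacked = NULL) {
  if (is.null(stacked)) {
    stacked <- stack_landmarks(cohort, measurements, grid, spec)
  } else {
    grid <- attr(stacked, "grid")
    spec <- attr(stacked, "spec")
  }
  if (!nrow(stacked)) stop("stacked landmark dataset is empty")
  if (!any(stacked$status == 1)) stop("no events in the stacked dataset")
  x <- expand_basis(stacked, stacked$landmark, grid, basis)
  fit <- cox_partial_fit(x, stacked$entry, stacked$exit, stacked$status,
                         cluster = stacked$id)
  bh <- breslow_baseline(fit, stacked$entry, stacked$exit, stacked$status)
  structure(list(coefficients = fit$coefficients,
                 var = fit$var, rvar = fit$rvar,
                 baseline = bh, basis = basis, grid = grid, spec = spec,
                 cox = fit,
                 n = fit$n, nevent = fit$nevent,
                 n_subjects = fit$n_clusters,
                 call = match.call()),
            class = "dyncox")
}

#' @export
coef.dyncox <- function(object, ...) object$coefficients

#' @export
vcov.dyncox <- function(object, type = c("robust", "model"), ...) {
  type <- match.arg(type)
  if (type == "robust") object$rvar else object$var
}

#' @export
logLik.dyncox <- function(object, ...) {
  structure(object$cox$loglik, df = length(object$coefficients),
            class = "logLik")
}

#' @export
residuals.dyncox <- function(object, type = c("score"), ...) {
  match.arg(type)
  object$cox$score_residuals
}

#' @export
print.dyncox <- function(x, digits = 4, ...) {
  cat("Dynamic Cox landmark super-model\n")
  cat(sprintf("  %d landmarks on [%g, %g], window w = %g years\n",
              length(x$grid$points), x$grid$s0, x$grid$sL, x$grid$w))
  cat(sprintf("  stacked rows: %d, events: %d, subjects: %d\n",
              x$n, x$nevent, x$n_subjects))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' Summarize a dynamic Cox landmark super-model
#'
#' Per-term coefficients with model-based and robust standard errors and
#' Wald p-values (robust by default), grouped by covariate, in the style of
#' a coefficient table for a landmark super-model.
#'
#' @param object a `"dyncox"` fit.
#' @param se which standard errors drive the reported p-values.
#' @param ... unused.
#' @export
summary.dyncox <- function(object, se = c("robust", "model"), ...) {
  se <- match.arg(se)
  v <- if (se == "robust") object$rvar else object$var
  est <- object$coefficients
  sds <- sqrt(diag(v))
  zval <- est / sds
  tab <- data.frame(coef = est,
                    `se(model)` = sqrt(diag(object$var)),
                    `se(robust)` = sqrt(diag(object$rvar)),
                    z = zval,
                    `p` = 2 * stats::pnorm(-abs(zval)),
                    check.names = FALSE)
  structure(list(table = tab, se = se, n = object$n, nevent = object$nevent,
                 n_subjects = object$n_subjects, grid = object$grid,
                 loglik = object$cox$loglik),
            class = "summary.dyncox")
}

#' @export
print.summary.dyncox <- function(x, digits = 4, ...) {
  cat("Dynamic Cox landmark super-model\n")
  cat(sprintf("  stacked rows: %d, events: %d, subjects: %d, loglik: %.3f\n",
              x$n, x$nevent, x$n_subjects, x$loglik))
  cat(sprintf("  p-values from %s standard errors\n", x$se))
  stats::printCoefmat(as.matrix(x$table), digits = digits,
                      P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

# linear predictor for scaled covariates z (list/df) at landmark(s) s
dyncox_lp <- function(object, z, s) {
  x <- expand_basis(z, s, object$grid, object$basis)
  drop(x %*% object$coefficients)
}

#' Conditional w-year survival from a dynamic Cox super-model
#'
#' `S(s + w | s, Z) = exp(-sum_{t in (s, s+w]} dH0(t) * exp(lp))` with the
#' Breslow baseline increments of the stacked fit and the linear predictor
#' (theta included) evaluated at the landmark `s`.
#'
#' @param object a `"dyncox"` fit.
#' @param z named list/data frame of scaled covariate values at `s`.
#' @param s landmark time; must lie within the fitted grid range.
#' @param w prediction window (default: the grid's window).
#' @return Conditional survival probabilities in \[0, 1\].
#' @export
predict_dynamic_survival <- function(object, z, s, w = object$grid$w) {
  if (any(s < object$grid$s0 - 1e-9) || any(s > object$grid$sL + 1e-9)) {
    stop("landmark time outside the fitted grid range [",
         object$grid$s0, ", ", object$grid$sL, "]")
  }
  lp <- dyncox_lp(object, z, s)
  dH <- cumhaz_at(object$baseline, s + w) - cumhaz_at(object$baseline, s)
  unname(exp(-dH * exp(lp)))
}

#' Predict method for dynamic Cox super-models
#'
#' @param object a `"dyncox"` fit.
#' @param newdata data frame of scaled covariate values (one row per
#'   prediction) with a column per model covariate.
#' @param s landmark time(s), recycled against rows of `newdata`.
#' @param w prediction window.
#' @param type `"survival"` for conditional w-year survival, `"lp"` for
#'   the linear predictor (theta terms included).
#' @param ... unused.
#' @export
predict.dyncox <- function(object, newdata, s, w = object$grid$w,
                           type = c("survival", "lp"), ...) {
  type <- match.arg(type)
  if (type == "lp") return(dyncox_lp(object, newdata, s))
  predict_dynamic_survival(object, newdata, s, w)
}

#' Per-landmark conditional survival trajectory for one patient
#'
#' For each landmark where the patient is at risk and their biomarkers are
#' resolvable by carry-forward, computes the conditional w-year survival
#' probability; optionally also the within-window survival curve
#' `S(t | s) = exp(-(H0(t) - H0(s)) exp(lp))`, which always starts at 1 at
#' the window opening.
#'
#' @param object a `"dyncox"` fit.
#' @param patient one-row data frame with the raw baseline covariates
#'   (`age`, `sex`, `weight`) and optionally `time_years` to stop the
#'   trajectory at the end of follow-up.
#' @param measurements the patient's raw measurement rows.
#' @param w prediction window.
#' @param curves if `TRUE`, attach the within-window survival curves.
#' @return A data frame `(landmark, surv)`; with `curves = TRUE` an
#'   attribute `"curves"` holds one `(time, surv)` data frame per landmark.
#' @export
individual_trajectory <- function(object, patient, measurements,
                                  w = object$grid$w, curves = FALSE) {
  spec <- object$spec
  measurements <- measurements[order(measurements$obstime), , drop = FALSE]
  tmax <- if (!is.null(patient$time_years)) patient$time_years else Inf
  base <- apply_scaling(patient, spec)
  long_names <- spec_roles(spec, "longitudinal")
  pts <- object$grid$points[object$grid$points < tmax]
  out <- list(); cv <- list()
  for (s in pts) {
    z <- as.list(base[1, , drop = FALSE])
    ok <- TRUE
    for (b in long_names) {
      val <- covariate_at(measurements, s, b)
      if (is.na(val)) { ok <- FALSE; break }
      z[[b]] <- val / spec$divisor[spec$name == b]
    }
    if (!ok) next
    sv <- predict_dynamic_survival(object, z, s, w)
    out[[length(out) + 1L]] <- data.frame(landmark = s, surv = sv)
    if (curves) {
      bh <- object$baseline
      tt <- bh$event_times[bh$event_times > s & bh$event_times <= s + w]
      H <- cumhaz_at(bh, tt) - cumhaz_at(bh, s)
      lp <- dyncox_lp(object, z, s)
      cv[[length(cv) + 1L]] <- data.frame(time = c(s, tt),
                                          surv = c(1, exp(-H * exp(lp))))
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(landmark = numeric(0), surv = numeric(0))
  if (curves) attr(res, "curves") <- cv
  res
}

#' Dynamic hazard ratio curve for one covariate
#'
#' Evaluates `HR^w(s) = exp(b0 + b1*u + b2*u^2)` with
#' `u = (s - s0)/(sL - s0)` from the covariate's fitted effect-function
#' coefficients, with pointwise 95\% confidence intervals
#' `exp(g +/- 1.96 sqrt(c' V c))` from the (robust, by default) covariance
#' block.
#'
#' @param object a `"dyncox"` fit.
#' @param covariate covariate name in the basis specification.
#' @param s landmark times (default: the fitted grid).
#' @param se which covariance to use for the interval.
#' @return An object of class `"dynamic_hr"`: a data frame
#'   `(s, hr, lower, upper)` with the covariate name as attribute.
#' @export
dynamic_hr <- function(object, covariate, s = object$grid$points,
                       se = c("robust", "model")) {
  se <- match.arg(se)
  if (!covariate %in% names(object$basis$degrees)) {
    stop("covariate '", covariate, "' is not in the fitted model")
  }
  d <- object$basis$degrees[[covariate]]
  nms <- block_names(covariate, d)
  b <- object$coefficients[nms]
  V <- (if (se == "robust") object$rvar else object$var)[nms, nms,
                                                         drop = FALSE]
  u <- (s - object$grid$s0) / (object$grid$sL - object$grid$s0)
  cmat <- outer(u, 0:d, `^`)
  g <- drop(cmat %*% b)
  v <- rowSums((cmat %*% V) * cmat)
  out <- data.frame(s = s, hr = exp(g),
                    lower = exp(g - 1.96 * sqrt(v)),
                    upper = exp(g + 1.96 * sqrt(v)))
  attr(out, "covariate") <- covariate
  class(out) <- c("dynamic_hr", "data.frame")
  out
}

#' Evaluate a polynomial log hazard-ratio at given landmark times
#'
#' Convenience for desk calculations: `exp(b0 + b1*u + ...)` with
#' `u = s / span`.
#'
#' @param coefs coefficient vector `(b0, b1, ...)`.
#' @param s landmark time(s).
#' @param span standardization span `sL - s0` (default 10 years).
#' @return Hazard ratios.
#' @examples
#' hazard_ratio_poly(c(0.256, -1.498), 0) # 1.292
#' @export
hazard_ratio_poly <- function(coefs, s, span = 10) {
  exp(poly_eval(coefs, s / span))
}

#' Plot dynamic hazard-ratio curves
#'
#' @param x a `"dyncox"` fit.
#' @param covariates covariates to plot (default: all with degree >= 1).
#' @param ... passed to [graphics::plot()].
#' @export
plot.dyncox <- function(x, covariates = NULL, ...) {
  if (is.null(covariates)) {
    covariates <- names(x$basis$degrees)[x$basis$degrees >= 1]
  }
  old <- graphics::par(mfrow = c(1, length(covariates)))
  on.exit(graphics::par(old))
  for (k in covariates) {
    hr <- dynamic_hr(x, k)
    graphics::plot(hr$s, hr$hr, type = "l", ylim = range(hr$lower, hr$upper),
                   xlab = "landmark time (years)", ylab = "hazard ratio",
                   main = k, ...)
    graphics::lines(hr$s, hr$lower, lty = 2)
    graphics::lines(hr$s, hr$upper, lty = 2)
    graphics::abline(h = 1, col = "grey")
  }
  invisible(x)
}

#' Static baseline Cox model comparator
#'
#' Ordinary Cox model on the baseline values of all covariates (baseline
#' covariates plus the biomarker values carried forward to time 0), with
#' its own Breslow baseline hazard for conditional prediction.
#'
#' @inheritParams dyncox
#' @return An object of class `"static_cox"`.
#' @export
static_cox <- function(cohort, measurements, spec = covariate_specs()) {
  validate_cohort(cohort)
  measurements <- measurements[order(measurements$id, measurements$obstime), ,
                               drop = FALSE]
  loc <- locf_rows(measurements, 0)
  long_names <- spec_roles(spec, "longitudinal")
  base_names <- spec_roles(spec, "baseline")
  df <- cohort[, c("id", "time_years", "event", base_names)]
  for (nm in long_names) df[[nm]] <- loc[[nm]][match(df$id, loc$id)]
  keep <- stats::complete.cases(df[, long_names, drop = FALSE])
  df <- df[keep, , drop = FALSE]
  df <- apply_scaling(df, spec)
  x <- as.matrix(df[, c(base_names, long_names)])
  fit <- cox_partial_fit(x, entry = rep(0, nrow(df)), exit = df$time_years,
                         status = df$event, cluster = df$id)
  bh <- breslow_baseline(fit, rep(0, nrow(df)), df$time_years, df$event)
  structure(list(coefficients = fit$coefficients, var = fit$var,
                 rvar = fit$rvar, baseline = bh, spec = spec, cox = fit,
                 covariates = c(base_names, long_names),
                 n = fit$n, nevent = fit$nevent, call = match.call()),
            class = "static_cox")
}

#' @export
print.static_cox <- function(x, digits = 4, ...) {
  cat("Static baseline Cox model\n")
  cat(sprintf("  subjects: %d, events: %d\n", x$n, x$nevent))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.static_cox <- function(object, ...) object$coefficients

#' @export
vcov.static_cox <- function(object, type = c("model", "robust"), ...) {
  type <- match.arg(type)
  if (type == "model") object$var else object$rvar
}

#' Conditional survival from the static baseline model
#'
#' `S(s + w | s, z0) = S(s + w; z0) / S(s; z0)` with the static fit's own
#' baseline hazard and the baseline covariate vector `z0` held fixed.
#'
#' @param object a `"static_cox"` fit.
#' @param z0 data frame/list of scaled baseline covariate values.
#' @param s landmark time(s).
#' @param w prediction window.
#' @return Conditional survival probabilities.
#' @export
predict_static_conditional <- function(object, z0, s, w) {
  x <- as.matrix(as.data.frame(z0)[, object$covariates, drop = FALSE])
  lp <- drop(x %*% object$coefficients)
  dH <- cumhaz_at(object$baseline, s + w) - cumhaz_at(object$baseline, s)
  unname(exp(-dH * exp(lp)))
}
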