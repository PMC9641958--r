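#' Harrell's concordance index
#'
#' Fraction of comparable subject pairs whose predicted risks are
#' concordant with their observed survival ordering. A pair is comparable
#' iff the smaller observed time is an event (pairs with equal times are
#' comparable when exactly one is an event). Tied risks count 1/2.
#'
#' @param risk numeric risk scores (higher = higher predicted risk).
#' @param times observed times.
#' @param status event indicators in 0/1.
#' @return The C-index in \[0, 1\].
#' @examples
#' harrell_c(c(0.9, 0.5, 0.7), c(1, 2, 3), c(1, 1, 1)) # 2/3
#' @export
harrell_c <- function(risk, times, status) {
  n <- length(risk)
  stopifnot(length(times) == n, length(status) == n)
  comp <- 0; conc <- 0
  # i indexes the earlier event of the pair
  for (i in which(status == 1)) {
    later <- times > times[i] | (times == times[i] & status == 0)
    later[i] <- FALSE
    if (!any(later)) next
    comp <- comp + sum(later)
    conc <- conc + sum(risk[i] > risk[later]) + 0.5 * sum(risk[i] == risk[later])
  }
  if (comp == 0) stop("no comparable pairs")
  conc / comp
}

# left limit G(t-) of a censoring Kaplan-Meier curve
km_at_left <- function(km, t) {
  c(1, km$surv)[findInterval(t, km$times, left.open = TRUE) + 1L]
}

#' Inverse-probability-of-censoring-weighted Brier score
#'
#' Mean squared difference between the predicted event probability by
#' `horizon` and the observed outcome, with weights from the Kaplan-Meier
#' estimate of the censoring distribution on the evaluation set: subjects
#' with an event by the horizon get weight `1/G(T-)`, subjects observed
#' beyond the horizon get `1/G(horizon-)`, and subjects censored before the
#' horizon (outcome unknown) get weight 0. With no censoring the weights
#' are all 1 and the score is the plain mean squared error.
#'
#' @param pred_surv predicted survival probabilities at the horizon.
#' @param times observed times.
#' @param status event indicators in 0/1.
#' @param horizon evaluation horizon (same time origin as `times`).
#' @return The IPCW Brier score.
#' @export
brier_ipcw <- function(pred_surv, times, status, horizon) {
  n <- length(pred_surv)
  stopifnot(length(times) == n, length(status) == n)
  if (any(pred_surv < -1e-12 | pred_surv > 1 + 1e-12)) {
    stop("predictions must be probabilities in [0, 1]")
  }
  cens_km <- kaplan_meier(times, 1 - status)
  pred_event <- 1 - pred_surv
  is_event <- status == 1 & times <= horizon
  is_surv <- times >= horizon & !(status == 1 & times <= horizon)
  g_surv <- km_at_left(cens_km, horizon)
  wts <- numeric(n)
  if (any(is_event)) {
    g_ev <- km_at_left(cens_km, times[is_event])
    if (any(g_ev <= 0)) stop("inestimable weights: censoring survival reaches 0")
    wts[is_event] <- 1 / g_ev
  }
  if (any(is_surv)) {
    if (g_surv <= 0) stop("inestimable weights: censoring survival reaches 0")
    wts[is_surv] <- 1 / g_surv
  }
  err <- numeric(n)
  err[is_event] <- (1 - pred_event[is_event])^2
  err[is_surv] <- (0 - pred_event[is_surv])^2
  mean(wts * err)
}

#' Per-landmark discrimination and calibration of fitted models
#'
#' At each landmark `s` of the grid, builds the landmark dataset from the
#' evaluation subjects, computes each model's predicted w-year survival
#' (risk = 1 - survival), and evaluates Harrell's C-index within the
#' administratively censored window and the IPCW Brier score at horizon
#' `s + w`. Landmarks with fewer than 2 subjects, no comparable pairs, or
#' inestimable censoring weights are recorded as `NA` and excluded from
#' the cross-landmark means.
#'
#' @param dynamic_fit a [dyncox()] fit (or `NULL` to skip).
#' @param static_fit a [static_cox()] fit (or `NULL` to skip).
#' @param cohort,measurements evaluation data (subjects disjoint from the
#'   training subjects for honest assessment).
#' @param grid a [landmark_grid()]; defaults to the dynamic fit's grid.
#' @param w prediction window; defaults to the grid's.
#' @return An object of class `"metric_curve"`: a data frame
#'   `(model, metric, window, landmark, value)` with an `"overall"`
#'   attribute holding the cross-landmark means.
#' @export
evaluate_per_landmark <- function(dynamic_fit = NULL, static_fit = NULL,
                                  cohort, measurements,
                                  grid = dynamic_fit$grid, w = grid$w) {
  spec <- if (!is.null(dynamic_fit)) dynamic_fit$spec else static_fit$spec
  measurements <- measurements[order(measurements$id, measurements$obstime), ,
                               drop = FALSE]
  long_names <- spec_roles(spec, "longitudinal")
  base_names <- spec_roles(spec, "baseline")

  # baseline (s = 0) covariates for the static model, computed once
  z0 <- NULL
  if (!is.null(static_fit)) {
    loc0 <- locf_rows(measurements, 0)
    z0 <- cohort[, c("id", base_names)]
    for (nm in long_names) z0[[nm]] <- loc0[[nm]][match(z0$id, loc0$id)]
    z0 <- apply_scaling(z0, spec)
  }

  rows <- list()
  for (s in grid$points) {
    rl <- suppressWarnings(
      build_landmark_dataset(cohort, measurements, s, w, spec))
    add <- function(model, metric, value) {
      rows[[length(rows) + 1L]] <<- data.frame(
        model = model, metric = metric, window = w, landmark = s,
        value = value)
    }
    eval_one <- function(model, risk, pred_surv) {
      cval <- if (nrow(rl) >= 2) {
        tryCatch(harrell_c(risk, rl$exit, rl$status),
                 error = function(e) NA_real_)
      } else NA_real_
      bval <- if (nrow(rl) >= 2) {
        tryCatch(brier_ipcw(pred_surv, rl$exit, rl$status, s + w),
                 error = function(e) NA_real_)
      } else NA_real_
      add(model, "cindex", cval)
      add(model, "brier", bval)
    }
    if (!is.null(dynamic_fit) && nrow(rl)) {
      sd_ <- predict_dynamic_survival(dynamic_fit, rl, s, w)
      eval_one("dynamic", 1 - sd_, sd_)
    } else if (!is.null(dynamic_fit)) {
      eval_one("dynamic", numeric(0), numeric(0))
    }
    if (!is.null(static_fit) && nrow(rl)) {
      zr <- z0[match(rl$id, z0$id), , drop = FALSE]
      ss <- predict_static_conditional(static_fit, zr, s, w)
      eval_one("static", 1 - ss, ss)
    } else if (!is.null(static_fit)) {
      eval_one("static", numeric(0), numeric(0))
    }
  }
  out <- do.call(rbind, rows)
  overall <- stats::aggregate(value ~ model + metric, data = out, FUN = mean,
                              na.rm = TRUE, na.action = stats::na.pass)
  attr(out, "overall") <- overall
  attr(out, "window") <- w
  class(out) <- c("metric_curve", "data.frame")
  out
}

#' @export
print.metric_curve <- function(x, ...) {
  cat(sprintf("Per-landmark prediction metrics (window w = %g years)\n",
              attr(x, "window")))
  print(attr(x, "overall"))
  invisible(x)
}

#' Cross-landmark mean of a metric curve
#'
#' @param x a `"metric_curve"`.
#' @param model,metric selectors.
#' @return The mean over landmarks, `NA` cells excluded.
#' @export
overall_mean <- function(x, model, metric) {
  ov <- attr(x, "overall")
  ov$value[ov$model == model & ov$metric == metric]
}

#' Monte Carlo cross-validation plan
#'
#' @param iterations number of random train/test splits (default 200).
#' @param train_frac fraction of subjects in the training set, strictly
#'   between 0 and 1 (default 2/3); splits are by subject, never by
#'   stacked row.
#' @param seed integer seed making the whole procedure deterministic.
#' @return An object of class `"cv_plan"`.
#' @export
cv_plan <- function(iterations = 200, train_frac = 2 / 3, seed = 1) {
  if (iterations < 1) stop("iterations must be >= 1")
  if (train_frac <= 0 || train_frac >= 1) {
    stop("train_frac must be strictly between 0 and 1")
  }
  structure(list(iterations = iterations, train_frac = train_frac,
                 seed = seed), class = "cv_plan")
}

#' Monte Carlo cross-validation of dynamic and static models
#'
#' Repeatedly splits subjects into training and test sets, fits the dynamic
#' super-model and the static baseline model on the training subjects, and
#' evaluates both per landmark on the test subjects. Reports per-landmark
#' means over iterations and the overall cross-landmark means. Iterations
#' whose training set cannot be fitted are skipped (an error is raised if
#' more than 10\% are skipped).
#'
#' @param cohort,measurements full data set.
#' @param grid a [landmark_grid()].
#' @param basis a [basis_spec()].
#' @param spec a [covariate_specs()].
#' @param plan a [cv_plan()].
#' @return A list of class `"mc_cv"` with `per_landmark` (mean metric per
#'   model/metric/landmark over iterations), `overall` (cross-landmark
#'   means), `n_skipped`, `plan`.
#' @export
monte_carlo_cv <- function(cohort, measurements, grid = landmark_grid(),
                           basis = basis_spec(), spec = covariate_specs(),
                           plan = cv_plan()) {
  set.seed(plan$seed)
  ids <- cohort$id
  n_train <- floor(plan$train_frac * length(ids))
  if (n_train < 1 || n_train >= length(ids)) {
    stop("train_frac leaves an empty training or test set")
  }
  acc <- list(); skipped <- 0L
  for (it in seq_len(plan$iterations)) {
    train_ids <- sample(ids, n_train)
    tr_c <- cohort[cohort$id %in% train_ids, , drop = FALSE]
    te_c <- cohort[!cohort$id %in% train_ids, , drop = FALSE]
    tr_m <- measurements[measurements$id %in% train_ids, , drop = FALSE]
    te_m <- measurements[!measurements$id %in% train_ids, , drop = FALSE]
    fits <- tryCatch({
      list(dyn = dyncox(tr_c, tr_m, grid, basis, spec),
           sta = static_cox(tr_c, tr_m, spec))
    }, error = function(e) {
      message("iteration ", it, " skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(fits)) { skipped <- skipped + 1L; next }
    mc <- evaluate_per_landmark(fits$dyn, fits$sta, te_c, te_m, grid, grid$w)
    mc$iteration <- it
    acc[[length(acc) + 1L]] <- as.data.frame(mc)
  }
  if (skipped > 0.1 * plan$iterations) {
    stop(skipped, " of ", plan$iterations, " iterations failed to fit")
  }
  all_rows <- do.call(rbind, acc)
  per_landmark <- stats::aggregate(value ~ model + metric + window + landmark,
                                   data = all_rows, FUN = mean, na.rm = TRUE,
                                   na.action = stats::na.pass)
  overall <- stats::aggregate(value ~ model + metric, data = per_landmark,
                              FUN = mean, na.rm = TRUE,
                              na.action = stats::na.pass)
  structure(list(per_landmark = per_landmark, overall = overall,
                 n_skipped = skipped, plan = plan),
            class = "mc_cv")
}

#' @export
print.mc_cv <- function(x, ...) {
  cat(sprintf("Monte Carlo cross-validation: %d iterations (%d skipped)\n",
              x$plan$iterations, x$n_skipped))
  print(x$overall)
  invisible(x)
}
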