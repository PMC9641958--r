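# Reproducible pipeline commands: simulate / fit / predict / evaluate /
# report, driven by a serializable configuration list.

#' Build a run configuration
#'
#' A plain serializable list controlling the pipeline commands. Every run
#' echoes its effective configuration as YAML into the output directory and
#' appends to `run.log` there.
#'
#' @param out_dir output directory (created if needed).
#' @param cohort,longitudinal input CSV paths (for fit/evaluate/predict).
#' @param model path of the fitted-model YAML (written by `fit`, read by
#'   `predict`/`report`).
#' @param grid list `(s0, sL, spacing, w)`.
#' @param basis list `(degrees, theta_degree)`.
#' @param n,seed simulation size and seed.
#' @param iterations,train_frac Monte Carlo cross-validation settings.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(out_dir = ".",
                       cohort = file.path(out_dir, "cohort.csv"),
                       longitudinal = file.path(out_dir, "longitudinal.csv"),
                       model = file.path(out_dir, "model.yaml"),
                       grid = list(s0 = 0, sL = 10, spacing = 0.25, w = 5),
                       basis = list(degrees = c(age = 0, weight = 0,
                                                hematocrit = 1, gfr = 1,
                                                proteinuria = 2),
                                    theta_degree = 2),
                       n = 407, seed = 1,
                       iterations = 200, train_frac = 2 / 3) {
  structure(list(out_dir = out_dir, cohort = cohort,
                 longitudinal = longitudinal, model = model,
                 grid = grid, basis = basis, n = n, seed = seed,
                 iterations = iterations, train_frac = train_frac),
            class = "run_config")
}

config_grid <- function(config) {
  do.call(landmark_grid, config$grid)
}

config_basis <- function(config) {
  basis_spec(unlist(config$basis$degrees), config$basis$theta_degree)
}

write_atomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

run_log <- function(config, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
  message(msg)
  cat(msg, "\n", file = file.path(config$out_dir, "run.log"), append = TRUE)
}

#' Serialize / restore a fitted dynamic Cox model as YAML
#'
#' Stores coefficients, both covariances, the Breslow baseline hazard table
#' and the grid/basis/scaling configuration in plain text, sufficient to
#' reproduce predictions exactly.
#'
#' @param object a `"dyncox"` fit.
#' @param path YAML file path.
#' @export
write_dyncox <- function(object, path) {
  payload <- list(
    coefficients = as.list(object$coefficients),
    var = apply(object$var, 1, as.list),
    rvar = apply(object$rvar, 1, as.list),
    baseline = list(event_times = object$baseline$event_times,
                    increments = object$baseline$increments),
    grid = object$grid[c("s0", "sL", "spacing", "w")],
    basis = list(degrees = as.list(object$basis$degrees),
                 theta_degree = object$basis$theta_degree),
    n = object$n, nevent = object$nevent, n_subjects = object$n_subjects)
  yaml::write_yaml(payload, path, precision = 17)
  invisible(path)
}

#' @rdname write_dyncox
#' @export
read_dyncox <- function(path) {
  p <- yaml::read_yaml(path)
  cf <- unlist(p$coefficients)
  nm <- names(cf)
  vm <- matrix(unlist(p$var), length(nm), length(nm), byrow = TRUE,
               dimnames = list(nm, nm))
  rv <- matrix(unlist(p$rvar), length(nm), length(nm), byrow = TRUE,
               dimnames = list(nm, nm))
  inc <- as.numeric(unlist(p$baseline$increments))
  bh <- structure(list(event_times = as.numeric(unlist(p$baseline$event_times)),
                       increments = inc, cumulative = cumsum(inc)),
                  class = "breslow_hazard")
  structure(list(coefficients = cf, var = vm, rvar = rv, baseline = bh,
                 grid = do.call(landmark_grid, p$grid),
                 basis = basis_spec(unlist(p$basis$degrees),
                                    p$basis$theta_degree),
                 spec = covariate_specs(),
                 cox = NULL, n = p$n, nevent = p$nevent,
                 n_subjects = p$n_subjects),
            class = "dyncox")
}

#' Run a pipeline command
#'
#' Commands: `"simulate"` writes a synthetic cohort, longitudinal table and
#' a `truth.yaml` sidecar; `"fit"` fits the dynamic super-model and the
#' static comparator and writes the model YAML plus a coefficient report;
#' `"predict"` scores one subject's measurement file per landmark;
#' `"evaluate"` runs Monte Carlo cross-validation and writes tidy metric
#' CSVs; `"report"` writes a coefficient text table and a dynamic-HR CSV
#' over the grid. All artifacts are written atomically and the effective
#' configuration is echoed to the output directory.
#'
#' @param command one of simulate, fit, predict, evaluate, report.
#' @param config a [run_config()].
#' @param subject for `predict`: path of the subject's measurements CSV;
#'   a `subject_baseline` CSV path (1-row cohort-format table) is also
#'   required.
#' @param subject_baseline see `subject`.
#' @return Invisibly, a character vector of the artifact paths written.
#' @export
run <- function(command = c("simulate", "fit", "predict", "evaluate",
                            "report"),
                config = run_config(), subject = NULL,
                subject_baseline = NULL) {
  command <- match.arg(command)
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  write_atomic(function(f) yaml::write_yaml(unclass(config), f),
               file.path(config$out_dir, "config.yaml"))
  artifacts <- file.path(config$out_dir, "config.yaml")

  if (command == "simulate") {
    sim <- simulate_cohort(sim_params(n_subjects = config$n,
                                      seed = config$seed))
    write_atomic(function(f) write_cohort(sim$cohort, f), config$cohort)
    write_atomic(function(f) write_longitudinal(sim$measurements, f),
                 config$longitudinal)
    truth_path <- file.path(config$out_dir, "truth.yaml")
    write_atomic(function(f) yaml::write_yaml(
      list(effects = lapply(sim$truth$effects, as.numeric),
           baseline_hazard_rate = sim$truth$baseline_hazard_rate,
           time_scale_span = sim$truth$time_scale_span), f), truth_path)
    run_log(config, "simulate: n=", config$n, " seed=", config$seed,
            " events=", sum(sim$cohort$event))
    artifacts <- c(artifacts, config$cohort, config$longitudinal, truth_path)
  } else if (command == "fit") {
    cohort <- read_cohort(config$cohort)
    meas <- read_longitudinal(config$longitudinal, cohort = cohort)
    fit <- dyncox(cohort, meas, config_grid(config), config_basis(config))
    write_atomic(function(f) write_dyncox(fit, f), config$model)
    rep_path <- file.path(config$out_dir, "coefficients.csv")
    s <- summary(fit)
    write_atomic(function(f) utils::write.csv(
      cbind(term = rownames(s$table), s$table), f, row.names = FALSE),
      rep_path)
    run_log(config, "fit: rows=", fit$n, " events=", fit$nevent,
            " subjects=", fit$n_subjects)
    artifacts <- c(artifacts, config$model, rep_path)
  } else if (command == "predict") {
    if (is.null(subject) || is.null(subject_baseline)) {
      stop("predict requires 'subject' and 'subject_baseline' CSV paths")
    }
    fit <- read_dyncox(config$model)
    pat <- utils::read.csv(subject_baseline, stringsAsFactors = FALSE)
    meas <- utils::read.csv(subject, stringsAsFactors = FALSE)
    traj <- individual_trajectory(fit, pat[1, , drop = FALSE], meas)
    out_path <- file.path(config$out_dir, "prediction.csv")
    write_atomic(function(f) utils::write.csv(traj, f, row.names = FALSE),
                 out_path)
    run_log(config, "predict: ", nrow(traj), " landmarks")
    artifacts <- c(artifacts, out_path)
  } else if (command == "evaluate") {
    cohort <- read_cohort(config$cohort)
    meas <- read_longitudinal(config$longitudinal, cohort = cohort)
    cv <- monte_carlo_cv(cohort, meas, config_grid(config),
                         config_basis(config),
                         plan = cv_plan(config$iterations, config$train_frac,
                                        config$seed))
    m_path <- file.path(config$out_dir, "metrics.csv")
    s_path <- file.path(config$out_dir, "metrics_summary.csv")
    write_atomic(function(f) utils::write.csv(cv$per_landmark, f,
                                              row.names = FALSE), m_path)
    write_atomic(function(f) utils::write.csv(cv$overall, f,
                                              row.names = FALSE), s_path)
    run_log(config, "evaluate: ", config$iterations, " iterations, ",
            cv$n_skipped, " skipped")
    artifacts <- c(artifacts, m_path, s_path)
  } else if (command == "report") {
    fit <- read_dyncox(config$model)
    hr_path <- file.path(config$out_dir, "dynamic_hr.csv")
    dyn_cov <- names(fit$basis$degrees)
    hr_tab <- do.call(rbind, lapply(dyn_cov, function(k) {
      h <- dynamic_hr(fit, k)
      cbind(covariate = k, as.data.frame(h))
    }))
    write_atomic(function(f) utils::write.csv(hr_tab, f, row.names = FALSE),
                 hr_path)
    txt_path <- file.path(config$out_dir, "model_report.txt")
    write_atomic(function(f) {
      con <- file(f, "w")
      on.exit(close(con))
      writeLines(c("Dynamic Cox landmark super-model",
                   sprintf("stacked rows: %d  events: %d  subjects: %d",
                           fit$n, fit$nevent, fit$n_subjects),
                   utils::capture.output(print(
                     data.frame(coef = fit$coefficients,
                                `se(robust)` = sqrt(diag(fit$rvar)),
                                check.names = FALSE)))), con)
    }, txt_path)
    run_log(config, "report written")
    artifacts <- c(artifacts, hr_path, txt_path)
  }
  invisible(artifacts)
}
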