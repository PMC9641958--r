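test_that("basis expansion builds the polynomial design in u", {
  g <- landmark_grid(0, 10, 0.25, 5)
  x <- expand_basis(list(z = 1), 4, g, basis_spec(c(z = 1), theta_degree = 0))
  expect_equal(unname(drop(x)), c(1, 0.4))
  x2 <- expand_basis(list(z = 2), 5, g, basis_spec(c(z = 2), theta_degree = 0))
  expect_equal(unname(drop(x2)), c(2, 1.0, 0.5))
  # at s = s0, all interaction and theta columns vanish
  x3 <- expand_basis(list(z = 3), 0, g, basis_spec(c(z = 2), theta_degree = 2))
  expect_equal(unname(drop(x3)), c(3, 0, 0, 0, 0))
  expect_equal(colnames(x3), c("z", "z:u", "z:u^2", "theta:u", "theta:u^2"))
  expect_error(expand_basis(list(a = 1), 0, g, basis_spec(c(z = 0))),
               "absent")
})

test_that("the super-model collapses to a plain Cox fit on one landmark", {
  sim <- simulate_cohort(sim_params(n_subjects = 200, seed = 14,
                                    baseline_hazard_rate = 0.08))
  g <- landmark_grid(0, 10, 0.25, 100) # window covers all follow-up
  r0 <- build_landmark_dataset(sim$cohort, sim$measurements, 0, g$w)
  stacked0 <- r0
  attr(stacked0, "grid") <- g
  attr(stacked0, "spec") <- covariate_specs()
  class(stacked0) <- c("landmark_stack", "data.frame")
  degs <- c(age = 0, sex = 0, weight = 0, hematocrit = 0, proteinuria = 0,
            gfr = 0)
  dfit <- dyncox(stacked = stacked0, basis = basis_spec(degs,
                                                        theta_degree = 0))
  sfit <- static_cox(sim$cohort, sim$measurements)
  expect_equal(dfit$coefficients[names(sfit$coefficients)],
               sfit$coefficients, tolerance = 1e-7)
  # and their conditional predictions coincide
  z <- as.list(stacked0[3, ])
  expect_equal(predict_dynamic_survival(dfit, z, 0, 5),
               unname(predict_static_conditional(sfit, z, 0, 5)),
               tolerance = 1e-7)
})

test_that("conditional survival follows the Breslow window integral", {
  fit <- toy_dyncox()
  # w = 0: empty integral
  expect_equal(predict_dynamic_survival(fit, list(z = 1.3), 2, 0), 1.0)
  # z = 0 (lp = 0), both increments in (0, 3]
  expect_equal(predict_dynamic_survival(fit, list(z = 0), 0, 3),
               exp(-(1 / (2 + sqrt(2)) + 1 / (1 + sqrt(2)))),
               tolerance = 1e-6)
  # single increment of 0.1 at lp = 0
  fit2 <- toy_dyncox(beta = 0, event_times = 1, increments = 0.1)
  expect_equal(predict_dynamic_survival(fit2, list(z = 5), 0.5, 1), exp(-0.1))
  expect_error(predict_dynamic_survival(fit, list(z = 0), 11, 5),
               "outside the fitted grid")
})

test_that("predicted survival is monotone in the window and in risk", {
  fit <- toy_dyncox()
  ws <- c(0, 0.5, 1, 1.5, 2, 3)
  sv <- vapply(ws, function(w) predict_dynamic_survival(fit, list(z = 1),
                                                        0, w), numeric(1))
  expect_true(all(diff(sv) <= 1e-12))
  expect_true(all(sv >= 0 & sv <= 1))
  # higher covariate value with a positive coefficient -> lower survival
  zs <- seq(-2, 2, by = 0.5)
  sv2 <- vapply(zs, function(z) predict_dynamic_survival(fit, list(z = z),
                                                         0, 3), numeric(1))
  expect_true(all(diff(sv2) < 0))
})

test_that("individual trajectories start at 1 within each window", {
  sim <- simulate_cohort(sim_params(n_subjects = 250, seed = 15,
                                    baseline_hazard_rate = 0.08))
  fit <- dyncox(sim$cohort, sim$measurements)
  pat <- sim$cohort[3, , drop = FALSE]
  pm <- sim$measurements[sim$measurements$id == pat$id, ]
  tr <- individual_trajectory(fit, pat, pm, curves = TRUE)
  expect_true(nrow(tr) >= 1)
  expect_true(all(tr$landmark < pat$time_years))
  expect_true(all(tr$surv >= 0 & tr$surv <= 1))
  for (cv in attr(tr, "curves")) {
    expect_equal(cv$surv[1], 1)
    expect_true(all(diff(cv$surv) <= 1e-12))
  }
  # patient with no resolvable covariates yields an empty trajectory
  none <- individual_trajectory(fit, pat, pm[0, ])
  expect_equal(nrow(none), 0)
})

test_that("dynamic hazard ratios follow the fitted effect polynomial", {
  expect_equal(hazard_ratio_poly(c(0.256, -1.498), 0), exp(0.256))
  expect_equal(hazard_ratio_poly(c(0, log(2)), 10), 2)
  fit <- toy_dyncox(beta = 0)
  hr <- dynamic_hr(fit, "z", s = c(0, 5, 10))
  expect_equal(hr$hr, c(1, 1, 1))
  expect_true(all(hr$lower <= hr$hr & hr$hr <= hr$upper))
  expect_error(dynamic_hr(fit, "nope"), "not in the fitted model")
})

test_that("constant effects are recovered with a degree-0 basis", {
  p <- sim_params(n_subjects = 2000, seed = 33,
                  effects = list(gfr = -0.5), baseline_hazard_rate = 0.12)
  sim <- simulate_cohort(p)
  fit <- dyncox(sim$cohort, sim$measurements,
                grid = landmark_grid(0, 10, 0.25, w = 0.25),
                basis = basis_spec(c(gfr = 0), theta_degree = 0))
  se <- sqrt(diag(fit$rvar))
  expect_lt(abs(fit$coefficients[["gfr"]] - (-0.5)), 2 * se[["gfr"]])
})

test_that("a decaying time-varying effect is recovered within 2 SE", {
  p <- sim_params(
    n_subjects = 2000, seed = 34,
    trajectories = list(
      hematocrit = c(int_mean = 29.51, int_sd = 6.2, slope_mean = 0,
                     slope_sd = 0.5, resid_sd = 0.5),
      proteinuria = c(int_mean = 2.41, int_sd = 2.2, slope_mean = 0,
                      slope_sd = 0.25, resid_sd = 0.6),
      gfr = c(int_mean = 8.91, int_sd = 5, slope_mean = 0, slope_sd = 0.7,
              resid_sd = 1.2)),
    effects = list(hematocrit = c(0.3, -1.5)),
    baseline_hazard_rate = 0.12)
  sim <- simulate_cohort(p)
  fit <- dyncox(sim$cohort, sim$measurements,
                grid = landmark_grid(0, 10, 0.25, w = 0.25),
                basis = basis_spec(c(hematocrit = 1), theta_degree = 0))
  se <- sqrt(diag(fit$rvar))
  expect_lt(abs(fit$coefficients[["hematocrit"]] - 0.3),
            2 * se[["hematocrit"]])
  expect_lt(abs(fit$coefficients[["hematocrit:u"]] - (-1.5)),
            2 * se[["hematocrit:u"]])
})

test_that("static conditional predictions behave at the boundaries", {
  sim <- simulate_cohort(sim_params(n_subjects = 250, seed = 16,
                                    baseline_hazard_rate = 0.08))
  sfit <- static_cox(sim$cohort, sim$measurements)
  z0 <- as.data.frame(as.list(stats::setNames(rep(0, 6), sfit$covariates)))
  # lp = 0 -> prediction is the baseline-hazard-only conditional survival
  H <- sfit$baseline
  s5 <- predict_static_conditional(sfit, z0, 0, 5)
  expect_equal(s5, exp(-sum(H$increments[H$event_times <= 5])))
  # non-increasing in w at fixed s
  sv <- vapply(c(1, 2, 5, 8), function(w)
    predict_static_conditional(sfit, z0, 1, w), numeric(1))
  expect_true(all(diff(sv) <= 1e-12))
  # s = 0 is the ordinary w-year prediction: S(0) = 1
  expect_equal(predict_static_conditional(sfit, z0, 0, 0), 1)
})

test_that("summaries and methods expose the fit consistently", {
  sim <- simulate_cohort(sim_params(n_subjects = 200, seed = 17,
                                    baseline_hazard_rate = 0.08))
  fit <- dyncox(sim$cohort, sim$measurements)
  s <- summary(fit)
  expect_s3_class(s, "summary.dyncox")
  expect_equal(rownames(s$table), names(coef(fit)))
  expect_true(all(s$table$p >= 0 & s$table$p <= 1))
  expect_equal(dim(vcov(fit)), rep(length(coef(fit)), 2))
  expect_equal(nrow(residuals(fit)), fit$n_subjects)
  expect_output(print(fit), "Dynamic Cox landmark super-model")
})
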