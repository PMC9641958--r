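toy_design <- function() {
  list(x = matrix(c(0, 1, 0), ncol = 1, dimnames = list(NULL, "z")),
       entry = c(0, 0, 0), exit = c(1, 2, 3), status = c(1, 1, 0))
}

test_that("the 3-subject toy has the closed-form estimate ln(2)/2", {
  d <- toy_design()
  f <- cox_partial_fit(d$x, d$entry, d$exit, d$status)
  expect_equal(unname(f$coefficients), log(2) / 2, tolerance = 1e-6)
  expect_lt(f$grad_norm, 1e-8)
})

test_that("the fitter agrees with a 1-D likelihood-maximization oracle", {
  set.seed(99)
  compared <- 0L
  for (k in 1:50) {
    n <- sample(5:30, 1)
    entry <- ifelse(stats::runif(n) < 0.5, 0, stats::runif(n, 0, 0.5))
    exit <- entry + stats::rexp(n, 1)
    status <- stats::rbinom(n, 1, 0.7)
    if (!any(status == 1)) status[1] <- 1
    z <- stats::rnorm(n)
    b_oracle <- oracle_beta(z, entry, exit, status)
    # tiny samples can have a monotone partial likelihood (infinite MLE);
    # only instances with an interior maximum have a well-defined oracle
    if (abs(b_oracle) > 4.5) next
    f <- cox_partial_fit(matrix(z, ncol = 1), entry, exit, status)
    expect_equal(unname(f$coefficients), b_oracle, tolerance = 1e-6)
    compared <- compared + 1L
  }
  expect_gte(compared, 40L)
})

test_that("the fitter agrees with an independent implementation", {
  set.seed(5)
  n <- 60
  entry <- stats::runif(n, 0, 1)
  exit <- entry + stats::rexp(n)
  status <- stats::rbinom(n, 1, 0.6)
  x <- cbind(a = stats::rnorm(n), b = stats::rbinom(n, 1, 0.4))
  cl <- rep(1:30, each = 2)
  f <- cox_partial_fit(x, entry, exit, status, cluster = cl)
  ref <- survival::coxph(survival::Surv(entry, exit, status) ~ x +
                           survival::cluster(cl), ties = "breslow")
  expect_equal(unname(f$coefficients), unname(coef(ref)), tolerance = 1e-7)
  expect_equal(unname(f$var), unname(ref$naive.var), tolerance = 1e-6)
  expect_equal(unname(f$rvar), unname(ref$var), tolerance = 1e-6)
})

test_that("degenerate designs and event-free data are rejected", {
  d <- toy_design()
  same <- matrix(1, 3, 1, dimnames = list(NULL, "z"))
  expect_error(cox_partial_fit(same, d$entry, d$exit, d$status),
               "rank deficient")
  x2 <- cbind(d$x, z2 = 2 * d$x[, 1])
  expect_error(cox_partial_fit(x2, d$entry, d$exit, d$status), "z2")
  expect_error(cox_partial_fit(d$x, d$entry, d$exit, c(0, 0, 0)),
               "no events")
  expect_error(cox_partial_fit(d$x, c(0, 0, 3), d$exit, d$status),
               "entry < exit")
})

test_that("partial likelihood is invariant to replicating all rows", {
  d <- toy_design()
  f1 <- cox_partial_fit(d$x, d$entry, d$exit, d$status)
  idx <- rep(1:3, 2)
  f2 <- cox_partial_fit(d$x[idx, , drop = FALSE], d$entry[idx], d$exit[idx],
                        d$status[idx])
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
})

test_that("episode splitting does not change the fit", {
  set.seed(3)
  n <- 25
  exit <- stats::rexp(n, 0.5) + 0.1
  status <- stats::rbinom(n, 1, 0.7)
  z <- stats::rnorm(n)
  f1 <- cox_partial_fit(matrix(z, ncol = 1), rep(0, n), exit, status)
  # split each subject at half its follow-up into two contiguous episodes
  half <- exit / 2
  x2 <- matrix(rep(z, each = 2), ncol = 1)
  entry2 <- as.vector(rbind(0, half))
  exit2 <- as.vector(rbind(half, exit))
  status2 <- as.vector(rbind(0, status))
  f2 <- cox_partial_fit(x2, entry2, exit2, status2)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
})

test_that("Breslow baseline increments match hand computation on the toy", {
  d <- toy_design()
  f <- cox_partial_fit(d$x, d$entry, d$exit, d$status)
  bh <- breslow_baseline(f, d$entry, d$exit, d$status)
  expect_equal(bh$event_times, c(1, 2))
  expect_equal(bh$increments, c(1 / (2 + sqrt(2)), 1 / (1 + sqrt(2))),
               tolerance = 1e-6)
  expect_true(all(diff(bh$cumulative) > 0))
})

test_that("null-model Breslow hazard equals Nelson-Aalen exactly", {
  set.seed(11)
  n <- 40
  exit <- stats::rexp(n) + 0.05
  status <- stats::rbinom(n, 1, 0.6); status[1] <- 1
  bh <- breslow_baseline(fit = NULL, entry = rep(0, n), exit = exit,
                         status = status, linear_predictors = rep(0, n))
  taus <- sort(unique(exit[status == 1]))
  na_inc <- vapply(taus, function(t) {
    sum(status == 1 & exit == t) / sum(exit >= t)
  }, numeric(1))
  expect_identical(bh$increments, na_inc)
  # and no events -> empty hazard
  bh0 <- breslow_baseline(NULL, rep(0, 3), c(1, 2, 3), c(0, 0, 0),
                          linear_predictors = rep(0, 3))
  expect_length(bh0$increments, 0)
})

test_that("sandwich covariance is symmetric positive semi-definite", {
  set.seed(21)
  for (k in 1:5) {
    n <- 50
    entry <- stats::runif(n, 0, 0.3)
    exit <- entry + stats::rexp(n)
    status <- stats::rbinom(n, 1, 0.5); if (!any(status)) status[1] <- 1
    x <- cbind(a = stats::rnorm(n), b = stats::runif(n))
    f <- cox_partial_fit(x, entry, exit, status, cluster = rep(1:10, 5))
    expect_equal(f$rvar, t(f$rvar), tolerance = 1e-10)
    expect_true(all(eigen(f$rvar, symmetric = TRUE,
                          only.values = TRUE)$values > -1e-10))
    expect_equal(f$var, t(f$var), tolerance = 1e-10)
  }
})

test_that("Kaplan-Meier matches the hand-computed product limit", {
  km <- kaplan_meier(c(1, 1.5, 2, 3), c(1, 0, 1, 0))
  expect_equal(km_at(km, 2), 0.375) # (3/4) * (1/2)
  expect_equal(km_at(km, 1.4), 0.75)
  expect_equal(km_at(km, 0.5), 1)
  # all censored -> survival stays at 1
  km1 <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km1$surv == 1))
  # single subject with an event -> survival drops to 0
  km2 <- kaplan_meier(1, 1)
  expect_equal(km_at(km2, 1), 0)
  expect_error(kaplan_meier(numeric(0), numeric(0)), "empty")
  expect_error(kaplan_meier(c(0, 1), c(1, 1)), "positive")
})

test_that("Kaplan-Meier intervals contain the point estimate", {
  set.seed(6)
  km <- kaplan_meier(stats::rexp(80) + 0.01, stats::rbinom(80, 1, 0.7))
  ok <- !is.na(km$lower)
  expect_true(all(km$lower[ok] <= km$surv[ok] + 1e-12))
  expect_true(all(km$upper[ok] >= km$surv[ok] - 1e-12))
  expect_true(all(diff(km$surv) <= 0))
  expect_true(all(km$surv >= 0 & km$surv <= 1))
})
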