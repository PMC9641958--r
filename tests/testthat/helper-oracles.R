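# Independent oracles used across tests. These re-derive quantities by the
# most naive possible route (double loops, 1-D optimization) so that the
# vectorized implementations are checked against a separate code path.

# naive Breslow-ties log partial likelihood for one covariate column,
# counting-process rows with left-open risk sets
oracle_logpl <- function(beta, z, entry, exit, status) {
  taus <- sort(unique(exit[status == 1]))
  ll <- 0
  for (t in taus) {
    ev <- which(status == 1 & exit == t)
    risk <- which(entry < t & t <= exit)
    ll <- ll + sum(beta * z[ev]) - length(ev) * log(sum(exp(beta * z[risk])))
  }
  ll
}

oracle_beta <- function(z, entry, exit, status, interval = c(-5, 5)) {
  stats::optimize(function(b) oracle_logpl(b, z, entry, exit, status),
                  interval = interval, maximum = TRUE, tol = 1e-10)$maximum
}

# naive pairwise C-index (independent of harrell_c's loop structure)
oracle_cindex <- function(risk, times, status) {
  comp <- 0; conc <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    usable <- (times[i] < times[j] && status[i] == 1) ||
      (times[i] == times[j] && status[i] == 1 && status[j] == 0)
    if (!usable) next
    comp <- comp + 1
    if (risk[i] > risk[j]) conc <- conc + 1
    else if (risk[i] == risk[j]) conc <- conc + 0.5
  }
  conc / comp
}

# small hand-made cohort: 3 subjects with one baseline visit each
tiny_cohort <- function() {
  data.frame(id = 1:3, time_years = c(3, 6, 12), event = c(1, 1, 0),
             age = c(40, 50, 60), sex = c("male", "female", "male"),
             weight = c(60, 70, 80), stringsAsFactors = FALSE)
}

tiny_measurements <- function() {
  data.frame(id = rep(1:3, each = 2), obstime = rep(c(0, 1), 3),
             hematocrit = c(30, 31, 28, 29, 33, 32),
             proteinuria = c(1, 1.2, 2, 2.1, 0.5, 0.4),
             gfr = c(9, 10, 8, 8.5, 11, 12))
}

# minimal hand-constructed dynamic fit for closed-form prediction checks:
# one covariate "z" with a constant effect, no theta term
toy_dyncox <- function(beta = log(sqrt(2)),
                       event_times = c(1, 2),
                       increments = c(1 / (2 + sqrt(2)), 1 / (1 + sqrt(2))),
                       grid = landmark_grid(0, 10, 0.25, 5)) {
  structure(list(
    coefficients = c(z = beta),
    var = matrix(0.01, dimnames = list("z", "z")),
    rvar = matrix(0.01, dimnames = list("z", "z")),
    baseline = structure(list(event_times = event_times,
                              increments = increments,
                              cumulative = cumsum(increments)),
                         class = "breslow_hazard"),
    basis = basis_spec(c(z = 0), theta_degree = 0),
    grid = grid, spec = covariate_specs(),
    n = 3, nevent = 2, n_subjects = 3), class = "dyncox")
}
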