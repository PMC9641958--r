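# Counting-process Cox partial likelihood with Breslow ties, delayed entry
# (risk set at t: entry < t <= exit), Newton-Raphson with step halving, and
# a cluster-robust sandwich variance from score residuals.

# cumulative-sum lookup helper: value of cumsum vector at index, 0 for idx 0
cs_at <- function(cs, idx) c(0, cs)[idx + 1L]
cs_at_rows <- function(cs, idx) rbind(0, cs)[idx + 1L, , drop = FALSE]

# Risk-set sums S0, S1, S2 at the distinct event times, given weights r and
# precomputed order/lookup structures. S2 is packed as the upper triangle.
risk_sums <- function(pre, r, x, rx = x * r, need_s2 = TRUE) {
  cs0e <- cumsum(r[pre$ord_exit]); cs0n <- cumsum(r[pre$ord_entry])
  S0 <- cs_at(cs0n, pre$n_entry_lt) - cs_at(cs0e, pre$n_exit_lt)
  cs1e <- apply(rx[pre$ord_exit, , drop = FALSE], 2, cumsum)
  cs1n <- apply(rx[pre$ord_entry, , drop = FALSE], 2, cumsum)
  S1 <- cs_at_rows(cs1n, pre$n_entry_lt) - cs_at_rows(cs1e, pre$n_exit_lt)
  S2 <- NULL
  if (need_s2) {
    rxx <- x[, pre$pi, drop = FALSE] * x[, pre$pj, drop = FALSE] * r
    cs2e <- apply(rxx[pre$ord_exit, , drop = FALSE], 2, cumsum)
    cs2n <- apply(rxx[pre$ord_entry, , drop = FALSE], 2, cumsum)
    S2 <- cs_at_rows(cs2n, pre$n_entry_lt) - cs_at_rows(cs2e, pre$n_exit_lt)
  }
  list(S0 = S0, S1 = S1, S2 = S2)
}

unpack_sym <- function(v, p, pi, pj) {
  m <- matrix(0, p, p)
  m[cbind(pi, pj)] <- v
  m[cbind(pj, pi)] <- v
  m
}

cox_precompute <- function(x, entry, exit, status) {
  p <- ncol(x)
  tau <- sort(unique(exit[status == 1]))
  ord_exit <- order(exit); ord_entry <- order(entry)
  list(p = p, tau = tau,
       ord_exit = ord_exit, ord_entry = ord_entry,
       n_exit_lt = findInterval(tau, exit[ord_exit], left.open = TRUE),
       n_entry_lt = findInterval(tau, entry[ord_entry], left.open = TRUE),
       pi = rep(seq_len(p), times = seq(p, 1)),
       pj = unlist(lapply(seq_len(p), function(i) i:p)))
}

cox_eval <- function(beta, x, entry, exit, status, pre, ev, d, sx,
                     need_s2 = TRUE) {
  lp <- drop(x %*% beta)
  ctr <- mean(lp)
  r <- exp(lp - ctr)
  rs <- risk_sums(pre, r, x, need_s2 = need_s2)
  if (any(rs$S0 <= 0)) return(list(loglik = -Inf))
  loglik <- sum(lp[ev] - ctr) - sum(d * log(rs$S0))
  m <- rs$S1 / rs$S0
  grad <- colSums(sx) - colSums(d * m)
  info <- NULL
  if (need_s2) {
    info <- unpack_sym(colSums((d / rs$S0) * rs$S2), pre$p, pre$pi, pre$pj) -
      crossprod(m * sqrt(d))
  }
  list(loglik = loglik, grad = grad, info = info, S0 = rs$S0, m = m,
       r = r, lp = lp)
}

#' Fit a Cox model on counting-process data
#'
#' Maximizes the Breslow-ties log partial likelihood for left-truncated,
#' right-censored rows `(entry, exit, status)` by Newton-Raphson with step
#' halving. A row is at risk at time `t` iff `entry < t <= exit`. Returns
#' both the model-based covariance (inverse information) and a
#' cluster-robust sandwich covariance obtained by summing score residuals
#' within clusters (subjects), appropriate when one subject contributes
#' several correlated rows, as in a stacked landmark dataset.
#'
#' @param x numeric design matrix (one row per record) with column names.
#' @param entry,exit,status counting-process fields; `entry < exit`,
#'   `status` in 0/1 with at least one event.
#' @param cluster cluster identifiers (default: one cluster per row).
#' @param init optional starting coefficients (default 0).
#' @param max_iter,grad_tol,rel_tol convergence controls: stop when the
#'   gradient norm falls below `grad_tol` (1e-8) or the relative change in
#'   log partial likelihood falls below `rel_tol` (1e-9).
#' @return An object of class `"coxfit_cp"`: coefficients, `var`
#'   (model-based), `rvar` (robust), `loglik`, `iter`, `grad_norm`,
#'   `linear_predictors`, `score_residuals` (collapsed by cluster), `n`,
#'   `nevent`, `n_clusters`.
#' @export
cox_partial_fit <- function(x, entry, exit, status, cluster = NULL,
                            init = NULL, max_iter = 100L,
                            grad_tol = 1e-8, rel_tol = 1e-9) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- nrow(x); p <- ncol(x)
  stopifnot(length(entry) == n, length(exit) == n, length(status) == n)
  if (any(entry >= exit)) stop("every row must satisfy entry < exit")
  if (!any(status == 1)) stop("no events in the data")
  # the baseline hazard absorbs an implicit intercept, so a constant column
  # is as unidentifiable as an exactly collinear pair; check both at once
  qrx <- qr(cbind(`(baseline)` = 1, x))
  if (qrx$rank < p + 1L) {
    bad <- colnames(x)[setdiff(qrx$pivot[(qrx$rank + 1):(p + 1L)], 1L) - 1L]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  if (is.null(cluster)) cluster <- seq_len(n)

  pre <- cox_precompute(x, entry, exit, status)
  ev <- which(status == 1)
  j_of_ev <- match(exit[ev], pre$tau)
  d <- tabulate(j_of_ev, length(pre$tau))
  sx <- rowsum(x[ev, , drop = FALSE], j_of_ev)

  beta <- if (is.null(init)) rep(0, p) else init
  cur <- cox_eval(beta, x, entry, exit, status, pre, ev, d, sx)
  iter <- 0L
  repeat {
    gnorm <- sqrt(sum(cur$grad^2))
    if (gnorm < grad_tol) break
    if (iter >= max_iter) {
      stop(sprintf(paste0("Newton-Raphson did not converge in %d iterations ",
                          "(gradient norm %.3g, loglik %.6g)"),
                   max_iter, gnorm, cur$loglik))
    }
    step <- solve(cur$info, cur$grad)
    lambda <- 1
    repeat {
      cand <- cox_eval(beta + lambda * step, x, entry, exit, status,
                       pre, ev, d, sx)
      if (is.finite(cand$loglik) && cand$loglik >= cur$loglik - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) stop("step halving failed; likelihood not improving")
    }
    iter <- iter + 1L
    rel_change <- abs(cand$loglik - cur$loglik) /
      (abs(cur$loglik) + .Machine$double.eps)
    beta <- beta + lambda * step
    cur <- cand
    if (rel_change < rel_tol) break
  }
  gnorm <- sqrt(sum(cur$grad^2))

  vmat <- solve(cur$info)
  dimnames(vmat) <- list(colnames(x), colnames(x))

  # score residuals, collapsed within clusters -> sandwich covariance
  dH0 <- d / cur$S0
  cumH <- cumsum(dH0)
  cumHm <- apply(dH0 * cur$m, 2, cumsum)
  ix_exit <- findInterval(exit, pre$tau)
  ix_entry <- findInterval(entry, pre$tau)
  Hi <- cs_at(cumH, ix_exit) - cs_at(cumH, ix_entry)
  Hmi <- cs_at_rows(cumHm, ix_exit) - cs_at_rows(cumHm, ix_entry)
  U <- matrix(0, n, p)
  U[ev, ] <- x[ev, , drop = FALSE] - cur$m[j_of_ev, , drop = FALSE]
  U <- U - cur$r * (x * Hi - Hmi)
  Uc <- rowsum(U, cluster)
  rvar <- vmat %*% crossprod(Uc) %*% vmat
  dimnames(rvar) <- dimnames(vmat)

  structure(list(coefficients = stats::setNames(drop(beta), colnames(x)),
                 var = vmat, rvar = rvar,
                 loglik = cur$loglik, iter = iter, grad_norm = gnorm,
                 linear_predictors = cur$lp,
                 score_residuals = Uc,
                 n = n, nevent = sum(status == 1),
                 n_clusters = length(unique(cluster))),
            class = "coxfit_cp")
}

#' @export
print.coxfit_cp <- function(x, ...) {
  cat(sprintf("Cox counting-process fit: n = %d, events = %d, loglik = %.4f\n",
              x$n, x$nevent, x$loglik))
  se <- sqrt(diag(x$var)); rse <- sqrt(diag(x$rvar))
  print(data.frame(coef = x$coefficients, `se(model)` = se,
                   `se(robust)` = rse, check.names = FALSE))
  invisible(x)
}

#' Breslow baseline cumulative hazard
#'
#' Estimates the baseline hazard increments at each distinct event time
#' `t_j` as `d_j / sum_{risk set}(exp(lp_i))` with the left-open risk-set
#' convention `entry < t <= exit`.
#'
#' @param fit a `"coxfit_cp"` (only used for validation; pass
#'   `linear_predictors` explicitly when scoring new data).
#' @param entry,exit,status counting-process fields used in the fit.
#' @param linear_predictors per-row linear predictors (defaults to the
#'   fit's).
#' @return An object of class `"breslow_hazard"` with `event_times`,
#'   `increments`, `cumulative`.
#' @export
breslow_baseline <- function(fit, entry, exit, status,
                             linear_predictors = fit$linear_predictors) {
  tau <- sort(unique(exit[status == 1]))
  if (!length(tau)) {
    return(structure(list(event_times = numeric(0), increments = numeric(0),
                          cumulative = numeric(0)),
                     class = "breslow_hazard"))
  }
  r <- exp(linear_predictors)
  ord_exit <- order(exit); ord_entry <- order(entry)
  cs0e <- cumsum(r[ord_exit]); cs0n <- cumsum(r[ord_entry])
  n_exit_lt <- findInterval(tau, exit[ord_exit], left.open = TRUE)
  n_entry_lt <- findInterval(tau, entry[ord_entry], left.open = TRUE)
  S0 <- cs_at(cs0n, n_entry_lt) - cs_at(cs0e, n_exit_lt)
  ev <- which(status == 1)
  d <- tabulate(match(exit[ev], tau), length(tau))
  inc <- d / S0
  structure(list(event_times = tau, increments = inc,
                 cumulative = cumsum(inc)),
            class = "breslow_hazard")
}

# cumulative baseline hazard at time t (step function, right-continuous)
cumhaz_at <- function(bh, t) {
  cs_at(bh$cumulative, findInterval(t, bh$event_times))
}

#' Kaplan-Meier estimate with Greenwood standard errors
#'
#' Product-limit estimator via [survival::survfit()], with 95\% confidence
#' intervals on the log cumulative-hazard (log-log) scale so that bounds
#' stay inside \[0, 1\].
#'
#' @param times positive follow-up times.
#' @param status event indicators (1 = event, 0 = censored).
#' @return An object of class `"km_curve"` with `times`, `surv`, `se`
#'   (Greenwood SE of the survival probability), `lower`, `upper`.
#' @export
kaplan_meier <- function(times, status) {
  if (!length(times)) stop("empty input")
  if (any(times <= 0)) stop("times must be positive")
  sf <- survival::survfit(survival::Surv(times, status) ~ 1,
                          conf.type = "log-log")
  structure(list(times = sf$time, surv = sf$surv,
                 se = sf$surv * sf$std.err,
                 lower = sf$lower, upper = sf$upper,
                 n = length(times), nevent = sum(status == 1)),
            class = "km_curve")
}

#' Survival probability from a Kaplan-Meier curve at given times
#'
#' @param km a `"km_curve"`.
#' @param t times at which to evaluate the step function.
#' @return Survival probabilities (right-continuous step function).
#' @export
km_at <- function(km, t) {
  c(1, km$surv)[findInterval(t, km$times) + 1L]
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d\n", x$n, x$nevent))
  invisible(x)
}
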