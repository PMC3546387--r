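# Independent oracles and randomised-instance generators shared across tests.

# Quadrature-based subject cumulative hazard: integrates
# h0(s) * exp(eta + beta_t * z(s)) directly, splitting at covariate switch
# points so the integrand is smooth on every panel. Deliberately independent
# of cumulative_hazard_tvc()'s analytic branches.
oracle_cumhaz <- function(b, eta, beta_t, traj, t) {
  stopifnot(length(t) == 1L)
  if (t == 0) return(0)
  f <- function(s) hazard_at(b, s) * exp(eta + beta_t * value_at(traj, s))
  pieces <- if (is_piecewise_constant(traj)) {
    exposure_intervals(traj, horizon = t)
  } else {
    data.frame(start = 0, stop = t)
  }
  sum(mapply(function(a, z) {
    stats::integrate(f, a, z, rel.tol = 1e-11, abs.tol = 0,
                     subdivisions = 500L)$value
  }, pieces$start, pieces$stop))
}

# relative discrepancy that treats two infinities as equal
rel_err <- function(x, y) {
  both_inf <- is.infinite(x) & is.infinite(y) & sign(x) == sign(y)
  out <- abs(x - y) / pmax(abs(y), .Machine$double.xmin)
  out[both_inf] <- 0
  out
}

random_baseline <- function() {
  fam <- sample(c("exponential", "weibull", "gompertz"), 1)
  lam <- exp(stats::runif(1, log(1e-3), log(1)))
  switch(fam,
    exponential = bh_exponential(lam),
    weibull     = bh_weibull(lam, stats::runif(1, 0.4, 2.5)),
    gompertz    = bh_gompertz(lam, stats::runif(1, -0.5, 0.5))
  )
}

random_pc_trajectory <- function() {
  type <- sample(c("single", "multi", "invariant"), 1,
                 prob = c(0.4, 0.4, 0.2))
  switch(type,
    single    = traj_single_switch(stats::runif(1, 0, 3)),
    multi     = traj_piecewise_binary(
                  cumsum(stats::runif(sample(1:5, 1), 0.1, 2))),
    invariant = traj_time_invariant(sample(0:1, 1))
  )
}

# baseline families matched on lambda for the reduction/consistency checks
matched_families <- function(lam) {
  list(exponential = bh_exponential(lam),
       weibull = bh_weibull(lam, 1),
       gompertz = bh_gompertz(lam, 0))
}

ami_baseline <- function() bh_weibull(0.001, 0.6)
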