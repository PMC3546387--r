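test_that("cumulative_hazard_tvc matches hand-computed and quadrature values", {
  b <- bh_exponential(1)
  # pre-switch hazard 1, post-switch hazard 2 on (1, 2]
  expect_equal(cumulative_hazard_tvc(b, 0, log(2), traj_single_switch(1), 2),
               3)
  # switch beyond t: pre-switch segment only
  bw <- bh_weibull(0.001, 0.6)
  expect_equal(
    cumulative_hazard_tvc(bw, 0, 0.5, traj_single_switch(100), 100),
    0.001 * 100^0.6)
  # beta_t = 0: covariate has no effect, any trajectory
  for (traj in list(traj_single_switch(2), traj_piecewise_binary(c(1, 3)),
                    traj_linear_dose(0.7), traj_time_invariant(0))) {
    expect_equal(cumulative_hazard_tvc(bw, 0.4, 0, traj, 7),
                 exp(0.4) * cumulative_hazard_at(bw, 7))
  }
  expect_equal(cumulative_hazard_tvc(bw, 0, 0.5, traj_single_switch(2), 0), 0)
})

test_that("cumulative_hazard_tvc agrees with direct quadrature of the hazard", {
  set.seed(42)
  for (rep in 1:60) {
    b <- random_baseline()
    eta <- runif(1, -1, 1)
    beta_t <- runif(1, -1.5, 1.5)
    traj <- random_pc_trajectory()
    t <- runif(1, 0.2, 8)
    expect_equal(cumulative_hazard_tvc(b, eta, beta_t, traj, t),
                 oracle_cumhaz(b, eta, beta_t, traj, t),
                 tolerance = 1e-9)
  }
})

test_that("linear-dose cumulative hazard: closed forms match quadrature", {
  set.seed(43)
  for (rep in 1:40) {
    b <- random_baseline()
    eta <- runif(1, -1, 1)
    k <- runif(1, 0.2, 2)
    beta_t <- runif(1, -1.5, 1.5)  # both signs: exercises the pgamma branch
    traj <- traj_linear_dose(k)
    t <- runif(1, 0.2, 5)
    expect_equal(cumulative_hazard_tvc(b, eta, beta_t, traj, t),
                 oracle_cumhaz(b, eta, beta_t, traj, t),
                 tolerance = 1e-8)
  }
})

test_that("closed-form piecewise inversion picks the correct branch", {
  b <- bh_exponential(1)
  tr <- traj_single_switch(1)
  expect_equal(invert_closed_form(b, 0, log(2), tr, 0.5), 0.5)  # pre-switch
  expect_equal(invert_closed_form(b, 0, log(2), tr, 2), 1.5)    # post-switch
  # a target exactly at the breakpoint hazard belongs to the later interval
  expect_equal(invert_closed_form(b, 0, log(2), tr, 1), 1)
  # exponential linear dose: solve 0.5 (e^T - 1) = 1 analytically
  expect_equal(invert_closed_form(bh_exponential(0.5), 0, 1,
                                  traj_linear_dose(1), 1), log(3))
  expect_equal(invert_numeric(bh_exponential(0.5), 0, 1,
                              traj_linear_dose(1), 1), log(3),
               tolerance = 1e-10)
  expect_equal(invert_numeric(b, 0, 0.3, traj_single_switch(1), 0), 0)
})

test_that("closed-form and numeric inversion agree over randomized instances", {
  set.seed(7)
  for (rep in 1:120) {
    b <- random_baseline()
    eta <- runif(1, -1, 1)
    beta_t <- runif(1, -1.5, 1.5)
    traj <- if (rep %% 4 == 0) traj_linear_dose(runif(1, 0.2, 2))
            else random_pc_trajectory()
    if (!is_piecewise_constant(traj) && b$family == "weibull" &&
        beta_t * traj$k > 0) beta_t <- -beta_t  # closed form needs bk < 0
    target <- -log(runif(1))
    cf <- invert_closed_form(b, eta, beta_t, traj, target)
    nm <- invert_numeric(b, eta, beta_t, traj, target)
    expect_lt(rel_err(cf, nm), 1e-8)
  }
})

test_that("inversion round-trips the cumulative hazard on a log grid", {
  set.seed(11)
  for (rep in 1:25) {
    b <- random_baseline()
    eta <- runif(1, -1, 1)
    beta_t <- runif(1, -1.5, 1.5)
    traj <- random_pc_trajectory()
    for (h in 10^seq(-3, 0.8, length.out = 8)) {
      t <- invert_closed_form(b, eta, beta_t, traj, h)
      if (is.finite(t)) {
        expect_equal(cumulative_hazard_tvc(b, eta, beta_t, traj, t), h,
                     tolerance = 1e-8)
      } else {
        expect_gte(h, cumulative_hazard_tvc(b, eta, beta_t, traj, Inf))
      }
    }
  }
})

test_that("unsupported closed-form combinations fail loudly", {
  bw <- bh_weibull(0.5, 1.7)
  expect_error(
    invert_closed_form(bw, 0, 0.5, traj_linear_dose(1), 1),
    "No closed-form inverse")
  # but the numeric inverse handles it
  t <- invert_numeric(bw, 0, 0.5, traj_linear_dose(1), 1)
  expect_equal(cumulative_hazard_tvc(bw, 0, 0.5, traj_linear_dose(1), t), 1,
               tolerance = 1e-8)
})

test_that("weibull transformed-scale dose formula inverts z(t) = k t^nu", {
  set.seed(13)
  for (rep in 1:20) {
    b <- bh_weibull(exp(runif(1, log(0.01), 0)), runif(1, 0.4, 2.5))
    eta <- runif(1, -1, 1)
    k <- runif(1, 0.2, 2)
    beta_t <- runif(1, -1.5, 1.5)
    target <- -log(runif(1))
    t <- invert_weibull_transformed_dose(b, eta, beta_t, k, target)
    if (!is.finite(t)) next
    # oracle: quadrature of h0(s) exp(eta + beta_t k s^nu)
    H <- stats::integrate(function(s) {
      b$lambda * b$nu * s^(b$nu - 1) * exp(eta + beta_t * k * s^b$nu)
    }, 0, t, rel.tol = 1e-11, abs.tol = 0)$value
    expect_equal(H, target, tolerance = 1e-7)
    # with nu = 1 it coincides with the literal linear-dose inverse
  }
  b1 <- bh_weibull(0.3, 1)
  expect_equal(invert_weibull_transformed_dose(b1, 0.2, -0.4, 0.8, 0.5),
               invert_closed_form(b1, 0.2, -0.4, traj_linear_dose(0.8), 0.5))
})

test_that("saturating hazards yield the never-event sentinel consistently", {
  b <- bh_gompertz(0.5, -0.8)  # total baseline hazard 0.625
  tr <- traj_single_switch(0.4)
  tot <- cumulative_hazard_tvc(b, 0.1, -0.5, tr, Inf)
  expect_identical(invert_closed_form(b, 0.1, -0.5, tr, tot * 1.01), Inf)
  expect_identical(invert_numeric(b, 0.1, -0.5, tr, tot * 1.01), Inf)
  t <- invert_closed_form(b, 0.1, -0.5, tr, tot * 0.99)
  expect_true(is.finite(t))
  # protective linear dose under an exponential baseline also saturates
  be <- bh_exponential(0.5)
  tot2 <- cumulative_hazard_tvc(be, 0, -2, traj_linear_dose(1), Inf)
  expect_identical(invert_closed_form(be, 0, -2, traj_linear_dose(1),
                                      tot2 + 0.1), Inf)
})

test_that("draw_event_times is seeded, monotone in u, and reduction-exact", {
  b <- ami_baseline()
  subj <- make_subjects(eta = rnorm(10), beta_t = log(0.5),
                        trajectory = traj_single_switch(500))
  d1 <- draw_event_times(subj, b, seed = 99)
  d2 <- draw_event_times(subj, b, seed = 99)
  expect_identical(d1$time, d2$time)

  # event time strictly decreasing in u for one subject
  u <- sort(runif(20, 0.01, 0.99))
  t_u <- invert_closed_form(b, 0.3, log(0.5), traj_piecewise_binary(c(200, 900)),
                            -log(u))
  expect_true(all(diff(t_u) < 0))

  # beta_t = 0: a switch trajectory is indistinguishable from never-treated
  s1 <- make_subjects(rnorm(10), 0, traj_single_switch(300))
  s2 <- make_subjects(s1$eta, 0, traj_time_invariant(0))
  expect_identical(draw_event_times(s1, b, seed = 5)$time,
                   draw_event_times(s2, b, seed = 5)$time)
})

test_that("numeric method of draw_event_times matches the closed form", {
  b <- bh_gompertz(0.2, 0.1)
  subj <- make_subjects(eta = rnorm(5), beta_t = 0.7,
                        trajectory = traj_piecewise_binary(c(1, 3)))
  dc <- draw_event_times(subj, b, seed = 3)
  dn <- draw_event_times(subj, b, seed = 3, method = "numeric")
  expect_equal(dn$time, dc$time, tolerance = 1e-8)
})
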