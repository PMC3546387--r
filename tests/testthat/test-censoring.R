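test_that("fixed-percentile censoring observes the requested event fraction", {
  out <- censor_fixed_percentile(as.numeric(1:100), p = 0.32)
  expect_equal(sum(out$status), 32)
  expect_equal(attr(out, "censor_time"),
               as.numeric(quantile(1:100, 0.32, type = 7)))
  expect_true(all(out$time[out$status == 0] == attr(out, "censor_time")))

  # never-event subjects are always censored at the cutoff
  times <- c(1, 2, 3, Inf, Inf)
  out2 <- censor_fixed_percentile(times, p = 0.32)
  expect_equal(out2$status[4:5], c(0L, 0L))
  expect_true(all(is.finite(out2$time)))

  # degenerate: every event precedes the cutoff
  out3 <- censor_fixed_percentile(c(1, 1, 1, 5), p = 0.9)
  expect_true(all(out3$status[1:3] == 1L))
  expect_error(censor_fixed_percentile(c(Inf, Inf)), "infinite")
})

test_that("uniform censoring is seeded and spans [lower, q75]", {
  times <- exp(rnorm(500, 5, 1))
  o1 <- censor_uniform(times, seed = 4)
  o2 <- censor_uniform(times, seed = 4)
  expect_identical(o1$time, o2$time)
  cens <- attr(o1, "censor_time")
  expect_true(all(cens >= 1 & cens <= quantile(times, 0.75)))
  frac <- mean(o1$status)
  expect_gt(frac, 0)
  expect_lt(frac, 1)
  # censoring dominates when events are far out
  o3 <- censor_uniform(rep(1e9, 50), seed = 1)
  expect_true(all(o3$status == 0L))
})

test_that("counting-process expansion follows the conventions", {
  subj <- make_subjects(0.2, log(0.5), traj_single_switch(5))
  # event after the switch: two records, event on the last
  rec <- expand_counting_process(subj, tibble::tibble(time = 8, status = 1L))
  expect_equal(rec$start, c(0, 5))
  expect_equal(rec$stop, c(5, 8))
  expect_equal(rec$status, c(0L, 1L))
  expect_equal(rec$z, c(0, 1))
  expect_equal(rec$eta, c(0.2, 0.2))

  # death before treatment: a single untreated record
  rec2 <- expand_counting_process(subj, tibble::tibble(time = 3, status = 1L))
  expect_equal(nrow(rec2), 1L)
  expect_equal(rec2$z, 0)
  expect_equal(rec2$status, 1L)

  # censored mid-exposure under an alternating trajectory
  subj3 <- make_subjects(0, 0.3, traj_piecewise_binary(c(2, 4)))
  rec3 <- expand_counting_process(subj3, tibble::tibble(time = 3, status = 0L))
  expect_equal(rec3$start, c(0, 2))
  expect_equal(rec3$stop, c(2, 3))
  expect_equal(rec3$status, c(0L, 0L))
  expect_equal(rec3$z, c(0, 1))

  # observation exactly at a switch: the zero-length record is dropped
  rec4 <- expand_counting_process(subj, tibble::tibble(time = 5, status = 1L))
  expect_equal(nrow(rec4), 1L)
  expect_equal(rec4$stop, 5)
})

test_that("records tile follow-up exactly for random cohorts", {
  set.seed(31)
  n <- 40
  trajs <- replicate(n, random_pc_trajectory(), simplify = FALSE)
  subj <- make_subjects(rnorm(n), log(0.7), trajs)
  d <- draw_event_times(subj, ami_baseline())
  out <- censor_fixed_percentile(d$time, 0.5)
  rec <- expand_counting_process(subj, out)
  by_subj <- split(rec, rec$subject_id)
  expect_equal(length(by_subj), n)
  for (i in seq_len(n)) {
    ri <- by_subj[[as.character(i)]]
    expect_equal(ri$start[1], 0)
    expect_equal(ri$stop[nrow(ri)], out$time[i])
    if (nrow(ri) > 1) expect_equal(ri$start[-1], ri$stop[-nrow(ri)])
    expect_true(all(ri$stop > ri$start))
    expect_equal(sum(ri$stop - ri$start), out$time[i])
    expect_equal(sum(ri$status), out$status[i])
    if (out$status[i] == 1L) expect_equal(ri$status[nrow(ri)], 1L)
  }
})

test_that("linear-dose export requires and uses a discretisation grid", {
  subj <- make_subjects(0, 0.01, traj_linear_dose(2))
  outc <- tibble::tibble(time = 3.5, status = 1L)
  expect_error(expand_counting_process(subj, outc), "dose_grid")
  rec <- expand_counting_process(subj, outc, dose_grid = 1:10)
  expect_equal(rec$start, c(0, 1, 2, 3))
  expect_equal(rec$stop, c(1, 2, 3, 3.5))
  expect_equal(rec$z, 2 * c(0, 1, 2, 3))  # z evaluated at interval starts
})

test_that("ever-treated coding shows the immortal-time bias direction", {
  # a mid-follow-up treatment with no true effect, wrongly coded as a
  # baseline covariate, must bias the hazard ratio downward
  set.seed(17)
  n <- 4000
  b <- ami_baseline()
  t0 <- runif(n, 1, 13581)
  subj <- make_subjects(rnorm(n, 0.5, 0.9), beta_t = 0,
                        trajectory = lapply(t0, traj_single_switch))
  d <- draw_event_times(subj, b)
  out <- censor_fixed_percentile(d$time, 0.32)
  ever_treated <- as.integer(t0 <= out$time)  # treated during follow-up
  fit_wrong <- survival::coxph(
    survival::Surv(out$time, out$status) ~ ever_treated, timefix = FALSE)
  expect_lt(unname(coef(fit_wrong)), 0)  # truth is log HR = 0
  # the counting-process fit does not share the bias
  rec <- expand_counting_process(subj, out)
  fit_right <- survival::coxph(
    survival::Surv(start, stop, status) ~ z, data = rec, timefix = FALSE)
  expect_lt(abs(unname(coef(fit_right))), abs(unname(coef(fit_wrong))))
})

test_that("counting-process CSV round-trips at full precision", {
  subj <- make_subjects(c(0.1, -0.2), log(0.8), traj_single_switch(1 / 3))
  d <- draw_event_times(subj, bh_exponential(0.5), seed = 2)
  out <- censor_fixed_percentile(d$time, 0.5)
  rec <- expand_counting_process(subj, out)
  path <- withr::local_tempfile(fileext = ".csv")
  write_counting_process(rec, path)
  back <- utils::read.csv(path)
  expect_equal(names(back), names(rec))
  expect_identical(back$stop, rec$stop)
  expect_identical(back$eta, rec$eta)
})
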