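#' Treatment-assignment scenarios for the power study
#'
#' Builds the per-subject covariate trajectories of the five binary
#' treatment scenarios, over a follow-up window of `window` days:
#'
#' * `"S1"` — 50% of subjects (exact split) receive a time-invariant
#'   treatment fixed at baseline (`traj_single_switch(0)`); the rest are
#'   never treated.
#' * `"S2"` — every subject is assigned a treatment start time drawn
#'   uniformly on `[1, window]`, then stays treated (subjects can die
#'   before their treatment starts).
#' * `"S3"` — as S2, with start times uniform on `[1, short_window]`.
#' * `"S4"` — 50% of subjects alternate treatment with three switches at
#'   `window/3`, `2*window/3` and `window`; the rest are never treated.
#' * `"S5"` — as S4 with only the first two switches.
#'
#' @param scenario One of `"S1"` ... `"S5"`.
#' @param n Number of subjects.
#' @param window Follow-up horizon in days (default 13581).
#' @param short_window Horizon for S3 start times (default 6000 days).
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @return A list of `n` [trajectory] objects.
#' @examples
#' assign_treatment("S4", n = 4, seed = 1)
#' @export
assign_treatment <- function(scenario, n, window = 13581,
                             short_window = 6000, seed = NULL) {
  if (!scenario %in% paste0("S", 1:5)) {
    stop("Unknown scenario `", scenario, "`; expected S1..S5.",
         call. = FALSE)
  }
  stopifnot(n >= 1, window > 0, short_window > 0)
  if (!is.null(seed)) set.seed(seed)
  half_split <- function(make_treated) {
    treated <- sample.int(n, floor(n / 2))
    out <- rep(list(traj_time_invariant(0)), n)
    out[treated] <- rep(list(make_treated), length(treated))
    out
  }
  switch(scenario,
    S1 = half_split(traj_single_switch(0)),
    S2 = lapply(stats::runif(n, 1, window), traj_single_switch),
    S3 = lapply(stats::runif(n, 1, short_window), traj_single_switch),
    S4 = half_split(traj_piecewise_binary(c(window / 3, 2 * window / 3,
                                            window))),
    S5 = half_split(traj_piecewise_binary(c(window / 3, 2 * window / 3)))
  )
}

#' One Monte-Carlo replicate of the power study
#'
#' Samples a cohort (with replacement) from the covariate population,
#' assigns treatment trajectories under the given scenario, generates event
#' times with `beta_t = log(hr)`, applies the censoring mechanism, expands
#' the data to counting-process records, and fits
#' `coxph(Surv(start, stop, status) ~ z + <fixed covariates>)`. Returns the
#' two-sided Wald p-value of the treatment coefficient together with the
#' replicate diagnostics.
#'
#' @param population Covariate population from [synth_population()].
#' @param baseline A [baseline_hazard()].
#' @param scenario Treatment scenario, `"S1"` ... `"S5"`.
#' @param hr True treatment hazard ratio (`beta_t = log(hr)`).
#' @param n_subjects Cohort size sampled per replicate.
#' @param censoring `"fixed_percentile"` or `"uniform"`.
#' @param p_event Event fraction for fixed-percentile censoring.
#' @param censor_lower Lower bound (days) for uniform censoring.
#' @param window,short_window Scenario windows in days.
#' @param seed Integer seed for the replicate (all of its randomness).
#' @return A one-row tibble: `p_value`, `estimate` (fitted `beta_t`), `se`,
#'   `died_pre_treatment` (fraction of treatment-assigned subjects with an
#'   observed event before their treatment start), `converged`.
#' @export
run_replicate <- function(population, baseline, scenario, hr,
                          n_subjects = 2500,
                          censoring = c("fixed_percentile", "uniform"),
                          p_event = 0.32, censor_lower = 1,
                          window = 13581, short_window = 6000,
                          seed = NULL) {
  censoring <- match.arg(censoring)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(population), n_subjects, replace = TRUE)
  cohort <- population[idx, , drop = FALSE]
  cohort$id <- seq_len(n_subjects)
  trajs <- assign_treatment(scenario, n_subjects, window, short_window)
  subjects <- make_subjects(cohort$eta, log(hr), trajs)
  drawn <- draw_event_times(subjects, baseline)
  outcomes <- switch(censoring,
    fixed_percentile = censor_fixed_percentile(drawn$time, p = p_event),
    uniform = censor_uniform(drawn$time, lower = censor_lower)
  )
  t0 <- vapply(trajs, function(tr) {
    if (inherits(tr, "traj_single_switch")) tr$t0
    else if (inherits(tr, "traj_piecewise_binary")) tr$switch_times[1]
    else Inf  # never treated: no treatment start to die before
  }, numeric(1))
  assigned <- is.finite(t0)
  died_pre <- if (any(assigned)) {
    mean(outcomes$status[assigned] == 1L &
           outcomes$time[assigned] < t0[assigned])
  } else NA_real_
  records <- expand_counting_process(subjects, outcomes)
  covars <- population_covariate_names(population)
  dat <- dplyr::left_join(records, cohort[, c("id", covars)],
                          by = c(subject_id = "id"))
  fml <- stats::reformulate(c("z", covars),
                            response = "survival::Surv(start, stop, status)")
  # timefix = FALSE: simulated times are continuous doubles, so the default
  # tie-rounding can collapse short intervals drawn near a switch time
  fit <- tryCatch(
    suppressWarnings(survival::coxph(fml, data = dat, timefix = FALSE)),
    error = function(e) NULL
  )
  if (is.null(fit) || is.na(stats::coef(fit)[["z"]])) {
    return(tibble::tibble(p_value = NA_real_, estimate = NA_real_,
                          se = NA_real_, died_pre_treatment = died_pre,
                          converged = FALSE))
  }
  est <- stats::coef(fit)[["z"]]
  se <- sqrt(diag(stats::vcov(fit)))[["z"]]
  tibble::tibble(
    p_value = 2 * stats::pnorm(-abs(est / se)),
    estimate = est, se = se,
    died_pre_treatment = died_pre,
    converged = TRUE
  )
}

#' Monte-Carlo power over a hazard-ratio grid
#'
#' Runs the full power experiment: for each combination of scenario,
#' censoring mechanism and true hazard ratio it repeats [run_replicate()]
#' and reports the proportion of replicates in which the treatment
#' coefficient was significant at `alpha` (two-sided Wald), with the
#' binomial Monte-Carlo standard error \eqn{\sqrt{p(1-p)/R}}. For the
#' uniform-start scenarios it also reports the average fraction of subjects
#' observed to die before their treatment start. The covariate population
#' is generated once and re-sampled with replacement each replicate; every
#' replicate draws its own seed derived from `seed`, so the grid is fully
#' reproducible and independent of evaluation order.
#'
#' @inheritParams run_replicate
#' @param scenarios Character vector of scenarios to run.
#' @param censoring Character vector of censoring mechanisms to run.
#' @param hr_grid Hazard ratios (default 0.5 to 0.95 by 0.05).
#' @param n_replicates Replicates per grid cell (default 1000).
#' @param n_pop Size of the generated covariate population (default
#'   115856).
#' @param population Optional pre-built population (overrides `n_pop`).
#' @param alpha Significance level of the Wald test.
#' @param seed Master seed.
#' @return A `power_grid` tibble: `scenario`, `censoring`, `hr`, `n`,
#'   `replicates`, `power`, `mc_se`, `pct_died_pre_treatment`, `n_failed`.
#' @examples
#' \donttest{
#' pg <- estimate_power(n_subjects = 200, n_replicates = 20,
#'                      hr_grid = 0.7, scenarios = "S1",
#'                      censoring = "fixed_percentile", seed = 1)
#' }
#' @export
estimate_power <- function(n_subjects = 2500, n_replicates = 1000,
                           hr_grid = seq(0.5, 0.95, by = 0.05),
                           baseline = bh_weibull(0.001, 0.6),
                           scenarios = paste0("S", 1:5),
                           censoring = c("fixed_percentile", "uniform"),
                           p_event = 0.32, censor_lower = 1,
                           window = 13581, short_window = 6000,
                           n_pop = 115856, population = NULL,
                           alpha = 0.05, seed = 1) {
  stopifnot(n_replicates >= 1, all(hr_grid > 0 & hr_grid <= 1))
  censoring <- match.arg(censoring, c("fixed_percentile", "uniform"),
                         several.ok = TRUE)
  if (is.null(population)) {
    population <- synth_population(n_pop, seed = derive_seed(seed, 0L))
  }
  grid <- tidyr::expand_grid(scenario = scenarios, censoring = censoring,
                             hr = hr_grid)
  counter <- 0L
  cells <- purrr::pmap(grid, function(scenario, censoring, hr) {
    reps <- purrr::map(seq_len(n_replicates), function(r) {
      counter <<- counter + 1L
      run_replicate(population, baseline, scenario, hr,
                    n_subjects = n_subjects, censoring = censoring,
                    p_event = p_event, censor_lower = censor_lower,
                    window = window, short_window = short_window,
                    seed = derive_seed(seed, counter))
    })
    reps <- dplyr::bind_rows(reps)
    ok <- reps$converged & !is.na(reps$p_value)
    R <- sum(ok)
    pw <- mean(reps$p_value[ok] <= alpha)
    tibble::tibble(
      n = n_subjects, replicates = R,
      power = pw, mc_se = sqrt(pw * (1 - pw) / R),
      pct_died_pre_treatment = 100 * mean(reps$died_pre_treatment[ok]),
      n_failed = n_replicates - R
    )
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(cells))
  class(out) <- c("power_grid", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "seed") <- seed
  attr(out, "baseline") <- baseline
  out
}

# deterministic small-integer seed stream derived from the master seed
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + as.double(counter) * 104729) %%
               2147483629) + 1L
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for power-grid results
#'
#' `tidy()` returns the grid as a plain tibble (one row per scenario x
#' censoring x hazard ratio cell); `glance()` returns a one-row summary of
#' the experiment.
#'
#' @param x A `power_grid` from [estimate_power()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.power_grid <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "power_grid")
  tibble::as_tibble(out)
}

#' @rdname tidy.power_grid
#' @export
glance.power_grid <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    scenarios = length(unique(x$scenario)),
    hr_min = min(x$hr), hr_max = max(x$hr),
    replicates = max(x$replicates + x$n_failed),
    alpha = attr(x, "alpha"),
    seed = attr(x, "seed")
  )
}

#' Plot power curves
#'
#' Power against true hazard ratio, one colour per treatment scenario,
#' faceted by censoring mechanism, with +/- 2 Monte-Carlo-standard-error
#' bars.
#'
#' @param object A `power_grid` from [estimate_power()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_grid <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$hr, y = .data$power,
                                    colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(0, .data$power - 2 * .data$mc_se),
      ymax = pmin(1, .data$power + 2 * .data$mc_se))) +
    ggplot2::facet_wrap(ggplot2::vars(.data$censoring)) +
    ggplot2::labs(x = "True hazard ratio", y = "Estimated power",
                  colour = "Scenario") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_bw()
}

#' @rdname autoplot.power_grid
#' @param x A `power_grid`.
#' @export
plot.power_grid <- function(x, ...) print(autoplot(x, ...))
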