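#' Censoring mechanisms
#'
#' Two censoring schemes for simulated event times.
#'
#' `censor_fixed_percentile()` censors administratively at the empirical
#' `p`-th percentile `c` of the finite event times (linear-interpolation
#' quantile, `type = 7`), so that a fraction of about `p` of the subjects
#' is observed to fail: subjects with \eqn{T \le c} keep their event time
#' with `status = 1`, all others are censored at `c`. The default
#' `p = 0.32` mirrors a cohort in which 32% of subjects die before the
#' administrative end of follow-up.
#'
#' `censor_uniform()` draws a per-subject random censoring time uniformly
#' on `[lower, q75]`, where `q75` is the 75th percentile of the finite
#' event times and `lower` defaults to 1 day; the observed time is the
#' minimum of the event and censoring times.
#'
#' Infinite event times (never-event subjects) are allowed and always come
#' out censored.
#'
#' @param times Numeric vector of event times (`Inf` allowed).
#' @param p Fraction of subjects observed to fail, in (0, 1).
#' @param lower Lower bound of the uniform censoring distribution (days).
#' @param seed Optional integer seed for the random censoring draws.
#' @return A tibble with columns `time` (observed follow-up) and `status`
#'   (1 = event, 0 = censored). The censoring time(s) are attached as
#'   attribute `"censor_time"`.
#' @examples
#' censor_fixed_percentile(c(1, 5, 10, 50, Inf), p = 0.32)
#' @export
censor_fixed_percentile <- function(times, p = 0.32) {
  if (length(times) == 0L) stop("`times` must be nonempty.", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1) {
    stop("`p` must be a single fraction in (0, 1).", call. = FALSE)
  }
  fin <- is.finite(times)
  if (!any(fin)) {
    stop("All event times are infinite; no percentile exists.",
         call. = FALSE)
  }
  cens <- as.numeric(stats::quantile(times[fin], probs = p, type = 7))
  out <- tibble::tibble(
    time = pmin(times, cens),
    status = as.integer(times <= cens)
  )
  attr(out, "censor_time") <- cens
  out
}

#' @rdname censor_fixed_percentile
#' @export
censor_uniform <- function(times, lower = 1, seed = NULL) {
  if (length(times) == 0L) stop("`times` must be nonempty.", call. = FALSE)
  fin <- is.finite(times)
  if (!any(fin)) {
    stop("All event times are infinite; no percentile exists.",
         call. = FALSE)
  }
  q75 <- as.numeric(stats::quantile(times[fin], probs = 0.75, type = 7))
  if (q75 <= lower) {
    stop("75th percentile of event times is at or below `lower`; the ",
         "uniform censoring window is empty.", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  cens <- stats::runif(length(times), min = lower, max = q75)
  out <- tibble::tibble(
    time = pmin(times, cens),
    status = as.integer(times <= cens)
  )
  attr(out, "censor_time") <- cens
  out
}

#' Expand subjects into counting-process (start-stop) records
#'
#' Splits each subject's observed follow-up `[0, time]` into intervals on
#' which the time-varying covariate is constant, the representation needed
#' to fit a Cox model with a time-varying covariate via
#' `survival::coxph(Surv(start, stop, status) ~ ...)`. Intervals are
#' `(start, stop]` in fitting semantics; each subject's records are
#' contiguous from 0 to the observed time, `status = 1` appears only on the
#' final record of a subject whose outcome was an event, and zero-length
#' intervals (an observation time falling exactly on a switch) are dropped.
#'
#' Piecewise-constant trajectories expand exactly at their switch times. A
#' linear-dose trajectory is continuous, so it is discretised on the
#' user-supplied `dose_grid`, carrying `z` evaluated at each interval's
#' start — a documented approximation.
#'
#' @param subjects Cohort tibble from [make_subjects()].
#' @param outcomes Tibble with columns `time`, `status` as returned by the
#'   censoring functions, one row per subject.
#' @param dose_grid Increasing vector of cut times (required only when the
#'   cohort contains linear-dose trajectories).
#' @return A tibble with columns `subject_id`, `start`, `stop`, `status`,
#'   `z`, `eta`.
#' @examples
#' subj <- make_subjects(0, log(0.5), traj_single_switch(5))
#' expand_counting_process(subj, tibble::tibble(time = 8, status = 1L))
#' @export
expand_counting_process <- function(subjects, outcomes, dose_grid = NULL) {
  stopifnot(is.data.frame(subjects), is.data.frame(outcomes),
            nrow(subjects) == nrow(outcomes),
            all(c("time", "status") %in% names(outcomes)))
  if (any(!is.finite(outcomes$time)) || any(outcomes$time <= 0)) {
    stop("Observed times must be finite and > 0.", call. = FALSE)
  }
  n <- nrow(subjects)
  trajs <- subjects$trajectory
  obs <- outcomes$time
  cuts <- vector("list", n)
  zval <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- trajs[[i]]
    if (is_piecewise_constant(tr)) {
      seg <- traj_segments(tr)
      keep <- seg$start < obs[i]
      cuts[[i]] <- seg$start[keep]
      zval[[i]] <- seg$z[keep]
    } else {
      if (is.null(dose_grid)) {
        stop("A linear-dose trajectory requires an explicit `dose_grid` ",
             "for counting-process export.", call. = FALSE)
      }
      gs <- unique(c(0, dose_grid[dose_grid > 0 & dose_grid < obs[i]]))
      cuts[[i]] <- gs
      zval[[i]] <- value_at(tr, gs)
    }
  }
  len <- lengths(cuts)
  start <- unlist(cuts, use.names = FALSE)
  stop_ <- unlist(lapply(seq_len(n), function(i) {
    c(cuts[[i]][-1], obs[i])
  }), use.names = FALSE)
  last <- cumsum(len)
  status <- integer(length(start))
  status[last] <- as.integer(outcomes$status)
  tibble::tibble(
    subject_id = rep(subjects$id, len),
    start = start,
    stop = stop_,
    status = status,
    z = unlist(zval, use.names = FALSE),
    eta = rep(subjects$eta, len)
  )
}

#' Write counting-process records to CSV
#'
#' One row per record, header `subject_id,start,stop,status,z,eta` (plus
#' any extra columns present), times written with 17 significant digits so
#' the file round-trips to the same doubles.
#'
#' @param records Tibble from [expand_counting_process()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_counting_process <- function(records, path) {
  out <- as.data.frame(records)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
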