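#' Time-varying covariate trajectories
#'
#' A trajectory is an evaluable path \eqn{z(t)} for the single time-varying
#' covariate of the simulation model. Four types are supported:
#'
#' * `traj_single_switch(t0)` — a binary exposure that changes from 0 to 1
#'   at time `t0` and stays at 1 (e.g. organ transplant). `t0 = 0` encodes
#'   treatment fixed at baseline.
#' * `traj_piecewise_binary(switch_times)` — a binary exposure alternating
#'   0/1 at each switch time, starting untreated at time 0 (e.g. episodic
#'   medication use). Any number of switches is allowed.
#' * `traj_linear_dose(k)` — cumulative exposure at constant dose rate,
#'   \eqn{z(t) = k t} (e.g. daily drug dose, occupational radiation).
#' * `traj_time_invariant(z)` — a constant covariate, the degenerate case
#'   that reduces the machinery to the classical time-invariant generator.
#'
#' Switch instants belong to the post-switch state (left-closed convention):
#' for a single switch, \eqn{z(t) = 0} for \eqn{t < t_0} and \eqn{z(t) = 1}
#' for \eqn{t \ge t_0}. This keeps the subject-level cumulative hazard
#' continuous and its piecewise inverse well defined.
#'
#' @param t0 Switch time, \eqn{\ge 0}.
#' @param switch_times Strictly increasing vector of positive switch times.
#' @param k Dose accumulation rate per unit time, \eqn{k > 0}.
#' @param z Constant covariate value.
#' @return An object of class `trajectory` (subclass per type).
#' @examples
#' tr <- traj_piecewise_binary(c(2, 4, 6))
#' value_at(tr, c(1, 3, 5, 7))
#' exposure_intervals(tr, horizon = 10)
#' @name trajectory
NULL

new_trajectory <- function(subclass, fields) {
  structure(fields, class = c(subclass, "trajectory"))
}

#' @rdname trajectory
#' @export
traj_single_switch <- function(t0) {
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0) || t0 < 0) {
    stop("`t0` must be a single finite time >= 0.", call. = FALSE)
  }
  new_trajectory("traj_single_switch", list(t0 = as.numeric(t0)))
}

#' @rdname trajectory
#' @export
traj_piecewise_binary <- function(switch_times) {
  st <- as.numeric(switch_times)
  if (length(st) < 1L || any(!is.finite(st)) || any(st <= 0) ||
      is.unsorted(st, strictly = TRUE)) {
    stop("`switch_times` must be a strictly increasing vector of times > 0.",
         call. = FALSE)
  }
  new_trajectory("traj_piecewise_binary", list(switch_times = st))
}

#' @rdname trajectory
#' @export
traj_linear_dose <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("`k` must be a single finite dose rate > 0.", call. = FALSE)
  }
  new_trajectory("traj_linear_dose", list(k = as.numeric(k)))
}

#' @rdname trajectory
#' @export
traj_time_invariant <- function(z) {
  if (!is.numeric(z) || length(z) != 1L || !is.finite(z)) {
    stop("`z` must be a single finite covariate value.", call. = FALSE)
  }
  new_trajectory("traj_time_invariant", list(z = as.numeric(z)))
}

#' @export
print.trajectory <- function(x, ...) {
  desc <- switch(class(x)[1],
    traj_single_switch   = sprintf("single switch 0 -> 1 at t0 = %g", x$t0),
    traj_piecewise_binary = sprintf("piecewise binary, switches at %s",
                                    paste(x$switch_times, collapse = ", ")),
    traj_linear_dose     = sprintf("linear dose z(t) = %g * t", x$k),
    traj_time_invariant  = sprintf("time-invariant z = %g", x$z)
  )
  cat(sprintf("<trajectory: %s>\n", desc))
  invisible(x)
}

is_trajectory <- function(x) inherits(x, "trajectory")

#' Is a trajectory piecewise constant?
#'
#' Piecewise-constant trajectories (single switch, piecewise binary,
#' time-invariant) admit a finite exposure-interval decomposition and
#' therefore exact piecewise inversion of the cumulative hazard; the linear
#' dose path is continuous and does not.
#'
#' @param traj A trajectory.
#' @return `TRUE` or `FALSE`.
#' @export
is_piecewise_constant <- function(traj) {
  if (!is_trajectory(traj)) stop("Expected a `trajectory`.", call. = FALSE)
  !inherits(traj, "traj_linear_dose")
}

#' Evaluate a trajectory
#'
#' Returns \eqn{z(t)}, vectorised over `t`, with the left-closed convention
#' at switch instants (the switch time itself takes the post-switch value).
#'
#' @param traj A trajectory (see [trajectory]).
#' @param t Vector of nonnegative times.
#' @return Numeric vector of covariate values.
#' @export
value_at <- function(traj, t) {
  UseMethod("value_at")
}

#' @export
value_at.default <- function(traj, t) {
  stop("Expected a `trajectory` object.", call. = FALSE)
}

#' @export
value_at.traj_single_switch <- function(traj, t) {
  check_times(t)
  as.numeric(t >= traj$t0)
}

#' @export
value_at.traj_piecewise_binary <- function(traj, t) {
  check_times(t)
  # number of switches passed (left-closed) determines parity
  n_passed <- findInterval(t, traj$switch_times)
  as.numeric(n_passed %% 2L == 1L)
}

#' @export
value_at.traj_linear_dose <- function(traj, t) {
  check_times(t)
  traj$k * t
}

#' @export
value_at.traj_time_invariant <- function(traj, t) {
  check_times(t)
  rep_len(traj$z, length(t))
}

check_times <- function(t) {
  if (any(t < 0, na.rm = TRUE)) stop("`t` must be >= 0.", call. = FALSE)
  invisible(t)
}

# Canonical segment representation of a piecewise-constant trajectory:
# list(start = s_0 = 0 < s_1 < ..., z = z_0, z_1, ...) with z_j holding on
# [s_j, s_{j+1}) and the last segment extending to Inf. Consecutive z differ.
traj_segments <- function(traj) {
  UseMethod("traj_segments")
}

#' @export
traj_segments.traj_single_switch <- function(traj) {
  if (traj$t0 == 0) list(start = 0, z = 1)
  else list(start = c(0, traj$t0), z = c(0, 1))
}

#' @export
traj_segments.traj_piecewise_binary <- function(traj) {
  k <- length(traj$switch_times)
  list(start = c(0, traj$switch_times),
       z = as.numeric(seq_len(k + 1L) %% 2L == 0L))
}

#' @export
traj_segments.traj_time_invariant <- function(traj) {
  list(start = 0, z = traj$z)
}

#' @export
traj_segments.traj_linear_dose <- function(traj) {
  stop("A linear-dose trajectory is continuous and has no finite ",
       "exposure-interval decomposition.", call. = FALSE)
}

#' Exposure-interval decomposition
#'
#' Decomposes a piecewise-constant trajectory into ordered half-open
#' intervals `[start, stop)` that partition `[0, horizon)`, with the
#' covariate constant on each interval and consecutive values differing.
#' This is the representation the inversion engine and the counting-process
#' exporter both consume.
#'
#' @param traj A piecewise-constant trajectory; calling this on a
#'   linear-dose trajectory is an error.
#' @param horizon Positive end of follow-up.
#' @return A tibble with columns `start`, `stop`, `z`.
#' @examples
#' exposure_intervals(traj_single_switch(5), horizon = 3)
#' @export
exposure_intervals <- function(traj, horizon) {
  if (!is.numeric(horizon) || length(horizon) != 1L || !is.finite(horizon) ||
      horizon <= 0) {
    stop("`horizon` must be a single finite time > 0.", call. = FALSE)
  }
  seg <- traj_segments(traj)
  keep <- seg$start < horizon
  start <- seg$start[keep]
  z <- seg$z[keep]
  stop_ <- c(start[-1], horizon)
  tibble::tibble(start = start, stop = stop_, z = z)
}
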