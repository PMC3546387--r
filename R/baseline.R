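#' Baseline hazard families for proportional-hazards simulation
#'
#' Constructs a baseline hazard from one of the three parametric families
#' that are closed under proportional hazards: exponential, Weibull, and
#' Gompertz. The Weibull uses the hazard parameterisation
#' \eqn{h_0(t) = \lambda \nu t^{\nu-1}} (so \eqn{H_0(t) = \lambda t^\nu}),
#' and the Gompertz uses \eqn{h_0(t) = \lambda e^{\alpha t}}.
#'
#' A Weibull with `nu = 1`, or a Gompertz with `alpha = 0`, is the same
#' hazard function as an exponential with the same `lambda`. For a Gompertz
#' with `alpha < 0` the total hazard saturates at \eqn{-\lambda/\alpha}, so a
#' fraction of subjects never experience the event (a cured fraction).
#'
#' @param family One of `"exponential"`, `"weibull"`, `"gompertz"`.
#' @param lambda Scale (rate) parameter \eqn{\lambda > 0}, per unit time.
#' @param nu Weibull shape \eqn{\nu > 0}; required iff `family = "weibull"`.
#' @param alpha Gompertz shape \eqn{\alpha} (any real, per unit time);
#'   required iff `family = "gompertz"`.
#'
#' @return An object of class `baseline_hazard`.
#' @examples
#' bh_weibull(lambda = 0.001, nu = 0.6)
#' baseline_hazard("gompertz", lambda = 0.2, alpha = -0.05)
#' @export
baseline_hazard <- function(family = c("exponential", "weibull", "gompertz"),
                            lambda, nu = NULL, alpha = NULL) {
  family <- match.arg(family)
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0) {
    stop("`lambda` must be a single finite number with lambda > 0.",
         call. = FALSE)
  }
  if (family == "weibull") {
    if (is.null(nu) || !is.numeric(nu) || length(nu) != 1L ||
        !is.finite(nu) || nu <= 0) {
      stop("Weibull baseline requires a single finite shape with nu > 0.",
           call. = FALSE)
    }
  } else if (!is.null(nu)) {
    stop("`nu` is only meaningful for the Weibull family.", call. = FALSE)
  }
  if (family == "gompertz") {
    if (is.null(alpha) || !is.numeric(alpha) || length(alpha) != 1L ||
        !is.finite(alpha)) {
      stop("Gompertz baseline requires a single finite shape `alpha`.",
           call. = FALSE)
    }
  } else if (!is.null(alpha)) {
    stop("`alpha` is only meaningful for the Gompertz family.", call. = FALSE)
  }
  structure(
    list(family = family, lambda = as.numeric(lambda),
         nu = if (family == "weibull") as.numeric(nu) else NULL,
         alpha = if (family == "gompertz") as.numeric(alpha) else NULL),
    class = "baseline_hazard"
  )
}

#' @rdname baseline_hazard
#' @export
bh_exponential <- function(lambda) baseline_hazard("exponential", lambda)

#' @rdname baseline_hazard
#' @export
bh_weibull <- function(lambda, nu) baseline_hazard("weibull", lambda, nu = nu)

#' @rdname baseline_hazard
#' @export
bh_gompertz <- function(lambda, alpha) {
  baseline_hazard("gompertz", lambda, alpha = alpha)
}

#' @export
print.baseline_hazard <- function(x, ...) {
  pars <- switch(x$family,
    exponential = sprintf("lambda = %g", x$lambda),
    weibull     = sprintf("lambda = %g, nu = %g", x$lambda, x$nu),
    gompertz    = sprintf("lambda = %g, alpha = %g", x$lambda, x$alpha)
  )
  cat(sprintf("<baseline_hazard: %s (%s)>\n", x$family, pars))
  invisible(x)
}

is_baseline_hazard <- function(x) inherits(x, "baseline_hazard")

check_baseline <- function(b) {
  if (!is_baseline_hazard(b)) {
    stop("Expected a `baseline_hazard` object; see `baseline_hazard()`.",
         call. = FALSE)
  }
  invisible(b)
}

#' Baseline hazard, cumulative hazard, and its inverse
#'
#' `hazard_at()` evaluates \eqn{h_0(t)}; `cumulative_hazard_at()` evaluates
#' \eqn{H_0(t) = \int_0^t h_0(s)\,ds}; `inverse_cumulative_hazard()`
#' evaluates \eqn{H_0^{-1}(h)}. All three are vectorised over the time /
#' hazard argument. `Inf` is an accepted time (giving the total hazard,
#' which is finite only for a Gompertz with negative shape), and
#' `inverse_cumulative_hazard()` returns `Inf` when `h` meets or exceeds a
#' saturating total hazard — the "never-event" sentinel.
#'
#' For a Weibull with `nu < 1` the hazard diverges as \eqn{t \to 0};
#' `hazard_at()` returns `Inf` at `t = 0` in that case.
#'
#' @param b A [baseline_hazard()].
#' @param t Vector of nonnegative times.
#' @param h Vector of nonnegative cumulated hazards.
#' @return A numeric vector.
#' @examples
#' b <- bh_weibull(0.001, 0.6)
#' cumulative_hazard_at(b, c(1, 100))
#' inverse_cumulative_hazard(b, 0.001)
#' @export
hazard_at <- function(b, t) {
  check_baseline(b)
  if (any(t < 0, na.rm = TRUE)) stop("`t` must be >= 0.", call. = FALSE)
  switch(b$family,
    exponential = rep_len(b$lambda, length(t)),
    weibull     = b$lambda * b$nu * t^(b$nu - 1),
    gompertz    = b$lambda * exp(b$alpha * t)
  )
}

#' @rdname hazard_at
#' @export
cumulative_hazard_at <- function(b, t) {
  check_baseline(b)
  if (any(t < 0, na.rm = TRUE)) stop("`t` must be >= 0.", call. = FALSE)
  cumhaz0(b, t)
}

# internal, no validation: H0(t), elementwise, Inf-safe
cumhaz0 <- function(b, t) {
  switch(b$family,
    exponential = b$lambda * t,
    weibull     = b$lambda * t^b$nu,
    gompertz    = if (b$alpha == 0) b$lambda * t
                  else (b$lambda / b$alpha) * expm1(b$alpha * t)
  )
}

#' @rdname hazard_at
#' @export
inverse_cumulative_hazard <- function(b, h) {
  check_baseline(b)
  if (any(h < 0, na.rm = TRUE)) stop("`h` must be >= 0.", call. = FALSE)
  inv_cumhaz0(b, h)
}

# internal, no validation: H0^{-1}(h), returns Inf past a saturating total
inv_cumhaz0 <- function(b, h) {
  switch(b$family,
    exponential = h / b$lambda,
    weibull     = (h / b$lambda)^(1 / b$nu),
    gompertz    = {
      if (b$alpha == 0) {
        h / b$lambda
      } else {
        out <- rep_len(Inf, length(h))
        ok <- if (b$alpha < 0) h < -b$lambda / b$alpha else !is.na(h)
        out[ok] <- log1p(b$alpha * h[ok] / b$lambda) / b$alpha
        out[is.na(h)] <- NA_real_
        out
      }
    }
  )
}

# total achievable baseline cumulative hazard (Inf unless Gompertz alpha < 0)
total_cumhaz0 <- function(b) {
  if (b$family == "gompertz" && b$alpha < 0) -b$lambda / b$alpha else Inf
}

#' Simulate event times under time-invariant covariates
#'
#' Applies the inverse cumulative hazard transform
#' \eqn{T = H_0^{-1}\{-\log(u) / e^{\eta}\}} with \eqn{u \sim U(0,1)} and a
#' fixed linear predictor \eqn{\eta = \beta'x}. This is the classical
#' time-invariant generator; the time-varying analogue is
#' [draw_event_times()].
#'
#' @param b A [baseline_hazard()].
#' @param eta Fixed linear predictor(s) \eqn{\beta'x} (recycled against `u`).
#' @param u Uniform(0,1) draws, strictly inside the open interval.
#' @return Event times; `Inf` where the total hazard saturates below
#'   \eqn{-\log(u) e^{-\eta}}.
#' @examples
#' simulate_invariant_time(bh_exponential(1), eta = 0, u = exp(-2)) # = 2
#' @export
simulate_invariant_time <- function(b, eta, u) {
  check_baseline(b)
  if (any(u <= 0 | u >= 1, na.rm = TRUE)) {
    stop("`u` must lie strictly inside (0, 1).", call. = FALSE)
  }
  inv_cumhaz0(b, -log(u) / exp(eta))
}
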